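#' Combination policy for PSF propagation
#'
#' The published descriptions of pathway signal flow state qualitatively that
#' signal passes through activating/inhibiting interactions and through
#' complex and linker nodes, without printing the update equations.  The
#' concrete rules live in one policy object so variants can be swapped:
#'
#' * `convergent`: how a non-complex node combines contributions from its
#'   incoming edges (`"mean"` default, or `"sum"`).
#' * `complex`: how a complex node combines them (`"min"` default - the
#'   complex is bottlenecked by its scarcest member - or `"prod"`).
#' * inhibition always contributes `weight / value(source)`, activation
#'   `weight * value(source)`; the node's own expression enters
#'   multiplicatively.
#'
#' The defaults make all-neutral input (FC = 1 everywhere) a fixed point of
#' the propagation.
#'
#' @param convergent `"mean"` or `"sum"`.
#' @param complex `"min"` or `"prod"`.
#' @return A `psf_policy` list.
#' @export
psf_policy <- function(convergent = c("mean", "sum"),
                       complex = c("min", "prod")) {
  structure(list(convergent = match.arg(convergent),
                 complex = match.arg(complex)),
            class = "psf_policy")
}

#' Node-level expression from fold changes
#'
#' A node's expression value is the geometric mean of the fold changes of its
#' genes; 1 for nodes without genes (linkers, sinks, pure-gate complexes).
#' Pathway genes absent from the fold-change input are imputed at the neutral
#' value 1 with a warning.
#'
#' @param node A node list (id, genes, ...) from a `tmm_pathway`.
#' @param fc_column Named positive numeric vector of per-gene fold changes.
#' @param warn_missing Warn about genes imputed at 1.
#' @return Positive scalar.
#' @export
node_fc <- function(node, fc_column, warn_missing = TRUE) {
  g <- node$genes
  if (length(g) == 0) return(1)
  present <- g %in% names(fc_column)
  if (!all(present) && warn_missing) {
    warning("genes missing from expression input, imputed at FC = 1: ",
            paste(g[!present], collapse = ", "), call. = FALSE)
  }
  v <- fc_column[g[present]]
  if (length(v) == 0) return(1)
  if (any(v <= 0)) stop("fold changes must be strictly positive", call. = FALSE)
  exp(mean(log(c(v, rep(1, sum(!present))))))
}

#' Propagate fold changes through a pathway (PSF)
#'
#' Single pass in topological order.  Input nodes take their own expression
#' value.  For every other node, each incoming edge contributes
#' `weight * v(source)` (activation) or `weight / v(source)` (inhibition);
#' contributions are combined by the policy (arithmetic mean for
#' intermediate/linker/sink nodes, minimum for complexes, by default) and
#' multiplied by the node's own expression value.  The sink value is the
#' pathway's PSF score; values at branch-tagged nodes are the branch
#' activities.  Deterministic: identical inputs give identical outputs.
#'
#' @param graph A validated `tmm_pathway`.
#' @param fc_column Named positive numeric vector of per-gene fold changes.
#' @param policy A [psf_policy()].
#' @param warn_missing Warn once about pathway genes absent from `fc_column`.
#' @return A `psf_profile` list: `node_values` (named vector),
#'   `branch_activities`, `pathway_activity` (the sink value).
#' @export
compute_psf <- function(graph, fc_column, policy = psf_policy(),
                        warn_missing = TRUE) {
  topo <- attr(graph, "topo")
  if (is.null(topo)) {
    graph <- validate_pathway(graph)
    topo <- attr(graph, "topo")
  }
  if (any(fc_column <= 0)) {
    stop("fold changes must be strictly positive", call. = FALSE)
  }
  e <- graph$edges
  v <- numeric(length(topo))
  names(v) <- topo
  for (id in topo) {
    node <- graph$nodes[[id]]
    own <- node_fc(node, fc_column, warn_missing = warn_missing)
    inc <- which(e$target == id)
    if (length(inc) == 0) {
      v[id] <- own
      next
    }
    contrib <- ifelse(e$sign[inc] == "activation",
                      e$weight[inc] * v[e$source[inc]],
                      e$weight[inc] / v[e$source[inc]])
    m <- if (node$kind == "complex") {
      switch(policy$complex, min = min(contrib), prod = prod(contrib))
    } else {
      switch(policy$convergent, mean = mean(contrib), sum = sum(contrib))
    }
    v[id] <- own * m
  }
  br <- branch_terminals(graph)
  structure(list(node_values = v,
                 branch_activities = stats::setNames(v[br], names(br)),
                 pathway_activity = unname(v[graph$sink])),
            class = "psf_profile")
}

#' PSF activities for every sample of a fold-change matrix
#'
#' Column-wise [compute_psf()].  Missing pathway genes are warned about once
#' for the whole matrix, then imputed silently per sample.
#'
#' @param graph A validated `tmm_pathway`.
#' @param fc Positive fold-change matrix (genes x samples).
#' @param policy A [psf_policy()].
#' @return Data frame with one row per sample: `sample`, `pathway`,
#'   `activity`, `log10_activity`, then one column per branch.
#' @export
psf_matrix <- function(graph, fc, policy = psf_policy()) {
  if (ncol(fc) == 0) stop("empty sample set", call. = FALSE)
  missing <- setdiff(pathway_genes(graph), rownames(fc))
  if (length(missing)) {
    warning(sprintf("pathway '%s': %d gene(s) missing from expression input, imputed at FC = 1: %s",
                    graph$name, length(missing), paste(missing, collapse = ", ")),
            call. = FALSE)
  }
  graph <- validate_pathway(graph)
  profs <- lapply(seq_len(ncol(fc)), function(j) {
    compute_psf(graph, fc[, j], policy = policy, warn_missing = FALSE)
  })
  act <- vapply(profs, `[[`, numeric(1), "pathway_activity")
  br <- t(vapply(profs, `[[`, numeric(length(branch_terminals(graph))),
                 "branch_activities"))
  out <- data.frame(sample = colnames(fc), pathway = graph$name,
                    activity = act, log10_activity = log10(act),
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(br)) {
    colnames(br) <- names(branch_terminals(graph))
    out <- cbind(out, as.data.frame(br, check.names = FALSE))
  }
  rownames(out) <- NULL
  out
}
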