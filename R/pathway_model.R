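NODE_KINDS <- c("input", "intermediate", "complex", "linker", "sink")
EDGE_SIGNS <- c("activation", "inhibition")

#' Load a TMM pathway graph from its JSON definition
#'
#' Reads a pathway definition (nodes, signed edges, sink, branch annotations)
#' and validates it into a `tmm_pathway` object.  The expected JSON layout is
#'
#' ```
#' {
#'   "name": "ALT",
#'   "sink": "telomere_elongation",
#'   "nodes": [ {"id": "...", "label": "...", "kind": "input",
#'               "genes": ["RAD51", ...], "branch": "strand invasion"}, ... ],
#'   "edges": [ {"source": "...", "target": "...",
#'               "sign": "activation", "weight": 1}, ... ]
#' }
#' ```
#'
#' `kind` is one of `input`, `intermediate`, `complex`, `linker`, `sink`;
#' `genes` may be empty for linker/sink (and for complexes that only gate
#' their members); `branch` is optional and tags the terminal node of a named
#' pathway sub-branch.  Gene symbols are upper-cased on load.
#'
#' @param path Path to a pathway JSON file.
#' @return A validated `tmm_pathway` object.
#' @seealso [tmm_pathway()] for the packaged TEL/ALT definitions,
#'   [read_sif()] for the tabular import, [write_pathway()].
#' @export
load_pathway <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(raw$nodes) || is.null(raw$edges) || is.null(raw$sink)) {
    stop("pathway file must declare 'nodes', 'edges' and 'sink'", call. = FALSE)
  }
  nodes <- lapply(raw$nodes, function(n) {
    list(
      id = as.character(n$id),
      label = if (is.null(n$label)) as.character(n$id) else as.character(n$label),
      kind = as.character(n$kind),
      genes = toupper(unlist(n$genes, use.names = FALSE) %||% character(0)),
      branch = if (is.null(n$branch)) NA_character_ else as.character(n$branch)
    )
  })
  edges <- do.call(rbind, lapply(raw$edges, function(e) {
    data.frame(
      source = as.character(e$source),
      target = as.character(e$target),
      sign = as.character(e$sign %||% "activation"),
      weight = as.numeric(e$weight %||% 1),
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(edges)) {
    edges <- data.frame(source = character(0), target = character(0),
                        sign = character(0), weight = numeric(0))
  }
  g <- new_pathway(name = as.character(raw$name %||% "pathway"),
                  nodes = nodes, edges = edges,
                  sink = as.character(raw$sink))
  validate_pathway(g)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

new_pathway <- function(name, nodes, edges, sink) {
  names(nodes) <- vapply(nodes, `[[`, character(1), "id")
  structure(list(name = name, nodes = nodes, edges = edges, sink = sink),
            class = "tmm_pathway")
}

#' Validate a pathway graph
#'
#' Checks every structural invariant: unique node ids, declared edge
#' endpoints, no self-loops, valid kinds/signs, positive weights, exactly one
#' sink with no outgoing edges, inputs with no incoming edges, complexes with
#' at least two incoming edges, linkers with empty gene sets, acyclicity, and
#' that every node lies on some input-to-sink path.  Each failure is raised
#' with a distinct message naming the offending nodes or edges.
#'
#' @param graph A `tmm_pathway` object.
#' @return The graph, invisibly annotated with its topological order.
#' @export
validate_pathway <- function(graph) {
  stopifnot(inherits(graph, "tmm_pathway"))
  ids <- vapply(graph$nodes, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate node id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  kinds <- vapply(graph$nodes, `[[`, character(1), "kind")
  bad_kind <- ids[!kinds %in% NODE_KINDS]
  if (length(bad_kind)) {
    stop("unknown node kind for: ", paste(bad_kind, collapse = ", "), call. = FALSE)
  }
  e <- graph$edges
  dangling <- setdiff(unique(c(e$source, e$target)), ids)
  if (length(dangling)) {
    stop("dangling edge endpoint: ", paste(dangling, collapse = ", "), call. = FALSE)
  }
  if (any(e$source == e$target)) {
    stop("self-loop on node: ",
         paste(unique(e$source[e$source == e$target]), collapse = ", "), call. = FALSE)
  }
  if (any(!e$sign %in% EDGE_SIGNS)) {
    stop("edge sign must be 'activation' or 'inhibition'", call. = FALSE)
  }
  if (any(!is.finite(e$weight)) || any(e$weight <= 0)) {
    stop("edge weights must be positive", call. = FALSE)
  }
  sinks <- unname(ids[kinds == "sink"])
  if (length(sinks) != 1L || !identical(graph$sink, sinks)) {
    stop("graph must declare exactly one sink node (kind 'sink') matching the ",
         "'sink' field; found: ", paste(sinks, collapse = ", "), call. = FALSE)
  }
  indeg <- table(factor(e$target, levels = ids))
  outdeg <- table(factor(e$source, levels = ids))
  if (any(indeg[ids[kinds == "input"]] > 0)) {
    stop("input node with incoming edges: ",
         paste(ids[kinds == "input"][indeg[ids[kinds == "input"]] > 0],
               collapse = ", "), call. = FALSE)
  }
  if (outdeg[graph$sink] > 0) {
    stop("sink node has outgoing edges: ", graph$sink, call. = FALSE)
  }
  cplx <- ids[kinds == "complex"]
  if (any(indeg[cplx] < 2)) {
    stop("complex node with fewer than 2 incoming edges: ",
         paste(cplx[indeg[cplx] < 2], collapse = ", "), call. = FALSE)
  }
  linker_genes <- vapply(graph$nodes[kinds == "linker"],
                         function(n) length(n$genes), integer(1))
  if (any(linker_genes > 0)) {
    stop("linker node with a non-empty gene set: ",
         paste(ids[kinds == "linker"][linker_genes > 0], collapse = ", "),
         call. = FALSE)
  }
  topo <- topological_order(graph) # raises on cycles
  # every node must lie on some input -> sink path: reachable from an input
  # and able to reach the sink
  fwd <- reachable_from(ids[kinds == "input"], e$source, e$target, ids)
  bwd <- reachable_from(graph$sink, e$target, e$source, ids)
  stranded <- ids[!(fwd & bwd)]
  if (length(stranded)) {
    stop("node not on any input-to-sink path: ",
         paste(stranded, collapse = ", "), call. = FALSE)
  }
  br <- branch_terminals(graph)
  attr(graph, "topo") <- topo
  invisible(graph)
}

# breadth-first reachability over the given (from, to) edge orientation
reachable_from <- function(seeds, from, to, ids) {
  seen <- ids %in% seeds
  names(seen) <- ids
  frontier <- seeds
  while (length(frontier)) {
    nxt <- unique(to[from %in% frontier])
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  seen
}

#' Topological ordering of a pathway graph
#'
#' Kahn's algorithm; node ids are returned so that every edge's source
#' precedes its target.  Ties are broken by declaration order, making the
#' ordering (and hence downstream propagation) deterministic.
#'
#' @param graph A `tmm_pathway`.
#' @return Character vector of node ids.
#' @export
topological_order <- function(graph) {
  ids <- names(graph$nodes)
  e <- graph$edges
  indeg <- as.integer(table(factor(e$target, levels = ids)))
  names(indeg) <- ids
  order_out <- character(0)
  avail <- ids[indeg == 0L]
  while (length(avail)) {
    v <- avail[1L]
    avail <- avail[-1L]
    order_out <- c(order_out, v)
    kids <- e$target[e$source == v]
    for (k in kids) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) avail <- c(avail, k)
    }
  }
  if (length(order_out) < length(ids)) {
    stop("cycle detected involving nodes: ",
         paste(setdiff(ids, order_out), collapse = ", "), call. = FALSE)
  }
  order_out
}

#' Branch terminals of a pathway graph
#'
#' Maps each branch tag (e.g. "TERT", "Holliday junction processing") to the
#' single node that carries it.  The PSF value at that node is the branch's
#' activity, extracted after whole-pathway propagation.
#'
#' @param graph A `tmm_pathway`.
#' @return Named character vector: branch tag -> node id (empty if untagged).
#' @export
branch_terminals <- function(graph) {
  tags <- vapply(graph$nodes, `[[`, character(1), "branch")
  tags <- tags[!is.na(tags)]
  if (anyDuplicated(tags)) {
    stop("branch tag on more than one node: ",
         paste(unique(tags[duplicated(tags)]), collapse = ", "), call. = FALSE)
  }
  out <- names(tags)
  names(out) <- unname(tags)
  out
}

#' Union of gene symbols in a pathway
#'
#' @param graph A `tmm_pathway`.
#' @return Sorted character vector of distinct HGNC symbols.
#' @export
pathway_genes <- function(graph) {
  sort(unique(unlist(lapply(graph$nodes, `[[`, "genes"), use.names = FALSE)))
}

#' Packaged TMM pathway definitions
#'
#' Loads the bundled reconstruction of the curated TEL (telomerase-dependent,
#' 26 genes) or ALT (alternative lengthening of telomeres, 37 genes) pathway.
#' The originally curated gene-to-node assignment is hosted externally and
#' not redistributed; the packaged JSON files reconstruct the published
#' branch structure (TEL: TERT activation, TERC expression, dyskerin,
#' telomerase assembly, telomere recruitment, synthesis with DNA polymerase
#' alpha/CST; ALT: DNA damage response, APB formation, telomere recruitment
#' to APB, strand invasion, templated synthesis by polymerase delta, Holliday
#' junction processing) with the published gene totals, and are plain
#' editable files so the curated lists can be dropped in.
#'
#' @param which `"TEL"` or `"ALT"`.
#' @return A validated `tmm_pathway`.
#' @export
tmm_pathway <- function(which = c("TEL", "ALT")) {
  which <- match.arg(which)
  f <- system.file("extdata", "pathways",
                   paste0(tolower(which), "_reconstructed.json"),
                   package = "tmmflow", mustWork = TRUE)
  load_pathway(f)
}

#' Write a pathway graph back to JSON
#'
#' Round-trips with [load_pathway()]: the re-parsed graph has the same node
#' ids, kinds, gene sets, edges and signs.
#'
#' @param graph A `tmm_pathway`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pathway <- function(graph, path) {
  nodes <- lapply(unname(graph$nodes), function(n) {
    out <- list(id = n$id, label = n$label, kind = n$kind,
                genes = as.list(n$genes))
    if (!is.na(n$branch)) out$branch <- n$branch
    out
  })
  edges <- lapply(seq_len(nrow(graph$edges)), function(i) {
    as.list(graph$edges[i, c("source", "target", "sign", "weight")])
  })
  jsonlite::write_json(
    list(name = graph$name, sink = graph$sink, nodes = nodes, edges = edges),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Import a pathway skeleton from a SIF-like TSV
#'
#' Reads a three-column, headerless table (`source`, `sign`, `target`; sign
#' `activation`/`inhibition`) and builds a pathway in which every node with
#' no outgoing edge except the single terminal is rejected unless exactly one
#' terminal exists, which becomes the sink.  Node kinds are inferred: no
#' incoming edges -> `input`, the terminal -> `sink`, otherwise
#' `intermediate`; each non-sink node is assigned its own id as gene symbol
#' (edit the JSON written by [write_pathway()] to refine kinds, gene sets and
#' branches).  JSON is the authoritative format; this import exists for
#' interoperability.
#'
#' @param path Path to the TSV.
#' @return A validated `tmm_pathway`.
#' @export
read_sif <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop("SIF import needs columns: source, sign, target", call. = FALSE)
  names(tab)[1:3] <- c("source", "sign", "target")
  ids <- unique(c(tab$source, tab$target))
  terminals <- setdiff(ids, tab$source)
  if (length(terminals) != 1L) {
    stop("SIF import requires exactly one terminal (sink) node; found: ",
         paste(terminals, collapse = ", "), call. = FALSE)
  }
  inputs <- setdiff(ids, tab$target)
  nodes <- lapply(ids, function(id) {
    kind <- if (id == terminals) "sink" else if (id %in% inputs) "input" else "intermediate"
    list(id = id, label = id, kind = kind,
         genes = if (kind == "sink") character(0) else toupper(id),
         branch = NA_character_)
  })
  edges <- data.frame(source = tab$source, target = tab$target,
                      sign = tab$sign, weight = 1, stringsAsFactors = FALSE)
  validate_pathway(new_pathway(basename(path), nodes, edges, terminals))
}

#' @export
print.tmm_pathway <- function(x, ...) {
  cat(sprintf("tmm_pathway '%s': %d nodes, %d edges, %d genes, sink '%s'\n",
              x$name, length(x$nodes), nrow(x$edges),
              length(pathway_genes(x)), x$sink))
  br <- branch_terminals(x)
  if (length(br)) {
    cat("branches:", paste(names(br), collapse = "; "), "\n")
  }
  invisible(x)
}
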