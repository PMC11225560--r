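# Shared fixtures and independent oracles.

# Build a tmm_pathway in code without touching JSON.
make_graph <- function(name, nodes, edges, sink) {
  g <- structure(list(
    name = name,
    nodes = stats::setNames(nodes, vapply(nodes, `[[`, character(1), "id")),
    edges = edges, sink = sink), class = "tmm_pathway")
  validate_pathway(g)
}

node <- function(id, kind, genes = character(0), branch = NA_character_) {
  list(id = id, label = id, kind = kind, genes = genes, branch = branch)
}

edges_df <- function(...) {
  e <- matrix(c(...), ncol = 3, byrow = TRUE)
  data.frame(source = e[, 1], target = e[, 3], sign = e[, 2], weight = 1,
             stringsAsFactors = FALSE)
}

# A -> B -> C chain with one gene per non-sink node.
chain_graph <- function(fc_genes = c(A = "GA", B = "GB")) {
  make_graph("chain",
             list(node("A", "input", fc_genes[["A"]]),
                  node("B", "intermediate", fc_genes[["B"]]),
                  node("C", "sink")),
             edges_df("A", "activation", "B",
                      "B", "activation", "C"),
             "C")
}

# Random DAG with mixed kinds and signs, <= max_nodes nodes, plus a gene pool.
# Construction guarantees validity: layered parents, one terminal sink.
random_dag <- function(seed, max_nodes = 30, p_inhibit = 0.3,
                       unit_weights = FALSE,
                       gene_pool = paste0("G", 1:40)) {
  set.seed(seed)
  k <- sample(4:max_nodes, 1)
  ids <- paste0("n", seq_len(k))
  edges <- NULL
  n_parents <- integer(k)
  for (i in 2:k) {
    np <- sample(1:min(3, i - 1), 1)
    parents <- sample(ids[seq_len(i - 1)], np)
    n_parents[i] <- np
    sign <- sample(c("activation", "inhibition"), np, replace = TRUE,
                   prob = c(1 - p_inhibit, p_inhibit))
    w <- if (unit_weights) rep(1, np) else round(stats::runif(np, 0.5, 2), 3)
    edges <- rbind(edges, data.frame(source = parents, target = ids[i],
                                     sign = sign, weight = w,
                                     stringsAsFactors = FALSE))
  }
  # terminal sink collects every node without outgoing edges
  loose <- setdiff(ids, unique(edges$source))
  edges <- rbind(edges, data.frame(source = loose, target = "sinknode",
                                   sign = "activation", weight = 1,
                                   stringsAsFactors = FALSE))
  nodes <- lapply(seq_len(k), function(i) {
    id <- ids[i]
    if (n_parents[i] == 0) {
      node(id, "input", sample(gene_pool, sample(1:3, 1)))
    } else if (n_parents[i] >= 2 && stats::runif(1) < 0.4) {
      node(id, "complex",
           if (stats::runif(1) < 0.5) character(0) else sample(gene_pool, 1))
    } else if (stats::runif(1) < 0.3) {
      node(id, "linker")
    } else {
      node(id, "intermediate", sample(gene_pool, sample(1:2, 1)))
    }
  })
  nodes <- c(nodes, list(node("sinknode", "sink")))
  g <- make_graph(paste0("rand", seed), nodes, edges, "sinknode")
  fc <- stats::setNames(exp(stats::rnorm(length(gene_pool), sd = 0.5)),
                        gene_pool)
  list(graph = g, fc = fc)
}

# Independent recursive memoized PSF evaluator (the oracle for compute_psf).
psf_oracle <- function(graph, fc, policy = list(convergent = "mean",
                                                complex = "min")) {
  memo <- new.env()
  own_value <- function(n) {
    if (length(n$genes) == 0) return(1)
    v <- ifelse(n$genes %in% names(fc), fc[n$genes], 1)
    exp(mean(log(v)))
  }
  value <- function(id) {
    if (exists(id, envir = memo, inherits = FALSE)) return(memo[[id]])
    n <- graph$nodes[[id]]
    inc <- graph$edges[graph$edges$target == id, , drop = FALSE]
    v <- if (nrow(inc) == 0) {
      own_value(n)
    } else {
      contrib <- vapply(seq_len(nrow(inc)), function(i) {
        pv <- value(inc$source[i])
        if (inc$sign[i] == "activation") inc$weight[i] * pv
        else inc$weight[i] / pv
      }, numeric(1))
      agg <- if (n$kind == "complex") {
        if (policy$complex == "min") min(contrib) else prod(contrib)
      } else {
        if (policy$convergent == "mean") mean(contrib) else sum(contrib)
      }
      own_value(n) * agg
    }
    memo[[id]] <- v
    v
  }
  value(graph$sink)
}

# Piecewise-linear three-regime curve used by the threshold-recovery tests:
# slopes 0.2 / 1 / 5 with breaks at quantiles 0.3 and 0.7.
pwl3 <- function(q) {
  ifelse(q <= 0.3, 0.2 * q,
         ifelse(q <= 0.7, 0.06 + 1 * (q - 0.3), 0.46 + 5 * (q - 0.7)))
}
pwl3_thresholds <- c(t_low = 0.2 * 0.3, t_high = 0.06 + 0.4)

# NB counts with the generator's parameterization (var = mu + disp * mu^2).
rnb <- function(n, mu, disp) stats::rnbinom(n, mu = mu, size = 1 / disp)
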