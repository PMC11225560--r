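test_that("packaged pathway definitions carry the curated gene totals and branches", {
  alt <- tmm_pathway("ALT")
  tel <- tmm_pathway("TEL")
  expect_length(pathway_genes(alt), 37)
  expect_length(pathway_genes(tel), 26)
  expect_setequal(
    names(branch_terminals(alt)),
    c("DNA damage response", "APB formation", "telomere recruitment to APB",
      "strand invasion", "templated synthesis", "Holliday junction processing"))
  expect_true(all(c("TERT", "TERC", "dyskerin") %in%
                    names(branch_terminals(tel))))
})

test_that("every input of the packaged graphs reaches the sink", {
  for (g in list(tmm_pathway("ALT"), tmm_pathway("TEL"))) {
    kinds <- vapply(g$nodes, `[[`, character(1), "kind")
    inputs <- names(g$nodes)[kinds == "input"]
    # independent breadth-first scan over the raw edge table
    for (start in inputs) {
      frontier <- start
      seen <- character(0)
      while (length(frontier)) {
        seen <- union(seen, frontier)
        frontier <- setdiff(g$edges$target[g$edges$source %in% frontier], seen)
      }
      expect_true(g$sink %in% seen)
    }
  }
})

test_that("minimal two-node pathway loads and round-trips", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"name":"mini","sink":"S",
    "nodes":[{"id":"A","kind":"input","genes":["TERT"]},
             {"id":"S","kind":"sink","genes":[]}],
    "edges":[{"source":"A","target":"S","sign":"activation"}]}', f)
  g <- load_pathway(f)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$sink, "S")
  expect_equal(g$nodes$A$genes, "TERT")

  f2 <- withr::local_tempfile(fileext = ".json")
  write_pathway(g, f2)
  g2 <- load_pathway(f2)
  expect_equal(names(g2$nodes), names(g$nodes))
  expect_equal(g2$edges, g$edges)
  expect_equal(lapply(g2$nodes, `[[`, "kind"), lapply(g$nodes, `[[`, "kind"))
})

test_that("packaged graphs survive a write/load round trip unchanged", {
  for (which in c("ALT", "TEL")) {
    g <- tmm_pathway(which)
    f <- withr::local_tempfile(fileext = ".json")
    write_pathway(g, f)
    g2 <- load_pathway(f)
    expect_equal(names(g2$nodes), names(g$nodes))
    expect_equal(g2$edges, g$edges)
    expect_equal(lapply(g2$nodes, `[[`, "genes"),
                 lapply(g$nodes, `[[`, "genes"))
    expect_equal(branch_terminals(g2), branch_terminals(g))
  }
})

test_that("validation failures are distinct and named", {
  base_nodes <- list(node("A", "input", "GA"), node("S", "sink"))
  base_edges <- edges_df("A", "activation", "S")

  # dangling endpoint
  expect_error(
    make_graph("g", base_nodes, edges_df("A", "activation", "B"), "S"),
    "dangling")
  # duplicate id
  expect_error(
    make_graph("g", c(base_nodes, list(node("A", "input", "GX"))),
               base_edges, "S"),
    "duplicate node id")
  # cycle, naming involved nodes
  expect_error(
    make_graph("g",
               list(node("A", "input", "GA"), node("B", "intermediate", "GB"),
                    node("C", "intermediate", "GC"), node("S", "sink")),
               edges_df("A", "activation", "B",
                        "B", "activation", "C",
                        "C", "activation", "B",
                        "C", "activation", "S"),
               "S"),
    "cycle.*B")
  # zero or multiple sinks
  expect_error(
    make_graph("g", list(node("A", "input", "GA"),
                         node("S", "sink"), node("S2", "sink")),
               edges_df("A", "activation", "S", "A", "activation", "S2"),
               "S"),
    "exactly one sink")
  # complex with a single incoming edge
  expect_error(
    make_graph("g",
               list(node("A", "input", "GA"), node("B", "complex"),
                    node("S", "sink")),
               edges_df("A", "activation", "B", "B", "activation", "S"),
               "S"),
    "complex")
  # linker with genes
  expect_error(
    make_graph("g",
               list(node("A", "input", "GA"), node("L", "linker", "GL"),
                    node("S", "sink")),
               edges_df("A", "activation", "L", "L", "activation", "S"),
               "S"),
    "linker")
  # node off every input-to-sink path
  expect_error(
    make_graph("g",
               list(node("A", "input", "GA"), node("B", "input", "GB"),
                    node("S", "sink")),
               base_edges, "S"),
    "input-to-sink")
})

test_that("topological order puts every edge forward", {
  g <- chain_graph()
  expect_equal(topological_order(g), c("A", "B", "C"))

  for (seed in 1:50) {
    d <- random_dag(seed)
    ord <- topological_order(d$graph)
    pos <- stats::setNames(seq_along(ord), ord)
    # independent exhaustive edge scan
    expect_true(all(pos[d$graph$edges$source] < pos[d$graph$edges$target]),
                label = sprintf("all edges forward (seed %d)", seed))
  }
})

test_that("a branch tag on two nodes is rejected", {
  expect_error(
    make_graph("g",
               list(node("A", "input", "GA", branch = "b1"),
                    node("B", "intermediate", "GB", branch = "b1"),
                    node("S", "sink")),
               edges_df("A", "activation", "B", "B", "activation", "S"),
               "S"),
    "branch tag")
  expect_length(branch_terminals(chain_graph()), 0)
})

test_that("SIF import infers kinds and builds a valid graph", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("tert\tactivation\ttelomerase",
               "terc\tactivation\ttelomerase",
               "telomerase\tactivation\toutput"), f)
  g <- read_sif(f)
  expect_equal(g$sink, "output")
  expect_equal(g$nodes$tert$kind, "input")
  expect_equal(g$nodes$telomerase$kind, "intermediate")
  expect_equal(g$nodes$tert$genes, "TERT")
})
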