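make_de_fixture <- function(seed, n_genes = 60, n_per_group = 10,
                            fold = 1, disp = 0.1) {
  set.seed(seed)
  n <- 2 * n_per_group
  mu <- matrix(50, n_genes, n)
  mu[1, seq_len(n_per_group)] <- 50 * fold # gene 1 carries the signal
  counts <- matrix(rnb(length(mu), mu = mu, disp = disp), nrow = n_genes,
                   dimnames = list(sprintf("g%03d", 1:n_genes),
                                   sprintf("s%03d", 1:n)))
  labels <- rep(c("ALT_high_TEL_high", "ALT_low_TEL_low"), each = n_per_group)
  list(counts = counts, labels = labels)
}

test_that("null contrasts produce almost no significant genes", {
  frac <- sapply(1:5, function(s) {
    fx <- make_de_fixture(s, fold = 1)
    de <- differential_expression(fx$counts, fx$labels,
                                  target = "ALT_high_TEL_high")
    mean(de$p_adjusted < 0.05)
  })
  expect_lte(mean(frac), 0.01)
})

test_that("an implanted four-fold gene is detected in almost every seed", {
  hits <- sapply(1:100, function(s) {
    fx <- make_de_fixture(s, n_genes = 50, n_per_group = 20, fold = 4)
    de <- differential_expression(fx$counts, fx$labels,
                                  target = "ALT_high_TEL_high")
    de$p_adjusted[1] < 0.05 && de$direction[1] == "up"
  })
  expect_gte(sum(hits), 95)
})

test_that("undersized groups are rejected", {
  fx <- make_de_fixture(1)
  expect_error(
    differential_expression(fx$counts[, 1:11],
                            c(rep("ALT_high_TEL_high", 1),
                              rep("ALT_low_TEL_low", 10)),
                            target = "ALT_high_TEL_high"),
    "at least 2 samples")
})

test_that("swapping target and reference negates fold changes, keeps p", {
  fx <- make_de_fixture(7, fold = 3)
  de1 <- differential_expression(fx$counts, fx$labels,
                                 target = "ALT_high_TEL_high")
  de2 <- differential_expression(fx$counts, fx$labels,
                                 target = "ALT_low_TEL_low",
                                 reference = "ALT_high_TEL_high")
  expect_equal(de2$log2fc, -de1$log2fc)
  expect_equal(de2$p, de1$p)
})

test_that("BH adjustment equals the literal step-up and stays monotone", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))

  set.seed(151)
  p <- stats::runif(100)
  got <- bh_adjust(p)
  # literal step-up oracle
  ord <- order(p, decreasing = TRUE)
  m <- length(p)
  adj <- numeric(m)
  running <- 1
  for (k in seq_along(ord)) {
    i <- ord[k]
    rank_i <- m - k + 1
    running <- min(running, p[i] * m / rank_i)
    adj[i] <- running
  }
  expect_equal(got, adj, tolerance = 1e-12)
  expect_true(all(diff(got[order(p)]) >= 0))
  expect_true(all(got >= p))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("recurrence tallies count cancer types per direction", {
  de_row <- function(genes, dir) {
    data.frame(gene = genes, log2fc = 1, p = 0.001, p_adjusted = 0.01,
               direction = dir, stringsAsFactors = FALSE)
  }
  per_cancer <- list(
    C1 = rbind(de_row(c("BRIP1", "CLSPN", "AURKB"), "up"),
               de_row("OGN", "down")),
    C2 = rbind(de_row(c("BRIP1", "CLSPN"), "up"), de_row("C7", "down")),
    C3 = rbind(de_row("BRIP1", "up"), de_row(c("OGN", "C7"), "down")))
  up <- recurrence_tally(per_cancer, "up")
  expect_equal(up$n_cancer_types[up$gene == "BRIP1"], 3L)
  expect_equal(up$n_cancer_types[up$gene == "CLSPN"], 2L)
  expect_equal(up$n_cancer_types[up$gene == "AURKB"], 1L)
  down <- recurrence_tally(per_cancer, "down")
  expect_equal(down$n_cancer_types[down$gene == "OGN"], 2L)

  one <- recurrence_tally(per_cancer[1], "up")
  expect_true(all(one$n_cancer_types <= 1))
  empty <- recurrence_tally(list(), "up")
  expect_equal(nrow(empty), 0)
})

test_that("hypergeometric over-representation matches enumeration", {
  sets <- list(exact = paste0("G", 1:5))
  universe <- paste0("G", 1:10)
  out <- ora_hypergeometric(paste0("G", 1:5), sets, universe)
  expect_equal(out$p, 1 / choose(10, 5), tolerance = 1e-12)

  out0 <- ora_hypergeometric(paste0("G", 6:8), sets, universe)
  expect_equal(out0$overlap, 0)
  expect_equal(out0$p, 1)

  # random sets against a brute-force tail enumeration
  set.seed(161)
  uni <- paste0("U", 1:25)
  de <- sample(uni, 8)
  rnd <- lapply(1:50, function(i) sample(uni, sample(3:12, 1)))
  names(rnd) <- paste0("set", 1:50)
  got <- ora_hypergeometric(de, rnd, uni)
  for (i in 1:50) {
    K <- got$set_size[i]; k <- got$overlap[i]
    N <- 25; n <- 8
    p_brute <- sum(sapply(k:min(K, n), function(j) {
      choose(K, j) * choose(N - K, n - j) / choose(N, n)
    }))
    expect_equal(got$p[i], p_brute, tolerance = 1e-12)
    expect_lte(got$overlap[i], min(K, n))
  }
  expect_equal(got$q, stats::p.adjust(got$p, "BH"))
  expect_error(ora_hypergeometric("G1", sets, character(0)), "universe")
})

test_that("GMT files round-trip through the reader", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("cell_cycle\tdesc\tTRIP13\tTPX2\tMCM7",
               "ecm\tdesc\tADAMTS8\tOGN"), f)
  sets <- read_gmt(f)
  expect_equal(sets$cell_cycle, c("TRIP13", "TPX2", "MCM7"))
  expect_equal(sets$ecm, c("ADAMTS8", "OGN"))
  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines("only_name\tdesc", bad)
  expect_error(read_gmt(bad), "fewer than 3")
})
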