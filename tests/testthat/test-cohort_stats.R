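test_that("Kruskal-Wallis matches the literal rank formula", {
  expect_equal(kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))$H, 0)

  groups <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  kw <- kruskal_wallis(groups)
  # independent literal-formula recomputation (no ties)
  values <- unlist(groups)
  r <- rank(values)
  N <- length(values)
  Rj <- tapply(r, rep(1:3, each = 3), sum)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / 3) - 3 * (N + 1)
  expect_equal(kw$H, unname(H), tolerance = 1e-12)
  expect_equal(kw$p, stats::pchisq(H, 2, lower.tail = FALSE),
               tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(kruskal_wallis(list(c(1, 2, 3))), "two groups")
})

test_that("Dunn z matches a brute-force tie-corrected rank computation", {
  g <- list(a = c(1, 1, 2, 5), b = c(2, 2, 3, 3, 9), c = c(1, 3, 3, 7))
  out <- dunn_test(g)
  expect_equal(nrow(out), 3)

  # brute force: pooled ranks, tie correction, all pairs
  values <- unlist(g, use.names = FALSE)
  lab <- rep(names(g), lengths(g))
  r <- rank(values)
  N <- length(values)
  tie <- sum(sapply(split(values, values), function(v) length(v)^3 - length(v)))
  tiec <- tie / (12 * (N - 1))
  for (i in seq_len(nrow(out))) {
    p <- c(out$group1[i], out$group2[i])
    z <- (mean(r[lab == p[1]]) - mean(r[lab == p[2]])) /
      sqrt((N * (N + 1) / 12 - tiec) *
             (1 / sum(lab == p[1]) + 1 / sum(lab == p[2])))
    expect_equal(out$z[i], z, tolerance = 1e-12)
    expect_equal(out$p_raw[i], 2 * stats::pnorm(-abs(z)), tolerance = 1e-12)
  }
  expect_equal(out$p_adjusted, stats::p.adjust(out$p_raw, "BH"))

  same <- dunn_test(list(x = c(1, 2, 3), y = c(1, 2, 3)))
  expect_equal(same$z, 0)
  expect_equal(same$p_adjusted, 1)
  two <- dunn_test(list(x = c(1, 5, 3), y = c(2, 8, 4)))
  expect_equal(two$p_adjusted, two$p_raw)
})

test_that("Dunn and Kruskal-Wallis agree qualitatively on null fixtures", {
  for (seed in 1:10) {
    set.seed(seed)
    g <- split(stats::rnorm(60), rep(1:3, 20))
    dt <- dunn_test(g)
    kw <- kruskal_wallis(g)
    if (all(dt$p_adjusted > 0.3)) expect_gt(kw$p, 0.05)
  }
})

test_that("Kaplan-Meier reproduces the hand product-limit values", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 0))
  expect_equal(km$survival[km$time == 1], 2 / 3)
  expect_equal(km$survival[km$time == 2], 1 / 3)
  expect_equal(km$survival[km$time == 3], 1 / 3)

  all_cens <- km_estimate(c(4, 8, 2), c(0, 0, 0))
  expect_true(all(all_cens$survival == 1))
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")
})

test_that("KM tracks the exponential truth within its Greenwood band", {
  set.seed(101)
  lambda <- 0.02
  t <- stats::rexp(200, lambda)
  cens <- stats::runif(200, 0, 120)
  km <- km_estimate(pmin(t, cens), as.integer(t <= cens))
  keep <- km$n_risk >= 10
  inside <- exp(-lambda * km$time[keep]) >= km$lower[keep] &
    exp(-lambda * km$time[keep]) <= km$upper[keep]
  expect_gte(mean(inside), 0.9)
})

test_that("log-rank matches the hypergeometric O-E/V oracle", {
  dup <- logrank(c(1, 2, 3, 1, 2, 3), c(1, 1, 0, 1, 1, 0),
                 rep(c("a", "b"), each = 3))
  expect_equal(dup$chisq, 0)

  times <- c(3, 5, 7, 2, 4, 8, 9)
  events <- c(1, 1, 0, 1, 1, 1, 0)
  grp <- c("a", "a", "a", "b", "b", "b", "b")
  # hand oracle over distinct event times
  o_minus_e <- 0; v <- 0
  for (tt in sort(unique(times[events == 1]))) {
    at_risk <- times >= tt
    d <- sum(events == 1 & times == tt)
    n <- sum(at_risk)
    n1 <- sum(at_risk & grp == "a")
    d1 <- sum(events == 1 & times == tt & grp == "a")
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  lr <- logrank(times, events, grp)
  expect_equal(lr$chisq, o_minus_e^2 / v, tolerance = 1e-9)

  set.seed(111)
  five <- logrank(stats::rexp(100), stats::rbinom(100, 1, 0.7),
                  rep(letters[1:5], 20), pairwise = TRUE)
  expect_equal(nrow(five$pairwise), 10)
  expect_error(logrank(c(1, 2), c(0, 0), c("a", "b")), "events")
})

test_that("Cox coefficient maximizes the partial likelihood against a grid", {
  set.seed(121)
  n <- 60
  x <- rep(0:1, each = n / 2)
  t <- stats::rexp(n, 0.01 * exp(0.7 * x))
  t <- t + stats::runif(n, 0, 1e-4) # break ties so Efron = Breslow = exact
  ev <- rep(1L, n)
  hr <- cox_hr(t, ev, factor(x, levels = 0:1, labels = c("ref", "alt")),
               reference = "ref")
  # dense grid over the literal log partial likelihood
  logpl <- function(b) {
    s <- 0
    for (i in which(ev == 1)) {
      risk <- t >= t[i]
      s <- s + b * x[i] - log(sum(exp(b * x[risk])))
    }
    s
  }
  grid <- seq(-2, 3, by = 1e-4)
  b_star <- grid[which.max(sapply(grid, logpl))]
  expect_equal(hr$coef, b_star, tolerance = 1e-4)
  expect_equal(hr$HR, exp(hr$coef))
  expect_error(cox_hr(c(1, 2), c(0, 0), c("a", "b")), "events")
})

test_that("Cox score test equals the log-rank statistic on tie-free data", {
  set.seed(131)
  n <- 80
  x <- rep(c("a", "b"), each = n / 2)
  t <- stats::rexp(n, ifelse(x == "a", 0.01, 0.02))
  ev <- as.integer(stats::runif(n) < 0.8)
  fit <- survival::coxph(survival::Surv(t, ev) ~ x, ties = "breslow")
  lr <- logrank(t, ev, x)
  expect_equal(unname(summary(fit)$sctest["test"]), lr$chisq,
               tolerance = 1e-6)
})

test_that("Pearson correlation handles the closed-form and sampling cases", {
  x <- c(1, 3, 7, 9, 12)
  expect_equal(pearson_correlation(x, x)$r, 1)
  expect_equal(pearson_correlation(x, -2 * x)$r, -1)
  set.seed(141)
  z <- stats::rnorm(200)
  y <- 0.5 * z + sqrt(1 - 0.25) * stats::rnorm(200)
  expect_lt(abs(pearson_correlation(z, y)$r - 0.5), 0.15)
  expect_error(pearson_correlation(rep(1, 5), 1:5), "variance")
  expect_error(pearson_correlation(1:2, 2:3), "3 complete")
})

test_that("purity summaries are stratified medians only", {
  ph <- rep(c("ALT_low_TEL_low", "ALT_high_TEL_high"), each = 4)
  pur <- c(0.2, 0.4, 0.6, NA, 0.9, 0.7, 0.8, 1.0)
  out <- purity_by_phenotype(pur, ph)
  expect_equal(out$median_purity[out$phenotype == "ALT_low_TEL_low"], 0.4)
  expect_equal(out$median_purity[out$phenotype == "ALT_high_TEL_high"], 0.85)
  expect_equal(out$n, c(4L, 3L))
})
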