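#' Kruskal-Wallis comparison of activity across groups
#'
#' Rank-based H statistic with tie correction and a chi-square p-value on
#' k - 1 degrees of freedom, via [stats::kruskal.test()].  Used to compare
#' PSF activities across MSS / MSI-L / MSI-H groups.
#'
#' @param groups List of at least two numeric vectors.
#' @return List with `H`, `p`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("need at least two groups", call. = FALSE)
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(values, g)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter))
}

#' Dunn's post hoc test with Benjamini-Hochberg adjustment
#'
#' Pairwise z statistics on the pooled, tie-corrected ranks:
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) * (1/n_i + 1/n_j))` with tie
#' correction `T = sum(t^3 - t) / (12 (N - 1))`; two-sided p-values, adjusted
#' across the pairs by BH.
#'
#' @param groups Named list of at least two numeric vectors.
#' @return Data frame: `group1`, `group2`, `z`, `p_raw`, `p_adjusted`.
#' @export
dunn_test <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("need at least two groups", call. = FALSE)
  }
  if (is.null(names(groups))) names(groups) <- seq_along(groups)
  values <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  r <- rank(values)
  N <- length(values)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(names(groups), 2)
  z <- apply(pairs, 2, function(p) {
    num <- rbar[p[1]] - rbar[p[2]]
    den <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[p[1]] + 1 / n[p[2]]))
    if (den == 0) 0 else unname(num / den)
  })
  p_raw <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
             z = z, p_raw = p_raw,
             p_adjusted = stats::p.adjust(p_raw, method = "BH"),
             stringsAsFactors = FALSE)
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator via [survival::survfit()].  Fully censored input
#' gives a survival curve identically 1.
#'
#' @param times Non-negative follow-up times.
#' @param events 0/1 event indicators.
#' @return Data frame of the step function: `time`, `n_risk`, `n_event`,
#'   `survival`, `std_err` (Greenwood, on survival), `lower`, `upper`.
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) == length(events))
  if (any(times < 0)) stop("negative time", call. = FALSE)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "log")
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             survival = fit$surv, std_err = fit$std.err * fit$surv,
             lower = fit$lower, upper = fit$upper)
}

#' Log-rank test across strata, optionally pairwise
#'
#' Standard (O - E)^2 / V statistic via [survival::survdiff()].  With
#' `pairwise = TRUE` every pair of strata is tested and the p-values are BH
#' adjusted, matching the pairwise comparison of TMM phenotype survival.
#'
#' @param times,events Survival input.
#' @param strata Grouping vector, at least two levels with one event total.
#' @param pairwise Also return the pairwise table.
#' @return List with `chisq`, `df`, `p`; if `pairwise`, a data frame
#'   `pairwise` (`group1`, `group2`, `chisq`, `p_raw`, `p_adjusted`).
#' @export
logrank <- function(times, events, strata, pairwise = FALSE) {
  strata <- as.factor(strata)
  if (nlevels(droplevels(strata)) < 2) stop("need at least two strata", call. = FALSE)
  if (sum(events) == 0) stop("no events in any stratum", call. = FALSE)
  sd_all <- survival::survdiff(survival::Surv(times, events) ~ strata)
  out <- list(chisq = unname(sd_all$chisq),
              df = length(sd_all$n) - 1,
              p = stats::pchisq(sd_all$chisq, length(sd_all$n) - 1,
                                lower.tail = FALSE))
  if (pairwise) {
    lv <- levels(droplevels(strata))
    pairs <- utils::combn(lv, 2)
    rows <- apply(pairs, 2, function(p) {
      idx <- strata %in% p
      if (sum(events[idx]) == 0) return(c(NA_real_, NA_real_))
      sd <- survival::survdiff(
        survival::Surv(times[idx], events[idx]) ~ droplevels(strata[idx]))
      c(unname(sd$chisq), stats::pchisq(sd$chisq, 1, lower.tail = FALSE))
    })
    out$pairwise <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                               chisq = rows[1, ], p_raw = rows[2, ],
                               p_adjusted = stats::p.adjust(rows[2, ], method = "BH"),
                               stringsAsFactors = FALSE)
  }
  out
}

#' Cox proportional hazards ratios versus a reference group
#'
#' Fits [survival::coxph()] (Efron tie handling) with the grouping variable
#' coded against `reference`, and reports per-level hazard ratios with Wald
#' confidence intervals, as in the phenotype-versus-ALT^low TEL^low hazard
#' models.  Optionally stratified (baseline hazard per stratum, e.g. cancer
#' type).
#'
#' @param times,events Survival input.
#' @param group Factor-like covariate.
#' @param reference Reference level (default: first level).
#' @param strata Optional stratification variable.
#' @param conf_level Confidence level for the interval.
#' @return Data frame: `term`, `coef`, `HR`, `lower`, `upper`, `p`.
#' @export
cox_hr <- function(times, events, group, reference = NULL, strata = NULL,
                   conf_level = 0.95) {
  if (sum(events) == 0) stop("no events", call. = FALSE)
  group <- as.factor(group)
  if (!is.null(reference)) group <- stats::relevel(group, ref = reference)
  df <- data.frame(times = times, events = events, group = group)
  if (is.null(strata)) {
    fit <- survival::coxph(survival::Surv(times, events) ~ group, data = df,
                           ties = "efron")
  } else {
    df$str <- as.factor(strata)
    fit <- survival::coxph(
      survival::Surv(times, events) ~ group + survival::strata(str),
      data = df, ties = "efron")
  }
  s <- summary(fit, conf.int = conf_level)
  co <- s$coefficients
  ci <- s$conf.int
  data.frame(term = sub("^group", "", rownames(co)),
             coef = co[, "coef"],
             HR = ci[, 1],
             lower = ci[, 3], upper = ci[, 4],
             p = co[, "Pr(>|z|)"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pearson correlation with a t-based p-value
#'
#' Used for protein-versus-RNA comparisons.
#'
#' @param x,y Numeric vectors, length >= 3, nonzero variance.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance input", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Median tumor purity per phenotype
#'
#' Descriptive stratified summary of an externally supplied purity column;
#' no purity estimation is performed.
#'
#' @param purity Numeric vector in `[0, 1]` (NA allowed).
#' @param phenotype Phenotype label per sample.
#' @return Data frame: `phenotype`, `n`, `median_purity`.
#' @export
purity_by_phenotype <- function(purity, phenotype) {
  stopifnot(length(purity) == length(phenotype))
  ok <- !is.na(purity)
  med <- tapply(purity[ok], phenotype[ok], stats::median)
  n <- tapply(purity[ok], phenotype[ok], length)
  data.frame(phenotype = names(med), n = as.integer(n),
             median_purity = as.numeric(med),
             row.names = NULL, stringsAsFactors = FALSE)
}
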