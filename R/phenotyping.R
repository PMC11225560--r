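#' The five TMM phenotype labels
#'
#' Reachable labels of the classifier: the four corner cells of the 3x3
#' low/middle/high grid plus the collapsed middle class.
#' @export
TMM_PHENOTYPES <- c("ALT_high_TEL_low", "ALT_low_TEL_low",
                    "ALT_middle_TEL_middle", "ALT_high_TEL_high",
                    "ALT_low_TEL_high")

segmented_rss <- function(x, y, b) {
  X <- cbind(1, x, pmax(x - b[1], 0), pmax(x - b[2], 0))
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

#' Fit a two-breakpoint segmented regression to an activity distribution
#'
#' The knee-finding step behind TMM thresholding: the sorted activity values
#' are regressed on their rank quantile `(i - 0.5) / n` with a continuous
#' piecewise-linear model having two breakpoints.  Candidate breakpoint
#' pairs are scanned on a decile-spaced quantile grid and the best pair is
#' refined by local optimization of the residual sum of squares, making the
#' fit deterministic.  The thresholds `t_low < t_high` are the fitted values
#' at the two breakpoints: samples at or below `t_low` fall in the low
#' regime, above `t_high` in the high regime.
#'
#' @param values Numeric vector with at least 20 distinct values (log10 PSF
#'   activities in the default pipeline).
#' @param x Optional regressor.  When `NULL` (the cohort-thresholding path)
#'   the values are sorted and regressed on their rank quantile; when given,
#'   the `(x, values)` pairs are fitted as supplied — the classical
#'   segmented-regression form, used when the pairing carries information
#'   (e.g. recovery simulations with noise on the response).
#' @param axis Label carried on the model (`"ALT"`, `"TEL"`, ...).
#' @param scale Scale the values are on (`"log10"` or `"linear"`); recorded
#'   only, never applied.
#' @param grid_step Spacing of the coarse breakpoint grid on the quantile
#'   axis.
#' @return A `threshold_model`: `t_low`, `t_high`, breakpoints (quantile
#'   positions), slopes, residual sum of squares, approximate breakpoint
#'   standard errors, `n`.
#' @export
fit_segmented <- function(values, x = NULL, axis = "ALT",
                          scale = c("log10", "linear"), grid_step = 0.05) {
  scale <- match.arg(scale)
  if (is.null(x)) {
    values <- values[is.finite(values)]
  } else {
    stopifnot(length(x) == length(values))
    keep <- is.finite(values) & is.finite(x)
    values <- values[keep]
    x <- x[keep]
  }
  n <- length(values)
  if (n < 20 || length(unique(values)) < 20) {
    stop("need at least 20 distinct finite values to place two breakpoints",
         call. = FALSE)
  }
  if (stats::sd(values) == 0) stop("degenerate constant input", call. = FALSE)
  if (is.null(x)) {
    y <- sort(values)
    x <- (seq_len(n) - 0.5) / n
  } else {
    ord <- order(x)
    y <- values[ord]
    x <- x[ord]
  }

  cand <- stats::quantile(x, seq(grid_step, 1 - grid_step, by = grid_step),
                          names = FALSE)
  pairs <- expand.grid(b1 = cand, b2 = cand)
  pairs <- pairs[pairs$b2 > pairs$b1, ]
  rss <- mapply(function(b1, b2) segmented_rss(x, y, c(b1, b2)),
                pairs$b1, pairs$b2)
  best <- as.numeric(pairs[which.min(rss), ])

  obj <- function(b) {
    # keep at least a couple of points in every segment
    if (sum(x <= b[1]) < 2 || sum(x > b[1] & x <= b[2]) < 2 ||
        sum(x > b[2]) < 2 || b[2] <= b[1]) return(Inf)
    segmented_rss(x, y, b)
  }
  opt <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  b <- sort(opt$par)

  X <- cbind(1, x, pmax(x - b[1], 0), pmax(x - b[2], 0))
  fit <- stats::lm.fit(X, y)
  cf <- fit$coefficients
  t_low <- unname(cf[1] + cf[2] * b[1])
  t_high <- unname(cf[1] + cf[2] * b[2] + cf[3] * (b[2] - b[1]))
  sigma2 <- opt$value / max(n - 6, 1)
  se <- tryCatch({
    H <- stats::optimHess(b, function(bb) segmented_rss(x, y, bb))
    sqrt(pmax(diag(solve(H / (2 * sigma2))), 0))
  }, error = function(e) rep(NA_real_, 2))

  structure(list(axis = axis, scale = scale,
                 t_low = t_low, t_high = t_high,
                 breakpoints = b,
                 slopes = unname(c(cf[2], cf[2] + cf[3], cf[2] + cf[3] + cf[4])),
                 rss = opt$value, breakpoint_se = se, n = n),
            class = "threshold_model")
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf("threshold_model [%s, %s]: t_low = %.4g, t_high = %.4g (n = %d, rss = %.4g)\n",
              x$axis, x$scale, x$t_low, x$t_high, x$n, x$rss))
  invisible(x)
}

axis_category <- function(value, model) {
  ifelse(value <= model$t_low, "low",
         ifelse(value > model$t_high, "high", "middle"))
}

#' Classify samples into the five TMM phenotypes
#'
#' Each axis is cut into low (`value <= t_low`), middle, and high
#' (`value > t_high`) by its threshold model; ties sit in the lower
#' category.  Of the nine grid cells only the four corners name distinct
#' phenotypes; any sample with a middle category on either axis collapses to
#' `ALT_middle_TEL_middle`.  The uncollapsed cell is kept in `raw_cell` so
#' the rule can be audited.
#'
#' @param alt_value,tel_value Numeric vectors of equal length, on the scale
#'   the models were fitted on.
#' @param alt_model,tel_model `threshold_model`s for the two axes.
#' @param sample Optional sample ids.
#' @return Data frame: `sample`, `alt_value`, `tel_value`, `alt_cat`,
#'   `tel_cat`, `raw_cell`, `phenotype` (factor over [TMM_PHENOTYPES]).
#' @export
classify <- function(alt_value, tel_value, alt_model, tel_model,
                     sample = NULL) {
  stopifnot(length(alt_value) == length(tel_value))
  if (is.null(sample)) sample <- as.character(seq_along(alt_value))
  alt_cat <- axis_category(alt_value, alt_model)
  tel_cat <- axis_category(tel_value, tel_model)
  raw <- paste0("ALT_", alt_cat, "_TEL_", tel_cat)
  phen <- ifelse(alt_cat == "middle" | tel_cat == "middle",
                 "ALT_middle_TEL_middle", raw)
  data.frame(sample = sample,
             alt_value = alt_value, tel_value = tel_value,
             alt_cat = alt_cat, tel_cat = tel_cat,
             raw_cell = raw,
             phenotype = factor(phen, levels = TMM_PHENOTYPES),
             stringsAsFactors = FALSE)
}

#' Phenotype prevalence table
#'
#' Counts and fractions of each phenotype, overall or within strata (e.g.
#' cancer types).  Fractions sum to 1 per stratum.
#'
#' @param calls A classification data frame from [classify()] (or any data
#'   frame with a `phenotype` column).
#' @param strata Optional grouping vector, one entry per call.
#' @return Data frame: (`stratum`,) `phenotype`, `count`, `fraction`.
#' @export
phenotype_prevalence <- function(calls, strata = NULL) {
  if (nrow(calls) == 0) stop("empty input", call. = FALSE)
  phen <- factor(calls$phenotype, levels = TMM_PHENOTYPES)
  if (is.null(strata)) {
    tab <- table(phenotype = phen)
    out <- data.frame(phenotype = names(tab),
                      count = as.integer(tab),
                      fraction = as.numeric(tab) / sum(tab),
                      stringsAsFactors = FALSE)
  } else {
    stopifnot(length(strata) == nrow(calls))
    tab <- table(stratum = strata, phenotype = phen)
    frac <- prop.table(tab, margin = 1)
    out <- data.frame(as.data.frame(tab, stringsAsFactors = FALSE),
                      fraction = as.data.frame(frac)$Freq)
    names(out) <- c("stratum", "phenotype", "count", "fraction")
  }
  out
}

#' Fit thresholds and classify a cohort in one step
#'
#' Convenience wrapper over [fit_segmented()] and [classify()]: fits the two
#' axis models on the pooled (pan-cohort) log10 activities by default, or
#' per stratum when `scope = "per_stratum"`.
#'
#' @param alt_log10,tel_log10 Log10 PSF activities per sample.
#' @param sample Sample ids.
#' @param scope `"pooled"` (default) or `"per_stratum"`.
#' @param strata Required for `scope = "per_stratum"`.
#' @return List: `calls` (classification data frame), `alt_model`,
#'   `tel_model` (or per-stratum lists of models).
#' @export
phenotype_cohort <- function(alt_log10, tel_log10, sample = NULL,
                             scope = c("pooled", "per_stratum"),
                             strata = NULL) {
  scope <- match.arg(scope)
  if (scope == "pooled") {
    am <- fit_segmented(alt_log10, axis = "ALT")
    tm <- fit_segmented(tel_log10, axis = "TEL")
    calls <- classify(alt_log10, tel_log10, am, tm, sample = sample)
    return(list(calls = calls, alt_model = am, tel_model = tm))
  }
  stopifnot(!is.null(strata), length(strata) == length(alt_log10))
  pieces <- lapply(split(seq_along(alt_log10), strata), function(idx) {
    am <- fit_segmented(alt_log10[idx], axis = "ALT")
    tm <- fit_segmented(tel_log10[idx], axis = "TEL")
    list(calls = classify(alt_log10[idx], tel_log10[idx], am, tm,
                          sample = sample[idx]),
         alt_model = am, tel_model = tm)
  })
  list(calls = do.call(rbind, lapply(pieces, `[[`, "calls")),
       alt_model = lapply(pieces, `[[`, "alt_model"),
       tel_model = lapply(pieces, `[[`, "tel_model"))
}
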