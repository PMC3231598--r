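#' Root-mean-squared error
#'
#' @param predicted,expected numeric vectors or matrices of equal shape
#'   (columns = ions).
#' @return For matrices, a named vector with one entry per column plus
#'   `pooled` (all residuals together); for vectors, a single value.
#' @export
rmse <- function(predicted, expected) {
  predicted <- as.matrix(predicted); expected <- as.matrix(expected)
  if (!all(dim(predicted) == dim(expected))) stop("length mismatch")
  if (nrow(predicted) < 1) stop("need at least one pair")
  per <- sqrt(colMeans((predicted - expected)^2))
  names(per) <- colnames(expected) %||% paste0("y", seq_along(per))
  if (length(per) == 1) return(unname(per))
  c(per, pooled = sqrt(mean((predicted - expected)^2)))
}

#' Obtained-vs-expected comparison regression
#'
#' Ordinary least squares of the obtained values on the expected ones with
#' t-based confidence intervals; for an accurate model the slope, intercept
#' and correlation should approximate 1, 0 and 1, and the intervals should
#' contain 1 and 0.
#'
#' @param predicted obtained values (y).
#' @param expected reference values (x).
#' @param conf confidence level (default 0.95).
#' @return An object of class `comparison_regression` with `slope`,
#'   `slope_ci`, `intercept`, `intercept_ci`, `r`, `n` and `contains_ideal`
#'   (do the intervals cover 1 and 0 simultaneously?).
#' @export
comparison_regression <- function(predicted, expected, conf = 0.95) {
  stopifnot(length(predicted) == length(expected))
  if (length(expected) < 3) stop("need at least 3 pairs")
  if (stats::var(expected) == 0) stop("expected values have zero variance")
  fit <- stats::lm(predicted ~ expected)
  ci <- suppressWarnings(stats::confint(fit, level = conf))
  cf <- stats::coef(fit)
  structure(list(slope = cf[[2]], slope_ci = unname(ci[2, ]),
                 intercept = cf[[1]], intercept_ci = unname(ci[1, ]),
                 r = stats::cor(predicted, expected), n = length(expected),
                 conf = conf,
                 contains_ideal = ci[2, 1] <= 1 && 1 <= ci[2, 2] &&
                   ci[1, 1] <= 0 && 0 <= ci[1, 2]),
            class = "comparison_regression")
}

#' @export
print.comparison_regression <- function(x, ...) {
  cat(sprintf("slope %.4f [%.4f, %.4f], intercept %.3g [%.3g, %.3g], r %.4f (n=%d)\n",
              x$slope, x$slope_ci[1], x$slope_ci[2], x$intercept,
              x$intercept_ci[1], x$intercept_ci[2], x$r, x$n))
  cat(if (x$contains_ideal) "intervals contain the ideal slope 1 / intercept 0\n"
      else "intervals exclude the ideal slope/intercept\n")
  invisible(x)
}

#' Single-electrode interpolation baseline
#'
#' The conventional one-electrode determination: invert the fitted
#' calibration line `E = e0 + s log10(a)` for the activity, ignoring any
#' interferent contribution, then convert activity to concentration with the
#' activity model of the measurement regime (the ionic strength is solved by
#' fixed-point iteration since it depends on the answer). Potentials
#' outside the calibrated activity span are flagged via the
#' `"extrapolated"` attribute.
#'
#' @param E potentials in mV.
#' @param fit a `calibration_fit` for the designated electrode.
#' @param charge signed charge of the reported ion.
#' @param params an [activity_params()] object for the measurement regime.
#' @param max_iter,tol fixed-point controls for the activity-to-
#'   concentration conversion.
#' @return Concentrations in mol/L with attribute `"extrapolated"`.
#' @export
single_ise_baseline <- function(E, fit, charge, params = activity_params(),
                                max_iter = 50, tol = 1e-12) {
  a <- 10^((E - fit$e0_hat) / fit$slope)
  conc <- a
  for (i in seq_len(max_iter)) {
    I <- params$background_ionic_strength +
      0.5 * conc * (charge^2 + abs(charge))
    conc_new <- a / activity_coefficient(charge, I, params)
    if (max(abs(conc_new - conc) / pmax(conc, 1e-300)) < tol) {
      conc <- conc_new
      break
    }
    conc <- conc_new
  }
  extrap <- a < fit$a_range[1] | a > fit$a_range[2]
  attr(conc, "extrapolated") <- extrap
  conc
}

#' Percentage relative errors
#'
#' `100 |predicted - expected| / expected` per element; rows with an
#' expected value of zero are excluded (and counted). Aggregation is by the
#' mean (or median) per ion.
#'
#' @param predicted,expected matrices (columns = ions) or vectors.
#' @param aggregate `"mean"` (default) or `"median"`.
#' @return An object of class `error_report` with `per_sample` (long table),
#'   `aggregate` (named per-ion vector plus `pooled`), and `n_excluded`.
#' @export
relative_errors <- function(predicted, expected,
                            aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  predicted <- as.matrix(predicted); expected <- as.matrix(expected)
  stopifnot(all(dim(predicted) == dim(expected)))
  ions <- colnames(expected) %||% paste0("y", seq_len(ncol(expected)))
  agg_fun <- if (aggregate == "mean") mean else stats::median
  per <- do.call(rbind, lapply(seq_len(ncol(expected)), function(k) {
    data.frame(row = seq_len(nrow(expected)), ion = ions[k],
               expected = expected[, k], predicted = predicted[, k],
               rel_err_pct = ifelse(expected[, k] > 0,
                                    100 * abs(predicted[, k] - expected[, k]) /
                                      expected[, k], NA_real_))
  }))
  n_excluded <- sum(is.na(per$rel_err_pct))
  ok <- !is.na(per$rel_err_pct)
  agg <- vapply(ions, function(i)
    agg_fun(per$rel_err_pct[ok & per$ion == i]), numeric(1))
  agg <- c(agg, pooled = agg_fun(per$rel_err_pct[ok]))
  structure(list(per_sample = per, aggregate = agg,
                 n_excluded = n_excluded, statistic = aggregate),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("Relative errors (%% of expected, %s over %d values%s):\n",
              x$statistic, sum(!is.na(x$per_sample$rel_err_pct)),
              if (x$n_excluded) sprintf(", %d zero-expected excluded",
                                        x$n_excluded) else ""))
  print(round(x$aggregate, 2))
  invisible(x)
}

#' Paired Student's t test against nominal values
#'
#' Two-tailed paired t test: `t = mean(d) / (sd(d)/sqrt(n))` with
#' `d = predicted - nominal` and `df = n - 1`, reported with the critical
#' value of the t distribution at the configured confidence level
#' (e.g. 2.57 for 5 degrees of freedom at 95%). A zero-variance difference
#' with a nonzero mean yields an infinite statistic.
#'
#' @param predicted,nominal paired numeric vectors (n >= 2).
#' @param conf confidence level (default 0.95).
#' @return An object of class `paired_t_test`: `t`, `df`, `critical`, `p`,
#'   `mean_diff` and `significant` (is |t| above the critical value?).
#' @export
paired_t_test <- function(predicted, nominal, conf = 0.95) {
  stopifnot(length(predicted) == length(nominal), length(predicted) >= 2)
  d <- predicted - nominal
  n <- length(d)
  sd_d <- stats::sd(d)
  t_stat <- if (sd_d == 0) {
    if (mean(d) == 0) 0 else sign(mean(d)) * Inf
  } else mean(d) / (sd_d / sqrt(n))
  df <- as.integer(n - 1)
  crit <- stats::qt(1 - (1 - conf) / 2, df)
  p <- if (is.infinite(t_stat)) 0 else 2 * stats::pt(-abs(t_stat), df)
  structure(list(t = t_stat, df = df, critical = crit, p = p,
                 mean_diff = mean(d), conf = conf,
                 significant = abs(t_stat) > crit),
            class = "paired_t_test")
}

#' @export
print.paired_t_test <- function(x, ...) {
  cat(sprintf("Paired t test: t = %.3f, df = %d, critical t* = %.2f (%.0f%%), p = %.3g\n",
              x$t, x$df, x$critical, 100 * x$conf, x$p))
  cat(if (x$significant)
    "significant difference from the nominal values\n"
    else "no significant difference from the nominal values\n")
  invisible(x)
}
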