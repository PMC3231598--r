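#' Predict ion concentrations from array potentials
#'
#' Forward pass of a fitted [et_fit()] model: scale the potentials with the
#' stored training-range map, propagate through the hidden layer and the
#' linear output, and unscale to concentrations. Inputs falling outside the
#' training range are flagged as extrapolation (a warning plus the logical
#' attribute `"extrapolated"` on the result) but still evaluated.
#'
#' @param object an `et_model`.
#' @param newdata matrix/data frame of potentials with the training column
#'   count (a `sample_id` column, if present, is dropped).
#' @param ... unused.
#' @return Matrix of concentrations (mol/L), one column per ion.
#' @export
predict.et_model <- function(object, newdata, ...) {
  if (missing(newdata)) newdata <- object$x
  if (is.data.frame(newdata)) {
    keep <- setdiff(names(newdata), "sample_id")
    newdata <- as.matrix(newdata[, keep, drop = FALSE])
  }
  if (ncol(newdata) != object$n_inputs)
    stop("expected ", object$n_inputs, " potential columns, got ",
         ncol(newdata))
  X <- apply_scaling(newdata, object$input_scaling)
  extrap <- apply(abs(X) > 1 + 1e-8, 1, any)
  if (any(extrap))
    warning(sum(extrap), " sample(s) outside the calibrated potential range",
            " (extrapolation)")
  out <- predict_theta(object$theta, newdata, object$n_inputs,
                       object$hidden, object$n_outputs, object$transfer,
                       object$input_scaling, object$output_scaling,
                       object$log_outputs)
  colnames(out) <- object$ions
  attr(out, "extrapolated") <- extrap
  out
}

#' @export
fitted.et_model <- function(object, ...) {
  out <- suppressWarnings(predict(object, object$x))
  attr(out, "extrapolated") <- NULL
  out
}

#' @export
residuals.et_model <- function(object, ...) object$y - fitted(object)

#' @export
coef.et_model <- function(object, ...) {
  w <- mlp_unpack(object$theta, object$n_inputs, object$hidden,
                  object$n_outputs)
  nm <- c(paste0("W1[", rep(seq_len(object$hidden), object$n_inputs), ",",
                 rep(seq_len(object$n_inputs), each = object$hidden), "]"),
          paste0("b1[", seq_len(object$hidden), "]"),
          paste0("W2[", rep(seq_len(object$n_outputs), object$hidden), ",",
                 rep(seq_len(object$hidden), each = object$n_outputs), "]"),
          paste0("b2[", seq_len(object$n_outputs), "]"))
  stats::setNames(object$theta, nm)
}

#' @export
print.et_model <- function(x, ...) {
  cat(sprintf("Electronic-tongue inverse model: %d-%d-%d MLP (%s/purelin)\n",
              x$n_inputs, x$hidden, x$n_outputs, x$transfer))
  cat(sprintf("  strategy: %s, %d epochs (%s), best of %d restart(s)\n",
              x$control$strategy, x$epochs, x$status,
              nrow(x$restarts)))
  cat(sprintf("  F = %.4g, E_D = %.4g, E_W = %.4g, alpha = %.3g, beta = %.3g, gamma_eff = %.1f / %d\n",
              x$F, x$E_D, x$E_W, x$alpha, x$beta, x$gamma,
              mlp_npar(x$n_inputs, x$hidden, x$n_outputs)))
  tr_rmse <- sqrt(mean((fitted(x) - x$y)^2))
  cat(sprintf("  train RMSE %.3g mol/L", tr_rmse))
  if (!is.null(x$x_test)) {
    pr <- suppressWarnings(predict(x, as.matrix(x$x_test)))
    cat(sprintf("; test RMSE %.3g mol/L", sqrt(mean((pr - as.matrix(x$y_test))^2))))
  }
  cat("\n")
  invisible(x)
}

#' Summarise a fitted electronic-tongue model
#'
#' Reports per-ion RMSE and the obtained-vs-expected comparison regression
#' (slope, intercept, correlation, with confidence intervals) on the
#' training and, when available, the external test subset.
#'
#' @param object an `et_model`.
#' @param conf confidence level for the regression intervals.
#' @param ... unused.
#' @export
summary.et_model <- function(object, conf = 0.95, ...) {
  subsets <- list(train = list(x = object$x, y = object$y))
  if (!is.null(object$x_test))
    subsets$test <- list(x = as.matrix(object$x_test),
                         y = as.matrix(object$y_test))
  rows <- list()
  for (nm in names(subsets)) {
    pred <- suppressWarnings(predict(object, subsets[[nm]]$x))
    yy <- subsets[[nm]]$y
    for (k in seq_len(ncol(yy))) {
      cr <- comparison_regression(pred[, k], yy[, k], conf = conf)
      rows[[length(rows) + 1]] <- data.frame(
        subset = nm, ion = object$ions[k] %||% paste0("y", k),
        rmse = sqrt(mean((pred[, k] - yy[, k])^2)),
        slope = cr$slope, slope_lo = cr$slope_ci[1], slope_hi = cr$slope_ci[2],
        intercept = cr$intercept, intercept_lo = cr$intercept_ci[1],
        intercept_hi = cr$intercept_ci[2], r = cr$r,
        ideal = cr$contains_ideal)
    }
  }
  out <- list(model = object, table = do.call(rbind, rows), conf = conf)
  class(out) <- "summary.et_model"
  out
}

#' @export
print.summary.et_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("\nObtained-vs-expected comparison (%.0f%% confidence):\n",
              100 * x$conf))
  tab <- x$table
  tab[, sapply(tab, is.numeric)] <- signif(tab[, sapply(tab, is.numeric)], 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Obtained-vs-expected plot for a fitted model
#'
#' One panel per ion showing predictions against the expected values for the
#' training subset (and the test subset, when present), the identity line
#' (dashed) and the comparison regression (solid).
#'
#' @param x an `et_model`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.et_model <- function(x, ...) {
  q <- x$n_outputs
  old <- graphics::par(mfrow = c(1, q))
  on.exit(graphics::par(old))
  pred_tr <- fitted(x)
  has_test <- !is.null(x$x_test)
  if (has_test)
    pred_te <- suppressWarnings(predict(x, as.matrix(x$x_test)))
  for (k in seq_len(q)) {
    ex <- x$y[, k]; ob <- pred_tr[, k]
    if (has_test) { ex <- c(ex, as.matrix(x$y_test)[, k]); ob <- c(ob, pred_te[, k]) }
    graphics::plot(x$y[, k], pred_tr[, k],
                   xlab = sprintf("expected c(%s) / M", x$ions[k]),
                   ylab = sprintf("obtained c(%s) / M", x$ions[k]),
                   xlim = range(ex), ylim = range(c(ex, ob)), pch = 1, ...)
    if (has_test)
      graphics::points(as.matrix(x$y_test)[, k], pred_te[, k], pch = 17)
    graphics::abline(0, 1, lty = 2)
    graphics::abline(stats::lm(ob ~ ex), lty = 1)
  }
  invisible(x)
}
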