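# Core response-curve fit on the activity scale.
#
# Strategy: (1) provisional line through the upper half of the activity
# range; (2) decide whether the series shows low-end flattening; (3) if so,
# select the linear region (activities above ~10x the provisional flattening
# point) and fit it by OLS; (4) optionally refine by least squares on the
# full two-parameter response E = e0 + s log10(a + b), adopting the refined
# parameters only when they describe the linear-region points at least as
# well as the plain OLS line (this keeps an ideal two-straight-segment
# series exact while removing the curvature bias of real Nikolsky-type
# responses).
fit_response_curve <- function(E, a, refine = TRUE) {
  stopifnot(length(E) == length(a), all(is.finite(E)), all(is.finite(a)),
            all(a > 0))
  o <- order(a)
  a <- a[o]; E <- E[o]
  x <- log10(a)
  n <- length(a)
  if (n < 2) stop("need at least 2 points")
  res <- list(n = n, a_range = range(a))
  if (n == 2) {
    s <- diff(E) / diff(x)
    res <- c(res, list(slope = s, e0 = E[1] - s * x[1], b = 0, r2 = 1,
                       residual_sd = 0, linear_range = range(a),
                       curved = FALSE, refined = FALSE))
    return(res)
  }
  hi <- which(x >= max(x) - diff(range(x)) / 2)
  if (length(hi) < 3) hi <- order(x, decreasing = TRUE)[seq_len(min(3, n))]
  f0 <- stats::lm(E[hi] ~ x[hi])
  e00 <- stats::coef(f0)[[1]]; s0 <- stats::coef(f0)[[2]]
  if (!is.finite(s0) || s0 == 0) stop("no identifiable linear response")
  sd0 <- stats::sd(stats::residuals(f0))
  if (!is.finite(sd0)) sd0 <- 0
  dev_low <- E[1] - (e00 + s0 * x[1])
  # a genuine low-end plateau deviates in the slope direction: extrapolating
  # the line to very low activity overshoots the plateau, so the observed
  # low-end potential falls on the e0 + s*log10(a_bg) side of the line
  curved <- sign(dev_low) == sign(s0) && abs(dev_low) > max(2, 6 * sd0)
  if (curved) {
    a_star <- 10^((E[1] - e00) / s0)
    region <- which(a > 10 * a_star)
    if (length(region) < 3) region <- order(a, decreasing = TRUE)[seq_len(min(3, n))]
  } else {
    a_star <- 0
    region <- seq_len(n)
  }
  f1 <- stats::lm(E[region] ~ x[region])
  e01 <- stats::coef(f1)[[1]]; s1 <- stats::coef(f1)[[2]]
  best <- list(slope = s1, e0 = e01, b = a_star, refined = FALSE)
  if (refine && curved) {
    b0 <- max(a_star, min(a) * 1e-3)
    fitn <- try(minpack.lm::nlsLM(
      E ~ e0 + s * log10(a + exp(lb)),
      start = list(e0 = e01, s = s1, lb = log(b0)),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (!inherits(fitn, "try-error")) {
      cf <- stats::coef(fitn)
      pred_nls <- cf[["e0"]] + cf[["s"]] * log10(a[region] + exp(cf[["lb"]]))
      mse_nls <- mean((E[region] - pred_nls)^2)
      mse_ols <- mean(stats::residuals(f1)^2)
      if (is.finite(mse_nls) && mse_nls <= mse_ols + 1e-12)
        best <- list(slope = cf[["s"]], e0 = cf[["e0"]], b = exp(cf[["lb"]]),
                     refined = TRUE)
    }
  }
  pred <- if (best$refined)
    best$e0 + best$slope * log10(a[region] + best$b)
  else best$e0 + best$slope * x[region]
  rss <- sum((E[region] - pred)^2)
  tss <- sum((E[region] - mean(E[region]))^2)
  res$slope <- best$slope
  res$e0 <- best$e0
  res$b <- best$b
  res$r2 <- if (tss > 0) max(0, min(1, 1 - rss / tss)) else 1
  res$residual_sd <- sqrt(rss / max(1, length(region) - 2))
  res$linear_range <- range(a[region])
  res$curved <- curved
  res$refined <- best$refined
  res
}

# Activities of a primary-ion series: per-point ionic strength is the
# background plus the ion's own (counter-ion inclusive) contribution plus any
# extra contribution from co-dissolved species (e.g. a fixed interferent).
primary_activities <- function(conc, charge, params, extra_ionic_strength = 0) {
  I <- params$background_ionic_strength + extra_ionic_strength +
    0.5 * conc * (charge^2 + abs(charge))
  activity_coefficient(charge, I, params) * conc
}

#' Fit an electrode calibration (IUPAC slope)
#'
#' Regresses potential on the log10 activity of the primary ion over an
#' automatically selected linear region, with a curvature-aware refinement
#' of the full response `E = e0 + s log10(a + b)` (see Details of the
#' package vignette). Activities, not concentrations, are used on the
#' abscissa.
#'
#' @param E potentials in mV.
#' @param conc primary-ion molar concentrations.
#' @param charge signed charge of the primary ion.
#' @param params an [activity_params()] object describing the calibration
#'   regime (background electrolyte etc.).
#' @param extra_ionic_strength additional fixed ionic-strength contribution
#'   (mol/L), e.g. from a constant interferent level.
#' @param refine logical; refine the linear fit against the full low-end
#'   response model (default TRUE).
#' @param sensor_id optional id stored in the result.
#' @return An object of class `calibration_fit` with elements `slope`
#'   (mV/decade), `e0_hat` (mV), `linear_range` (activity, mol/L), `r2`,
#'   `residual_sd` (mV), `flattening` (activity at which the response bends,
#'   mol/L) and bookkeeping fields.
#' @export
fit_calibration <- function(E, conc, charge = -1, params = activity_params(),
                            extra_ionic_strength = 0, refine = TRUE,
                            sensor_id = NA_character_) {
  a <- primary_activities(conc, charge, params, extra_ionic_strength)
  fit <- fit_response_curve(E, a, refine = refine)
  structure(list(sensor_id = sensor_id, slope = fit$slope, e0_hat = fit$e0,
                 linear_range = fit$linear_range, r2 = fit$r2,
                 residual_sd = fit$residual_sd, flattening = fit$b,
                 curved = fit$curved, refined = fit$refined, n = fit$n,
                 a_range = fit$a_range, charge = charge),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("Calibration fit%s: slope %.2f mV/decade, e0 %.1f mV, r2 %.4f\n",
              if (is.na(x$sensor_id)) "" else paste0(" [", x$sensor_id, "]"),
              x$slope, x$e0_hat, x$r2))
  cat(sprintf("  linear range (activity): %.3g .. %.3g mol/L; flattening %.3g mol/L\n",
              x$linear_range[1], x$linear_range[2], x$flattening))
  invisible(x)
}

# IUPAC two-segment construction on a fitted response: intersect the
# extrapolated linear segment with the horizontal low-concentration segment
# (mean potential of the plateau points).
lod_construction <- function(E, a, refine = TRUE) {
  o <- order(a)
  a <- a[o]; E <- E[o]
  fit <- fit_response_curve(E, a, refine = refine)
  if (!fit$curved)
    stop("estimation error: series shows no low-concentration plateau")
  plateau <- which(a <= fit$b / 20)
  if (!length(plateau)) {
    warning("plateau barely sampled; using the lowest point only")
    plateau <- 1L
  }
  E_h <- mean(E[plateau])
  a_star <- 10^((E_h - fit$e0) / fit$slope)
  list(fit = fit, lod = a_star)
}

#' IUPAC detection limit
#'
#' Graphical IUPAC construction for potentiometric detection limits: the
#' activity at the intersection of the extrapolated linear-response segment
#' and the extrapolated horizontal low-concentration segment. The series
#' must extend well below the flattening point (accuracy improves the deeper
#' the plateau is sampled; about 1.5 decades below gives < 5% bias).
#'
#' @inheritParams fit_calibration
#' @return Detection limit on the activity scale, mol/L.
#' @export
detection_limit <- function(E, conc, charge = -1, params = activity_params(),
                            extra_ionic_strength = 0) {
  a <- primary_activities(conc, charge, params, extra_ionic_strength)
  lod_construction(E, a)$lod
}

#' Potentiometric selectivity coefficient
#'
#' Fixed-interference (mixed-solution) method: for each constant interferent
#' level, the primary-ion calibration flattens near the activity
#' \eqn{a_i^* = a_{bg} + k^{pot} a_j^{z_i/z_j}}; the coefficient follows as
#' \eqn{\log k = \log_{10}[(a_i^* - LOD)/a_j^{z_i/z_j}]}, where the optional
#' `lod` (the electrode's own interferent-free detection limit, activity
#' scale) removes the electrode's intrinsic background from the flattening
#' point. Without `lod` the estimate is biased high when the interferent
#' contribution does not dominate the background. The `nonlinear_fit` method
#' fits the full response with free selectivity and background terms over
#' all runs jointly and serves as a cross-check.
#'
#' @param E potentials in mV.
#' @param c_primary,c_interferent molar concentrations per row; rows with a
#'   common interferent level form one run.
#' @param z_primary,z_interferent signed charges.
#' @param params an [activity_params()] object for the run regime.
#' @param method `"fixed_interference"` (default) or `"nonlinear_fit"`.
#' @param lod optional interferent-free detection limit (activity, mol/L).
#' @return An object of class `selectivity_estimate`: `log_k` (log10 of the
#'   selectivity coefficient), `per_level` table, `method` and `flagged`
#'   (TRUE when the interference was unidentifiable at every level).
#' @export
selectivity_coefficient <- function(E, c_primary, c_interferent,
                                    z_primary, z_interferent,
                                    params = activity_params(),
                                    method = c("fixed_interference",
                                               "nonlinear_fit"),
                                    lod = NULL) {
  method <- match.arg(method)
  stopifnot(length(E) == length(c_primary),
            length(E) == length(c_interferent))
  p <- z_primary / z_interferent
  levels <- sort(unique(c_interferent[c_interferent > 0]))
  if (!length(levels))
    stop("mixed-solution runs need at least one nonzero interferent level")
  per_level <- data.frame(level = levels, a_j = NA_real_, a_star = NA_real_,
                          log_k = NA_real_, flagged = TRUE)
  aj_all <- rep(NA_real_, length(E))
  for (li in seq_along(levels)) {
    idx <- which(abs(c_interferent - levels[li]) <=
                   1e-12 * max(levels[li], 1e-300))
    cp <- c_primary[idx]
    I <- params$background_ionic_strength +
      0.5 * cp * (z_primary^2 + abs(z_primary)) +
      0.5 * levels[li] * (z_interferent^2 + abs(z_interferent))
    a_p <- activity_coefficient(z_primary, I, params) * cp
    a_j <- activity_coefficient(z_interferent, I, params) * levels[li]
    aj_all[idx] <- a_j
    a_j0 <- a_j[which.min(cp)]  # interferent activity where primary is negligible
    per_level$a_j[li] <- a_j0
    cons <- try(lod_construction(E[idx], a_p), silent = TRUE)
    if (inherits(cons, "try-error")) next
    excess <- cons$lod - (lod %||% 0)
    per_level$a_star[li] <- cons$lod
    if (excess <= 0 || (!is.null(lod) && excess < 0.1 * lod)) {
      per_level$log_k[li] <- -Inf
      next
    }
    per_level$log_k[li] <- log10(excess) - p * log10(a_j0)
    per_level$flagged[li] <- FALSE
  }
  if (method == "fixed_interference") {
    ok <- !per_level$flagged
    log_k <- if (any(ok)) mean(per_level$log_k[ok]) else -Inf
    flagged <- !any(ok)
  } else {
    ok_rows <- which(c_interferent > 0)
    Ef <- E[ok_rows]
    I <- params$background_ionic_strength +
      0.5 * c_primary[ok_rows] * (z_primary^2 + abs(z_primary)) +
      0.5 * c_interferent[ok_rows] * (z_interferent^2 + abs(z_interferent))
    a_p <- activity_coefficient(z_primary, I, params) * c_primary[ok_rows]
    a_j <- aj_all[ok_rows]
    start_k <- per_level$log_k[!per_level$flagged]
    lk0 <- if (length(start_k) && all(is.finite(start_k)))
      mean(start_k) * log(10) else log(1e-3)
    b_fix <- lod %||% 0
    f0 <- fit_response_curve(Ef, a_p)
    # background fixed at the measured interferent-free detection limit when
    # available (a free background term is near-unidentifiable once the
    # interference dominates); otherwise it is fitted too
    fitn <- try(minpack.lm::nlsLM(
      Ef ~ e0 + s * log10(a_p + b_fix + exp(lk) * a_j^p),
      start = list(e0 = f0$e0, s = f0$slope, lk = lk0),
      control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
    if (inherits(fitn, "try-error"))
      fitn <- minpack.lm::nlsLM(
        Ef ~ e0 + s * log10(a_p + exp(lb) + exp(lk) * a_j^p),
        start = list(e0 = f0$e0, s = f0$slope,
                     lb = log(max(b_fix, min(a_p) * 1e-2)), lk = lk0),
        control = minpack.lm::nls.lm.control(maxiter = 500))
    log_k <- stats::coef(fitn)[["lk"]] / log(10)
    flagged <- FALSE
  }
  structure(list(log_k = log_k, per_level = per_level, method = method,
                 exponent = p, flagged = flagged),
            class = "selectivity_estimate")
}

#' @export
print.selectivity_estimate <- function(x, ...) {
  cat(sprintf("Selectivity estimate (%s): log k = %.3f%s\n", x$method,
              x$log_k, if (x$flagged) " [unidentifiable]" else ""))
  print(x$per_level, ...)
  invisible(x)
}

#' Slope reproducibility (% RSD)
#'
#' Relative standard deviation of calibration slopes across sessions,
#' `100 * sd(slopes) / |mean(slopes)|`.
#'
#' @param slopes numeric vector of session slopes, or a list of
#'   `calibration_fit` objects.
#' @return Percent RSD.
#' @export
slope_reproducibility <- function(slopes) {
  if (is.list(slopes))
    slopes <- vapply(slopes, function(f) f$slope, numeric(1))
  if (length(slopes) < 2) stop("need at least 2 sessions")
  100 * stats::sd(slopes) / abs(mean(slopes))
}

# Pick interferent levels for a selectivity experiment so the interference
# term comfortably exceeds the electrode's own background (crude design
# heuristic on the concentration scale; capped at the 1 M stock).
choose_selectivity_levels <- function(sensor, zi, zj) {
  k <- 10^sensor$log_k_pot[[1]]
  p <- zi / zj
  target <- max(30 * sensor$background_activity, 3e-5)
  c1 <- (target / k)^(1 / p)
  if (c1 >= 0.25) return(c(0.3, 1))
  c(c1, min(5 * c1, 1))
}

#' Characterize every electrode of a panel
#'
#' Runs, per electrode: a deep single-ion calibration (slope, detection
#' limit), mixed-solution selectivity runs against the other modelled ion,
#' and repeated short sessions for slope reproducibility. All experiments
#' are simulated from the panel itself; pass `noise_sd = 0` for noise-free
#' parameter recovery.
#'
#' @param panel an [et_panel()].
#' @param params an [activity_params()] object for the calibration regime
#'   (default: 0.05 M background electrolyte).
#' @param noise_sd reading-noise override in mV (default: each sensor's own).
#' @param seed integer seed (required when noise is active).
#' @param cal_conc calibration concentration grid.
#' @param n_sessions reproducibility sessions (set 0 to skip).
#' @return List with `table` (one row per electrode: slope, detection limit,
#'   log selectivity coefficient, slope % RSD) and `fits` (the per-electrode
#'   `calibration_fit` objects, used e.g. by [single_ise_baseline()]).
#' @export
characterize_array <- function(panel,
                               params = activity_params(background_ionic_strength = 0.05),
                               noise_sd = NULL, seed = NULL,
                               cal_conc = lgrid(1e-8, 1e-2, 18),
                               n_sessions = 5) {
  rows <- list(); fits <- list()
  seed_i <- 0L
  for (id in names(panel$sensors)) {
    sensor <- panel$sensors[[id]]
    zi <- panel$charges[[sensor$primary_ion]]
    seed_i <- seed_i + 1L
    s_cal <- if (is.null(seed)) NULL else seed + 10L * seed_i
    cal <- simulate_calibration(panel, id, conc = cal_conc, params = params,
                                noise_sd = noise_sd, seed = s_cal)
    fit <- fit_calibration(cal$E, cal$conc, charge = zi, params = params,
                           sensor_id = id)
    lod <- detection_limit(cal$E, cal$conc, charge = zi, params = params)
    interferent <- setdiff(names(panel$charges), sensor$primary_ion)[1]
    zj <- panel$charges[[interferent]]
    lvls <- choose_selectivity_levels(sensor, zi, zj)
    runs <- generate_selectivity_runs(panel, id, interferent, lvls,
                                      params = params)
    Em <- array_response(panel, runs, params = params, noise_sd = noise_sd,
                         seed = if (is.null(s_cal)) NULL else s_cal + 1L)
    sel <- selectivity_coefficient(Em[[id]],
                                   runs[[paste0("c_", sensor$primary_ion)]],
                                   runs[[paste0("c_", interferent)]],
                                   zi, zj, params = params, lod = lod)
    rsd <- if (n_sessions >= 2)
      slope_reproducibility(simulate_sessions(panel, id,
                                              n_sessions = n_sessions,
                                              params = params,
                                              seed = (seed %||% 1L) + 100L + seed_i))
    else NA_real_
    rows[[id]] <- data.frame(id = id, primary_ion = sensor$primary_ion,
                             slope = fit$slope, e0_hat = fit$e0_hat,
                             r2 = fit$r2, lod = lod,
                             interferent = interferent,
                             log_k_pot = sel$log_k, slope_rsd_pct = rsd,
                             stringsAsFactors = FALSE)
    fits[[id]] <- fit
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, fits = fits)
}
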