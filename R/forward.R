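# Scalar Nikolsky-Eisenmann law on the activity scale. `interference` is the
# already-summed selectivity-weighted interferent term.
.nikolsky <- function(e0, slope, a_primary, a_bg, interference = 0) {
  arg <- a_primary + a_bg + interference
  if (any(arg <= 0))
    stop("non-positive argument of the response logarithm")
  e0 + slope * log10(arg)
}

#' Electrode potential for one solution
#'
#' Evaluates the Nikolsky-Eisenmann response
#' \eqn{E = E^0 + s\log_{10}[a_i + a_{bg} + \sum_j k^{pot}_{i,j} a_j^{z_i/z_j}]}
#' with activities \eqn{a = \gamma c} from the configured activity model.
#' Charge ratios use signed charges, so for the anion pairs here the
#' exponents are positive (perchlorate primary with sulfide interferent gives
#' 1/2; sulfide primary with perchlorate interferent gives 2).
#'
#' @param sensor a [sensor_spec()].
#' @param conc named vector of molar concentrations; must include the
#'   sensor's primary ion (interferents absent from `conc` contribute 0).
#' @param charges named signed-charge vector (e.g. `panel$charges`).
#' @param params an [activity_params()] object.
#' @return Potential in mV.
#' @export
electrode_potential <- function(sensor, conc, charges,
                                params = activity_params()) {
  if (!sensor$primary_ion %in% names(conc))
    stop("solution does not declare the primary ion ", sensor$primary_ion)
  a <- activities(conc, charges, params)
  zi <- charges[[sensor$primary_ion]]
  interference <- 0
  for (j in names(sensor$log_k_pot)) {
    aj <- if (j %in% names(a)) a[[j]] else 0
    interference <- interference +
      10^sensor$log_k_pot[[j]] * aj^(zi / charges[[j]])
  }
  .nikolsky(sensor$e0, sensor$slope, a[[sensor$primary_ion]],
            sensor$background_activity, interference)
}

#' Array response over a sample table
#'
#' Evaluates every panel electrode on every sample row and optionally adds
#' seeded Gaussian reading noise. With all noise standard deviations at zero
#' (and `seed = NULL`) the result is deterministic and bit-reproducible.
#'
#' @param panel an [et_panel()].
#' @param samples a sample table with a `sample_id` column and one `c_<ion>`
#'   column per declared ion (mol/L).
#' @param params an [activity_params()] object describing the measurement
#'   regime (e.g. background electrolyte or none).
#' @param noise_sd optional scalar overriding every sensor's `noise_sd`
#'   (use 0 for noise-free responses).
#' @param seed integer seed; required whenever the effective noise is > 0.
#' @return A data frame: `sample_id` plus one mV column per electrode id.
#' @export
array_response <- function(panel, samples, params = activity_params(),
                           noise_sd = NULL, seed = NULL) {
  ions <- names(panel$charges)
  cols <- paste0("c_", ions)
  missing_cols <- setdiff(cols, names(samples))
  if (length(missing_cols))
    stop("sample table lacks column(s): ", paste(missing_cols, collapse = ", "))
  extra <- grep("^c_", names(samples), value = TRUE)
  if (length(setdiff(extra, cols)))
    stop("sample table references undeclared ion(s): ",
         paste(sub("^c_", "", setdiff(extra, cols)), collapse = ", "))
  n <- nrow(samples)
  conc_mat <- as.matrix(samples[, cols, drop = FALSE])
  colnames(conc_mat) <- ions
  E <- matrix(NA_real_, n, length(panel$sensors),
              dimnames = list(NULL, names(panel$sensors)))
  if (n > 0) {
    for (i in seq_len(n)) {
      cc <- conc_mat[i, ]
      for (s in names(panel$sensors))
        E[i, s] <- electrode_potential(panel$sensors[[s]], cc,
                                       panel$charges, params)
    }
  }
  sds <- vapply(panel$sensors, function(s) noise_sd %||% s$noise_sd,
                numeric(1))
  if (n > 0 && any(sds > 0)) {
    if (is.null(seed))
      stop("a seed is required when reading noise is enabled")
    noise <- with_seed(seed,
      matrix(stats::rnorm(n * length(sds)), n) %*% diag(sds, length(sds)))
    E <- E + noise
  }
  out <- data.frame(sample_id = if (n) samples$sample_id else character(0),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(E))
  rownames(out) <- NULL
  out
}
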