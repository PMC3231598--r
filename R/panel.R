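#' Declare an ionic species
#'
#' @param name identifier, e.g. `"ClO4"` or `"S"`.
#' @param charge signed integer charge; must be nonzero (perchlorate -1,
#'   sulfide -2).
#' @return An object of class `ion`.
#' @export
ion <- function(name, charge) {
  stopifnot(is.character(name), nchar(name) > 0,
            is.numeric(charge), charge == round(charge), charge != 0)
  structure(list(name = name, charge = as.integer(charge)), class = "ion")
}

#' Declare one ion-selective electrode
#'
#' Parameters of the Nikolsky-Eisenmann response law
#' \deqn{E = E^0 + s \log_{10}\!\big[a_i + a_{bg} +
#'   \textstyle\sum_j k^{pot}_{i,j} a_j^{z_i/z_j}\big]}
#' for a single electrode. The additive background activity `background_activity`
#' produces the low-concentration flattening of the calibration curve and is
#' what the IUPAC two-segment detection-limit construction recovers.
#'
#' @param id electrode identifier (e.g. `"P1"`).
#' @param primary_ion name of the primary ion.
#' @param e0 standard (intercept) potential in mV.
#' @param slope response slope in mV/decade (negative for anions).
#' @param log_k_pot named numeric vector of log10 potentiometric selectivity
#'   coefficients, one entry per interfering ion.
#' @param background_activity low-end background activity in mol/L (> 0);
#'   equals the electrode's detection limit on the activity scale.
#' @param noise_sd per-reading Gaussian measurement noise, mV.
#' @param drift_sd session-to-session standard-potential drift, mV.
#' @return An object of class `sensor_spec`.
#' @export
sensor_spec <- function(id, primary_ion, e0, slope, log_k_pot = numeric(),
                        background_activity, noise_sd = 0.5, drift_sd = 1.0) {
  stopifnot(is.character(id), is.character(primary_ion),
            is.numeric(slope), slope != 0,
            is.numeric(background_activity), background_activity > 0,
            noise_sd >= 0, drift_sd >= 0)
  if (length(log_k_pot) && is.null(names(log_k_pot)))
    stop("`log_k_pot` must be a named vector (interferent -> log10 k)")
  structure(list(id = id, primary_ion = primary_ion, e0 = e0, slope = slope,
                 log_k_pot = log_k_pot,
                 background_activity = background_activity,
                 noise_sd = noise_sd, drift_sd = drift_sd),
            class = "sensor_spec")
}

#' Assemble a sensor panel
#'
#' @param ions list of [ion()] objects; names must be unique.
#' @param sensors list of [sensor_spec()] objects; every primary ion and
#'   every selectivity key must be declared in `ions`.
#' @return An object of class `et_panel` with elements `ions`, `sensors` and
#'   the convenience named charge vector `charges`.
#' @export
et_panel <- function(ions, sensors) {
  ion_names <- vapply(ions, `[[`, character(1), "name")
  if (anyDuplicated(ion_names)) stop("ion names must be unique")
  charges <- vapply(ions, `[[`, numeric(1), "charge")
  names(charges) <- ion_names
  ids <- vapply(sensors, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("sensor ids must be unique")
  for (s in sensors) {
    if (!s$primary_ion %in% ion_names)
      stop("sensor ", s$id, ": undeclared primary ion ", s$primary_ion)
    bad <- setdiff(names(s$log_k_pot), ion_names)
    if (length(bad))
      stop("sensor ", s$id, ": undeclared interferent(s) ",
           paste(bad, collapse = ", "))
  }
  names(sensors) <- ids
  structure(list(ions = ions, sensors = sensors, charges = charges),
            class = "et_panel")
}

#' Default five-electrode sulfide/perchlorate panel
#'
#' The shipped panel encodes the response characteristics of the five
#' all-solid-state electrodes of the study array: the perchlorate electrode
#' P1, sulfide electrodes S1-S3 and the generic quaternary-ammonium
#' electrode G (modelled as sulfide-primary with its strong perchlorate
#' cross-response). Slopes, detection limits (used as background activities)
#' and log selectivity coefficients are the measured values; standard
#' potentials are arbitrary per-electrode constants since they cancel in
#' slope and selectivity estimation.
#'
#' @param noise_sd per-reading noise in mV applied to every electrode.
#' @param drift_sd session-to-session standard-potential drift in mV.
#' @return An `et_panel`.
#' @export
default_panel <- function(noise_sd = 0.5, drift_sd = 1.0) {
  et_panel(
    ions = list(ion("ClO4", -1), ion("S", -2)),
    sensors = list(
      sensor_spec("P1", "ClO4", e0 = 355, slope = -57.7,
                  log_k_pot = c(S = -1.96), background_activity = 5.2e-6,
                  noise_sd = noise_sd, drift_sd = drift_sd),
      sensor_spec("S1", "S", e0 = -120, slope = -33.3,
                  log_k_pot = c(ClO4 = -2.68), background_activity = 1.3e-5,
                  noise_sd = noise_sd, drift_sd = drift_sd),
      sensor_spec("S2", "S", e0 = -95, slope = -30.9,
                  log_k_pot = c(ClO4 = -3.23), background_activity = 9.8e-6,
                  noise_sd = noise_sd, drift_sd = drift_sd),
      sensor_spec("S3", "S", e0 = -60, slope = -28.9,
                  log_k_pot = c(ClO4 = -3.75), background_activity = 9.9e-6,
                  noise_sd = noise_sd, drift_sd = drift_sd),
      sensor_spec("G", "S", e0 = -150, slope = -44.3,
                  log_k_pot = c(ClO4 = 1.13), background_activity = 8.3e-6,
                  noise_sd = noise_sd, drift_sd = drift_sd)))
}

#' @export
print.et_panel <- function(x, ...) {
  cat("Sensor panel:", length(x$sensors), "electrodes,",
      length(x$ions), "ions (",
      paste(sprintf("%s %+d", names(x$charges), x$charges), collapse = ", "),
      ")\n")
  tab <- do.call(rbind, lapply(x$sensors, function(s) {
    ks <- if (length(s$log_k_pot))
      paste(sprintf("%s=%.2f", names(s$log_k_pot), s$log_k_pot),
            collapse = ", ") else "-"
    data.frame(id = s$id, primary = s$primary_ion, e0_mV = s$e0,
               slope = s$slope, a_bg = s$background_activity,
               log_k_pot = ks, noise_sd = s$noise_sd)
  }))
  rownames(tab) <- NULL
  print(tab, ...)
  invisible(x)
}

#' Read or write a sensor-panel file (YAML)
#'
#' The file layout has a top-level `ions` list (`name`, `charge`) and a
#' `sensors` list (`id`, `primary_ion`, `e0_mV`, `slope_mV_per_decade`,
#' `log_k_pot` map, `background_activity_M`, `noise_sd_mV`, `drift_sd_mV`).
#' A copy of the default panel ships as
#' `system.file("extdata", "panel_default.yaml", package = "etongue")`.
#'
#' @param path file path.
#' @return `read_panel` returns an `et_panel`; `write_panel` returns `path`
#'   invisibly.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$ions) || is.null(y$sensors))
    stop("panel file must declare `ions` and `sensors`: ", path)
  ions <- lapply(y$ions, function(i) ion(i$name, i$charge))
  sensors <- lapply(y$sensors, function(s) {
    k <- unlist(s$log_k_pot) %||% numeric()
    sensor_spec(s$id, s$primary_ion, e0 = s$e0_mV,
                slope = s$slope_mV_per_decade, log_k_pot = k,
                background_activity = s$background_activity_M,
                noise_sd = s$noise_sd_mV %||% 0.5,
                drift_sd = s$drift_sd_mV %||% 1.0)
  })
  et_panel(ions, sensors)
}

#' @rdname read_panel
#' @param panel an `et_panel` to serialize.
#' @export
write_panel <- function(panel, path) {
  y <- list(
    ions = lapply(panel$ions, function(i) list(name = i$name, charge = i$charge)),
    sensors = lapply(unname(panel$sensors), function(s)
      list(id = s$id, primary_ion = s$primary_ion, e0_mV = s$e0,
           slope_mV_per_decade = s$slope,
           log_k_pot = as.list(s$log_k_pot),
           background_activity_M = s$background_activity,
           noise_sd_mV = s$noise_sd, drift_sd_mV = s$drift_sd)))
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}
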