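#' Define a cumulative standard-addition sequence
#'
#' @param id sequence identifier.
#' @param steps data frame with one row per addition step and, per ion
#'   `<x>`, columns `v_<x>` (added volume, L; 0 when that ion is not added)
#'   and `s_<x>` (stock concentration, mol/L).
#' @param initial_volume starting volume in L.
#' @param initial_concentrations named vector of starting molar
#'   concentrations (ions absent start at 0).
#' @return An object of class `addition_sequence`.
#' @export
addition_sequence <- function(id, steps, initial_volume = 0.025,
                              initial_concentrations = numeric()) {
  stopifnot(is.data.frame(steps), nrow(steps) >= 1, initial_volume > 0)
  vcols <- grep("^v_", names(steps), value = TRUE)
  if (!length(vcols)) stop("steps must contain v_<ion> columns")
  for (vc in vcols) {
    sc <- sub("^v_", "s_", vc)
    if (!sc %in% names(steps)) stop("missing stock column ", sc)
    if (any(steps[[vc]] < 0)) stop("added volumes must be >= 0")
  }
  structure(list(id = id, steps = steps, initial_volume = initial_volume,
                 initial_concentrations = initial_concentrations),
            class = "addition_sequence")
}

#' Execute a cumulative-addition sequence by mass balance
#'
#' After each step, for every ion,
#' \eqn{c_{new} = (c_{old} V_{old} + c_{stock} v_{add}) / (V_{old} + \sum v_{add})};
#' additions of one ion dilute all others. One sample row is produced per
#' step; total moles of every ion are conserved exactly up to floating-point
#' arithmetic.
#'
#' @param seq an [addition_sequence()].
#' @return A sample table: `sample_id`, `sequence_id`, `step`, one `c_<ion>`
#'   column per ion, `volume` (L) and `role` (NA, to be assigned later).
#' @export
cumulative_additions <- function(seq) {
  stopifnot(inherits(seq, "addition_sequence"))
  steps <- seq$steps
  ions <- sub("^v_", "", grep("^v_", names(steps), value = TRUE))
  ions <- union(ions, names(seq$initial_concentrations))
  V <- seq$initial_volume
  conc <- stats::setNames(rep(0, length(ions)), ions)
  init <- seq$initial_concentrations
  conc[names(init)] <- init
  n <- nrow(steps)
  out <- matrix(NA_real_, n, length(ions), dimnames = list(NULL, ions))
  vol <- numeric(n)
  for (k in seq_len(n)) {
    moles <- conc * V
    added_V <- 0
    for (x in ions) {
      vc <- paste0("v_", x)
      if (vc %in% names(steps) && steps[[vc]][k] > 0) {
        moles[x] <- moles[x] + steps[[paste0("s_", x)]][k] * steps[[vc]][k]
        added_V <- added_V + steps[[vc]][k]
      }
    }
    V <- V + added_V
    conc <- moles / V
    out[k, ] <- conc
    vol[k] <- V
  }
  res <- data.frame(sample_id = sprintf("seq%s_%02d", seq$id, seq_len(n)),
                    sequence_id = rep(seq$id, n), step = seq_len(n),
                    stringsAsFactors = FALSE)
  for (x in ions) res[[paste0("c_", x)]] <- out[, x]
  res$volume <- vol
  res$role <- NA_character_
  res
}

# Volumes to add in one step so that the listed target concentrations are hit
# exactly after mutual dilution. `targets`/`stocks` are named over the added
# ions; returns named volumes (L).
solve_step_volumes <- function(V, conc, targets, stocks) {
  ions <- names(targets)
  if (length(ions) == 1) {
    x <- ions[1]
    c0 <- conc[[x]] %||% 0
    if (stocks[[x]] <= targets[[x]])
      stop("stock ", stocks[[x]], " M cannot reach target ", targets[[x]], " M")
    v <- V * (targets[[x]] - c0) / (stocks[[x]] - targets[[x]])
    if (v <= 0) stop("target below current concentration; dilution-only steps unsupported")
    return(stats::setNames(v, x))
  }
  if (length(ions) != 2) stop("at most two ions per combined step")
  a <- ions[1]; b <- ions[2]
  ca <- conc[[a]] %||% 0; cb <- conc[[b]] %||% 0
  A <- matrix(c(stocks[[a]] - targets[[a]], -targets[[a]],
                -targets[[b]], stocks[[b]] - targets[[b]]),
              2, 2, byrow = TRUE)
  rhs <- c((targets[[a]] - ca) * V, (targets[[b]] - cb) * V)
  v <- solve(A, rhs)
  if (any(v <= 0)) stop("infeasible combined addition step")
  stats::setNames(v, ions)
}

# Pick the standard stock level for a target concentration: the weaker of the
# two shipped levels while targets are low, the stronger one afterwards.
pick_stock <- function(target, stocks, switch_at) {
  if (target < switch_at) stocks[1] else stocks[2]
}

#' Default two-ion experimental design configuration
#'
#' Seven cumulative-addition sequences whose step counts sum to 79 samples:
#' two single-ion sequences along the axes, one combined equal-concentration
#' diagonal, two sequences adding one ion over a fixed level of the other,
#' and two combined unequal-ratio sequences filling the interior. Each ion
#' uses two standard levels (1e-3 and 1e-2 M, drawn from the 1e-4..1 M stock
#' series) and spans 5.0e-6 to 3.3e-4 M.
#'
#' @param initial_volume starting vessel volume (L).
#' @return A config list consumed by [generate_design()].
#' @export
default_design_config <- function(initial_volume = 0.025) {
  list(
    initial_volume = initial_volume,
    stocks = c(1e-3, 1e-2),
    stock_switch = 4e-5,
    range = c(5.0e-6, 3.3e-4),
    sequences = list(
      list(id = 1, targets = list(ClO4 = lgrid(5.0e-6, 3.3e-4, 12))),
      list(id = 2, targets = list(S = lgrid(5.0e-6, 3.3e-4, 12))),
      list(id = 3, targets = list(ClO4 = lgrid(5.0e-6, 3.3e-4, 12),
                                  S = lgrid(5.0e-6, 3.3e-4, 12))),
      list(id = 4, initial = c(S = 1.0e-4),
           targets = list(ClO4 = lgrid(8.0e-6, 3.0e-4, 11))),
      list(id = 5, initial = c(ClO4 = 1.0e-4),
           targets = list(S = lgrid(8.0e-6, 3.0e-4, 11))),
      list(id = 6, targets = list(ClO4 = lgrid(8.0e-6, 2.8e-4, 11),
                                  S = lgrid(5.5e-6, 1.3e-4, 11))),
      list(id = 7, targets = list(S = lgrid(8.0e-6, 2.8e-4, 10),
                                  ClO4 = lgrid(5.5e-6, 1.3e-4, 10)))))
}

#' Build the addition sequences of a design configuration
#'
#' Solves, step by step, the microvolumes of standard needed to hit each
#' sequence's target concentrations exactly (accounting for mutual dilution
#' in combined additions).
#'
#' @param config a design configuration, see [default_design_config()].
#' @return List of [addition_sequence()] objects.
#' @export
design_sequences <- function(config = default_design_config()) {
  lapply(config$sequences, function(sq) {
    ions <- names(sq$targets)
    n <- unique(vapply(sq$targets, length, integer(1)))
    if (length(n) != 1) stop("sequence ", sq$id, ": unequal target lengths")
    V <- config$initial_volume
    conc <- stats::setNames(rep(0, 2), c("ClO4", "S"))
    init <- sq$initial %||% numeric()
    conc[names(init)] <- init
    steps <- data.frame(matrix(0, n, 0))
    for (x in c("ClO4", "S")) {
      steps[[paste0("v_", x)]] <- rep(0, n)
      steps[[paste0("s_", x)]] <- rep(config$stocks[1], n)
    }
    for (k in seq_len(n)) {
      tg <- vapply(sq$targets, `[[`, numeric(1), k)
      names(tg) <- ions
      st <- vapply(tg, pick_stock, numeric(1),
                   stocks = config$stocks, switch_at = config$stock_switch)
      v <- solve_step_volumes(V, conc, as.list(tg), as.list(st))
      for (x in ions) {
        steps[[paste0("v_", x)]][k] <- v[[x]]
        steps[[paste0("s_", x)]][k] <- st[[x]]
      }
      # advance the exact mass balance
      moles <- conc * V
      moles[ions] <- moles[ions] + st * v
      V <- V + sum(v)
      conc <- moles / V
    }
    addition_sequence(sq$id, steps, config$initial_volume, init)
  })
}

#' Generate the two-ion mixture design
#'
#' Runs every configured addition sequence through the mass balance and
#' stacks the rows into the 79-sample design table. Nonzero concentrations
#' are validated against the declared range and both ions must attain the
#' range extremes.
#'
#' @param config a design configuration, see [default_design_config()].
#' @return Sample table with 79 rows (`role` = NA, assigned by
#'   [split_train_test()]).
#' @export
generate_design <- function(config = default_design_config()) {
  seqs <- design_sequences(config)
  tab <- do.call(rbind, lapply(seqs, cumulative_additions))
  tab$sample_id <- sprintf("d%02d", seq_len(nrow(tab)))
  rng <- config$range
  for (x in c("ClO4", "S")) {
    v <- tab[[paste0("c_", x)]]
    pos <- v[v > 0]
    if (any(pos < rng[1] * (1 - 1e-9)) || any(pos > rng[2] * (1 + 1e-9)))
      stop("config error: sequence concentrations leave the design range")
    if (min(pos) > rng[1] * (1 + 1e-9) || max(pos) < rng[2] * (1 - 1e-9))
      stop("config error: design does not span the declared range for ", x)
  }
  tab
}

#' Split the design into training and test subsets
#'
#' Any sample attaining a per-ion extreme (the minimum -- including the zero
#' rows of single-ion sequences -- the smallest nonzero value, or the
#' maximum of either ion) is forced into the training subset so the test
#' subset never requires extrapolation; the remaining rows are assigned by a
#' seeded random draw.
#'
#' @param table design sample table.
#' @param seed integer seed for the random assignment.
#' @param n_test number of test samples (default 20, leaving 59 for
#'   training with the default design).
#' @return The table with `role` set to `"train"` or `"test"`.
#' @export
split_train_test <- function(table, seed, n_test = 20) {
  n <- nrow(table)
  forced <- rep(FALSE, n)
  near <- function(v, t) abs(v - t) <= 1e-9 * max(abs(t), 1e-300)
  for (x in grep("^c_", names(table), value = TRUE)) {
    v <- table[[x]]
    lims <- c(min(v), max(v))
    if (any(v > 0)) lims <- c(lims, min(v[v > 0]))
    for (t in lims)
      forced <- forced | (if (t == 0) v == 0 else near(v, t))
  }
  free <- which(!forced)
  if (length(free) < n_test)
    stop("split error: fewer assignable rows (", length(free),
         ") than requested test samples (", n_test, ")")
  test_idx <- with_seed(seed, sample(free, n_test))
  table$role <- "train"
  table$role[test_idx] <- "test"
  table
}

#' Generate spiked application samples
#'
#' Emulates the evaluation of wastewater-like samples: per-sample baseline
#' concentrations are drawn uniformly from `baseline_range` for each ion,
#' then both ions are spiked from a 0.01 M standard through the
#' cumulative-addition mass balance to a fixed ladder of target levels, the
#' last one the 5.0e-4 M maximum.
#'
#' @param n number of application samples (default 6).
#' @param baseline_range per-ion uniform range of the unspiked sample, mol/L.
#' @param spike_targets common concentration ladder reached by the spikes.
#' @param stock spike standard concentration, mol/L.
#' @param initial_volume sample volume before spiking, L.
#' @param seed integer seed for the baseline draw.
#' @return Sample table with one baseline row (step 0) and one row per
#'   spike level for each sample; `role` = `"application"`.
#' @export
generate_spiked_samples <- function(n = 6,
                                    baseline_range = c(0.3e-6, 3.4e-5),
                                    spike_targets = c(5e-5, 1.2e-4, 2.5e-4, 5.0e-4),
                                    stock = 0.01, initial_volume = 0.025,
                                    seed) {
  stopifnot(n >= 1, baseline_range[1] > 0,
            baseline_range[2] > baseline_range[1],
            all(diff(spike_targets) > 0),
            max(spike_targets) <= 5.0e-4 * (1 + 1e-12),
            min(spike_targets) > baseline_range[2])
  base <- with_seed(seed,
    matrix(stats::runif(2 * n, baseline_range[1], baseline_range[2]), n, 2,
           dimnames = list(NULL, c("ClO4", "S"))))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    V <- initial_volume
    conc <- base[i, ]
    rows <- data.frame(sample_id = sprintf("w%d_s0", i),
                       sequence_id = sprintf("w%d", i), step = 0,
                       c_ClO4 = conc[["ClO4"]], c_S = conc[["S"]],
                       volume = V, role = "application",
                       stringsAsFactors = FALSE)
    for (k in seq_along(spike_targets)) {
      tg <- list(ClO4 = spike_targets[k], S = spike_targets[k])
      v <- solve_step_volumes(V, as.list(conc), tg,
                              list(ClO4 = stock, S = stock))
      moles <- conc * V + stock * v[c("ClO4", "S")]
      V <- V + sum(v)
      conc <- moles / V
      rows <- rbind(rows, data.frame(
        sample_id = sprintf("w%d_s%d", i, k),
        sequence_id = sprintf("w%d", i), step = k,
        c_ClO4 = conc[["ClO4"]], c_S = conc[["S"]],
        volume = V, role = "application", stringsAsFactors = FALSE))
    }
    out[[i]] <- rows
  }
  do.call(rbind, out)
}

#' Generate mixed-solution selectivity runs
#'
#' For each fixed interferent level, builds a primary-ion calibration series
#' spanning several decades around the expected response-flattening point
#' \eqn{a_{bg} + k^{pot} a_j^{z_i/z_j}} (computed from the generating sensor
#' parameters), as used by the fixed-interference selectivity method.
#'
#' @param panel an [et_panel()].
#' @param sensor_id electrode to probe.
#' @param interferent name of the interfering ion.
#' @param fixed_levels molar interferent concentrations, one run per level
#'   (a level of 0 degenerates to a plain calibration).
#' @param params an [activity_params()] object for the run regime.
#' @param n_points primary-ion grid size per run.
#' @param decades_below,decades_above extent of the primary grid around the
#'   expected flattening concentration, in decades.
#' @return Sample table with `c_<primary>` varying and `c_<interferent>`
#'   constant within each run (`sequence_id` identifies the run).
#' @export
generate_selectivity_runs <- function(panel, sensor_id, interferent,
                                      fixed_levels,
                                      params = activity_params(),
                                      n_points = 12, decades_below = 2.5,
                                      decades_above = 1.5) {
  if (!length(fixed_levels)) stop("`fixed_levels` must be nonempty")
  sensor <- panel$sensors[[sensor_id]]
  if (is.null(sensor)) stop("unknown sensor ", sensor_id)
  if (!interferent %in% names(panel$charges))
    stop("undeclared interferent ", interferent)
  zi <- panel$charges[[sensor$primary_ion]]
  zj <- panel$charges[[interferent]]
  out <- vector("list", length(fixed_levels))
  for (li in seq_along(fixed_levels)) {
    cj <- fixed_levels[li]
    conc_j <- stats::setNames(cj, interferent)
    aj <- if (cj > 0) activities(conc_j, panel$charges, params)[[interferent]] else 0
    k <- if (interferent %in% names(sensor$log_k_pot))
      10^sensor$log_k_pot[[interferent]] else 0
    flat_a <- sensor$background_activity + k * aj^(zi / zj)
    I0 <- ionic_strength(conc_j, panel$charges, params)
    flat_c <- flat_a / activity_coefficient(zi, I0, params)
    grid <- lgrid(flat_c / 10^decades_below, flat_c * 10^decades_above,
                  n_points)
    tab <- data.frame(
      sample_id = sprintf("sel_%s_%s_L%d_%02d", sensor_id, interferent, li,
                          seq_len(n_points)),
      sequence_id = sprintf("sel_%s_%s_L%d", sensor_id, interferent, li),
      step = seq_len(n_points), stringsAsFactors = FALSE)
    tab[[paste0("c_", sensor$primary_ion)]] <- grid
    tab[[paste0("c_", interferent)]] <- cj
    tab$role <- NA_character_
    out[[li]] <- tab
  }
  do.call(rbind, out)
}

#' Simulate a single-ion calibration series
#'
#' Builds a cumulative-addition sequence hitting the requested concentration
#' grid for the sensor's primary ion (standards chosen from the 1e-4..1 M
#' stock series), runs the mass balance and evaluates the electrode,
#' optionally with seeded reading noise. Calibrations default to the 0.05 M
#' background-electrolyte regime.
#'
#' @param panel an [et_panel()].
#' @param sensor_id electrode to calibrate.
#' @param conc target concentration grid (mol/L) of the primary ion.
#' @param params an [activity_params()] object (default: 0.05 M background).
#' @param noise_sd reading noise override in mV (default: the sensor's own).
#' @param seed integer seed, required if the effective noise is > 0.
#' @param e0_shift additive standard-potential offset in mV (session drift).
#' @return Data frame with columns `conc` (achieved mol/L) and `E` (mV).
#' @export
simulate_calibration <- function(panel, sensor_id, conc = lgrid(1e-8, 1e-3, 16),
                                 params = activity_params(background_ionic_strength = 0.05),
                                 noise_sd = NULL, seed = NULL, e0_shift = 0) {
  sensor <- panel$sensors[[sensor_id]]
  if (is.null(sensor)) stop("unknown sensor ", sensor_id)
  stopifnot(all(diff(conc) > 0), all(conc > 0))
  ionx <- sensor$primary_ion
  stocks_avail <- 10^(-4:0)
  V <- 0.025
  cc <- 0
  n <- length(conc)
  steps <- data.frame(v = rep(0, n), s = rep(0, n))
  names(steps) <- paste0(c("v_", "s_"), ionx)
  for (k in seq_len(n)) {
    st <- stocks_avail[min(findInterval(conc[k] * 100, stocks_avail,
                                        left.open = TRUE) + 1,
                           length(stocks_avail))]
    v <- solve_step_volumes(V, stats::setNames(list(cc), ionx),
                            stats::setNames(list(conc[k]), ionx),
                            stats::setNames(list(st), ionx))
    steps[[paste0("v_", ionx)]][k] <- v
    steps[[paste0("s_", ionx)]][k] <- st
    moles <- cc * V + st * v
    V <- V + v
    cc <- moles / V
  }
  seqn <- addition_sequence(paste0("cal_", sensor_id), steps, 0.025)
  tab <- cumulative_additions(seqn)
  achieved <- tab[[paste0("c_", ionx)]]
  sensor2 <- sensor
  sensor2$e0 <- sensor$e0 + e0_shift
  E <- vapply(achieved, function(ci)
    electrode_potential(sensor2, stats::setNames(ci, ionx), panel$charges,
                        params), numeric(1))
  sd_eff <- noise_sd %||% sensor$noise_sd
  if (sd_eff > 0) {
    if (is.null(seed)) stop("a seed is required when reading noise is enabled")
    E <- E + with_seed(seed, stats::rnorm(n, 0, sd_eff))
  }
  data.frame(conc = achieved, E = E)
}

#' Simulate repeated calibration sessions
#'
#' Emulates daily check calibrations: each session draws a standard-potential
#' offset from the sensor's `drift_sd` and fresh reading noise, then fits the
#' response slope over a short grid placed in the linear range. Used to
#' estimate slope reproducibility (% RSD).
#'
#' @param panel,sensor_id electrode to calibrate.
#' @param n_sessions number of sessions (default 5, i.e. five consecutive
#'   days).
#' @param conc session concentration grid; by default 5 points spanning two
#'   decades of the electrode's linear range (starting about one decade
#'   above its flattening concentration).
#' @param params an [activity_params()] object (default: 0.05 M background).
#' @param seed integer seed.
#' @return Numeric vector of fitted session slopes (mV/decade).
#' @export
simulate_sessions <- function(panel, sensor_id, n_sessions = 5,
                              conc = NULL,
                              params = activity_params(background_ionic_strength = 0.05),
                              seed) {
  stopifnot(n_sessions >= 2)
  sensor <- panel$sensors[[sensor_id]]
  if (is.null(sensor)) stop("unknown sensor ", sensor_id)
  zi <- panel$charges[[sensor$primary_ion]]
  if (is.null(conc)) {
    g_bg <- activity_coefficient(zi, params$background_ionic_strength, params)
    c_lo <- 12 * sensor$background_activity / g_bg
    conc <- lgrid(c_lo, 100 * c_lo, 5)
  }
  with_seed(seed, {
    vapply(seq_len(n_sessions), function(i) {
      shift <- stats::rnorm(1, 0, sensor$drift_sd)
      cal <- simulate_calibration(panel, sensor_id, conc = conc,
                                  params = params, noise_sd = 0,
                                  e0_shift = shift)
      cal$E <- cal$E + stats::rnorm(nrow(cal), 0, sensor$noise_sd)
      # the session grid is placed inside the linear range, so the daily
      # check uses a plain OLS slope over the whole grid
      aa <- primary_activities(cal$conc, zi, params)
      unname(stats::coef(stats::lm(cal$E ~ log10(aa)))[2])
    }, numeric(1))
  })
}
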