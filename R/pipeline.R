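#' Pipeline configuration
#'
#' Collects every stage's settings for [run_pipeline()]. One master seed
#' passed to `run_pipeline()` deterministically derives all stage seeds.
#'
#' @param design design configuration, see [default_design_config()].
#' @param noise_sd per-reading noise in mV applied to every electrode
#'   (0.5 by default; set 0 for a noise-free run).
#' @param background_I_calibration ionic strength of the calibration
#'   background electrolyte, mol/L (0.05 M lithium acetate regime).
#' @param background_I_mixtures ionic-strength background of the mixture and
#'   application measurements (0: no background or buffer).
#' @param hidden,transfer inverse-model architecture (default 8 `tansig`
#'   hidden units).
#' @param control an [et_control()] list (default: Bayesian regularisation,
#'   5 restarts).
#' @param n_test test-subset size for [split_train_test()].
#' @param n_application number of spiked application samples.
#' @param spike_targets spike concentration ladder, mol/L.
#' @param baseline_electrodes named character vector designating the
#'   single-electrode baseline per ion.
#' @param eval_min_conc application rows enter the aggregate error and the
#'   paired t test only when the expected concentration exceeds this (mol/L).
#' @param n_sessions reproducibility sessions per electrode (0 skips).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(design = default_design_config(),
                            noise_sd = 0.5,
                            background_I_calibration = 0.05,
                            background_I_mixtures = 0,
                            hidden = 8, transfer = "tansig",
                            control = et_control(),
                            n_test = 20, n_application = 6,
                            spike_targets = c(5e-5, 1.2e-4, 2.5e-4, 5.0e-4),
                            baseline_electrodes = c(ClO4 = "P1", S = "S3"),
                            eval_min_conc = 1e-5,
                            n_sessions = 5) {
  structure(list(design = design, noise_sd = noise_sd,
                 background_I_calibration = background_I_calibration,
                 background_I_mixtures = background_I_mixtures,
                 hidden = hidden, transfer = transfer, control = control,
                 n_test = n_test, n_application = n_application,
                 spike_targets = spike_targets,
                 baseline_electrodes = baseline_electrodes,
                 eval_min_conc = eval_min_conc, n_sessions = n_sessions),
            class = "pipeline_config")
}

#' Run the full electronic-tongue study pipeline
#'
#' Simulate, characterise, train and evaluate in one call:
#' \enumerate{
#'   \item characterise every electrode (slope, detection limit, selectivity,
#'     slope reproducibility) from simulated calibrations;
#'   \item generate the 79-sample two-ion design, split it 59/20 and measure
#'     the array response (mixture regime, seeded noise);
#'   \item train the Bayesian-regularised inverse model (best of the
#'     configured restarts);
#'   \item generate spiked application samples, predict them with the model
#'     and with the designated single-electrode baselines;
#'   \item evaluate: RMSE, obtained-vs-expected regressions, percentage
#'     relative errors for both methods, paired t tests against the nominal
#'     concentrations.
#' }
#' With `outdir` set, all tables are written as full-precision CSV, the
#' model as JSON and a small JSON run log (seed, package version); the whole
#' bundle is regenerable from `(config, seed)` alone.
#'
#' @param panel an [et_panel()] (default [default_panel()]).
#' @param config a [pipeline_config()].
#' @param seed master seed; all stage seeds derive from it.
#' @param outdir optional output directory (created if needed).
#' @param make_plots write obtained-vs-expected and error-bar PDF figures
#'   into `outdir`.
#' @return A list (invisible when writing files) with components
#'   `characterization`, `design`, `potentials`, `model`, `application` and
#'   `evaluation`.
#' @export
run_pipeline <- function(panel = default_panel(), config = pipeline_config(),
                         seed = 1, outdir = NULL, make_plots = FALSE) {
  seeds <- derive_seeds(seed)
  act_cal <- activity_params(background_ionic_strength = config$background_I_calibration)
  act_mix <- activity_params(background_ionic_strength = config$background_I_mixtures)

  ## 1. per-electrode characterisation table
  char <- characterize_array(panel, params = act_cal,
                             noise_sd = config$noise_sd,
                             seed = seeds$characterization,
                             n_sessions = config$n_sessions)

  ## 2. design, split, array response
  design <- generate_design(config$design)
  design <- split_train_test(design, seed = seeds$split,
                             n_test = config$n_test)
  potentials <- array_response(panel, design, params = act_mix,
                               noise_sd = config$noise_sd,
                               seed = seeds$array_noise)
  sensor_ids <- names(panel$sensors)
  tr <- design$role == "train"
  conc_cols <- paste0("c_", names(panel$charges))
  x_train <- as.matrix(potentials[tr, sensor_ids])
  y_train <- as.matrix(design[tr, conc_cols])
  colnames(y_train) <- names(panel$charges)
  x_test <- as.matrix(potentials[!tr, sensor_ids])
  y_test <- as.matrix(design[!tr, conc_cols])
  colnames(y_test) <- names(panel$charges)

  ## 3. inverse model
  model <- et_fit(x_train, y_train, hidden = config$hidden,
                  transfer = config$transfer, x_test = x_test,
                  y_test = y_test, control = config$control,
                  seed = seeds$ann)

  ## 4. application samples: electronic tongue vs single-electrode baseline
  app <- generate_spiked_samples(n = config$n_application,
                                 spike_targets = config$spike_targets,
                                 seed = seeds$spike)
  app_pot <- array_response(panel, app, params = act_mix,
                            noise_sd = config$noise_sd,
                            seed = seeds$spike_noise)
  pred_et <- suppressWarnings(predict(model, as.matrix(app_pot[, sensor_ids])))
  expected <- as.matrix(app[, conc_cols])
  colnames(expected) <- names(panel$charges)
  pred_base <- expected * NA
  for (ionx in names(config$baseline_electrodes)) {
    el <- config$baseline_electrodes[[ionx]]
    pred_base[, ionx] <- single_ise_baseline(app_pot[[el]], char$fits[[el]],
                                             charge = panel$charges[[ionx]],
                                             params = act_mix)
  }

  ## 5. evaluation
  pred_train <- fitted(model)
  pred_test <- suppressWarnings(predict(model, x_test))
  regressions <- list()
  for (subset in c("train", "test")) {
    pr <- if (subset == "train") pred_train else pred_test
    yy <- if (subset == "train") y_train else y_test
    for (ionx in colnames(yy))
      regressions[[paste(subset, ionx, sep = "_")]] <-
        comparison_regression(pr[, ionx], yy[, ionx])
  }
  keep <- expected > config$eval_min_conc
  err_et <- relative_errors(pred_et, expected)
  err_base <- relative_errors(pred_base, expected)
  agg <- function(err, ionx) {
    ps <- err$per_sample
    mean(ps$rel_err_pct[ps$ion == ionx & !is.na(ps$rel_err_pct) &
                          ps$expected > config$eval_min_conc])
  }
  ions <- names(panel$charges)
  agg_et <- vapply(ions, function(i) agg(err_et, i), numeric(1))
  agg_base <- vapply(ions, function(i) agg(err_base, i), numeric(1))
  pooled_et <- mean(err_et$per_sample$rel_err_pct[
    !is.na(err_et$per_sample$rel_err_pct) &
      err_et$per_sample$expected > config$eval_min_conc])
  pooled_base <- mean(err_base$per_sample$rel_err_pct[
    !is.na(err_base$per_sample$rel_err_pct) &
      err_base$per_sample$expected > config$eval_min_conc])
  # paired t test per ion over per-sample mean predictions (rows above the
  # evaluation threshold), df = n_application - 1
  t_tests <- list()
  for (ionx in ions) {
    pm <- tapply(seq_len(nrow(app)), app$sequence_id, function(idx) {
      use <- idx[expected[idx, ionx] > config$eval_min_conc]
      c(pred = mean(pred_et[use, ionx]), nom = mean(expected[use, ionx]))
    })
    pm <- do.call(rbind, pm)
    t_tests[[ionx]] <- paired_t_test(pm[, "pred"], pm[, "nom"])
  }

  result <- list(
    panel = panel, config = config, seed = seed, seeds = seeds,
    characterization = char$table, calibration_fits = char$fits,
    design = design, potentials = potentials, model = model,
    application = list(samples = app, potentials = app_pot,
                       predicted_et = pred_et,
                       predicted_baseline = pred_base,
                       expected = expected),
    evaluation = list(
      rmse_train = rmse(pred_train, y_train),
      rmse_test = rmse(pred_test, y_test),
      regressions = regressions,
      errors_et = err_et, errors_baseline = err_base,
      mean_rel_err_et = agg_et, mean_rel_err_baseline = agg_base,
      pooled_rel_err_et = pooled_et, pooled_rel_err_baseline = pooled_base,
      t_tests = t_tests))

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_panel(panel, file.path(outdir, "panel.yaml"))
    write_et_csv(char$table, file.path(outdir, "characterization.csv"))
    write_et_csv(design, file.path(outdir, "design.csv"))
    write_et_csv(potentials, file.path(outdir, "potentials.csv"))
    write_et_csv(app, file.path(outdir, "application_samples.csv"))
    write_et_csv(app_pot, file.path(outdir, "application_potentials.csv"))
    write_et_csv(cbind(data.frame(sample_id = app$sample_id),
                       as.data.frame(pred_et),
                       stats::setNames(as.data.frame(pred_base),
                                       paste0(colnames(pred_base), "_baseline"))),
                 file.path(outdir, "application_predictions.csv"))
    write_et_csv(err_et$per_sample, file.path(outdir, "errors_et.csv"))
    write_et_csv(err_base$per_sample, file.path(outdir, "errors_baseline.csv"))
    reg_tab <- do.call(rbind, lapply(names(regressions), function(nm) {
      r <- regressions[[nm]]
      data.frame(comparison = nm, slope = r$slope,
                 slope_lo = r$slope_ci[1], slope_hi = r$slope_ci[2],
                 intercept = r$intercept, intercept_lo = r$intercept_ci[1],
                 intercept_hi = r$intercept_ci[2], r = r$r, n = r$n)
    }))
    write_et_csv(reg_tab, file.path(outdir, "comparison_regressions.csv"))
    write_et_model(model, file.path(outdir, "model.json"))
    log <- list(seed = seed, stage_seeds = seeds,
                package_version = as.character(utils::packageVersion("etongue")),
                r_version = R.version.string,
                timestamp = format(Sys.time(), tz = "UTC"),
                mean_rel_err_et = as.list(agg_et),
                mean_rel_err_baseline = as.list(agg_base),
                t_stats = lapply(t_tests, function(tt)
                  list(t = tt$t, df = tt$df, critical = tt$critical)))
    jsonlite::write_json(log, file.path(outdir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (make_plots) {
      grDevices::pdf(file.path(outdir, "model_fit.pdf"), width = 9, height = 4.5)
      plot(model)
      grDevices::dev.off()
      grDevices::pdf(file.path(outdir, "application_errors.pdf"),
                     width = 7, height = 4.5)
      bar <- rbind(ET = agg_et, single_ISE = agg_base)
      graphics::barplot(bar, beside = TRUE, ylab = "mean relative error / %",
                        legend.text = rownames(bar))
      grDevices::dev.off()
    }
    return(invisible(result))
  }
  result
}
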