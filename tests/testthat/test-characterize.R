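test_that("noise-free calibrations recover every generating panel parameter", {
  panel <- quiet_panel()
  prm <- act_bg(0.05)
  ch <- characterize_array(panel, params = prm, noise_sd = 0, n_sessions = 0)
  for (i in seq_len(nrow(ch$table))) {
    sn <- panel$sensors[[ch$table$id[i]]]
    expect_equal(ch$table$slope[i], sn$slope, tolerance = 0.1 / abs(sn$slope))
    expect_lt(abs(ch$table$lod[i] - sn$background_activity) /
                sn$background_activity, 0.05)
    expect_lt(abs(ch$table$log_k_pot[i] - sn$log_k_pot[[1]]), 0.05)
    expect_gt(ch$table$r2[i], 0.9999)
  }
})

test_that("two-point Nernstian data give the slope exactly", {
  prm <- activity_params()
  conc <- c(1e-4, 1e-3)
  a <- etongue:::primary_activities(conc, -1, prm)
  E <- 150 - 59.2 * log10(a)
  f <- fit_calibration(E, conc, charge = -1, params = prm)
  expect_equal(f$slope, -59.2, tolerance = 1e-12)
  expect_equal(f$e0_hat, 150, tolerance = 1e-9)
})

test_that("the IUPAC construction is exact on an ideal two-segment series", {
  a <- lgrid(1e-8, 1e-2, 25)
  E <- 100 - 55 * log10(pmax(a, 1e-5))
  lc <- etongue:::lod_construction(E, a)
  expect_equal(lc$lod, 1e-5, tolerance = 1e-9)
  # doubling the background activity doubles the recovered detection limit
  panel <- quiet_panel()
  prm <- act_bg(0.05)
  lods <- vapply(c(1, 2), function(m) {
    p2 <- panel
    p2$sensors$P1$background_activity <- m * 5.2e-6
    cal <- simulate_calibration(p2, "P1", params = prm, noise_sd = 0)
    detection_limit(cal$E, cal$conc, charge = -1, params = prm)
  }, numeric(1))
  expect_equal(lods[2] / lods[1], 2, tolerance = 0.02)
  # a series entirely in the linear regime has no plateau to intersect
  a_lin <- lgrid(1e-4, 1e-2, 10)
  expect_error(etongue:::lod_construction(90 - 59 * log10(a_lin), a_lin),
               "estimation error")
})

test_that("slope and detection limit are invariant to standard-potential shifts", {
  panel <- quiet_panel()
  prm <- act_bg(0.05)
  cal <- simulate_calibration(panel, "S2", params = prm, noise_sd = 0)
  f0 <- fit_calibration(cal$E, cal$conc, charge = -2, params = prm)
  f1 <- fit_calibration(cal$E + 25, cal$conc, charge = -2, params = prm)
  expect_equal(f1$slope, f0$slope, tolerance = 1e-9)
  expect_equal(f1$e0_hat, f0$e0_hat + 25, tolerance = 1e-9)
  expect_equal(detection_limit(cal$E + 25, cal$conc, charge = -2, params = prm),
               detection_limit(cal$E, cal$conc, charge = -2, params = prm),
               tolerance = 1e-9)
})

test_that("fixed-interference and nonlinear-fit selectivity agree; zero selectivity is flagged", {
  panel <- quiet_panel()
  prm <- act_bg(0.05)
  for (id in c("P1", "S3")) {
    sn <- panel$sensors[[id]]
    zi <- panel$charges[[sn$primary_ion]]
    interf <- names(sn$log_k_pot)
    zj <- panel$charges[[interf]]
    cal <- simulate_calibration(panel, id, conc = lgrid(1e-8, 1e-2, 18),
                                params = prm, noise_sd = 0)
    lod <- detection_limit(cal$E, cal$conc, charge = zi, params = prm)
    lv <- if (id == "P1") c(1e-3, 1e-2) else c(0.3, 1)
    runs <- generate_selectivity_runs(panel, id, interf, lv, params = prm)
    E <- array_response(panel, runs, prm)
    cp <- runs[[paste0("c_", sn$primary_ion)]]
    cj <- runs[[paste0("c_", interf)]]
    s_fi <- selectivity_coefficient(E[[id]], cp, cj, zi, zj, params = prm,
                                    lod = lod)
    s_nl <- selectivity_coefficient(E[[id]], cp, cj, zi, zj, params = prm,
                                    lod = lod, method = "nonlinear_fit")
    expect_lt(abs(s_fi$log_k - sn$log_k_pot[[interf]]), 0.05)
    expect_lt(abs(s_fi$log_k - s_nl$log_k), 0.1)
  }
  # an electrode with no cross-response: flattening never exceeds its own
  # background, the estimate is flagged unidentifiable
  p2 <- quiet_panel()
  p2$sensors$P1$log_k_pot <- c(S = -30)
  runs <- generate_selectivity_runs(p2, "P1", "S", 1e-2, params = prm)
  E <- array_response(p2, runs, prm)
  cal <- simulate_calibration(p2, "P1", params = prm, noise_sd = 0)
  lod <- detection_limit(cal$E, cal$conc, charge = -1, params = prm)
  s0 <- selectivity_coefficient(E$P1, runs$c_ClO4, runs$c_S, -1, -2,
                                params = prm, lod = lod)
  expect_true(s0$flagged)
  expect_identical(s0$log_k, -Inf)
})

test_that("slope reproducibility follows its definition and lands near 1% with shipped noise", {
  expect_equal(slope_reproducibility(c(-57, -57, -57)), 0)
  expect_equal(slope_reproducibility(c(-57, -58, -59)), 100 * 1 / 58)
  expect_error(slope_reproducibility(-57), "2 sessions")
  panel <- default_panel()  # noise 0.5 mV, drift 1 mV
  rsd <- vapply(names(panel$sensors), function(id)
    slope_reproducibility(simulate_sessions(panel, id,
                                            seed = 300 + match(id, names(panel$sensors)))),
    numeric(1))
  expect_gt(mean(rsd), 0.4)
  expect_lt(mean(rsd), 1.6)
})
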