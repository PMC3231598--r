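test_that("rmse follows its definition and is permutation invariant", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  # pairs (0, 3e-5) and (4e-5, 0): sqrt((9 + 16)/2) * 1e-5
  expect_equal(rmse(c(0, 4e-5), c(3e-5, 0)), sqrt(12.5) * 1e-5)
  set.seed(2)
  a <- runif(10); b <- runif(10); o <- sample(10)
  expect_equal(rmse(a, b), rmse(a[o], b[o]))
  m <- rmse(cbind(ClO4 = a, S = b), cbind(ClO4 = b, S = a))
  expect_named(m, c("ClO4", "S", "pooled"))
  expect_error(rmse(1:3, 1:4), "mismatch")
})

test_that("comparison regression: ideal data and textbook formulas", {
  x <- c(1, 2, 3, 4, 5)
  cr <- comparison_regression(x, x)
  expect_equal(cr$slope, 1, tolerance = 1e-12)
  expect_equal(cr$intercept, 0, tolerance = 1e-12)
  expect_equal(cr$r, 1, tolerance = 1e-12)
  expect_true(cr$contains_ideal)

  # hand OLS with t-based intervals on a 4-point set
  ex <- c(1, 2, 3, 4); ob <- c(1.1, 1.9, 3.2, 3.9)
  cr <- comparison_regression(ob, ex)
  Sxx <- sum((ex - mean(ex))^2)
  b1 <- sum((ex - mean(ex)) * (ob - mean(ob))) / Sxx
  b0 <- mean(ob) - b1 * mean(ex)
  s2 <- sum((ob - b0 - b1 * ex)^2) / 2
  tq <- stats::qt(0.975, 2)
  expect_equal(cr$slope, b1)
  expect_equal(cr$intercept, b0)
  expect_equal(cr$slope_ci, b1 + c(-1, 1) * tq * sqrt(s2 / Sxx))
  expect_equal(cr$intercept_ci,
               b0 + c(-1, 1) * tq * sqrt(s2 * (1 / 4 + mean(ex)^2 / Sxx)))
  expect_equal(cr$r, stats::cor(ob, ex))
  expect_error(comparison_regression(c(1, 2, 3), c(2, 2, 2)), "variance")
})

test_that("single-electrode interpolation inverts its own forward response", {
  panel <- quiet_panel()
  prm_cal <- act_bg(0.05)
  prm_mix <- activity_params()
  cal <- simulate_calibration(panel, "P1", params = prm_cal, noise_sd = 0)
  fit <- fit_calibration(cal$E, cal$conc, charge = -1, params = prm_cal)
  # single-ion samples across four decades, measured in the mixture regime
  cc <- lgrid(1e-6, 1e-2, 9)
  E <- vapply(cc, function(ci)
    electrode_potential(panel$sensors$P1, c(ClO4 = ci, S = 0),
                        panel$charges, prm_mix), numeric(1))
  # identity holds well above the electrode's own background term
  keep <- cc > 2e-4
  got <- single_ise_baseline(E, fit, charge = -1, params = prm_mix)
  expect_equal(as.vector(got)[keep], cc[keep], tolerance = 0.02)

  # interferent with k-weighted activity equal to the primary activity:
  # the one-electrode reading overestimates by about a factor of two
  sn <- panel$sensors$P1
  c_i <- 1e-4
  I <- oracle_ionic_strength(c(c_i), c(-1), 0)
  a_i <- oracle_gamma(-1, I) * c_i
  # choose c_S so that 10^log_k * a_S^(1/2) = a_i  (iterate the ionic strength)
  c_S <- 1e-4
  for (it in 1:30) {
    I2 <- oracle_ionic_strength(c(c_i, c_S), c(-1, -2), 0)
    c_S <- (a_i / 10^sn$log_k_pot[["S"]])^2 / oracle_gamma(-2, I2)
  }
  E2 <- electrode_potential(sn, c(ClO4 = c_i, S = c_S), panel$charges,
                            prm_mix)
  got2 <- single_ise_baseline(E2, fit, charge = -1, params = prm_mix)
  expect_equal(as.vector(got2) / c_i, 2, tolerance = 0.06)

  # far outside the calibrated span the result carries an extrapolation flag
  flag <- attr(single_ise_baseline(fit$e0_hat + fit$slope * log10(1e-12),
                                   fit, -1, prm_mix), "extrapolated")
  expect_true(flag)
})

test_that("relative errors: arithmetic, exclusion of zero expectations, aggregation", {
  er <- relative_errors(c(1.05e-4, 2e-4), c(1e-4, 2e-4))
  expect_equal(er$per_sample$rel_err_pct, c(5, 0))
  expect_equal(unname(er$aggregate["pooled"]), 2.5)
  er2 <- relative_errors(cbind(A = c(1, 2), B = c(3, 1)),
                         cbind(A = c(1, 0), B = c(3, 2)))
  expect_identical(er2$n_excluded, 1L)
  expect_equal(unname(er2$aggregate["B"]), mean(c(0, 50)))
  er3 <- relative_errors(c(1.2, 0.9), c(1, 1), aggregate = "median")
  expect_equal(unname(er3$aggregate["pooled"]), 15)
})

test_that("paired t test matches the direct formula and the stats oracle", {
  expect_equal(paired_t_test(c(1, 2, 3), c(1, 2, 3))$t, 0)
  tt <- paired_t_test(rnorm(6), rnorm(6))
  expect_identical(tt$df, 5L)
  expect_equal(round(tt$critical, 2), 2.57)
  # three-pair hand computation
  d <- c(0.2, -0.1, 0.4)
  th <- paired_t_test(c(1.2, 1.9, 3.4), c(1, 2, 3))
  expect_equal(th$t, mean(d) / (sd(d) / sqrt(3)))
  # independent oracle on random small datasets
  set.seed(33)
  for (i in 1:10) {
    n <- sample(4:9, 1)
    a <- rnorm(n); b <- rnorm(n)
    got <- paired_t_test(a, b)
    ref <- stats::t.test(a, b, paired = TRUE)
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(got$p, ref$p.value, tolerance = 1e-9)
  }
  # zero-variance nonzero difference: infinite statistic, reported as such
  ti <- paired_t_test(c(2, 3, 4), c(1, 2, 3))
  expect_identical(ti$t, Inf)
  expect_true(ti$significant)
})

test_that("expected prediction error never decreases with reading noise", {
  panel <- quiet_panel()
  prm <- activity_params()
  d <- split_train_test(generate_design(), seed = 71)
  ids <- names(panel$sensors)
  tr <- d$role == "train"
  yv <- as.matrix(d[, c("c_ClO4", "c_S")]); colnames(yv) <- c("ClO4", "S")
  pot <- array_response(panel, d, prm)
  m <- et_fit(as.matrix(pot[tr, ids]), yv[tr, ],
              control = et_control(n_restarts = 1, max_epochs = 150),
              seed = 5)
  app <- generate_spiked_samples(seed = 61)
  exp_m <- as.matrix(app[, c("c_ClO4", "c_S")]); colnames(exp_m) <- c("ClO4", "S")
  levels <- c(0, 0.5, 1, 2, 4)
  mean_err <- vapply(seq_along(levels), function(i) {
    errs <- vapply(1:5, function(r) {
      ap <- array_response(default_panel(noise_sd = levels[i]), app, prm,
                           seed = 900 + 10 * i + r)
      pr <- suppressWarnings(predict(m, as.matrix(ap[, ids])))
      ps <- relative_errors(pr, exp_m)$per_sample
      mean(ps$rel_err_pct[!is.na(ps$rel_err_pct) & ps$expected > 1e-5])
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_gte(stats::cor(levels, mean_err, method = "spearman"), 0)
})
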