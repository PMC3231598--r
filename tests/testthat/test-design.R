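test_that("cumulative additions follow the exact mass balance", {
  # 25 mL water + 25 mL of 1e-4 M stock -> 5e-5 M
  sq <- addition_sequence("x", data.frame(v_ClO4 = 0.025, s_ClO4 = 1e-4),
                          initial_volume = 0.025)
  expect_equal(cumulative_additions(sq)$c_ClO4, 5e-5)

  # zero-concentration stock is a pure dilution of everything present
  sq2 <- addition_sequence("x", data.frame(v_ClO4 = 0.025, s_ClO4 = 0),
                           initial_volume = 0.025,
                           initial_concentrations = c(ClO4 = 2e-4, S = 1e-4))
  out2 <- cumulative_additions(sq2)
  expect_equal(out2$c_ClO4, 1e-4)
  expect_equal(out2$c_S, 5e-5)
})

test_that("moles are conserved along every shipped design sequence", {
  cfg <- default_design_config()
  for (sq in design_sequences(cfg)) {
    tab <- cumulative_additions(sq)
    for (x in c("ClO4", "S")) {
      init <- (sq$initial_concentrations[x] %||% 0) * sq$initial_volume
      if (is.na(init)) init <- 0
      added <- cumsum(sq$steps[[paste0("s_", x)]] * sq$steps[[paste0("v_", x)]])
      expect_equal(tab[[paste0("c_", x)]] * tab$volume,
                   unname(init + added), tolerance = 1e-12)
    }
  }
})

test_that("shipped design has 79 samples spanning the declared range", {
  d <- generate_design()
  expect_identical(nrow(d), 79L)
  for (x in c("c_ClO4", "c_S")) {
    pos <- d[[x]][d[[x]] > 0]
    expect_equal(min(pos), 5.0e-6, tolerance = 1e-9)
    expect_equal(max(pos), 3.3e-4, tolerance = 1e-9)
  }
  # axis points (single-ion sequences) and interior combined points
  expect_gt(sum(d$c_ClO4 > 0 & d$c_S == 0), 0)
  expect_gt(sum(d$c_S > 0 & d$c_ClO4 == 0), 0)
  expect_gt(sum(d$c_S > 0 & d$c_ClO4 > 0), 30)
  # concentrations are hit exactly by the solved microvolumes
  cfg <- default_design_config()
  expect_equal(d$c_ClO4[d$sequence_id == 1], cfg$sequences[[1]]$targets$ClO4,
               tolerance = 1e-12)
  expect_equal(d$c_S[d$sequence_id == 3], cfg$sequences[[3]]$targets$S,
               tolerance = 1e-12)
})

test_that("train/test split is 59/20, keeps extremes in training and is seeded", {
  d <- generate_design()
  s1 <- split_train_test(d, seed = 11)
  expect_identical(sum(s1$role == "train"), 59L)
  expect_identical(sum(s1$role == "test"), 20L)
  for (x in c("c_ClO4", "c_S")) {
    v <- s1[[x]]
    extremes <- v == min(v) | abs(v - max(v)) < 1e-9 * max(v) |
      (v > 0 & abs(v - min(v[v > 0])) < 1e-9 * min(v[v > 0]))
    expect_true(all(s1$role[extremes] == "train"))
  }
  expect_identical(s1, split_train_test(d, seed = 11))
  expect_false(identical(s1$role, split_train_test(d, seed = 12)$role))
  expect_error(split_train_test(d, seed = 1, n_test = 70), "split error")
})

test_that("spiked application samples respect the declared protocol", {
  app <- generate_spiked_samples(seed = 5)
  expect_identical(length(unique(app$sequence_id)), 6L)
  base <- app[app$step == 0, ]
  expect_true(all(base$c_ClO4 >= 0.3e-6 & base$c_ClO4 <= 3.4e-5))
  expect_true(all(base$c_S >= 0.3e-6 & base$c_S <= 3.4e-5))
  expect_true(all(app$c_ClO4 <= 5.0e-4 * (1 + 1e-12)))
  expect_true(all(app$c_S <= 5.0e-4 * (1 + 1e-12)))
  # the top spike reaches the 5.0e-4 M maximum exactly
  expect_equal(max(app$c_ClO4), 5.0e-4, tolerance = 1e-12)
  expect_equal(max(app$c_S), 5.0e-4, tolerance = 1e-12)
  # both ions are spiked to common levels
  expect_equal(app$c_ClO4[app$step > 0], app$c_S[app$step > 0],
               tolerance = 1e-12)
  expect_identical(app, generate_spiked_samples(seed = 5))
  expect_false(identical(app$c_ClO4, generate_spiked_samples(seed = 6)$c_ClO4))
})

test_that("selectivity runs hold the interferent fixed and flatten where Eq. 1 predicts", {
  panel <- quiet_panel()
  prm <- act_bg(0.05)
  runs <- generate_selectivity_runs(panel, "P1", "S", c(1e-3, 1e-2),
                                    params = prm)
  expect_identical(length(unique(runs$sequence_id)), 2L)
  for (sid in unique(runs$sequence_id)) {
    sub <- runs[runs$sequence_id == sid, ]
    expect_identical(length(unique(sub$c_S)), 1L)
    expect_true(all(diff(sub$c_ClO4) > 0))
  }
  # noise-free response at the lowest primary concentration sits near the
  # plateau e0 + s log10(a_bg + k a_j^(1/2))
  sub <- runs[runs$sequence_id == unique(runs$sequence_id)[2], ]
  E <- array_response(panel, sub, prm)$P1
  sn <- panel$sensors$P1
  I <- oracle_ionic_strength(c(min(sub$c_ClO4), 1e-2), c(-1, -2), 0.05)
  plateau <- sn$e0 + sn$slope *
    log10(sn$background_activity +
            10^sn$log_k_pot[["S"]] * (oracle_gamma(-2, I) * 1e-2)^0.5)
  expect_equal(E[1], plateau, tolerance = 0.2)
  # zero interferent level degenerates to a plain calibration
  r0 <- generate_selectivity_runs(panel, "P1", "S", 0, params = prm)
  expect_true(all(r0$c_S == 0))
  expect_error(generate_selectivity_runs(panel, "P1", "S", numeric()),
               "nonempty")
})
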