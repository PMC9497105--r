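test_that("AP detection finds template spikes and ignores silence", {
  g <- sim_ap_train(3, cfg = sim_config(fs = 5e4, duration = 0.4))
  aps <- detect_aps(g$trace)
  expect_equal(nrow(aps), 3)
  expect_equal(aps$peak_time, g$truth$peak_times, tolerance = 2 / 5e4)
  flat <- trace(rep(-65, 5000), fs = 5e4, units = "mV", kind = "voltage")
  expect_equal(nrow(detect_aps(flat)), 0)
  # two APs 5 ms apart survive the 2 ms refractory window
  g2 <- sim_ap_train(2, isi_ms = 5, tau_ahp_ms = 2, ahp_amp_mv = 3,
                     cfg = sim_config(fs = 5e4, duration = 0.1))
  expect_equal(nrow(detect_aps(g2$trace)), 2)
})

test_that("half-width is exact on a triangular spike and recovered from templates", {
  # symmetric triangle: 2 ms base, threshold at the base -> 1 ms at half height
  fs <- 1e5
  up <- seq(0, 60, length.out = 100)
  tri <- c(rep(0, 200), up, rev(up)[-1], rep(0, 400))
  tr <- trace(tri, fs = fs, units = "mV", kind = "voltage")
  ap <- list(peak_time = 299 / fs, peak_v = 60, threshold_v = 0,
             threshold_time = 200 / fs)
  expect_equal(ap_half_width(tr, ap), 1.0, tolerance = 0.02)
  flat_ap <- list(peak_time = 299 / fs, peak_v = 0, threshold_v = 0,
                  threshold_time = 200 / fs)
  expect_error(ap_half_width(tr, flat_ap), class = "nociphys_degenerate_ap")

  g <- sim_ap_train(1, half_width_ms = 1.5,
                    cfg = sim_config(fs = 5e4, duration = 0.2))
  f <- ap_features(g$trace)
  expect_equal(f$half_width, 1.5, tolerance = 0.05)
  # doubling the sampling rate leaves the estimate within interpolation error
  g2 <- sim_ap_train(1, half_width_ms = 1.5,
                     cfg = sim_config(fs = 1e5, duration = 0.2))
  f2 <- ap_features(g2$trace)
  expect_equal(f2$half_width, f$half_width, tolerance = 0.03)
})

test_that("shoulder quantification separates templates and is offset-invariant", {
  g0 <- sim_ap_train(1, shoulder_frac = 0,
                     cfg = sim_config(fs = 5e4, duration = 0.2))
  f0 <- ap_features(g0$trace)
  expect_false(f0$has_shoulder)
  expect_lt(f0$shoulder_index, 0.03)
  g3 <- sim_ap_train(1, shoulder_frac = 0.3,
                     cfg = sim_config(fs = 5e4, duration = 0.2))
  f3 <- ap_features(g3$trace)
  expect_true(f3$has_shoulder)
  # adding a constant to the whole trace leaves the index unchanged
  shifted <- trace(g3$trace$samples + 12, fs = g3$trace$fs, units = "mV",
                   kind = "voltage")
  fs3 <- ap_features(shifted)
  expect_equal(fs3$shoulder_index, f3$shoulder_index, tolerance = 1e-6)
})

test_that("tau_AHP is recovered and respects its gating conditions", {
  g <- sim_ap_train(1, tau_ahp_ms = 8, ahp_amp_mv = 5,
                    cfg = sim_config(fs = 5e4, duration = 0.2))
  f <- ap_features(g$trace)
  expect_equal(f$tau_ahp, 8, tolerance = 0.05)
  # AHP below the 0.1 mV amplitude gate -> absent
  tiny <- sim_ap_train(1, ahp_amp_mv = 0.05,
                       cfg = sim_config(fs = 5e4, duration = 0.2))
  expect_true(is.na(ap_features(tiny$trace)$tau_ahp))
  # a second AP 10 ms later invalidates the first AP's 32 ms fit window
  pair <- sim_ap_train(2, isi_ms = 10, tau_ahp_ms = 8,
                       cfg = sim_config(fs = 5e4, duration = 0.2))
  fp <- ap_features(pair$trace)
  expect_true(is.na(fp$tau_ahp[[1]]))
})

test_that("resting potential is a stimulus-free window mean", {
  tr <- trace(rep(-65, 2000), fs = 1000, units = "mV", kind = "voltage")
  expect_equal(resting_potential(tr, c(0, 1)), -65)
  set.seed(33)
  noisy <- trace(-65 + rnorm(20000, 0, 2), fs = 1000, units = "mV",
                 kind = "voltage")
  expect_equal(resting_potential(noisy, c(0, 19.9)), -65,
               tolerance = 0.1)
  expect_error(resting_potential(tr, c(1, 1)),
               class = "nociphys_invalid_parameter")
  prot <- stimulus_protocol(tibble::tibble(
    onset_s = 0.5, duration_s = 0.2, kind = "current_step", magnitude = 50,
    magnitude_units = "pA"))
  expect_error(resting_potential(tr, c(0.4, 0.8), prot),
               class = "nociphys_contract_violation")
})

test_that("feature recovery holds across the template grid at 0.5 mV noise", {
  grid <- tidyr::expand_grid(hw = c(1, 2), sf = c(0, 0.3),
                             tau = c(5, 20))
  errs <- purrr::pmap(grid, function(hw, sf, tau) {
    g <- sim_ap_train(1, half_width_ms = hw, shoulder_frac = sf,
                      tau_ahp_ms = tau, ahp_amp_mv = 5,
                      cfg = sim_config(seed = round(hw * 7 + sf * 13 + tau),
                                       fs = 5e4, duration = 0.2,
                                       noise_sd = 0.5))
    f <- ap_features(g$trace)
    c(hw_err = abs(f$half_width - hw) / hw,
      tau_err = abs(f$tau_ahp - tau) / tau,
      shoulder_ok = identical(f$has_shoulder, sf > 0))
  })
  m <- do.call(rbind, errs)
  expect_lt(median(m[, "hw_err"]), 0.05)
  expect_lt(median(m[, "tau_err"], na.rm = TRUE), 0.05)
  expect_true(all(m[, "shoulder_ok"] == 1))
})
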