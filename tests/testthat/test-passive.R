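test_that("sweep averaging is a pointwise mean with the usual identities", {
  mk <- function(x) trace(x, fs = 1000, units = "pA", kind = "current")
  s <- sweep_set(list(mk(c(0, 2)), mk(c(2, 0))), stim_onset = 0)
  expect_equal(average_sweeps(s)$samples, c(1, 1))
  same <- sweep_set(rep(list(mk(c(1, 2))), 25), stim_onset = 0)
  expect_equal(average_sweeps(same)$samples, c(1, 2))
  expect_error(sweep_set(list(), 0), class = "nociphys_empty_input")
  # order invariance
  s2 <- sweep_set(list(mk(c(2, 0)), mk(c(0, 2))), stim_onset = 0)
  expect_equal(average_sweeps(s)$samples, average_sweeps(s2)$samples)
})

test_that("averaging 25 noisy sweeps shrinks the residual noise ~ 1/sqrt(n)", {
  cfg1 <- sim_config(seed = 21, fs = 5e4, duration = 0.12, noise_sd = 20)
  clean <- sim_capacitive_sweeps(20, 5, 500, n_sweeps = 1,
                                 cfg = sim_config(fs = 5e4, duration = 0.12))
  signal <- average_sweeps(clean$sweeps)$samples
  one <- average_sweeps(sim_capacitive_sweeps(
    20, 5, 500, n_sweeps = 1, cfg = cfg1)$sweeps)$samples
  many <- average_sweeps(sim_capacitive_sweeps(
    20, 5, 500, n_sweeps = 25, cfg = cfg1)$sweeps)$samples
  rmse <- function(x) sqrt(mean((x - signal)^2))
  expect_lt(rmse(many), rmse(one) / 3)   # 1/sqrt(25) = 1/5, with slack
})

test_that("fit_decay recovers exponential components and flags flat traces", {
  fs <- 1e5
  t_ms <- (0:999) / fs * 1000
  mono <- trace(-2000 * exp(-t_ms / 0.1), fs = fs, units = "pA",
                kind = "current")
  f <- fit_decay(mono, c(0, 999 / fs), n_components = 2)
  expect_equal(f$weighted_tau, 0.1, tolerance = 0.02)
  expect_equal(f$baseline, 0, tolerance = 1)

  bi <- trace(-1000 * exp(-t_ms / 0.05) - 500 * exp(-t_ms / 0.5),
              fs = fs, units = "pA", kind = "current")
  fb <- fit_decay(bi, c(0, 999 / fs), n_components = 2)
  # closed form: (1000*0.05 + 500*0.5) / 1500 = 0.2 ms
  expect_equal(fb$weighted_tau, 0.2, tolerance = 0.2 * 0.02)
  expect_equal(sort(fb$taus), c(0.05, 0.5), tolerance = 0.02)

  flat <- trace(rep(-5, 100), fs = 1000, units = "pA", kind = "current")
  ff <- fit_decay(flat, c(0, 0.099), n_components = 2)
  expect_true(ff$degenerate)
  expect_equal(ff$amplitudes, c(0, 0))
  expect_error(fit_decay(mono, c(0, 5e-5)),
               class = "nociphys_insufficient_data")
})

test_that("weighted tau is invariant to overall amplitude scaling", {
  fs <- 1e5
  t_ms <- (0:999) / fs * 1000
  y <- -800 * exp(-t_ms / 0.08) - 300 * exp(-t_ms / 0.4)
  f1 <- fit_decay(trace(y, fs = fs, units = "pA", kind = "current"),
                  c(0, 999 / fs))
  f2 <- fit_decay(trace(5 * y, fs = fs, units = "pA", kind = "current"),
                  c(0, 999 / fs))
  expect_equal(f1$weighted_tau, f2$weighted_tau, tolerance = 1e-4)
})

test_that("resistance and capacitance arithmetic does the unit bookkeeping", {
  expect_equal(input_resistance(-15, -3000), 5)
  expect_equal(input_resistance(-15, -1500), 10)
  expect_error(input_resistance(-15, 0), class = "nociphys_division_error")
  fake_fit <- structure(list(weighted_tau = 0.1, degenerate = FALSE),
                        class = "exp_fit")
  expect_equal(capacitance(fake_fit, 5), 20)   # 0.1 ms / 5 MOhm = 20 pF
  degen <- structure(list(weighted_tau = NA_real_, degenerate = TRUE),
                     class = "exp_fit")
  expect_warning(cm <- capacitance(degen, 5), regexp = "Degenerate")
  expect_equal(cm, 0)
  expect_error(capacitance(fake_fit, -1),
               class = "nociphys_invalid_parameter")
})

test_that("the full chain recovers Cm and Rs on noiseless sweeps", {
  g <- sim_capacitive_sweeps(20, 5, 500,
                             cfg = sim_config(fs = 1e5, duration = 0.12))
  props <- passive_properties(g$sweeps, v_step_mv = -15)
  expect_equal(props$c_m_pf, 20, tolerance = 0.02)
  expect_equal(props$r_input_mohm, 5, tolerance = 0.02)
  # steady-state estimate approximates Rs + Rin
  expect_equal(props$r_steady_mohm, 505, tolerance = 0.05)
})

test_that("capacitance bias grows as Rs/Rin and stays <2% for Rin/Rs >= 50", {
  ratios <- c(10, 50, 100, 500)
  errs <- vapply(ratios, function(r) {
    g <- sim_capacitive_sweeps(20, 5, 5 * r,
                               cfg = sim_config(fs = 1e5, duration = 0.12))
    abs(passive_properties(g$sweeps, v_step_mv = -15)$c_m_pf - 20) / 20
  }, numeric(1))
  expect_true(all(diff(errs) < 0))          # bias shrinks with Rin/Rs
  expect_true(all(errs[ratios >= 50] < 0.02))
})
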