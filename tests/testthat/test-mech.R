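test_that("inactivation fits recover the generator's weighted tau", {
  g <- sim_mech_current(-200, tau1 = 5, tau2 = 5,
                        cfg = sim_config(fs = 2e4, duration = 0.4))
  m <- fit_inactivation(g$trace, g$stim_onset)
  expect_true(m$responded)
  expect_equal(m$fit$weighted_tau, 5, tolerance = 0.02)
  expect_equal(m$fit$baseline, 0, tolerance = 0.01)

  flat <- sim_mech_current(0)
  expect_false(fit_inactivation(flat$trace, flat$stim_onset)$responded)

  # +50 pA leak offset: asymptote equals the shifted baseline, taus unchanged
  g2 <- g
  g2$trace <- trace(g$trace$samples + 50, fs = g$trace$fs, units = "pA",
                    kind = "current")
  m2 <- fit_inactivation(g2$trace, g$stim_onset)
  expect_equal(m2$baseline, 50, tolerance = 1e-4)
  expect_equal(m2$fit$weighted_tau, m$fit$weighted_tau, tolerance = 1e-3)

  short <- trace(rep(0, 200), fs = 2e4, units = "pA", kind = "current")
  expect_error(fit_inactivation(short, 0.005),
               class = "nociphys_insufficient_data")
})

test_that("RA/IA/SA bins follow the weighted tau with boundaries to IA", {
  expect_equal(classify_mech(5), "RA")
  expect_equal(classify_mech(10), "IA")
  expect_equal(classify_mech(30), "IA")
  expect_equal(classify_mech(32), "SA")
  expect_equal(classify_mech(c(2, 15, 100)), c("RA", "IA", "SA"))
  expect_error(classify_mech(0), class = "nociphys_invalid_parameter")
})

test_that("human and mouse responder criteria behave at their thresholds", {
  resp <- function(d, p) tibble::tibble(displacement_um = d, peak_pa = p)
  expect_false(responder_call_human(resp(c(5, 8), c(-10, -39))))
  expect_true(responder_call_human(resp(8, -41)))
  expect_true(is.na(responder_call_human(resp(12, -500))))
  expect_false(responder_call_mouse(resp(1:10, rep(-49, 10))))
  expect_true(responder_call_mouse(resp(1:10, rep(-51, 10))))
  detached <- resp(1:3, c(-10, -20, -400))
  detached$detached <- c(FALSE, FALSE, TRUE)
  expect_true(is.na(responder_call_mouse(detached)))
  expect_error(responder_call_mouse(resp(numeric(), numeric())),
               class = "nociphys_empty_input")
})

test_that("both amplitude conventions agree on clean responses", {
  g <- sim_mech_current(-250, tau1 = 8, tau2 = 40, frac1 = 0.6,
                        cfg = sim_config(fs = 2e4, duration = 0.5))
  m <- fit_inactivation(g$trace, g$stim_onset)
  a <- mech_amplitude(m)
  expect_equal(a$fit_weighted_pa, -250, tolerance = 0.02)
  expect_equal(a$relative_pa, -250, tolerance = 0.02)
  zero <- sim_mech_current(0)
  az <- mech_amplitude(fit_inactivation(zero$trace, zero$stim_onset))
  expect_equal(az$fit_weighted_pa, 0)
  expect_equal(az$relative_pa, 0)
  # pure noise: the relative method reports the noise extremum (its
  # documented bias), here several noise SDs below zero
  noise <- sim_mech_current(0, cfg = sim_config(seed = 4, fs = 2e4,
                                                duration = 0.3,
                                                noise_sd = 5))
  mn <- fit_inactivation(noise$trace, noise$stim_onset)
  expect_false(mn$responded)
  expect_lt(mn$peak_raw_pa, -5)
})

test_that("Fisher's exact test equals enumeration and the reference test", {
  expect_equal(fisher_exact(matrix(c(1, 1, 1, 1), 2)), 1.0)
  expect_equal(fisher_exact(matrix(c(0, 0, 7, 9), 2)), 1.0)
  m_paper <- matrix(c(5, 0, 13, 21), 2)   # responders WT/KO, 5/18 vs 0/21
  expect_equal(fisher_exact(m_paper), fisher_brute(m_paper),
               tolerance = 1e-12)
  expect_equal(fisher_exact(m_paper),
               stats::fisher.test(m_paper)$p.value, tolerance = 1e-9)
  set.seed(99)
  for (i in 1:50) {
    n <- sample(4:40, 1)
    m <- matrix(stats::rmultinom(1, n, prob = runif(4, 0.05, 1)), 2)
    expect_equal(fisher_exact(m), fisher_brute(m), tolerance = 1e-12)
    expect_equal(fisher_exact(m), stats::fisher.test(m)$p.value,
                 tolerance = 1e-9)
  }
  expect_error(fisher_exact(matrix(c(-1, 2, 3, 4), 2)),
               class = "nociphys_invalid_parameter")
})

test_that("population summaries count classes with caption-style percentages", {
  cells <- tibble::tibble(class_label = c(rep("SA", 5), rep("NR", 13)))
  s <- mech_population_summary(cells)
  expect_equal(s$percent[s$class_label == "SA"], 27.8)  # 5 of 18
  expect_equal(sum(s$fraction), 1, tolerance = 1e-12)
  all_nr <- mech_population_summary(tibble::tibble(class_label = rep("NR", 7)))
  expect_equal(all_nr$percent[all_nr$class_label == "NR"], 100)
  empty <- mech_population_summary(tibble::tibble(class_label = character()))
  expect_equal(empty$n, rep(0L, 4))
  labels <- c(rep("RA", 3), rep("IA", 2), rep("SA", 4), rep("NR", 1))
  s2 <- mech_population_summary(tibble::tibble(class_label = labels))
  expect_equal(s2$n, c(3L, 2L, 4L, 1L))
})

test_that("a full synthetic cell series classifies end to end", {
  mk_step <- function(d, peak, tau) {
    g <- sim_mech_current(peak, tau1 = tau, tau2 = tau,
                          cfg = sim_config(fs = 2e4, duration = 0.4))
    list(displacement_um = d, trace = g$trace, stim_onset = g$stim_onset)
  }
  steps <- dplyr::bind_rows(
    tibble::tibble(displacement_um = 6, trace = list(mk_step(6, -30, 50)$trace),
                   stim_onset = 0.05),
    tibble::tibble(displacement_um = 8,
                   trace = list(mk_step(8, -180, 50)$trace),
                   stim_onset = 0.05))
  out <- analyze_mech_cell(steps, species = "human", cell_id = "c1")
  expect_true(out$responder)
  expect_equal(out$class_label, "SA")
  expect_equal(out$weighted_tau, 50, tolerance = 0.03)
})
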