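test_that("dF/F0 normalizes against the pre-stimulus baseline", {
  prot <- mini_agonist_protocol()
  const <- trace(rep(2, 800), fs = 1, units = "ratio",
                 kind = "fluorescence_ratio")
  d <- dff(const, prot)
  expect_equal(unique(d$samples), 0)
  expect_equal(d$kind, "dff")
  x <- rep(1, 800); x[100] <- 1.4
  tr <- trace(x, fs = 1, units = "ratio", kind = "fluorescence_ratio")
  d2 <- dff(tr, prot)
  expect_equal(max(d2$samples), 0.4, tolerance = 1e-12)
  expect_equal(mean(d2$samples[1:59]), 0, tolerance = 1e-12)
  neg <- trace(rep(-1, 800), fs = 1, units = "ratio",
               kind = "fluorescence_ratio")
  expect_error(dff(neg, prot), class = "nociphys_invalid_baseline")
})

test_that("epoch peaks recover injected transient amplitudes", {
  pop <- sim_calcium_population(1, frac_caps = 1,
                                protocol = mini_agonist_protocol(),
                                cfg = sim_config(seed = 14, fs = 1))
  pk <- quiet_peaks(epoch_peaks(pop$cells$trace[[1]],
                                mini_agonist_protocol()))
  amp <- pop$truth$amp_caps[[1]]
  expect_equal(pk$peak[pk$kind == "capsaicin"], amp, tolerance = 0.01)
  # this cell is capsaicin-only: the mustard-oil epoch peak is ~0
  expect_lt(abs(pk$peak[pk$kind == "mustard_oil"]), 0.01)
  expect_equal(pk$peak[pk$kind == "high_k"], pop$truth$amp_high_k[[1]],
               tolerance = 0.01)
})

test_that("responder calling recovers generating fractions and excludes non-neurons", {
  prot <- mini_agonist_protocol()
  pop <- sim_calcium_population(300, frac_caps = 0.9, frac_highk_only = 0.1,
                                protocol = prot,
                                cfg = sim_config(seed = 15, fs = 1,
                                                 noise_sd = 0.01))
  cl <- classify_responders(pop$cells, prot)
  truth_frac <- mean(pop$truth$responds_capsaicin)
  got_frac <- mean(cl$responds_capsaicin[cl$is_neuron])
  expect_equal(got_frac, truth_frac, tolerance = 1e-9)
  expect_true(all(cl$is_neuron))
  # an all-flat cell fails the high-K neuron check
  flat <- tibble::tibble(
    cell_id = "flat",
    trace = list(trace(rep(1, length(pop$cells$trace[[1]]$samples)),
                       fs = 1, units = "ratio",
                       kind = "fluorescence_ratio")))
  clf <- classify_responders(flat, prot)
  expect_false(clf$is_neuron)
  expect_equal(clf$category, "not_neuron")
  # threshold at infinity -> no agonist responders (monotone endpoint)
  cl_inf <- classify_responders(pop$cells[1:5, ], prot,
                                threshold_sd = Inf, floor = Inf)
  expect_false(any(cl_inf$responds_capsaicin))
})

test_that("sensitization ratios recover the injected multiplier", {
  prot <- mini_sens_protocol()
  pop <- sim_calcium_population(60, frac_caps = 1, sens_multiplier = 1.4,
                                frac_sensitized = 1, protocol = prot,
                                cfg = sim_config(seed = 16, fs = 1))
  ratios <- quiet_peaks(sensitization_ratios(pop$cells, prot))
  expect_equal(mean(ratios$sens_ratio), 1.4, tolerance = 0.01)
  # scale invariance: multiplying a trace by a positive constant
  tr <- pop$cells$trace[[1]]
  scaled <- trace(3 * tr$samples, fs = tr$fs, units = tr$units,
                  kind = tr$kind)
  expect_equal(quiet_peaks(sensitization_ratio(scaled, prot)),
               quiet_peaks(sensitization_ratio(tr, prot)),
               tolerance = 1e-9)
  # a cell without a pulse-4 response yields NA
  flat <- trace(rep(1, length(tr$samples)), fs = 1, units = "ratio",
                kind = "fluorescence_ratio")
  expect_true(is.na(quiet_peaks(sensitization_ratio(flat, prot))))
  # protocol without the sensitizer between pulses 5 and 6 is rejected
  expect_error(sensitization_ratio(tr, mini_agonist_protocol()),
               class = "nociphys_invalid_protocol")
})

test_that("sensitized fractions reproduce caption-style percentages", {
  expect_equal(sensitized_fraction(c(rep(1.3, 753), rep(1.0, 70)))$percent, 91)
  expect_equal(sensitized_fraction(c(rep(1.3, 173), rep(1.0, 438)))$percent, 28)
  expect_equal(sensitized_fraction(rep(1.0, 319))$percent, 0)
  empty <- sensitized_fraction(numeric())
  expect_equal(empty$n_total, 0)
  expect_equal(empty$percent, 0)
})

test_that("percentage reporting rounds half away from zero at caption precision", {
  expect_equal(sensitized_fraction(c(rep(2, 183), rep(1, 17)))$percent, 92)
  # 5/18 = 27.78 at one decimal for small denominators
  expect_equal(sensitized_fraction(c(rep(2, 5), rep(1, 13)))$percent, 27.8)
  expect_equal(sensitized_fraction(c(rep(2, 173), rep(1, 438)))$percent, 28)
})

test_that("temperature matrices order cells by hottest-step response", {
  prot <- temperature_protocol(temps_c = c(35, 39, 43), interval_s = 120)
  pop <- sim_calcium_population(12, frac_caps = 1, protocol = prot,
                                cfg = sim_config(seed = 17, fs = 2,
                                                 noise_sd = 0.005))
  tm <- quiet_peaks(temperature_matrix(pop$cells, prot))
  expect_equal(dim(tm$matrix)[1], 12)
  # injected heat gains sort identically to the recovered ordering
  truth_order <- pop$truth$cell_id[order(-pop$truth$heat_gain)]
  expect_equal(tm$order$cell_id, truth_order)
  expect_equal(tm$mean_trace, colMeans(tm$matrix))
  # identical cells: every row equals the mean trace
  one <- pop$cells[1, ]
  twin <- dplyr::bind_rows(one, dplyr::mutate(one, cell_id = "cell9999"))
  tm2 <- quiet_peaks(temperature_matrix(twin, prot))
  expect_equal(tm2$matrix[1, ], tm2$matrix[2, ], ignore_attr = TRUE)
  empty <- temperature_matrix(pop$cells[0, ], prot)
  expect_equal(nrow(empty$matrix), 0)
})

test_that("condition averages partition neurons into exclusive categories", {
  prot <- mini_agonist_protocol()
  pop <- sim_calcium_population(80, frac_caps = 0.6,
                                frac_mo_given_caps = 0.5,
                                frac_highk_only = 0.2, protocol = prot,
                                cfg = sim_config(seed = 18, fs = 1,
                                                 noise_sd = 0.005))
  cl <- classify_responders(pop$cells, prot)
  avg <- condition_averages(cl)
  expect_equal(sum(unique(avg[, c("category", "n_cells")])$n_cells),
               sum(cl$is_neuron))
  # single cell in a category -> the average is that cell's trace
  solo <- cl[which(cl$category == "caps_only")[1], ]
  avg1 <- condition_averages(solo)
  expect_equal(avg1$mean_value, solo$trace[[1]]$samples)
})
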