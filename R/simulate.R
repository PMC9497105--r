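#' Simulate capacitive-transient current sweeps
#'
#' Generates the analytic current response of the single-compartment
#' series-resistance RC circuit to a voltage step: an instantaneous jump to
#' `v_step / Rs` decaying with time constant `Cm * (Rs || Rin)` toward the
#' steady state `v_step / (Rs + Rin)`, plus i.i.d. Gaussian noise per sweep.
#' This is the textbook model behind the capacitance recipe (average the
#' repeated responses, fit the first transient, divide the weighted decay
#' constant by the resistance estimated from the peak): in the physiological
#' limit `Rin >> Rs` the recipe recovers `Cm` exactly.
#'
#' @param cm_pf Membrane capacitance (pF).
#' @param rs_mohm Series (access) resistance (MOhm).
#' @param rin_mohm Input (membrane) resistance (MOhm).
#' @param v_step_mv Command voltage step (mV); the standard protocol
#'   hyperpolarizes by 15 mV for 100 ms.
#' @param n_sweeps Number of repeated sweeps.
#' @param cfg A [sim_config()]; `fs` defaults to 100 kHz for this generator.
#' @param step_onset_s,step_dur_s Step onset and duration (s).
#' @return A list with `sweeps` (a [sweep_set()]) and `truth` (the
#'   generating parameters, including the exact decay constant in ms).
#' @export
sim_capacitive_sweeps <- function(cm_pf, rs_mohm, rin_mohm, v_step_mv = -15,
                                  n_sweeps = 25,
                                  cfg = sim_config(fs = 1e5, duration = 0.12),
                                  step_onset_s = 0.01, step_dur_s = 0.1) {
  stopifnot_positive(cm_pf = cm_pf, rs_mohm = rs_mohm, rin_mohm = rin_mohm)
  if (n_sweeps < 1) {
    rlang::abort("`n_sweeps` must be >= 1.",
                 class = "nociphys_invalid_parameter")
  }
  n <- round(cfg$fs * cfg$duration)
  t <- (seq_len(n) - 1) / cfg$fs
  r_par <- rs_mohm * rin_mohm / (rs_mohm + rin_mohm)
  tau_s <- cm_pf * r_par * 1e-6        # pF * MOhm = us
  i_ss <- 1000 * v_step_mv / (rs_mohm + rin_mohm)   # mV/MOhm = nA -> pA
  i_jump <- 1000 * v_step_mv / rs_mohm - i_ss
  base <- numeric(n)
  on <- t >= step_onset_s & t < step_onset_s + step_dur_s
  base[on] <- i_ss + i_jump * exp(-(t[on] - step_onset_s) / tau_s)
  off <- t >= step_onset_s + step_dur_s
  base[off] <- -i_jump * exp(-(t[off] - step_onset_s - step_dur_s) / tau_s)
  sweeps <- with_seed(cfg$seed, lapply(seq_len(n_sweeps), function(i) {
    noise <- if (cfg$noise_sd > 0) stats::rnorm(n, 0, cfg$noise_sd) else 0
    trace(base + noise, fs = cfg$fs, units = "pA", kind = "current")
  }))
  list(sweeps = sweep_set(sweeps, stim_onset = step_onset_s),
       truth = list(cm_pf = cm_pf, rs_mohm = rs_mohm, rin_mohm = rin_mohm,
                    v_step_mv = v_step_mv, tau_ms = tau_s * 1000,
                    peak_pa = i_ss + i_jump, steady_pa = i_ss))
}

# Solve the fast repolarization time constant so the template's width at
# half threshold-to-peak amplitude equals `half_width_ms`. The repolarization
# is a two-exponential mixture (weight `shoulder_frac` on a 10x slower
# component) decaying toward an asymptote slightly below the AHP minimum.
solve_ap_shape <- function(amp, half_width_ms, shoulder_frac, ahp_amp,
                           t_rise_ms) {
  v_asym_depth <- ahp_amp + 0.1 * amp   # below the AHP minimum, scale-aware
  w_half <- (amp / 2 + v_asym_depth) / (amp + v_asym_depth)
  mix <- function(t, tau_f) {
    (1 - shoulder_frac) * exp(-t / tau_f) +
      shoulder_frac * exp(-t / (10 * tau_f))
  }
  t_cross <- function(tau_f) {
    stats::uniroot(function(t) mix(t, tau_f) - w_half,
                   lower = 0, upper = 1e4 * tau_f, tol = 1e-12)$root
  }
  target <- half_width_ms - t_rise_ms / 2
  tau_f <- stats::uniroot(function(tf) t_cross(tf) - target,
                          lower = 1e-4, upper = 1e3, tol = 1e-12)$root
  # time (from the peak) at which the decay reaches the AHP minimum
  w_min <- v_asym_depth / (amp + v_asym_depth)
  t_min <- stats::uniroot(function(t) mix(t, tau_f) - w_min,
                          lower = 0, upper = 1e5 * tau_f, tol = 1e-12)$root
  list(tau_f = tau_f, v_asym_depth = v_asym_depth, t_min = t_min, mix = mix)
}

#' Simulate a current-clamp trace containing template action potentials
#'
#' The waveform is a parametric template, not a conductance model: a linear
#' upstroke, an exponential repolarization with an optional additive slow
#' component (relative weight `shoulder_frac`, emulating the repolarization
#' "shoulder" of some nociceptors), truncation at the AHP minimum, and a
#' monoexponential afterhyperpolarization recovery with `tau_ahp_ms`. The
#' fast repolarization constant is solved numerically so the AP width at
#' half threshold-to-peak amplitude equals `half_width_ms` regardless of the
#' shoulder weight.
#'
#' @param n_aps Number of APs placed in the trace.
#' @param amp_mv AP amplitude above resting potential (mV).
#' @param half_width_ms Target half-width (ms).
#' @param shoulder_frac Relative weight of the slow repolarization
#'   component, in `[0, 1)`. 0 gives a pure monoexponential falling phase.
#' @param ahp_amp_mv AHP depth below rest (mV, >= 0).
#' @param tau_ahp_ms AHP recovery time constant (ms).
#' @param v_rest_mv Resting potential (mV).
#' @param cfg A [sim_config()]; 50 kHz sampling by default.
#' @param first_ap_s Time of the first AP upstroke (s).
#' @param isi_ms Inter-AP interval (ms).
#' @return A list with `trace` and `truth` (all shape parameters plus the
#'   exact peak times in seconds).
#' @export
sim_ap_train <- function(n_aps, amp_mv = 100, half_width_ms = 2,
                         shoulder_frac = 0, ahp_amp_mv = 5, tau_ahp_ms = 20,
                         v_rest_mv = -65,
                         cfg = sim_config(fs = 5e4, duration = 1),
                         first_ap_s = 0.02, isi_ms = 100) {
  if (shoulder_frac < 0 || shoulder_frac >= 1) {
    rlang::abort("`shoulder_frac` must lie in [0, 1).",
                 class = "nociphys_invalid_parameter")
  }
  stopifnot_positive(tau_ahp_ms = tau_ahp_ms, amp_mv = amp_mv,
                     half_width_ms = half_width_ms)
  if (ahp_amp_mv < 0) {
    rlang::abort("`ahp_amp_mv` must be >= 0.",
                 class = "nociphys_invalid_parameter")
  }
  n <- round(cfg$fs * cfg$duration)
  v <- rep(v_rest_mv, n)
  ap_starts <- first_ap_s + (seq_len(n_aps) - 1) * isi_ms / 1000
  t_rise_ms <- min(0.5, half_width_ms / 2)
  shape <- solve_ap_shape(amp_mv, half_width_ms, shoulder_frac, ahp_amp_mv,
                          t_rise_ms)
  peak_times <- numeric(0)
  if (n_aps > 0) {
    for (s in ap_starts) {
      i0 <- 1 + round(s * cfg$fs)
      if (i0 > n) break
      i1 <- min(n, i0 + round(isi_ms / 1000 * cfg$fs) - 1)
      tm <- ((i0:i1) - i0) / cfg$fs * 1000    # ms since upstroke start
      seg <- numeric(length(tm))
      rise <- tm < t_rise_ms
      seg[rise] <- v_rest_mv + amp_mv * tm[rise] / t_rise_ms
      td <- tm - t_rise_ms                    # ms since peak
      fall <- !rise & td <= shape$t_min
      v_asym <- v_rest_mv - shape$v_asym_depth
      seg[fall] <- v_asym +
        (amp_mv + shape$v_asym_depth) * shape$mix(td[fall], shape$tau_f)
      rec <- td > shape$t_min
      seg[rec] <- v_rest_mv -
        ahp_amp_mv * exp(-(td[rec] - shape$t_min) / tau_ahp_ms)
      v[i0:i1] <- seg
      peak_times <- c(peak_times, (i0 - 1) / cfg$fs + t_rise_ms / 1000)
    }
  }
  noisy <- with_seed(cfg$seed, {
    if (cfg$noise_sd > 0) v + stats::rnorm(n, 0, cfg$noise_sd) else v
  })
  list(trace = trace(noisy, fs = cfg$fs, units = "mV", kind = "voltage"),
       truth = list(n_aps = n_aps, amp_mv = amp_mv,
                    half_width_ms = half_width_ms,
                    shoulder_frac = shoulder_frac, ahp_amp_mv = ahp_amp_mv,
                    tau_ahp_ms = tau_ahp_ms, v_rest_mv = v_rest_mv,
                    peak_times = peak_times,
                    ahp_min_after_peak_ms = shape$t_min))
}

#' Simulate a mechanically-activated inward current
#'
#' Baseline zero until `latency_ms`, then an instantaneous step to `peak_pa`
#' (inward currents are negative) decaying as the biexponential
#' `frac1 * exp(-t/tau1) + (1 - frac1) * exp(-t/tau2)` back to baseline,
#' plus Gaussian noise. The ground truth records the amplitude-weighted
#' inactivation constant `frac1 * tau1 + (1 - frac1) * tau2` that the
#' RA/IA/SA classification is based on.
#'
#' @param peak_pa Peak current (pA, <= 0; 0 simulates a non-responder).
#' @param tau1_ms,tau2_ms Inactivation time constants (ms).
#' @param frac1 Amplitude fraction of the `tau1` component, in `[0, 1]`.
#' @param latency_ms Stimulus onset (ms); at least 20 ms of baseline is
#'   required by the fitting stage.
#' @param cfg A [sim_config()]; 20 kHz, 300 ms by default.
#' @return A list with `trace`, `stim_onset` (s) and `truth`.
#' @export
sim_mech_current <- function(peak_pa, tau1_ms = 5, tau2_ms = 5, frac1 = 1,
                             latency_ms = 50,
                             cfg = sim_config(fs = 2e4, duration = 0.3)) {
  stopifnot_positive(tau1_ms = tau1_ms, tau2_ms = tau2_ms)
  if (peak_pa > 0) {
    rlang::abort("`peak_pa` must be <= 0 (inward currents are negative).",
                 class = "nociphys_invalid_parameter")
  }
  if (frac1 < 0 || frac1 > 1) {
    rlang::abort("`frac1` must lie in [0, 1].",
                 class = "nociphys_invalid_parameter")
  }
  n <- round(cfg$fs * cfg$duration)
  t_ms <- (seq_len(n) - 1) / cfg$fs * 1000
  base <- numeric(n)
  post <- t_ms >= latency_ms
  td <- t_ms[post] - latency_ms
  base[post] <- peak_pa * (frac1 * exp(-td / tau1_ms) +
                             (1 - frac1) * exp(-td / tau2_ms))
  noisy <- with_seed(cfg$seed, {
    if (cfg$noise_sd > 0) base + stats::rnorm(n, 0, cfg$noise_sd) else base
  })
  list(trace = trace(noisy, fs = cfg$fs, units = "pA", kind = "current"),
       stim_onset = latency_ms / 1000,
       truth = list(peak_pa = peak_pa, tau1_ms = tau1_ms, tau2_ms = tau2_ms,
                    frac1 = frac1,
                    weighted_tau_ms = frac1 * tau1_ms + (1 - frac1) * tau2_ms,
                    latency_ms = latency_ms))
}

calcium_kernel <- function(t_rel, amp, rise_s = 2, tau_decay_s = 20) {
  k <- numeric(length(t_rel))
  up <- t_rel >= 0 & t_rel < rise_s
  k[up] <- amp * t_rel[up] / rise_s
  dn <- t_rel >= rise_s
  k[dn] <- amp * exp(-(t_rel[dn] - rise_s) / tau_decay_s)
  k
}

#' Simulate a calcium-imaging cell population with known responder labels
#'
#' Every cell carries a Fura-2-style ratio trace (baseline 1.0) with fast
#' rise / exponential decay transients at the stimuli it responds to. Cells
#' are assigned to mutually exclusive categories: capsaicin + mustard-oil,
#' capsaicin-only, mustard-oil-only and high-K-only; all cells respond to
#' the terminal high-K depolarization (the neuron check). Under a
#' sensitization protocol, a `frac_sensitized` subset of capsaicin
#' responders has its post-incubation (6th pulse) transient scaled to
#' `sens_multiplier` times its 4th-pulse transient. Under a temperature
#' protocol, capsaicin responders respond to heat steps with amplitudes
#' increasing in temperature.
#'
#' @param n_cells Number of cells.
#' @param frac_caps Fraction of capsaicin responders.
#' @param frac_mo_given_caps Fraction of capsaicin responders that also
#'   respond to mustard oil.
#' @param frac_highk_only Fraction of cells responding only to high K;
#'   the remainder `1 - frac_caps - frac_highk_only` is mustard-oil-only.
#' @param sens_multiplier Fold change of the 6th-pulse response in
#'   sensitized cells.
#' @param frac_sensitized Fraction of capsaicin responders sensitized.
#' @param protocol A [stimulus_protocol()]; must contain a high-K epoch.
#' @param cfg A [sim_config()]; 1 Hz sampling by default (`duration` is
#'   derived from the protocol).
#' @return A list with `cells` (tibble: `cell_id`, `trace` list-column),
#'   `truth` (per-cell labels and amplitudes) and `protocol`.
#' @export
sim_calcium_population <- function(n_cells, frac_caps = 1,
                                   frac_mo_given_caps = 0,
                                   frac_highk_only = 1 - frac_caps,
                                   sens_multiplier = 1, frac_sensitized = 0,
                                   protocol = sensitization_protocol(),
                                   cfg = sim_config(fs = 1, duration = 1)) {
  for (f in c(frac_caps, frac_mo_given_caps, frac_highk_only,
              frac_sensitized)) {
    if (f < 0 || f > 1) {
      rlang::abort("All fractions must lie in [0, 1].",
                   class = "nociphys_invalid_parameter")
    }
  }
  if (frac_caps + frac_highk_only > 1 + 1e-12) {
    rlang::abort("frac_caps + frac_highk_only must not exceed 1.",
                 class = "nociphys_invalid_parameter")
  }
  protocol <- as_protocol(protocol)
  if (!any(protocol$kind == "high_k")) {
    rlang::abort("Protocol must contain a high-K epoch.",
                 class = "nociphys_invalid_protocol")
  }
  dur <- protocol_duration(protocol)
  n <- round(cfg$fs * dur)
  t <- (seq_len(n) - 1) / cfg$fs
  caps_idx <- which(protocol$kind == "capsaicin")
  if (n_cells == 0) {
    return(list(cells = tibble::tibble(cell_id = character(),
                                       trace = list()),
                truth = tibble::tibble(cell_id = character(),
                                       category = character(),
                                       responds_capsaicin = logical(),
                                       responds_mustard_oil = logical(),
                                       sensitized = logical(),
                                       amp_caps = numeric()),
                protocol = protocol))
  }
  with_seed(cfg$seed, {
    u <- stats::runif(n_cells)
    p_caps <- frac_caps
    p_hk <- frac_caps + frac_highk_only
    category <- ifelse(u < p_caps, "capsaicin", ifelse(u < p_hk,
                       "high_k_only", "mustard_oil_only"))
    caps <- category == "capsaicin"
    mo <- caps & (stats::runif(n_cells) < frac_mo_given_caps)
    category[caps & mo] <- "caps_mo"
    category[caps & !mo] <- "caps_only"
    mo_only <- category == "mustard_oil_only"
    sens <- caps & (stats::runif(n_cells) < frac_sensitized)
    amp_caps <- stats::runif(n_cells, 0.3, 0.8)
    amp_mo <- stats::runif(n_cells, 0.2, 0.6)
    amp_hk <- stats::runif(n_cells, 0.8, 1.2)
    heat_gain <- stats::runif(n_cells, 0.3, 1.0)
    temps <- protocol$magnitude[protocol$kind == "temperature"]
    traces <- lapply(seq_len(n_cells), function(i) {
      x <- rep(1.0, n)
      for (e in seq_len(nrow(protocol))) {
        kind <- protocol$kind[[e]]
        amp <- switch(
          kind,
          capsaicin = if (caps[i]) {
            pulse_no <- match(e, caps_idx)
            a <- amp_caps[i]
            if (sens[i] && !is.na(pulse_no) && pulse_no >= 6)
              a <- a * sens_multiplier
            a
          } else 0,
          mustard_oil = if (mo[i] || mo_only[i]) amp_mo[i] else 0,
          high_k = amp_hk[i],
          temperature = if (caps[i] && length(temps) > 0) {
            heat_gain[i] *
              max(0, (protocol$magnitude[[e]] - 33) / (max(temps) - 33))
          } else 0,
          0)
        if (amp > 0) {
          x <- x + calcium_kernel(t - protocol$onset_s[[e]], amp)
        }
      }
      if (cfg$noise_sd > 0) x <- x + stats::rnorm(n, 0, cfg$noise_sd)
      trace(x, fs = cfg$fs, units = "ratio", kind = "fluorescence_ratio")
    })
    ids <- sprintf("cell%04d", seq_len(n_cells))
    list(cells = tibble::tibble(cell_id = ids, trace = traces),
         truth = tibble::tibble(cell_id = ids, category = category,
                                responds_capsaicin = caps,
                                responds_mustard_oil = mo | mo_only,
                                sensitized = sens, amp_caps = amp_caps,
                                amp_mo = amp_mo, amp_high_k = amp_hk,
                                heat_gain = heat_gain),
         protocol = protocol)
  })
}

#' Simulate an overdispersed genes-by-samples count matrix
#'
#' Negative-binomial counts with per-gene means (optionally per-group mean
#' vectors to emulate marker structure) scaled by per-sample library-size
#' multipliers. Ground truth records those multipliers, which a
#' median-of-ratios estimator should recover up to a common scale.
#'
#' @param n_genes,n_samples Matrix dimensions.
#' @param group_means Optional `n_genes x n_groups` matrix of expected
#'   counts; defaults to a single log-normal mean vector shared by all
#'   samples.
#' @param sample_groups Group label per sample (columns of `group_means`).
#' @param dispersion NB dispersion (`size = 1/dispersion`); must be > 0.
#' @param libsize Per-sample library-size multipliers; drawn uniformly from
#'   `libsize_range` when omitted.
#' @param libsize_range Range for random multipliers.
#' @param cfg A [sim_config()] (only the seed is used).
#' @return A list with `counts` (matrix) and `truth` (`libsize`, the mean
#'   structure and dispersion).
#' @export
sim_counts_matrix <- function(n_genes, n_samples, group_means = NULL,
                              sample_groups = NULL, dispersion = 0.05,
                              libsize = NULL, libsize_range = c(0.7, 1.4),
                              cfg = sim_config()) {
  stopifnot_positive(dispersion = dispersion)
  with_seed(cfg$seed, {
    if (is.null(group_means)) {
      group_means <- matrix(stats::rlnorm(n_genes, log(100), 1.2), ncol = 1)
    }
    if (any(group_means < 0)) {
      rlang::abort("All means must be >= 0.",
                   class = "nociphys_invalid_parameter")
    }
    if (is.null(sample_groups)) {
      sample_groups <- rep(1L, n_samples)
    }
    if (is.null(libsize)) {
      libsize <- stats::runif(n_samples, libsize_range[[1]],
                              libsize_range[[2]])
    }
    counts <- matrix(0, n_genes, n_samples,
                     dimnames = list(sprintf("gene%05d", seq_len(n_genes)),
                                     sprintf("sample%02d",
                                             seq_len(n_samples))))
    for (j in seq_len(n_samples)) {
      mu <- group_means[, sample_groups[[j]]] * libsize[[j]]
      counts[, j] <- stats::rnbinom(n_genes, mu = mu, size = 1 / dispersion)
    }
    list(counts = counts,
         truth = list(libsize = stats::setNames(libsize, colnames(counts)),
                      group_means = group_means,
                      sample_groups = sample_groups,
                      dispersion = dispersion))
  })
}
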