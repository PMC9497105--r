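#' Fit mechanical-current inactivation kinetics
#'
#' Biexponential fit from the post-stimulus current peak with the asymptote
#' fixed to the pre-stimulus baseline mean. The trace is zero-phase
#' low-pass filtered at 1 kHz first (matching the analysis bandwidth of the
#' recordings). A step without a discernible peak -- the inward deviation
#' never exceeding `max(6 x baseline SD, min_peak_pa)` -- is a no-response
#' result, not an error. Recordings whose post-stimulus baseline shifts by
#' more than 3 pre-stimulus SDs are flagged as leak-excluded.
#'
#' @param trace A current [trace()] (inward negative).
#' @param stim_onset Stimulus onset (s); at least 20 ms of pre-stimulus
#'   baseline is required.
#' @param lowpass Software filter cutoff in Hz (skipped if the trace is
#'   sampled too slowly to support it).
#' @param min_peak_pa Absolute floor for calling a discernible peak (pA).
#' @param peak_search_ms How far past the onset to search for the peak.
#' @return A list of class `mech_fit`: `responded`, `peak_pa` (relative to
#'   baseline, signed), `peak_time`, `baseline`, `leak_flag`, and -- for
#'   responding steps -- `fit` (an `exp_fit`) with `weighted_tau` in ms.
#' @export
fit_inactivation <- function(trace, stim_onset, lowpass = 1000,
                             min_peak_pa = 10, peak_search_ms = 100) {
  if (stim_onset - trace$t0 < 0.02) {
    rlang::abort("Need at least 20 ms of pre-stimulus baseline.",
                 class = "nociphys_insufficient_data")
  }
  filt <- if (lowpass < trace$fs / 2) lowpass_filter(trace, lowpass) else trace
  tt <- trace_times(filt)
  # the zero-phase filter leaks the stimulus backwards by ~2/cutoff; keep
  # that stretch out of the baseline estimate
  guard_s <- if (lowpass < trace$fs / 2) 2 / lowpass else 0
  pre <- filt$samples[tt < stim_onset - guard_s]
  baseline <- mean(pre)
  base_sd <- stats::sd(pre)
  i_on <- 1 + round((stim_onset - filt$t0) * filt$fs)
  i_hi <- min(length(filt$samples),
              i_on + round(peak_search_ms / 1000 * filt$fs))
  seg <- filt$samples[i_on:i_hi]
  i_peak <- i_on + which.min(seg) - 1          # inward = most negative
  peak_rel <- filt$samples[[i_peak]] - baseline
  # relative amplitude convention: raw-trace extremum minus raw baseline
  raw_base <- mean(trace$samples[tt < stim_onset])
  peak_raw <- min(trace$samples[i_on:i_hi]) - raw_base
  thresh <- max(6 * base_sd, min_peak_pa)
  n <- length(filt$samples)
  late_idx <- max(i_peak + 1, n - round(0.02 * filt$fs)):n
  late <- filt$samples[late_idx]
  if (-peak_rel < thresh) {
    # leak exclusion: late baseline shifted > 3 SD from the pre-stimulus mean
    leak_flag <- is.finite(base_sd) && base_sd > 0 &&
      abs(mean(late) - baseline) > 3 * base_sd
    return(structure(list(responded = FALSE, peak_pa = peak_rel,
                          peak_raw_pa = peak_raw, peak_time = tt[[i_peak]],
                          baseline = baseline, leak_flag = leak_flag,
                          fit = NULL),
                     class = "mech_fit"))
  }
  # seed tau, then fit out to ~5 tau past the peak; the fit starts past the
  # zero-phase filter transient (~1.5 / cutoff), where a filtered
  # exponential is again an exact exponential with the same tau
  dec <- filt$samples[i_peak:n] - baseline
  # seed on the initial contiguous decay only (up to the first return to
  # within 5% of baseline); distant noise samples would corrupt the slope
  below <- which(-dec < -peak_rel / 20)
  cut <- if (length(below) > 0) max(3L, below[[1]] - 1L) else length(dec)
  pos <- which(-dec[seq_len(cut)] > 0)
  tau_seed_ms <- if (length(pos) >= 3) {
    tms <- (pos - 1) / filt$fs * 1000
    sl <- stats::coef(stats::lm(log(-dec[pos]) ~ tms))[[2]]
    if (sl < 0) -1 / sl else 20
  } else 20
  skip_s <- if (lowpass < trace$fs / 2) 1.5 / lowpass else 1 / filt$fs
  w_start <- filt$t0 + (i_peak - 1) / filt$fs + skip_s
  w_end <- min(filt$t0 + (n - 1) / filt$fs,
               w_start + max(5 * tau_seed_ms, 2) / 1000)
  fit <- fit_decay(filt, window = c(w_start, w_end), n_components = 2,
                   baseline = baseline, amp_sign = "negative")
  # leak exclusion measured against the fitted decay, so slowly adapting
  # currents that have not finished inactivating are not misflagged
  late_ms <- (late_idx - i_peak) / filt$fs * 1000 - skip_s * 1000
  pred_late <- predict_exp_fit(fit, late_ms)
  leak_flag <- is.finite(base_sd) && base_sd > 0 &&
    abs(mean(late - pred_late)) > 3 * base_sd
  # re-reference component amplitudes to the stimulus onset, so the
  # weighted tau and weighted amplitude describe the current where it
  # starts, not where the fit window starts
  off_ms <- (w_start - stim_onset) * 1000
  amps <- fit$amplitudes
  # a component decaying below ~5% before the window starts is not
  # identifiable from the fitted stretch; treat it as spurious
  keep <- abs(amps) > 1e-9 * sum(abs(amps)) & off_ms / fit$taus < 3
  if (!any(keep)) keep <- abs(amps) > 1e-9 * sum(abs(amps))
  amps[!keep] <- 0
  amps[keep] <- amps[keep] * exp(pmin(off_ms / fit$taus[keep], 3))
  # components carrying <5% of the amplitude are fit debris (they absorb
  # residual baseline noise); they do not enter the weighted constant
  amps[abs(amps) < 0.05 * sum(abs(amps))] <- 0
  fit <- new_exp_fit(baseline = fit$baseline, amplitudes = amps,
                     taus = fit$taus, window = fit$window, rmse = fit$rmse,
                     n_components = fit$n_components,
                     degenerate = fit$degenerate)
  structure(list(responded = TRUE, peak_pa = peak_rel,
                 peak_raw_pa = peak_raw, peak_time = tt[[i_peak]],
                 baseline = baseline, leak_flag = leak_flag, fit = fit),
            class = "mech_fit")
}

#' Classify a mechanically-activated current by its inactivation constant
#'
#' Rapidly adapting (RA) below 10 ms, intermediate (IA) from 10 to 30 ms,
#' slowly adapting (SA) above 30 ms. Boundary values (exactly 10 or 30 ms)
#' are assigned to IA.
#'
#' @param weighted_tau Amplitude-weighted biexponential inactivation time
#'   constant in ms (> 0).
#' @return `"RA"`, `"IA"` or `"SA"`.
#' @export
classify_mech <- function(weighted_tau) {
  if (any(!is.finite(weighted_tau)) || any(weighted_tau <= 0)) {
    rlang::abort("`weighted_tau` must be positive.",
                 class = "nociphys_invalid_parameter")
  }
  dplyr::case_when(weighted_tau < 10 ~ "RA",
                   weighted_tau <= 30 ~ "IA",
                   TRUE ~ "SA")
}

#' Responder criteria for mechanical stimulation
#'
#' `responder_call_human()`: a cell is mechanically active if any
#' indentation step of at most 10 um evoked an inward current larger in
#' magnitude than 40 pA (i.e. more negative than -40 pA); with no step
#' <= 10 um tested the call is indeterminate (`NA`). Any qualifying step
#' suffices; the full series need not be exhausted.
#'
#' `responder_call_mouse()`: for the 10-step, 1-um-increment series, the
#' cell responds if the maximum evoked current magnitude exceeds 50 pA.
#' Cells flagged as detached mid-series are excluded (`NA`).
#'
#' @param responses A tibble with columns `displacement_um` and `peak_pa`
#'   (signed, relative to baseline); for the mouse call optionally a
#'   logical `detached` column.
#' @return `TRUE`, `FALSE` or `NA`.
#' @export
responder_call_human <- function(responses) {
  ok <- responses$displacement_um <= 10
  if (!any(ok)) return(NA)
  any(responses$peak_pa[ok] < -40)
}

#' @rdname responder_call_human
#' @export
responder_call_mouse <- function(responses) {
  if (nrow(responses) == 0) {
    rlang::abort("Empty step series.", class = "nociphys_empty_input")
  }
  if ("detached" %in% names(responses) && any(responses$detached)) {
    return(NA)
  }
  max(abs(responses$peak_pa)) > 50
}

#' Mechanical-current amplitude, both conventions
#'
#' The fit-weighted amplitude is the sum of the absolute biexponential
#' component amplitudes carrying the sign of the current, extrapolated from
#' the fit-window start back to the stimulus onset along each component;
#' the relative amplitude is the raw-trace extremum minus the pre-stimulus
#' baseline. On clean responses both agree; on noisy traces the relative
#' method is biased outward by the noise extremum, which is why the fit
#' method is preferred for small currents.
#'
#' @param mech A `mech_fit` from [fit_inactivation()].
#' @return A one-row tibble: `fit_weighted_pa`, `relative_pa`.
#' @export
mech_amplitude <- function(mech) {
  rel <- if (!is.null(mech$peak_raw_pa)) mech$peak_raw_pa else mech$peak_pa
  fw <- if (!is.null(mech$fit) && !mech$fit$degenerate) {
    off <- if (is.null(mech$fit_offset_ms)) 0 else mech$fit_offset_ms
    sign(rel) * sum(abs(mech$fit$amplitudes) * exp(off / mech$fit$taus))
  } else if (is.null(mech$fit)) {
    if (mech$responded) NA_real_ else 0
  } else 0
  tibble::tibble(fit_weighted_pa = fw,
                 relative_pa = if (mech$responded) rel else 0)
}

#' Analyze one cell's mechanical step series
#'
#' Fits every indentation step, applies the species responder criterion and
#' classifies the cell by the weighted inactivation constant of its
#' largest-amplitude responding step.
#'
#' @param steps A tibble with columns `displacement_um`, `trace`
#'   (list-column of current traces) and `stim_onset` (s).
#' @param species `"human"` (-40 pA criterion at <= 10 um) or `"mouse"`
#'   (50 pA criterion over the series).
#' @param cell_id Identifier carried into the output.
#' @return A one-row tibble: `cell_id`, `max_displacement_tested`,
#'   `peak_pa`, `fit_weighted_pa`, `weighted_tau`, `class_label`
#'   (RA/IA/SA/NR), `responder`, `leak_excluded`.
#' @export
analyze_mech_cell <- function(steps, species = c("human", "mouse"),
                              cell_id = "cell") {
  species <- match.arg(species)
  fits <- purrr::map2(steps$trace, steps$stim_onset,
                      function(tr, on) fit_inactivation(tr, on))
  per_step <- tibble::tibble(
    displacement_um = steps$displacement_um,
    peak_pa = purrr::map_dbl(fits, "peak_pa"),
    responded = purrr::map_lgl(fits, "responded"),
    leak = purrr::map_lgl(fits, "leak_flag"))
  responder <- if (species == "human") {
    responder_call_human(per_step)
  } else {
    responder_call_mouse(per_step)
  }
  best <- which(per_step$responded)
  best <- best[which.max(abs(per_step$peak_pa[best]))]
  has_fit <- length(best) == 1 && !is.null(fits[[best]]$fit)
  wt <- if (has_fit) fits[[best]]$fit$weighted_tau else NA_real_
  label <- if (isTRUE(responder) && is.finite(wt)) classify_mech(wt)
           else "NR"
  tibble::tibble(
    cell_id = cell_id,
    max_displacement_tested = max(steps$displacement_um),
    peak_pa = if (length(best) == 1) per_step$peak_pa[[best]] else 0,
    fit_weighted_pa = if (has_fit) mech_amplitude(fits[[best]])$fit_weighted_pa
                      else NA_real_,
    weighted_tau = if (label == "NR") NA_real_ else wt,
    class_label = label, responder = responder,
    leak_excluded = any(per_step$leak))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact p-value by enumeration over all tables with the observed margins,
#' summing the hypergeometric probabilities not exceeding that of the
#' observed table (with the customary relative tolerance for ties).
#'
#' @param table A 2x2 matrix (or coercible) of nonnegative integer counts.
#' @return The two-sided p-value.
#' @export
fisher_exact <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2, 2)) || any(m < 0) ||
      any(abs(m - round(m)) > 1e-8)) {
    rlang::abort("`table` must be a 2x2 matrix of nonnegative integers.",
                 class = "nociphys_invalid_parameter")
  }
  m <- round(m)
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); c2 <- sum(m[, 2])
  a <- m[1, 1]
  support <- max(0, r1 - c2):min(r1, c1)
  probs <- stats::dhyper(support, c1, c2, r1)
  p_obs <- stats::dhyper(a, c1, c2, r1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(1, p)
}

#' Population summary of mechanical-current classes
#'
#' Counts and fractions of RA/IA/SA responders and non-responders (NR).
#' Percentages follow the figure-caption convention: round half away from
#' zero, integer percent when the denominator resolves 1% steps and one
#' decimal otherwise (5 of 18 SA responders is 27.8%).
#'
#' @param cells A tibble with a `class_label` column (RA/IA/SA/NR), e.g.
#'   rows from [analyze_mech_cell()].
#' @return A tibble with one row per class: `class_label`, `n`, `fraction`,
#'   `percent`. Fractions sum to 1 (all zero for empty input).
#' @export
mech_population_summary <- function(cells) {
  lv <- c("RA", "IA", "SA", "NR")
  n_tot <- nrow(cells)
  counts <- vapply(lv, function(l) sum(cells$class_label == l), integer(1))
  tibble::tibble(
    class_label = lv, n = unname(counts),
    fraction = if (n_tot > 0) unname(counts) / n_tot else rep(0, 4),
    percent = vapply(unname(counts), format_percent, numeric(1),
                     n = n_tot, USE.NAMES = FALSE))
}
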