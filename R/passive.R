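#' Input resistance from a capacitive-transient peak
#'
#' Divides the applied voltage step by the relative current of the first
#' capacitive transient (peak minus pre-step baseline). With an
#' instantaneously charging pipette this ratio is dominated by the series
#' (access) resistance; the companion steady-state estimate reported by
#' [passive_properties()] lets users audit the difference.
#'
#' @param v_step_mv Voltage step (mV).
#' @param transient_peak_pa Peak current relative to the pre-step baseline
#'   (pA); must be nonzero.
#' @return Resistance in MOhm.
#' @export
input_resistance <- function(v_step_mv, transient_peak_pa) {
  if (transient_peak_pa == 0) {
    rlang::abort("Transient peak must be nonzero.",
                 class = "nociphys_division_error")
  }
  abs(v_step_mv / transient_peak_pa) * 1000
}

#' Whole-cell capacitance from a decay fit
#'
#' `Cm = weighted_tau / R`, with unit bookkeeping ms / MOhm = nF, reported
#' in pF. A degenerate fit (flat transient) yields 0 pF with a warning.
#'
#' @param fit An [fit_decay()] result.
#' @param r_mohm Resistance in MOhm (> 0).
#' @return Capacitance in pF.
#' @export
capacitance <- function(fit, r_mohm) {
  stopifnot_positive(r_mohm = r_mohm)
  wt <- fit$weighted_tau
  if (is.na(wt) || fit$degenerate) {
    rlang::warn("Degenerate fit: capacitance reported as 0 pF.")
    return(0)
  }
  if (wt <= 0) {
    rlang::abort("weighted_tau must be positive.",
                 class = "nociphys_invalid_parameter")
  }
  wt / r_mohm * 1000
}

#' Passive membrane properties from capacitive-transient sweeps
#'
#' The full recipe: average the repeated current responses to a small
#' hyperpolarizing voltage step, fit a biexponential decay to the first
#' capacitive transient (window: from the sample after the transient peak
#' to five seed time constants later), estimate resistance as
#' `|v_step / peak|` and capacitance as the weighted decay constant divided
#' by that resistance. Because the transient peak is measured against the
#' pre-step baseline, the resistance estimate approximates the series
#' resistance and the capacitance estimate is exact in the limit
#' `Rin >> Rs` (bias grows like `Rs / Rin`). The steady-state resistance
#' `|v_step / (steady - baseline)|`, which approximates `Rs + Rin`, is
#' reported alongside for audit.
#'
#' @param sweeps A [sweep_set()] of current sweeps with a common stimulus
#'   onset.
#' @param v_step_mv Command step (mV).
#' @param step_dur_s Step duration (s), used to bound the fit window.
#' @param peak_search_ms How far past the onset to search for the transient
#'   peak (ms).
#' @return A one-row tibble: `r_input_mohm`, `c_m_pf`, `weighted_tau_ms`,
#'   `peak_pa`, `baseline_pa`, `steady_pa`, `r_steady_mohm`, `rmse`.
#' @export
passive_properties <- function(sweeps, v_step_mv = -15, step_dur_s = 0.1,
                               peak_search_ms = 5) {
  avg <- average_sweeps(sweeps)
  onset <- sweeps$stim_onset
  pre <- avg$samples[trace_times(avg) < onset]
  if (length(pre) < 2) {
    rlang::abort("Need pre-step baseline samples before the stimulus onset.",
                 class = "nociphys_insufficient_data")
  }
  baseline <- mean(pre)
  i_on <- 1 + round((onset - avg$t0) * avg$fs)
  i_hi <- min(length(avg), i_on + round(peak_search_ms / 1000 * avg$fs))
  seg <- avg$samples[i_on:i_hi]
  i_peak <- i_on + which.max(abs(seg - baseline)) - 1
  peak_rel <- avg$samples[[i_peak]] - baseline
  r_est <- input_resistance(v_step_mv, peak_rel)
  # seed tau from a log-linear fit against the tail of the step epoch
  i_end_step <- min(length(avg), 1 + floor((onset + step_dur_s - avg$t0) *
                                             avg$fs) - 1)
  tail_idx <- max(i_peak + 1, i_end_step - round(0.1 * (i_end_step - i_peak))):i_end_step
  steady0 <- mean(avg$samples[tail_idx])
  dec <- avg$samples[(i_peak + 1):i_end_step] - steady0
  sgn <- sign(peak_rel)
  pos <- which(sgn * dec > max(sgn * dec) / 50)
  tau_seed_ms <- if (length(pos) >= 3) {
    tt <- (pos - 1) / avg$fs * 1000
    sl <- stats::coef(stats::lm(log(sgn * dec[pos]) ~ tt))[[2]]
    if (sl < 0) -1 / sl else 5
  } else 5
  w_start <- avg$t0 + i_peak / avg$fs          # sample after the peak
  w_end <- min(onset + step_dur_s,
               w_start + max(5 * tau_seed_ms / 1000, 12 / avg$fs))
  fit <- fit_decay(avg, window = c(w_start, w_end), n_components = 2)
  cm <- capacitance(fit, r_est)
  steady <- fit$baseline
  steady_rel <- steady - baseline
  r_steady <- if (abs(steady_rel) > 0) abs(v_step_mv / steady_rel) * 1000
              else NA_real_
  tibble::tibble(
    r_input_mohm = r_est, c_m_pf = cm, weighted_tau_ms = fit$weighted_tau,
    peak_pa = peak_rel, baseline_pa = baseline, steady_pa = steady,
    r_steady_mohm = r_steady, rmse = fit$rmse)
}
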