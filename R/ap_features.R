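smooth_for_aps <- function(trace, smooth_cutoff = NULL) {
  if (is.null(smooth_cutoff)) {
    smooth_cutoff <- min(5000, trace$fs / 4)
  }
  if (smooth_cutoff >= trace$fs / 2) return(trace)
  lowpass_filter(trace, smooth_cutoff)
}

#' Detect action potentials in a current-clamp trace
#'
#' An AP event is a suprathreshold upstroke: the smoothed derivative dV/dt
#' crossing `dvdt_threshold` defines the AP threshold (time and voltage),
#' and the subsequent local voltage maximum is the peak. Events within
#' `refractory_ms` of a previous peak are suppressed. The trace is
#' zero-phase low-pass filtered (default 5 kHz, or fs/4 if lower) before
#' the derivative so sampling noise does not trigger spurious crossings.
#'
#' @param trace A voltage [trace()].
#' @param dvdt_threshold Upstroke threshold in mV/ms (default 10).
#' @param refractory_ms Minimum separation between events (ms).
#' @param smooth_cutoff Low-pass cutoff in Hz applied before the
#'   derivative; `NULL` picks the default.
#' @param min_amp_mv Minimum threshold-to-peak amplitude for a genuine AP;
#'   slope crossings whose peak rises less than this above the crossing
#'   voltage are rejected as noise.
#' @return A tibble with one row per AP: `peak_time`, `peak_v`,
#'   `threshold_time`, `threshold_v`. Empty for silent traces.
#' @export
detect_aps <- function(trace, dvdt_threshold = 10, refractory_ms = 2,
                       smooth_cutoff = NULL, min_amp_mv = 20) {
  sm <- smooth_for_aps(trace, smooth_cutoff)
  v <- sm$samples
  n <- length(v)
  k <- max(1L, round(trace$fs * 1e-4))   # ~0.1 ms half-window slope
  if (n < 2 * k + 2) {
    return(tibble::tibble(peak_time = numeric(), peak_v = numeric(),
                          threshold_time = numeric(),
                          threshold_v = numeric()))
  }
  idx <- (k + 1):(n - k)
  dvdt <- (v[idx + k] - v[idx - k]) / (2 * k / trace$fs * 1000)  # mV/ms
  above <- dvdt >= dvdt_threshold
  crossings <- idx[which(above & !c(FALSE, above[-length(above)]))]
  out <- list()
  last_peak <- -Inf
  peak_span <- max(2L, round(trace$fs * 5e-3))  # search peak within 5 ms
  for (ci in crossings) {
    t_cross <- trace$t0 + (ci - 1) / trace$fs
    if (t_cross < last_peak + refractory_ms / 1000) next
    hi <- min(n, ci + peak_span)
    pk <- ci + which.max(v[ci:hi]) - 1
    # refine the peak on the raw trace (smoothing can flatten the apex)
    r_lo <- max(1L, pk - k); r_hi <- min(n, pk + k)
    pk <- r_lo + which.max(trace$samples[r_lo:r_hi]) - 1
    t_peak <- trace$t0 + (pk - 1) / trace$fs
    if (t_peak <= last_peak + refractory_ms / 1000) next
    if (v[[pk]] - v[[ci]] < min_amp_mv) next
    out[[length(out) + 1]] <- tibble::tibble(
      peak_time = t_peak, peak_v = v[[pk]], threshold_time = t_cross,
      threshold_v = v[[ci]])
    last_peak <- t_peak
  }
  if (length(out) == 0) {
    return(tibble::tibble(peak_time = numeric(), peak_v = numeric(),
                          threshold_time = numeric(),
                          threshold_v = numeric()))
  }
  dplyr::bind_rows(out)
}

interp_crossing <- function(t, v, level, rising) {
  # first index i where the segment (i, i+1) crosses `level`
  if (rising) {
    hit <- which(v[-length(v)] < level & v[-1] >= level)
  } else {
    hit <- which(v[-length(v)] >= level & v[-1] < level)
  }
  if (length(hit) == 0) return(NA_real_)
  i <- hit[[1]]
  t[i] + (level - v[i]) / (v[i + 1] - v[i]) * (t[i + 1] - t[i])
}

#' AP half-width
#'
#' Width of the action potential at 50% of the threshold-to-peak amplitude,
#' with linear interpolation between samples on both flanks.
#'
#' @param trace A voltage [trace()] (ideally the same smoothed trace used
#'   for detection).
#' @param ap One row of [detect_aps()] output (or a list with `peak_time`,
#'   `peak_v`, `threshold_time`, `threshold_v`).
#' @return Half-width in ms.
#' @export
ap_half_width <- function(trace, ap) {
  amp <- ap$peak_v - ap$threshold_v
  if (amp <= 0) {
    rlang::abort("Degenerate AP: peak is not above threshold.",
                 class = "nociphys_degenerate_ap")
  }
  level <- ap$threshold_v + amp / 2
  tt <- trace_times(trace)
  v <- trace$samples
  pre <- tt >= ap$threshold_time - 2e-3 & tt <= ap$peak_time
  post <- tt >= ap$peak_time & tt <= ap$peak_time + 50e-3
  t_up <- interp_crossing(tt[pre], v[pre], level, rising = TRUE)
  t_dn <- interp_crossing(tt[post], v[post], level, rising = FALSE)
  if (is.na(t_up) || is.na(t_dn)) {
    rlang::abort("Could not locate both half-amplitude crossings.",
                 class = "nociphys_degenerate_ap")
  }
  (t_dn - t_up) * 1000
}

# AHP minimum within `window_ms` after the peak.
find_ahp <- function(trace, ap, window_ms = 20) {
  tt <- trace_times(trace)
  sel <- which(tt > ap$peak_time & tt <= ap$peak_time + window_ms / 1000)
  if (length(sel) == 0) return(NULL)
  i <- sel[[which.min(trace$samples[sel])]]
  list(time = tt[[i]], v = trace$samples[[i]], index = i)
}

#' Repolarization shoulder index
#'
#' A monoexponential is fitted between the AP peak and the AHP minimum
#' (the voltage minimum within 20 ms after the peak). The shoulder index is
#' the largest positive residual (data above the fit) divided by the
#' threshold-to-peak amplitude; a repolarization with a genuine shoulder
#' bulges above the best monoexponential, a plain spike does not. The
#' binary call uses `call_threshold` (default 3% of AP amplitude, comfortably above the residual floor left by waveform discretization and filtering).
#'
#' @inheritParams ap_half_width
#' @param call_threshold Index above which `has_shoulder` is `TRUE`.
#' @return A list: `index`, `has_shoulder`. On fit failure both are `NA`.
#' @export
shoulder_index <- function(trace, ap, call_threshold = 0.03) {
  ahp <- find_ahp(trace, ap)
  if (is.null(ahp)) {
    return(list(index = NA_real_, has_shoulder = NA))
  }
  i_peak <- 1 + round((ap$peak_time - trace$t0) * trace$fs)
  w <- c(trace$t0 + (i_peak - 1) / trace$fs, ahp$time)
  fit <- tryCatch(fit_decay(trace, window = w, n_components = 1),
                  error = function(e) NULL)
  if (is.null(fit) || fit$degenerate) {
    return(list(index = NA_real_, has_shoulder = NA))
  }
  idx <- window_indices(trace, w)
  t_ms <- (idx - idx[[1]]) / trace$fs * 1000
  res <- trace$samples[idx] - predict_exp_fit(fit, t_ms)
  amp <- ap$peak_v - ap$threshold_v
  index <- max(0, max(res)) / amp
  list(index = index, has_shoulder = index > call_threshold)
}

#' AHP recovery time constant
#'
#' Monoexponential fit of fixed 32 ms length starting at the AHP minimum
#' (the voltage minimum within 20 ms after the AP peak). The feature is
#' gated: it is absent (`NA`) unless the AHP amplitude -- pre-AP baseline
#' minus AHP minimum -- is at least 0.1 mV and no second AP occurs within
#' the fit window; a trace ending before the window completes also yields
#' `NA`.
#'
#' @inheritParams ap_half_width
#' @param next_ap_time Peak time of the following AP (s), `Inf` if none.
#' @param baseline_v Pre-AP baseline voltage used for the amplitude gate;
#'   defaults to the AP threshold voltage.
#' @param fit_length_ms Fit window length (ms).
#' @param min_ahp_mv Minimum AHP amplitude for the fit to be attempted.
#' @return tau in ms, or `NA_real_` when gated out.
#' @export
ap_tau_ahp <- function(trace, ap, next_ap_time = Inf, baseline_v = NULL,
                       fit_length_ms = 32, min_ahp_mv = 0.1) {
  ahp <- find_ahp(trace, ap)
  if (is.null(ahp)) return(NA_real_)
  if (is.null(baseline_v)) baseline_v <- ap$threshold_v
  if (baseline_v - ahp$v < min_ahp_mv) return(NA_real_)
  w_end <- ahp$time + fit_length_ms / 1000
  if (next_ap_time <= w_end) return(NA_real_)
  if (w_end > trace$t0 + trace_duration(trace) - 1 / trace$fs) {
    return(NA_real_)
  }
  fit <- tryCatch(
    fit_decay(trace, window = c(ahp$time, w_end), n_components = 1),
    error = function(e) NULL)
  if (is.null(fit) || fit$degenerate) return(NA_real_)
  fit$taus[[1]]
}

#' Resting membrane potential
#'
#' Mean voltage over a stimulus-free window.
#'
#' @param trace A voltage [trace()].
#' @param window `(start, end)` in seconds.
#' @param protocol Optional [stimulus_protocol()]; the window must not
#'   overlap any of its epochs.
#' @return Mean voltage in mV.
#' @export
resting_potential <- function(trace, window, protocol = NULL) {
  if (window[[2]] <= window[[1]]) {
    rlang::abort("Empty window.", class = "nociphys_invalid_parameter")
  }
  if (!is.null(protocol)) {
    protocol <- as_protocol(protocol)
    overlap <- protocol$onset_s < window[[2]] &
      protocol$onset_s + protocol$duration_s > window[[1]]
    if (any(overlap)) {
      rlang::abort("Window overlaps a stimulation epoch.",
                   class = "nociphys_contract_violation")
    }
  }
  mean(trace$samples[window_indices(trace, window)])
}

#' Extract all AP features from a trace
#'
#' Runs detection and per-AP feature extraction (half-width, AHP metrics,
#' shoulder quantification, AHP recovery tau) on a zero-phase smoothed copy
#' of the trace. Absolute-voltage features (`v_rest`, `peak_v`,
#' `threshold_v`, `ahp_min_v`) depend on the trace's offset; all others are
#' offset- and translation-invariant.
#'
#' @param trace A voltage [trace()].
#' @param dvdt_threshold,refractory_ms,smooth_cutoff Passed to
#'   [detect_aps()].
#' @param shoulder_threshold Passed to [shoulder_index()].
#' @param rest_window Window for [resting_potential()]; defaults to the
#'   stretch before the first AP threshold (or the whole trace if silent).
#' @return A tibble with one row per AP: `peak_time`, `peak_v`,
#'   `threshold_v`, `half_width`, `ahp_min_v`, `ahp_min_time`,
#'   `ahp_amplitude`, `tau_ahp`, `shoulder_index`, `has_shoulder`,
#'   `v_rest`.
#' @export
ap_features <- function(trace, dvdt_threshold = 10, refractory_ms = 2,
                        smooth_cutoff = NULL, shoulder_threshold = 0.03,
                        rest_window = NULL) {
  sm <- smooth_for_aps(trace, smooth_cutoff)
  aps <- detect_aps(trace, dvdt_threshold, refractory_ms, smooth_cutoff)
  if (nrow(aps) == 0) {
    return(tibble::tibble(
      peak_time = numeric(), peak_v = numeric(), threshold_v = numeric(),
      half_width = numeric(), ahp_min_v = numeric(),
      ahp_min_time = numeric(), ahp_amplitude = numeric(),
      tau_ahp = numeric(), shoulder_index = numeric(),
      has_shoulder = logical(), v_rest = numeric()))
  }
  if (is.null(rest_window)) {
    r_end <- max(trace$t0 + 2 / trace$fs,
                 aps$threshold_time[[1]] - 2e-3)
    rest_window <- c(trace$t0, min(r_end, trace$t0 + trace_duration(trace)))
  }
  v_rest <- mean(sm$samples[window_indices(sm, rest_window)])
  rows <- purrr::map(seq_len(nrow(aps)), function(i) {
    ap <- aps[i, ]
    nxt <- if (i < nrow(aps)) aps$peak_time[[i + 1]] else Inf
    hw <- tryCatch(ap_half_width(sm, ap), error = function(e) NA_real_)
    ahp <- find_ahp(sm, ap)
    sh <- shoulder_index(sm, ap, call_threshold = shoulder_threshold)
    tibble::tibble(
      peak_time = ap$peak_time, peak_v = ap$peak_v,
      threshold_v = ap$threshold_v, half_width = hw,
      ahp_min_v = if (is.null(ahp)) NA_real_ else ahp$v,
      ahp_min_time = if (is.null(ahp)) NA_real_ else ahp$time,
      ahp_amplitude = if (is.null(ahp)) NA_real_ else v_rest - ahp$v,
      tau_ahp = ap_tau_ahp(sm, ap, next_ap_time = nxt,
                           baseline_v = v_rest),
      shoulder_index = sh$index, has_shoulder = sh$has_shoulder,
      v_rest = v_rest)
  })
  dplyr::bind_rows(rows)
}
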