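#' Baseline-normalized fluorescence (dF/F0)
#'
#' `(F - F0) / F0` with `F0` the mean signal over the window before the
#' first stimulus epoch.
#'
#' @param trace A fluorescence-ratio [trace()].
#' @param protocol A [stimulus_protocol()]; the first epoch onset defines
#'   the end of the baseline window.
#' @return A [trace()] of kind `dff`.
#' @export
dff <- function(trace, protocol) {
  protocol <- as_protocol(protocol)
  first_onset <- min(protocol$onset_s)
  if (first_onset <= trace$t0) {
    rlang::abort("First epoch must start after the trace begins (F0 window).",
                 class = "nociphys_invalid_baseline")
  }
  f0 <- mean(trace$samples[trace_times(trace) < first_onset])
  if (!is.finite(f0) || f0 <= 0) {
    rlang::abort("Baseline F0 must be positive.",
                 class = "nociphys_invalid_baseline")
  }
  trace((trace$samples - f0) / f0, fs = trace$fs, units = "dimensionless",
        kind = "dff", t0 = trace$t0)
}

#' Per-epoch peak amplitudes
#'
#' For each epoch the response amplitude is the signal maximum over
#' `[onset, onset + duration + post_window]` minus the local pre-epoch
#' baseline (mean over up to `baseline_window` seconds immediately before
#' the onset). The search window is truncated at the next epoch onset (with
#' a warning) and at the end of the trace.
#'
#' @param trace A ratio or dff [trace()].
#' @param protocol A [stimulus_protocol()].
#' @param post_window Seconds past the epoch end to keep searching, so slow
#'   transients are not missed.
#' @param baseline_window Seconds of local baseline before the onset.
#' @return A tibble: `epoch`, `kind`, `onset_s`, `magnitude`, `baseline`,
#'   `peak`.
#' @export
epoch_peaks <- function(trace, protocol, post_window = 30,
                        baseline_window = 10) {
  protocol <- as_protocol(protocol)
  tt <- trace_times(trace)
  t_end <- trace$t0 + trace_duration(trace)
  truncated <- FALSE
  rows <- purrr::map(seq_len(nrow(protocol)), function(e) {
    onset <- protocol$onset_s[[e]]
    w_hi <- onset + protocol$duration_s[[e]] + post_window
    if (e < nrow(protocol) && protocol$onset_s[[e + 1]] < w_hi) {
      truncated <<- TRUE
      w_hi <- protocol$onset_s[[e + 1]]
    }
    w_hi <- min(w_hi, t_end)
    b_lo <- max(trace$t0, onset - baseline_window)
    base_sel <- tt >= b_lo & tt < onset
    win_sel <- tt >= onset & tt < w_hi
    baseline <- if (any(base_sel)) mean(trace$samples[base_sel]) else NA_real_
    peak <- if (any(win_sel)) max(trace$samples[win_sel]) - baseline
            else NA_real_
    tibble::tibble(epoch = e, kind = protocol$kind[[e]], onset_s = onset,
                   magnitude = protocol$magnitude[[e]], baseline = baseline,
                   peak = peak)
  })
  if (truncated) {
    rlang::warn("Peak search window truncated at the next epoch onset.",
                class = "nociphys_truncation_warning")
  }
  dplyr::bind_rows(rows)
}

# population loops call epoch_peaks per cell; the truncation warning is
# raised once by the first cell and muffled for the rest
quiet_truncation <- function(code) {
  withCallingHandlers(code, nociphys_truncation_warning = function(w) {
    invokeRestart("muffleWarning")
  })
}

baseline_sd <- function(trace, protocol) {
  first_onset <- min(as_protocol(protocol)$onset_s)
  stats::sd(trace$samples[trace_times(trace) < first_onset])
}

#' Call agonist responders for a cell population
#'
#' An epoch counts as responding when its baseline-subtracted peak exceeds
#' both `threshold_sd` times the pre-first-stimulus baseline SD and an
#' absolute floor (defaults: 3 SD and 0.05 ratio/dff units; neither is
#' derived from the recordings, both are package choices). Cells that fail
#' the high-K test are not neurons and are excluded from responder
#' denominators. Categories are mutually exclusive: `caps_mo`,
#' `caps_only`, `mo_only`, `high_k_only`, `not_neuron`.
#'
#' @param cells A tibble with columns `cell_id` and `trace` (list-column).
#' @param protocol A [stimulus_protocol()] containing a high-K epoch.
#' @param threshold_sd Multiplier on the baseline SD.
#' @param floor Absolute response floor in trace units.
#' @return `cells` with added logical columns `responds_capsaicin`,
#'   `responds_mustard_oil`, `responds_menthol`, `responds_high_k`,
#'   `is_neuron` and a `category` column (the `trace` column is retained).
#' @export
classify_responders <- function(cells, protocol, threshold_sd = 3,
                                floor = 0.05) {
  protocol <- as_protocol(protocol)
  if (!any(protocol$kind == "high_k")) {
    rlang::abort("Protocol must contain a high-K epoch.",
                 class = "nociphys_invalid_protocol")
  }
  agonists <- c("capsaicin", "mustard_oil", "menthol", "high_k")
  calls <- purrr::map(seq_along(cells$trace), function(ci) {
    tr <- cells$trace[[ci]]
    pk <- if (ci == 1) epoch_peaks(tr, protocol)
          else quiet_truncation(epoch_peaks(tr, protocol))
    bsd <- baseline_sd(tr, protocol)
    thr <- max(threshold_sd * bsd, floor, na.rm = TRUE)
    vapply(agonists, function(a) {
      rows <- pk$kind == a
      any(rows) && any(pk$peak[rows] > thr, na.rm = TRUE)
    }, logical(1))
  })
  m <- do.call(rbind, calls)
  out <- cells
  out$responds_capsaicin <- m[, "capsaicin"]
  out$responds_mustard_oil <- m[, "mustard_oil"]
  out$responds_menthol <- m[, "menthol"]
  out$responds_high_k <- m[, "high_k"]
  out$is_neuron <- out$responds_high_k
  out$category <- dplyr::case_when(
    !out$is_neuron ~ "not_neuron",
    out$responds_capsaicin & out$responds_mustard_oil ~ "caps_mo",
    out$responds_capsaicin ~ "caps_only",
    out$responds_mustard_oil ~ "mo_only",
    TRUE ~ "high_k_only")
  out
}

#' Sensitization ratio of one cell (peak 6 / peak 4)
#'
#' The TRPV1 sensitization statistic: the ratio of the first
#' post-incubation capsaicin response (pulse 6) to the second-to-last
#' pre-incubation response (pulse 4). Requires a protocol with at least six
#' capsaicin pulses and the sensitizer epoch between pulses 5 and 6. Cells
#' whose pulse-4 response is below `floor` are excluded (`NA`), since the
#' ratio is then dominated by noise.
#'
#' @param trace A ratio or dff [trace()].
#' @param protocol A sensitization [stimulus_protocol()].
#' @param floor Minimum pulse-4 amplitude for a valid ratio.
#' @return The ratio (dimensionless), or `NA_real_` if excluded.
#' @export
sensitization_ratio <- function(trace, protocol, floor = 0.05) {
  protocol <- as_protocol(protocol)
  caps <- which(protocol$kind == "capsaicin")
  sens <- which(protocol$kind == "sensitizer")
  if (length(caps) < 6 || length(sens) == 0 ||
      !any(sens > caps[[5]] & sens < caps[[6]])) {
    rlang::abort(paste0("Sensitization protocol needs >= 6 capsaicin pulses",
                        " with the sensitizer between pulses 5 and 6."),
                 class = "nociphys_invalid_protocol")
  }
  pk <- epoch_peaks(trace, protocol)
  p4 <- pk$peak[[caps[[4]]]]
  p6 <- pk$peak[[caps[[6]]]]
  if (!is.finite(p4) || p4 < floor) return(NA_real_)
  p6 / p4
}

#' @rdname sensitization_ratio
#' @param cells A tibble with `cell_id` and `trace` columns.
#' @return For `sensitization_ratios()`: a tibble `cell_id`, `sens_ratio`.
#' @export
sensitization_ratios <- function(cells, protocol, floor = 0.05) {
  tibble::tibble(
    cell_id = cells$cell_id,
    sens_ratio = purrr::imap_dbl(cells$trace, function(tr, i) {
      if (i == 1) sensitization_ratio(tr, protocol, floor = floor)
      else quiet_truncation(sensitization_ratio(tr, protocol, floor = floor))
    }))
}

#' Fraction of sensitized cells
#'
#' A cell counts as sensitized when its peak-6/peak-4 ratio exceeds
#' `ratio_threshold` (default 1.1, a package choice). Cells with no valid
#' ratio are excluded from the denominator. The percentage follows the
#' figure-caption convention (round half away from zero; integer percent
#' when the denominator resolves 1% steps, one decimal otherwise).
#'
#' @param ratios A numeric vector of ratios, or a tibble with a
#'   `sens_ratio` column (e.g. from [sensitization_ratios()]).
#' @param ratio_threshold Sensitization call threshold.
#' @return A one-row tibble: `n_sensitized`, `n_total`, `fraction`,
#'   `percent`.
#' @export
sensitized_fraction <- function(ratios, ratio_threshold = 1.1) {
  if (is.data.frame(ratios)) ratios <- ratios$sens_ratio
  valid <- ratios[!is.na(ratios)]
  k <- sum(valid > ratio_threshold)
  n <- length(valid)
  tibble::tibble(n_sensitized = k, n_total = n,
                 fraction = if (n > 0) k / n else 0,
                 percent = format_percent(k, n))
}

#' Cells-by-time dF/F0 matrix for temperature challenges
#'
#' Builds the heatmap input: every cell's dF/F0 trace as one row, rows
#' ordered by descending peak response to the hottest temperature step
#' (ties broken by cell id), plus the column-wise mean trace across cells.
#'
#' @param cells A tibble with `cell_id` and `trace` columns; all traces
#'   must share length and sampling rate.
#' @param protocol A [stimulus_protocol()] containing temperature epochs.
#' @return A list of class `temperature_matrix`: `matrix` (cells x
#'   timepoints, rownames = cell ids), `time` (s), `mean_trace` (numeric),
#'   `order` (tibble with the hottest-step peaks).
#' @export
temperature_matrix <- function(cells, protocol) {
  protocol <- as_protocol(protocol)
  temp_rows <- protocol$kind == "temperature"
  if (!any(temp_rows)) {
    rlang::abort("Protocol contains no temperature epochs.",
                 class = "nociphys_invalid_protocol")
  }
  if (nrow(cells) == 0) {
    return(structure(list(matrix = matrix(numeric(), 0, 0),
                          time = numeric(), mean_trace = numeric(),
                          order = tibble::tibble(cell_id = character(),
                                                 hottest_peak = numeric())),
                     class = "temperature_matrix"))
  }
  lens <- vapply(cells$trace, length, integer(1))
  if (length(unique(lens)) != 1) {
    rlang::abort("All traces must have equal length to be aligned.",
                 class = "nociphys_alignment_error")
  }
  dffs <- purrr::map(cells$trace, dff, protocol = protocol)
  hottest <- which(temp_rows)[which.max(protocol$magnitude[temp_rows])]
  hot_peak <- purrr::imap_dbl(dffs, function(tr, i) {
    pk <- if (i == 1) epoch_peaks(tr, protocol)
          else quiet_truncation(epoch_peaks(tr, protocol))
    pk$peak[[hottest]]
  })
  ord <- order(-hot_peak, cells$cell_id)
  m <- do.call(rbind, purrr::map(dffs, "samples"))[ord, , drop = FALSE]
  rownames(m) <- cells$cell_id[ord]
  structure(
    list(matrix = m, time = trace_times(dffs[[1]]),
         mean_trace = colMeans(m),
         order = tibble::tibble(cell_id = cells$cell_id[ord],
                                hottest_peak = hot_peak[ord])),
    class = "temperature_matrix")
}

#' Average trace per responder category
#'
#' Pointwise mean fluorescence-ratio trace for each mutually exclusive
#' responder category (capsaicin only, mustard oil only, both, high-K
#' only) among confirmed neurons.
#'
#' @param cells Output of [classify_responders()] (must retain the `trace`
#'   list-column and `category`).
#' @return A long tibble: `category`, `n_cells`, `time`, `mean_value`.
#' @export
condition_averages <- function(cells) {
  cats <- c("caps_only", "mo_only", "caps_mo", "high_k_only")
  rows <- purrr::map(cats, function(cat) {
    sel <- cells$category == cat
    if (!any(sel)) return(NULL)
    m <- do.call(rbind, purrr::map(cells$trace[sel], "samples"))
    tibble::tibble(category = cat, n_cells = sum(sel),
                   time = trace_times(cells$trace[sel][[1]]),
                   mean_value = colMeans(m))
  })
  dplyr::bind_rows(rows)
}
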