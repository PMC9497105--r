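#' Construct a trace
#'
#' A trace is the atom every analysis in nociphys operates on: a uniformly
#' sampled single-channel time series with explicit units and sampling rate.
#' Voltage traces are in mV, currents in pA, Fura-2 ratios are dimensionless
#' `ratio` values and baseline-normalized fluorescence is `dimensionless`
#' (kind `dff`).
#'
#' @param samples Numeric vector of samples, all finite.
#' @param fs Sampling rate in Hz (> 0).
#' @param units One of `"mV"`, `"pA"`, `"ratio"`, `"dimensionless"`.
#' @param kind One of `"voltage"`, `"current"`, `"fluorescence_ratio"`,
#'   `"dff"`. Must be consistent with `units`.
#' @param t0 Time of the first sample in seconds from recording start.
#'
#' @return An object of class `noci_trace`.
#' @export
#' @examples
#' tr <- trace(sin(seq(0, 2 * pi, length.out = 100)), fs = 100, units = "mV",
#'             kind = "voltage")
#' trace_duration(tr)
trace <- function(samples, fs, units, kind, t0 = 0) {
  units <- match.arg(units, c("mV", "pA", "ratio", "dimensionless"))
  kind <- match.arg(kind, c("voltage", "current", "fluorescence_ratio", "dff"))
  if (!is.numeric(samples)) {
    rlang::abort("`samples` must be numeric.", class = "nociphys_format_error")
  }
  if (anyNA(samples) || any(!is.finite(samples))) {
    rlang::abort("All samples must be finite.", class = "nociphys_format_error")
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    rlang::abort("`fs` must be a single positive number (Hz).",
                 class = "nociphys_invalid_parameter")
  }
  expected_units <- c(voltage = "mV", current = "pA",
                      fluorescence_ratio = "ratio", dff = "dimensionless")
  if (units != expected_units[[kind]]) {
    rlang::abort(
      sprintf("Units '%s' are inconsistent with kind '%s' (expected '%s').",
              units, kind, expected_units[[kind]]),
      class = "nociphys_format_error")
  }
  structure(
    list(samples = as.numeric(samples), fs = fs, units = units,
         kind = kind, t0 = t0),
    class = "noci_trace")
}

#' @export
print.noci_trace <- function(x, ...) {
  cat(sprintf("<noci_trace> %s (%s), %d samples @ %g Hz, t0 = %g s\n",
              x$kind, x$units, length(x$samples), x$fs, x$t0))
  invisible(x)
}

#' @export
length.noci_trace <- function(x) length(x$samples)

#' Trace time axis and duration
#'
#' @param trace A [trace()].
#' @return `trace_times()` returns the vector of sample times in seconds;
#'   `trace_duration()` the duration in seconds.
#' @export
trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$samples) - 1) / trace$fs
}

trace_time_seq <- trace_times

#' @rdname trace_times
#' @export
trace_duration <- function(trace) length(trace$samples) / trace$fs

#' @export
as.data.frame.noci_trace <- function(x, ...) {
  data.frame(time = trace_time_seq(x), value = x$samples)
}

#' Convert a trace to a tibble
#'
#' @param x A [trace()].
#' @param ... Unused.
#' @return A tibble with columns `time` (s) and `value` (trace units).
#' @export
as_trace_tibble <- function(x, ...) {
  tibble::tibble(time = trace_time_seq(x), value = x$samples)
}

#' Read and write the native trace format
#'
#' The on-disk trace format is UTF-8 text: header lines `# fs_hz=`,
#' `# units=`, `# kind=` (and optionally `# t0_s=`), then one sample per
#' line. The format intentionally carries no vendor metadata; conversion
#' from acquisition formats is upstream of this package.
#'
#' @param path File path.
#' @return A [trace()].
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("Trace file '%s' does not exist.", path),
                 class = "nociphys_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  is_header <- startsWith(lines, "#")
  header <- lines[is_header]
  get_field <- function(key) {
    hit <- grep(sprintf("^#\\s*%s=", key), header, value = TRUE)
    if (length(hit) == 0) return(NULL)
    sub(sprintf("^#\\s*%s=\\s*", key), "", hit[[1]])
  }
  fs <- get_field("fs_hz")
  units <- get_field("units")
  kind <- get_field("kind")
  if (is.null(fs) || is.null(units) || is.null(kind)) {
    rlang::abort(
      "Trace header must declare fs_hz, units and kind.",
      class = "nociphys_format_error")
  }
  t0 <- get_field("t0_s")
  body <- lines[!is_header]
  body <- body[nzchar(trimws(body))]
  samples <- suppressWarnings(as.numeric(body))
  if (anyNA(samples)) {
    bad <- which(is.na(samples))[[1]]
    rlang::abort(
      sprintf("Non-numeric sample at data line %d: '%s'", bad, body[[bad]]),
      class = "nociphys_parse_error")
  }
  trace(samples, fs = as.numeric(fs), units = units, kind = kind,
        t0 = if (is.null(t0)) 0 else as.numeric(t0))
}

#' @rdname read_trace
#' @param trace A [trace()] to write.
#' @export
write_trace <- function(trace, path) {
  header <- c(sprintf("# fs_hz=%s", format(trace$fs, digits = 17)),
              sprintf("# units=%s", trace$units),
              sprintf("# kind=%s", trace$kind),
              sprintf("# t0_s=%s", format(trace$t0, digits = 17)))
  writeLines(c(header, format(trace$samples, digits = 17, trim = TRUE,
                              scientific = FALSE)), path)
  invisible(path)
}

#' Zero-phase low-pass filter
#'
#' Forward-backward (zero-phase) 4th-order Butterworth filtering, so feature
#' latencies are not biased by filter delay. The trace is reflection-padded
#' before filtering to suppress edge transients; residual edge effects are
#' confined to roughly `3 / cutoff` seconds at either end.
#'
#' @param trace A [trace()].
#' @param cutoff Cutoff frequency in Hz; must satisfy `0 < cutoff < fs / 2`.
#' @param order Filter order (default 4, applied twice by filtfilt).
#' @return A filtered trace with identical length and metadata.
#' @export
lowpass_filter <- function(trace, cutoff, order = 4) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0 ||
      cutoff >= trace$fs / 2) {
    rlang::abort(
      sprintf("`cutoff` must lie in (0, fs/2) = (0, %g) Hz.", trace$fs / 2),
      class = "nociphys_invalid_parameter")
  }
  mu <- mean(trace$samples)
  x <- trace$samples - mu      # demeaning kills the DC startup transient
  n <- length(x)
  bf <- signal::butter(order, cutoff / (trace$fs / 2), type = "low")
  pad <- min(n - 1, max(1L, ceiling(3 * trace$fs / cutoff)))
  xp <- c(2 * x[1] - rev(x[2:(pad + 1)]), x,
          2 * x[n] - rev(x[(n - pad):(n - 1)]))
  yp <- signal::filtfilt(bf, xp)
  trace(yp[(pad + 1):(pad + n)] + mu, fs = trace$fs, units = trace$units,
        kind = trace$kind, t0 = trace$t0)
}

#' Cut a trace into per-epoch sub-traces
#'
#' Each stimulus epoch of the protocol yields one sub-trace spanning
#' `[onset - pad_pre, onset + duration + pad_post]`. Pads may overlap
#' neighbouring epochs; samples can be shared between segments.
#'
#' @param trace A [trace()].
#' @param protocol A [stimulus_protocol()].
#' @param pad_pre,pad_post Padding in seconds added before/after each epoch.
#' @return A tibble with one row per epoch: `epoch` (index), `kind`,
#'   `onset_s`, `duration_s`, `magnitude` and a `trace` list-column of
#'   sub-traces whose `t0` is set to their true recording time.
#' @export
segment_trace <- function(trace, protocol, pad_pre = 0, pad_post = 0) {
  protocol <- as_protocol(protocol)
  t_end <- trace$t0 + trace_duration(trace)
  subs <- purrr::pmap(
    list(protocol$onset_s, protocol$duration_s, seq_len(nrow(protocol))),
    function(onset, dur, i) {
      if (onset < trace$t0 || onset + dur > t_end + 1e-9) {
        rlang::abort(
          sprintf("Epoch %d (%s, onset %g s) lies outside the trace (%g-%g s).",
                  i, protocol$kind[[i]], onset, trace$t0, t_end),
          class = "nociphys_range_error")
      }
      a <- max(trace$t0, onset - pad_pre)
      b <- min(t_end, onset + dur + pad_post)
      i0 <- 1 + round((a - trace$t0) * trace$fs)
      i1 <- min(length(trace$samples), 1 + floor((b - trace$t0) * trace$fs - 1e-9))
      trace(trace$samples[i0:i1], fs = trace$fs, units = trace$units,
            kind = trace$kind, t0 = trace$t0 + (i0 - 1) / trace$fs)
    })
  out <- tibble::as_tibble(protocol)
  out$epoch <- seq_len(nrow(out))
  out$trace <- subs
  dplyr::relocate(out, "epoch")
}

window_indices <- function(trace, window) {
  i0 <- 1 + round((window[[1]] - trace$t0) * trace$fs)
  i1 <- 1 + round((window[[2]] - trace$t0) * trace$fs)
  if (i0 < 1 || i1 > length(trace$samples) || i1 < i0) {
    rlang::abort("Window lies outside the trace.",
                 class = "nociphys_range_error")
  }
  i0:i1
}
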