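#' Construct a sweep set
#'
#' A sweep set bundles repeated traces of one stimulus (e.g. the 25 response
#' currents to a repeated voltage step), sharing sampling rate, units and a
#' common stimulus-onset time.
#'
#' @param sweeps List of [trace()] objects with identical length, `fs`,
#'   `units` and `kind`.
#' @param stim_onset Stimulus onset in seconds, common to all sweeps.
#' @return An object of class `noci_sweeps`.
#' @export
sweep_set <- function(sweeps, stim_onset) {
  if (length(sweeps) == 0) {
    rlang::abort("A sweep set needs at least one sweep.",
                 class = "nociphys_empty_input")
  }
  ref <- sweeps[[1]]
  ok <- vapply(sweeps, function(s) {
    inherits(s, "noci_trace") && length(s) == length(ref) &&
      s$fs == ref$fs && s$units == ref$units && s$kind == ref$kind
  }, logical(1))
  if (!all(ok)) {
    rlang::abort("All sweeps must be traces with identical length/fs/units.",
                 class = "nociphys_format_error")
  }
  structure(list(sweeps = sweeps, stim_onset = stim_onset),
            class = "noci_sweeps")
}

#' @export
print.noci_sweeps <- function(x, ...) {
  cat(sprintf("<noci_sweeps> %d sweeps of %d samples @ %g Hz, stim at %g s\n",
              length(x$sweeps), length(x$sweeps[[1]]), x$sweeps[[1]]$fs,
              x$stim_onset))
  invisible(x)
}

#' @export
length.noci_sweeps <- function(x) length(x$sweeps)

#' Pointwise average of a sweep set
#'
#' Averaging repeated responses before fitting suppresses uncorrelated noise
#' by roughly `1/sqrt(n)`; the capacitance recipe averages 25 sweeps.
#'
#' @param sweeps A [sweep_set()].
#' @return A single [trace()] with the same metadata.
#' @export
average_sweeps <- function(sweeps) {
  if (!inherits(sweeps, "noci_sweeps")) {
    rlang::abort("`sweeps` must be a sweep_set.",
                 class = "nociphys_format_error")
  }
  m <- vapply(sweeps$sweeps, function(s) s$samples,
              numeric(length(sweeps$sweeps[[1]])))
  ref <- sweeps$sweeps[[1]]
  avg <- if (is.matrix(m)) rowMeans(m) else m
  trace(avg, fs = ref$fs, units = ref$units, kind = ref$kind, t0 = ref$t0)
}
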