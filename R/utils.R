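#' Simulation configuration
#'
#' Bundles the sampling parameters and noise level shared by all synthetic
#' generators. Identical seed and parameters give bit-identical output.
#'
#' @param seed Integer RNG seed.
#' @param fs Sampling rate in Hz.
#' @param duration Trace duration in seconds (some generators derive their
#'   duration from a protocol instead and ignore this).
#' @param noise_sd Additive Gaussian noise SD in the trace's native units.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, fs = 20000, duration = 1, noise_sd = 0) {
  if (fs <= 0 || duration <= 0 || noise_sd < 0) {
    rlang::abort("Need fs > 0, duration > 0, noise_sd >= 0.",
                 class = "nociphys_invalid_parameter")
  }
  structure(list(seed = as.integer(seed), fs = fs, duration = duration,
                 noise_sd = noise_sd),
            class = "sim_config")
}

# Evaluate code under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Round half away from zero (figure-caption convention: 91.5 -> 92, not 91).
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Percentage with the caption convention: integer percent when the
# denominator resolves 1% steps, one decimal otherwise (e.g. 5/18 -> 27.8).
format_percent <- function(k, n) {
  if (n == 0) return(0)
  round_half_away(100 * k / n, digits = if (n >= 100) 0 else 1)
}

stopifnot_positive <- function(..., .class = "nociphys_invalid_parameter") {
  vals <- list(...)
  nms <- names(vals)
  for (i in seq_along(vals)) {
    v <- vals[[i]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
      rlang::abort(sprintf("`%s` must be positive and finite.", nms[[i]]),
                   class = .class)
    }
  }
  invisible(TRUE)
}
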