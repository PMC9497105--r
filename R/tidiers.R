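#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an exponential-decay fit
#'
#' @param x An `exp_fit` from [fit_decay()].
#' @param ... Unused.
#' @return One row per fitted component: `term`, `amplitude`, `tau_ms`.
#' @export
tidy.exp_fit <- function(x, ...) {
  tibble::tibble(term = paste0("component", seq_along(x$amplitudes)),
                 amplitude = x$amplitudes, tau_ms = x$taus)
}

#' @rdname tidy.exp_fit
#' @return For `glance()`: a one-row tibble with `baseline`,
#'   `weighted_tau_ms`, `rmse`, `n_components`, `degenerate`.
#' @export
glance.exp_fit <- function(x, ...) {
  tibble::tibble(baseline = x$baseline, weighted_tau_ms = x$weighted_tau,
                 rmse = x$rmse, n_components = x$n_components,
                 degenerate = x$degenerate)
}
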