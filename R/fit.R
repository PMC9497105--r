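#' Fit a mono- or biexponential decay
#'
#' Least-squares fit of `baseline + sum(A_i * exp(-t / tau_i))` over a
#' window of the trace, the workhorse behind capacitive-transient,
#' mechanical-current inactivation, repolarization and AHP-recovery fits.
#' Initial values come from a log-linear regression on the rectified decay;
#' the biexponential is seeded at `(tau/3, 3 tau)` with the amplitude split
#' 50/50, and up to 5 deterministic re-seeded restarts are attempted before
#' declaring failure. Components are returned sorted by tau ascending, and
#' the amplitude-weighted time constant `sum(|A_i| tau_i) / sum(|A_i|)` is
#' populated.
#'
#' @param trace A [trace()].
#' @param window `(start, end)` in seconds (absolute trace time); must
#'   contain at least 10 samples and start at/after the transient peak.
#' @param n_components 1 or 2.
#' @param baseline `NULL` to fit the asymptote freely, or a number to fix it
#'   (mechanical-current fits fix it to the pre-stimulus baseline mean).
#' @param amp_sign `"free"`, or `"negative"`/`"positive"` to constrain the
#'   component amplitudes to one sign (useful for monotone decays, where an
#'   opposite-sign component pair signals overfitting).
#' @param tau_max_ms Upper bound for the time constants; defaults to 20
#'   times the window span, since slower components are indistinguishable
#'   from the baseline within the window.
#' @return An object of class `exp_fit`: `baseline`, `amplitudes`, `taus`
#'   (ms), `weighted_tau` (ms), `window`, `rmse`, `n_components`,
#'   `degenerate`. A flat window yields a degenerate fit with zero
#'   amplitudes rather than an error.
#' @export
fit_decay <- function(trace, window, n_components = 2, baseline = NULL,
                      amp_sign = c("free", "negative", "positive"),
                      tau_max_ms = NULL) {
  amp_sign <- match.arg(amp_sign)
  if (!n_components %in% c(1, 2)) {
    rlang::abort("`n_components` must be 1 or 2.",
                 class = "nociphys_invalid_parameter")
  }
  idx <- window_indices(trace, window)
  if (length(idx) < 10) {
    rlang::abort("Fewer than 10 samples in the fit window.",
                 class = "nociphys_insufficient_data")
  }
  y <- trace$samples[idx]
  tt <- (idx - idx[[1]]) / trace$fs * 1000   # ms from window start
  b_fixed <- !is.null(baseline)
  b0 <- if (b_fixed) baseline else mean(utils::tail(y, max(5L, length(y) %/% 10)))
  r <- y - b0
  scale_y <- max(abs(r))
  if (scale_y < 1e-9 * max(1, abs(b0)) || stats::sd(y) == 0) {
    return(new_exp_fit(baseline = b0, amplitudes = rep(0, n_components),
                       taus = rep(NA_real_, n_components), window = window,
                       rmse = sqrt(mean((y - b0)^2)),
                       n_components = n_components, degenerate = TRUE))
  }
  sgn <- sign(r[[which.max(abs(r))]])
  use <- sgn * r > scale_y / 50
  tau0 <- if (sum(use) >= 3) {
    sl <- stats::coef(stats::lm(log(sgn * r[use]) ~ tt[use]))[[2]]
    if (sl < 0) -1 / sl else diff(range(tt)) / 5
  } else diff(range(tt)) / 5
  amp0 <- r[[1]]
  starts <- if (n_components == 1) {
    list(c(A1 = amp0, tau1 = tau0))
  } else {
    list(c(A1 = amp0 / 2, tau1 = tau0 / 3, A2 = amp0 / 2, tau2 = 3 * tau0))
  }
  if (is.null(tau_max_ms)) tau_max_ms <- 20 * max(diff(range(tt)), 1)
  model <- function(par) {
    v <- rep(if (b_fixed) b0 else par[["b"]], length(tt))
    for (i in seq_len(n_components)) {
      v <- v + par[[paste0("A", i)]] * exp(-tt / par[[paste0("tau", i)]])
    }
    v
  }
  mk_bounds <- function(st) {
    lower <- rep(-Inf, length(st))
    upper <- rep(Inf, length(st))
    names(lower) <- names(upper) <- names(st)
    lower[grep("^tau", names(st))] <- 1e-6
    upper[grep("^tau", names(st))] <- tau_max_ms
    if (amp_sign == "negative") upper[grep("^A", names(st))] <- 0
    if (amp_sign == "positive") lower[grep("^A", names(st))] <- 0
    list(lower = lower, upper = upper)
  }
  jitters <- c(1, 0.5, 2, 0.2, 5)
  best <- NULL
  for (j in jitters) {
    st <- starts[[1]]
    st[grep("tau", names(st))] <- st[grep("tau", names(st))] * j
    if (!b_fixed) st <- c(st, b = b0)
    bd <- mk_bounds(st)
    st <- pmin(pmax(st, bd$lower), bd$upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = st, lower = bd$lower, upper = bd$upper,
        fn = function(par) y - model(par),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && fit$info %in% 1:4) {
      if (is.null(best) || fit$deviance < best$deviance) best <- fit
      if (best$deviance <= 1e-12 * sum(y^2) + 1e-300) break
    }
  }
  if (is.null(best)) {
    rlang::abort(
      sprintf("Exponential fit failed to converge after %d restarts (window %g-%g s).",
              length(jitters), window[[1]], window[[2]]),
      class = "nociphys_fit_failure")
  }
  cf <- best$par
  amps <- cf[grep("^A", names(cf))]
  taus <- cf[grep("^tau", names(cf))]
  ord <- order(taus)
  amps <- unname(amps[ord])
  taus <- unname(taus[ord])
  b_hat <- if (b_fixed) baseline else unname(cf[["b"]])
  new_exp_fit(baseline = b_hat, amplitudes = amps, taus = taus,
              window = window, rmse = sqrt(best$deviance / length(y)),
              n_components = n_components,
              degenerate = sum(abs(amps)) < 1e-9 * max(1, scale_y))
}

new_exp_fit <- function(baseline, amplitudes, taus, window, rmse,
                        n_components, degenerate) {
  wt <- if (degenerate || all(abs(amplitudes) == 0)) {
    NA_real_
  } else {
    sum(abs(amplitudes) * taus) / sum(abs(amplitudes))
  }
  structure(
    list(baseline = baseline, amplitudes = amplitudes, taus = taus,
         weighted_tau = wt, window = window, rmse = rmse,
         n_components = n_components, degenerate = degenerate),
    class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit> %d component(s)%s\n", x$n_components,
              if (x$degenerate) " [degenerate]" else ""))
  cat("  baseline:", format(x$baseline, digits = 6), "\n")
  for (i in seq_along(x$amplitudes)) {
    cat(sprintf("  A%d = %s, tau%d = %s ms\n", i,
                format(x$amplitudes[[i]], digits = 6), i,
                format(x$taus[[i]], digits = 6)))
  }
  cat("  weighted tau:", format(x$weighted_tau, digits = 6), "ms; rmse:",
      format(x$rmse, digits = 4), "\n")
  invisible(x)
}

# Evaluate the fitted model at millisecond offsets from the window start.
predict_exp_fit <- function(fit, t_ms) {
  out <- rep(fit$baseline, length(t_ms))
  if (!fit$degenerate) {
    for (i in seq_along(fit$amplitudes)) {
      out <- out + fit$amplitudes[[i]] * exp(-t_ms / fit$taus[[i]])
    }
  }
  out
}
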