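# Shared fixture builders. Everything is generated in code; no data files.

quiet_peaks <- function(expr) {
  withCallingHandlers(expr, nociphys_truncation_warning = function(w) {
    invokeRestart("muffleWarning")
  })
}

# A short two-pulse + high-K protocol for fast calcium tests.
mini_agonist_protocol <- function() {
  agonist_protocol(agonists = c("capsaicin", "mustard_oil"),
                   pulse_s = 30, wash_s = 120)
}

# Compact sensitization protocol (shorter washes) to keep traces small.
mini_sens_protocol <- function() {
  sensitization_protocol(pulse_s = 30, wash_s = 150, sensitizer_s = 150)
}

# Independent brute-force Fisher oracle: enumerate all tables with the
# observed margins, probabilities from factorials via choose().
fisher_brute <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1]); n <- sum(m)
  support <- max(0, c1 - r2):min(r1, c1)
  prob <- vapply(support, function(a) {
    choose(r1, a) * choose(r2, c1 - a) / choose(n, c1)
  }, numeric(1))
  p_obs <- prob[[match(m[1, 1], support)]]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}
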