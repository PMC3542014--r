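# Shared fixtures, built in code.

# Static (non-decaying) parameter set: handy because the IRT mixture is then
# i.i.d. with a closed-form density.
static_params <- function(L0 = 1, w0 = 60, b0 = 6, delta = 0.002,
                          omega = 0) {
  dberm_params(L0 = L0, w0 = w0, b0 = b0, gamma = 0, alpha = 0, beta = 0,
               delta = delta, omega = omega)
}

# Random valid parameter sets for property-style tests.
random_valid_params <- function() {
  b0 <- runif(1, 2, 50)
  w0 <- b0 * runif(1, 3, 30)
  omega <- b0 * runif(1, 0, 0.9)
  alpha <- runif(1, 0.001, 0.1)
  beta <- alpha * runif(1, 1, 5)
  dberm_params(L0 = runif(1, 0, 5), w0 = w0, b0 = b0,
               gamma = runif(1, 0.0005, 0.1), alpha = alpha, beta = beta,
               delta = runif(1, 0.0005, 0.005), omega = omega)
}

# IRTs of a session record (first latency included per the record's flag).
record_irts <- function(record) {
  if (record$first_latency_included) {
    diff(c(0, record$response_times))
  } else {
    diff(record$response_times)
  }
}

# Small two-strain reference groups for quick fits.
reference_groups <- function(sdlog = 0.2, with_recovery = FALSE) {
  lapply(c("SHR", "WKY"), function(s) {
    group_distribution(
      reference_medians(s), sdlog = sdlog, strain = s,
      recovery_medians = if (with_recovery) reference_recovery(s))
  })
}
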