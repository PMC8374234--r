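# Shared fixtures; everything is generated in code at test time.

# A small deterministic waveform table on a uniform grid.
toy_waveform <- function(id = "w1", t0 = 0, dt = 0.02, n = 121,
                         f = function(t) exp(-((t - 0.6)^2) / 0.02)) {
  t <- t0 + (seq_len(n) - 1) * dt
  tibble::tibble(waveform_id = id, time_ms = t, amplitude_uV = f(t))
}

# A noiseless eCAP generated directly on an (already extended) grid, so a fit
# on it is a pure self-consistency run with no preprocessing mismatch.
clean_ecap <- function(cdld, ur, grid = time_grid(-0.25, 2.45, 0.005)) {
  forward_ecap(cdld, ur, grid)
}

# The validation suite is expensive; compute it once per test run.
.acceptance_cache <- new.env(parent = emptyenv())
acceptance_suite <- function() {
  if (is.null(.acceptance_cache$suite)) {
    .acceptance_cache$suite <- run_validation_suite(seed = 1,
                                                    n_waveforms = 100,
                                                    n_sweep = 20)
  }
  .acceptance_cache$suite
}

# Absolute relative errors of recovered step-two parameters against truth,
# components matched after latency sorting.
recovery_errors <- function(fit, truth) {
  comp <- fit$cdld$components
  truth <- truth[order(truth$mu, truth$sigma), ]
  abs(c(comp$alpha - truth$alpha, comp$mu - truth$mu,
        comp$sigma - truth$sigma)) /
    abs(c(truth$alpha, truth$mu, truth$sigma))
}
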