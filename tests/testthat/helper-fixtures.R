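# Shared fixtures: quiet generator settings for closed-form checks.

# Tissue parameters with noise and capacitive overshoot disabled, constant
# conductivity (no field dependence beyond the sigmoid floor/plateau).
quiet_params <- function(sigma_bulk = c("1" = 0.13, "10" = 0.04),
                         sigma_max = c("1" = 0.55, "10" = 0.67), ...) {
  tissue_params(sigma_bulk_by_pw = sigma_bulk, sigma_max_by_pw = sigma_max,
                noise_rel = 0, cap_transient_frac = 0, ...)
}

# Fixed-thickness plate and standard needle pair.
plate6 <- function() plate_geometry(6, 6, thickness_sd = 0)
needle1cm <- function() needle_pair_geometry(1.0, 0.5, 1.0)

# Random protocol on the sampling-clock grid (all durations integer
# multiples of dt), the timing an arbitrary-waveform generator can realize.
random_protocol <- function(dt_ns = 2, max_cycles = 12) {
  us <- 1000 / dt_ns
  pw <- sample(seq(0.5, 10, by = 0.5), 1)
  d1 <- sample(0:20, 1) * round(us) / us
  d2 <- sample(0:20, 1) * round(us) / us
  burst_protocol(pw, d1, d2, cycles = sample(seq_len(max_cycles), 1),
                 amplitude = 1, sampling_period = dt_ns)
}
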