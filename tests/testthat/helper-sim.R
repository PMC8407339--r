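# small screen configurations used across tests; one plate is 16 x 24 = 384
# positions (96 strains) unless a test needs the full 32 x 48 geometry

tiny_config <- function(..., seed = 42) {
  defaults <- list(n_strains = 96, n_rows = 16, n_cols = 24,
                   n_library_controls = 8, seed = seed)
  do.call(sim_config, modifyList(defaults, list(...)))
}

# noiseless, artifact-free configuration: every stochastic knob off unless
# overridden through ...
clean_config <- function(..., seed = 42) {
  base <- list(spatial_bias_amplitude = 0, plate_batch_sd = 0,
               replicate_noise_sd = 0, curve_noise_sd = 0,
               basal_offset_sd = 0,
               fraction_stress_inhibited = 0, fraction_basal_inhibited = 0)
  do.call(tiny_config, c(modifyList(base, list(...)), list(seed = seed)))
}

# closed-form logistic-with-lag trajectory, written independently of the
# package's growth_model() as the oracle for curve-shape tests
oracle_logistic <- function(t, gt, lag, n0, capacity) {
  r <- log(2) / gt
  ifelse(t < lag, n0,
         capacity * n0 * exp(r * (t - lag)) /
           (capacity + n0 * (exp(r * (t - lag)) - 1)))
}
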