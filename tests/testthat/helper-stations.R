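# Small station tables for tests, generated in code.

noiseless_table <- function(n = 200, seed = 11) {
  p <- population_params(n = n, iop_noise_sigma_log10 = 0,
                         lu_noise_sigma_log10 = 0)
  generate_dataset(p, seed = seed)
}

noisy_table <- function(n = 200, sigma = 0.14, seed = 11) {
  p <- population_params(n = n, iop_noise_sigma_log10 = sigma,
                         lu_noise_sigma_log10 = sigma)
  generate_dataset(p, seed = seed)
}
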