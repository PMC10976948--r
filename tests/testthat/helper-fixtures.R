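# Small seeded fixtures shared across test files.

small_spec <- function(n_bands = 40, class_sizes = c(8, 8, 12),
                       body_noise_sd = 0.5, edge_noise_sd = 3, seed = 11, ...) {
  synthetic_spec(n_bands = n_bands, class_sizes = class_sizes,
                 body_noise_sd = body_noise_sd, edge_noise_sd = edge_noise_sd,
                 seed = seed, ...)
}

noiseless_spec <- function(n_bands = 40, class_sizes = c(4, 4, 4), seed = 5) {
  synthetic_spec(n_bands = n_bands, class_sizes = class_sizes,
                 body_noise_sd = 0, edge_noise_sd = 1e-12, seed = seed)
}

# unlabelled table from a plain matrix on an integer wavelength grid
toy_table <- function(X, wl = seq(400, by = 2, length.out = ncol(X))) {
  spectra_table(X, wl)
}
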