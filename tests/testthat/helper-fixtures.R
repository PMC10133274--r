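# Small in-code fixtures shared across test files.

# A compact bundle: 16x16 lattice, 3 crops, 6 districts, 2 years.
tiny_bundle <- function(seed = 42, ...) {
  simulate_bundle(height = 16, width = 16, n_features = 16L, n_crops = 3L,
                  n_districts = 6L, years = 2013:2014,
                  correlation_length = 2, cross_crop_correlation = 0.5,
                  label_noise_sd = 0, selection_sharpness = 0,
                  cultivated_fraction = 0.6, seed = seed, ...)
}

tiny_examples <- function(bundle) {
  build_examples(bundle$grids, bundle$partition, bundle$assignments,
                 bundle$yields)
}

# A hand-sized model config for fast tests.
tiny_config <- function(n_crops = 3L, ...) {
  args <- list(...)
  defaults <- list(input_dim = 16L, hidden_dims = c(16L, 16L),
                   output_dim = n_crops, dropout_rate = 0,
                   epochs = 50L, batch_groups = 8L, seed = 1L)
  do.call(model_config, utils::modifyList(defaults, args))
}

# Lag-1 spatial autocorrelation (Moran-style): correlation between each
# pixel and its right/down neighbour, pooled.
lag1_autocor <- function(m) {
  right <- cbind(as.vector(m[, -ncol(m)]), as.vector(m[, -1]))
  down <- cbind(as.vector(m[-nrow(m), ]), as.vector(m[-1, ]))
  pairs <- rbind(right, down)
  stats::cor(pairs[, 1], pairs[, 2])
}
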