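# Shared fixtures: small noise-free phantoms are expensive enough to cache
# across test files (keyed by seed and abnormality).

.fixture_cache <- new.env(parent = emptyenv())

tiny_phantom <- function(seed = 1, abnormality = "none", noise_sigma = 0,
                         shape = c(24, 64, 64), n_frames = 12) {
  key <- paste(seed, abnormality, noise_sigma, paste(shape, collapse = "x"),
               n_frames, sep = "|")
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  ph <- generate_phantom(phantom_config(shape = shape, n_frames = n_frames,
                                        noise_sigma = noise_sigma,
                                        abnormality = abnormality,
                                        seed = seed))
  .fixture_cache[[key]] <- ph
  ph
}

# phantoms sized for network training (smaller grid, fewer frames)
train_phantom <- function(seed) {
  key <- paste("train", seed, sep = "|")
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  ph <- generate_phantom(phantom_config(shape = c(24, 48, 48), n_frames = 10,
                                        noise_sigma = 0, seed = seed))
  .fixture_cache[[key]] <- ph
  ph
}

# desk-scale network configurations used throughout the suite
smoke_rb_config <- function(...) {
  rb_unet_config(base_filters = 8, dropout_rate = 0, n_samples = 10,
                 target = c(32, 32, 32), init_seed = 11, ...)
}

smoke_fcdn_config <- function(...) {
  fc_densenet_config(growth_rate = 2, init_filters = 8, dropout_rate = 0,
                     n_samples = 10, target = c(32, 32, 32), init_seed = 11,
                     ...)
}

# brute-force Otsu oracle: exhaustive sweep over candidate thresholds with
# directly computed class statistics
otsu_bruteforce <- function(values) {
  u <- sort(unique(values))
  if (length(u) < 2) return(NA_real_)
  best <- -Inf
  best_tau <- NA_real_
  for (tau in u[-length(u)]) {
    lo <- values[values <= tau]
    hi <- values[values > tau]
    w0 <- length(lo) / length(values)
    w1 <- 1 - w0
    sb <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (sb > best + 1e-12) {  # strict improvement => lowest maximiser kept
      best <- sb
      best_tau <- tau
    }
  }
  best_tau
}
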