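# Shared fixtures and independent oracles.

# Centred 2D Gaussian blob image.
blob_image <- function(n = 64L, row = (n + 1) / 2, col = (n + 1) / 2,
                       sd = 4, peak = 1, background = 0) {
  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  background + peak * exp(-((rr - row)^2 + (cc - col)^2) / (2 * sd^2))
}

# Filled disc of the given radius (the "light blob" of the scale analysis).
disc_image <- function(n, radius, row = (n + 1) / 2, col = (n + 1) / 2) {
  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  ((rr - row)^2 + (cc - col)^2 <= radius^2) * 1.0
}

# Independent mirror-index oracle: walk the symmetric (edge-repeating)
# reflection by hand: ..., 2, 1 | 1, 2, ... and ..., n-1, n | n, n-1, ...
reflect_scalar <- function(i, n) {
  while (i < 1L || i > n) {
    if (i < 1L) i <- 1L - i
    if (i > n) i <- 2L * n + 1L - i
  }
  i
}

# The shared synthetic-trained model is expensive (about 40 s); train it once
# per test run and reuse across classification, pipeline and acceptance tests.
.shared <- new.env()
shared_model <- function() {
  if (is.null(.shared$model)) {
    pats <- generate_patches(scene_params(rows = 256L, cols = 256L, seed = 7),
                             n_per_class = 450L)
    cfg <- pipeline_config(seed = 7)
    .shared$patches <- pats
    .shared$cfg <- cfg
    .shared$model <- train_bouton_model(pats$patches, pats$labels, cfg)
  }
  .shared
}
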