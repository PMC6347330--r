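# Shared desk-scale fixtures, all built in code.

# Tiny standard extractor: 8x8x3 input, two conv blocks + two fc layers.
tiny_extractor <- function(seed = 1) {
  build_toy_extractor(seed, toy_architecture(input = c(8L, 8L, 3L),
                                             filters = c(4L, 6L),
                                             fc_units = c(20L, 10L)))
}

# Fully linear extractor (no rectifier, no pooling): an exact affine map.
linear_extractor <- function(seed = 5, size = 8L) {
  build_toy_extractor(seed, toy_architecture(input = c(size, size, 3L),
                                             filters = c(4L, 6L),
                                             fc_units = c(20L, 10L),
                                             rectify = FALSE, pool = FALSE))
}

# Dense matrix M and offset d with extract_features(v) = M %*% v + d for a
# linear extractor, obtained by probing with basis images. The independent
# oracle for all linear-algebra checks.
probe_linear_map <- function(extractor, layers = layer_names(extractor)) {
  dims <- extractor$arch$input
  n_pix <- prod(dims)
  feat <- function(img) {
    fs <- extract_features(img, extractor, layers)
    unlist(lapply(layers, function(l) fs[[l]]), use.names = FALSE)
  }
  d <- feat(array(0, dims))
  M <- matrix(0, length(d), n_pix)
  for (j in seq_len(n_pix)) {
    e <- numeric(n_pix); e[j] <- 1
    M[, j] <- feat(array(e, dims)) - d
  }
  list(M = M, d = d, dims = dims)
}

random_image <- function(dims, seed) {
  set.seed(seed)
  array(runif(prod(dims), 0, 255), dims)
}

# Simple run + design fixture with known block amplitudes.
fixture_run <- function(n_blocks = 40, n_vox = 20, amp_sd = 2, seed = 7, ...) {
  design <- block_design(onsets = 24 + seq(0, by = 8, length.out = n_blocks),
                         durations = rep(8, n_blocks),
                         labels = sprintf("b%02d", seq_len(n_blocks)))
  set.seed(seed)
  amps <- matrix(rnorm(n_blocks * n_vox, sd = amp_sd), n_blocks, n_vox)
  run <- simulate_run(design, amps, seed = seed + 1, ...)
  list(run = run, design = design, amps = amps)
}
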