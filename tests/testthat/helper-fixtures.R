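# Shared fixtures built in code.

# A noise-free, pose-free spec: US and histology sides coincide exactly.
identity_spec <- function(seed = 1L, ...) {
  phantom_spec(seed = seed, n_patients = 1L, slices_per_patient = 1L,
               shrinkage_factor = 1, rotation_deg = 0, translation_mm = c(0, 0),
               landmark_jitter_sd_mm = 0, annotation_noise_sd_mm = 0, ...)
}

# Noise-free but with the full pose difference (shrinkage + rotation +
# translation): registration must still be exact.
posed_spec <- function(seed = 1L, ...) {
  phantom_spec(seed = seed, n_patients = 1L, slices_per_patient = 1L,
               landmark_jitter_sd_mm = 0, annotation_noise_sd_mm = 0, ...)
}

# Circle polygon (counter-clockwise) for analytic geometry cases.
circle_poly <- function(center, radius, n = 720L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}

# Random small blob mask for metric oracles.
random_blob_mask <- function(nr, nc, seed) {
  set.seed(seed)
  m <- matrix(0L, nr, nc)
  cx <- runif(1, nc * 0.3, nc * 0.7); cy <- runif(1, nr * 0.3, nr * 0.7)
  r <- runif(1, min(nr, nc) * 0.15, min(nr, nc) * 0.3)
  for (i in seq_len(nr)) for (j in seq_len(nc))
    if ((i - cy)^2 + (j - cx)^2 <= r^2) m[i, j] <- 1L
  m
}

# Brute-force correspondence-based landmark sets.
random_point_set <- function(n, seed) {
  set.seed(seed)
  cbind(runif(n, -10, 10), runif(n, -10, 10))
}
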