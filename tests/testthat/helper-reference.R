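# Independent naive reference implementations used as oracles.
# Deliberately written as explicit triple loops over voxels, sharing no code
# with the package's vectorized operators.

naive_metrics <- function(stack, threshold, policy = "biomass") {
  v <- stack$intensities
  d <- dim(v)
  dz <- stack$dz
  L <- numeric(0); M <- numeric(0)
  occ_count <- 0; intensity_sum <- 0
  for (y in seq_len(d[1])) {
    for (x in seq_len(d[2])) {
      top <- 0L; cnt <- 0L
      for (z in seq_len(d[3])) {
        if (v[y, x, z] >= threshold) {
          top <- z
          cnt <- cnt + 1L
          occ_count <- occ_count + 1
          intensity_sum <- intensity_sum + v[y, x, z]
        }
      }
      if (cnt > 0L || policy == "all") {
        L <- c(L, top * dz)
        M <- c(M, cnt * dz)
      }
    }
  }
  bv <- occ_count * stack$dx * stack$dy * dz
  list(
    max_thickness = if (length(L)) max(L) else 0,
    biovolume = bv,
    compactness = if (bv > 0) intensity_sum / bv else NA_real_,
    roughness_variance = if (length(L)) mean((L - mean(L))^2) else NA_real_,
    continuity_ratio = if (length(L) && mean(L) > 0) mean(M) / mean(L) else NA_real_
  )
}

# Brute-force Otsu: scan every candidate threshold t (occupied iff >= t),
# computing class weights and means directly from the raw values.
brute_force_otsu <- function(x, bit_depth = 8L) {
  best_t <- NA_integer_
  best_v <- -Inf
  for (t in 1:(2^bit_depth - 1)) {
    lo <- x[x < t]; hi <- x[x >= t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(x)
    bcv <- w0 * (1 - w0) * (mean(hi) - mean(lo))^2
    if (bcv > best_v + 1e-12) {
      best_v <- bcv
      best_t <- t
    }
  }
  best_t
}

random_stack <- function(n = 8L, seed = 1L, bit_depth = 8L) {
  set.seed(seed)
  v <- array(sample(0:(2^bit_depth - 1), n^3, replace = TRUE), dim = c(n, n, n))
  voxel_stack(v, dx = 0.2, dy = 0.3, dz = 0.5, bit_depth = bit_depth)
}

expect_metrics_equal_naive <- function(stack, threshold) {
  got <- compute_metrics(stack, method = "fixed", threshold = threshold)
  ref <- naive_metrics(stack, threshold)
  expect_identical(got$max_thickness, ref$max_thickness)
  expect_equal(got$biovolume, ref$biovolume, tolerance = 1e-12)
  expect_equal(got$compactness, ref$compactness, tolerance = 1e-12)
  expect_equal(got$roughness_variance, ref$roughness_variance, tolerance = 1e-12)
  expect_equal(got$continuity_ratio, ref$continuity_ratio, tolerance = 1e-12)
}
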