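make_column_stack <- function(occupied_planes, nz = 4L, dz = 0.5) {
  # single-column binary stack with the given occupied plane indices
  occ <- array(FALSE, dim = c(1, 1, nz))
  occ[1, 1, occupied_planes] <- TRUE
  binary_stack(occ, dx = 0.1, dy = 0.1, dz = dz,
               threshold_used = 1, method = "fixed")
}

test_that("local thickness includes internal gaps, mask thickness excludes them", {
  contiguous <- thickness_profiles_from_binary(make_column_stack(1:3))
  expect_equal(contiguous$local_thickness, 1.5)
  expect_equal(contiguous$mask_thickness, 1.5)

  gapped <- thickness_profiles_from_binary(make_column_stack(c(1, 3)))
  expect_equal(gapped$local_thickness, 1.5)   # top plane 3 -> 3 * 0.5
  expect_equal(gapped$mask_thickness, 1.0)    # 2 occupied voxels * 0.5
})

test_that("empty columns contribute L = M = 0 under include-all, are dropped under biomass", {
  occ <- array(FALSE, dim = c(1, 2, 4))
  occ[1, 1, 1:2] <- TRUE
  b <- binary_stack(occ, 0.1, 0.1, 0.5, threshold_used = 1, method = "fixed")
  all_cols <- thickness_profiles_from_binary(b, column_policy = "all")
  expect_equal(all_cols$n_columns, 2L)
  expect_equal(sort(all_cols$local_thickness), c(0, 1))
  biomass <- thickness_profiles_from_binary(b)
  expect_equal(biomass$n_columns, 1L)
})

test_that("fixed-threshold segmentation obeys the >= threshold rule", {
  v <- array(0, dim = c(2, 2, 2))
  s <- voxel_stack(v, 0.1, 0.1, 0.5)
  expect_false(any(segment_stack(s, "fixed", threshold = 1)$occupancy))
  expect_true(all(segment_stack(s, "fixed", threshold = 0)$occupancy))
  expect_error(segment_stack(s, "fixed", threshold = 256), "bit_depth")
  expect_error(segment_stack(s, "fixed"), "required")
})

test_that("Otsu matches a brute-force between-class-variance search", {
  for (seed in 1:10) {
    set.seed(seed)
    # bimodal stack: modes near 20 and 200
    v <- array(round(c(rnorm(200, 20, 5), rnorm(312, 200, 10))), dim = c(8, 8, 8))
    v <- pmin(pmax(v, 0), 255)
    s <- voxel_stack(v, 0.1, 0.1, 0.5)
    b <- segment_stack(s, "otsu")
    expect_identical(b$threshold_used, brute_force_otsu(as.vector(v)))
    expect_gt(b$threshold_used, 20)
    expect_lt(b$threshold_used, 200)
  }
})

test_that("Otsu on a constant stack is signalled as degenerate", {
  s <- voxel_stack(array(7, dim = c(2, 2, 2)), 0.1, 0.1, 0.5)
  expect_error(segment_stack(s, "otsu"), "degenerate")
})

test_that("all five metrics equal the naive reference on random stacks", {
  for (seed in 1:30) {
    s <- random_stack(8L, seed = seed)
    expect_metrics_equal_naive(s, threshold = sample(1:255, 1))
  }
})

test_that("metric identities: single-voxel height, biovolume arithmetic, compactness", {
  # single occupied voxel at the top plane of a 40-plane stack, dz = 0.5
  v <- array(0, dim = c(4, 4, 40))
  v[2, 3, 40] <- 200
  s <- voxel_stack(v, 0.1, 0.1, 0.5)
  m <- compute_metrics(s, method = "fixed", threshold = 100)
  expect_equal(m$max_thickness, 20)             # plane 40 * 0.5 um
  expect_equal(m$biovolume, 0.005)              # one voxel
  expect_equal(m$compactness, 200 / 0.005)      # 40000 counts/um^3

  # doubling intensities doubles compactness, leaves the mask unchanged
  s2 <- voxel_stack(v * 2, 0.1, 0.1, 0.5, bit_depth = 16L)
  m2 <- compute_metrics(s2, method = "fixed", threshold = 100)
  expect_equal(m2$compactness, 2 * m$compactness)
  expect_equal(m2$biovolume, m$biovolume)
})

test_that("roughness is translation-invariant and continuity is bounded", {
  set.seed(42)
  hm <- matrix(sample(2:10, 64, replace = TRUE) * 0.5, 8, 8)
  a <- make_structured_stack(hm, nz = 30, noise_sd = 0)
  b <- make_structured_stack(hm + 2, nz = 30, noise_sd = 0)  # +4 planes everywhere
  ma <- compute_metrics(a$stack)
  mb <- compute_metrics(b$stack)
  expect_equal(mb$roughness_variance, ma$roughness_variance, tolerance = 1e-12)
  expect_gte(ma$continuity_ratio, 0)
  expect_lte(ma$continuity_ratio, 1)
  expect_gte(ma$max_thickness, mean(a$truth$true_height_map))
})

test_that("metrics are invariant under x/y axis permutation", {
  s <- random_stack(8L, seed = 99)
  sp <- voxel_stack(aperm(s$intensities, c(2, 1, 3)), s$dy, s$dx, s$dz)
  m1 <- compute_metrics(s, method = "fixed", threshold = 128)
  m2 <- compute_metrics(sp, method = "fixed", threshold = 128)
  for (f in c("max_thickness", "biovolume", "compactness",
              "roughness_variance", "continuity_ratio"))
    expect_equal(m2[[f]], m1[[f]], tolerance = 1e-12)
})

test_that("biovolume is additive over disjoint occupied regions", {
  v1 <- array(0, dim = c(4, 4, 6)); v1[1:2, , 1:3] <- 200
  v2 <- array(0, dim = c(4, 4, 6)); v2[3:4, , 2:5] <- 200
  both <- v1 + v2
  bv <- function(v) biovolume(segment_stack(
    voxel_stack(v, 0.1, 0.1, 0.5), "fixed", threshold = 100))
  expect_equal(bv(both), bv(v1) + bv(v2))
})

test_that("empty biofilms report explicit zeros/NA, never silent values", {
  s <- voxel_stack(array(0, dim = c(4, 4, 4)), 0.1, 0.1, 0.5)
  m <- compute_metrics(s, method = "fixed", threshold = 10)
  expect_equal(m$max_thickness, 0)
  expect_equal(m$biovolume, 0)
  expect_true(is.na(m$compactness))
  expect_true(is.na(m$roughness_variance))
  expect_true(is.na(m$continuity_ratio))
  expect_warning(max_thickness(thickness_profiles(numeric(0), numeric(0))),
                 "empty")
})

test_that("minimum-object-size filter removes speckles but keeps the slab", {
  sim <- make_slab_stack(nx = 8, ny = 8, nz = 10, height_um = 2, noise_sd = 0)
  v <- sim$stack$intensities
  v[5, 5, 9] <- 250                  # isolated bright speckle above the slab
  s <- voxel_stack(v, 0.1, 0.1, 0.5)
  plain <- compute_metrics(s, method = "fixed", threshold = 100)
  filtered <- compute_metrics(s, method = "fixed", threshold = 100,
                              min_object_size = 5L)
  expect_equal(plain$max_thickness, 4.5)       # speckle at plane 9
  expect_equal(filtered$max_thickness, 2)      # slab only
  expect_equal(filtered$biovolume, sim$truth$true_metrics$biovolume)
})
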