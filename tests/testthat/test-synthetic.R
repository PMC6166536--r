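test_that("a uniform noiseless slab has the advertised analytic truth", {
  sim <- make_slab_stack(nx = 64, ny = 64, nz = 40, voxel = c(0.1, 0.1, 0.5),
                         height_um = 10, noise_sd = 0)
  tm <- sim$truth$true_metrics
  expect_equal(tm$max_thickness, 10)
  expect_equal(tm$roughness_variance, 0)
  expect_equal(tm$continuity_ratio, 1)
  expect_equal(tm$biovolume, 64 * 64 * 20 * 0.005)  # 20 planes per column
  # truth equals a naive reference computed on the noiseless stack
  ref <- naive_metrics(sim$stack, threshold = 110)
  expect_equal(tm$max_thickness, ref$max_thickness)
  expect_equal(tm$biovolume, ref$biovolume)
  expect_equal(tm$compactness, ref$compactness)
  expect_equal(tm$roughness_variance, ref$roughness_variance)
  expect_equal(tm$continuity_ratio, ref$continuity_ratio)
})

test_that("requested heights are quantized to round(h/dz) planes", {
  sim <- make_slab_stack(nx = 4, ny = 4, nz = 25, voxel = c(0.1, 0.1, 0.35),
                         height_um = 7.0, noise_sd = 0)
  occ <- segment_stack(sim$stack, "fixed", threshold = 100)$occupancy
  expect_equal(sum(occ[1, 1, ]), 20)              # round(7.0 / 0.35) = 20
  expect_equal(sim$truth$true_height_map[1, 1], 20 * 0.35)
})

test_that("a zero-height slab is all background with zero biovolume", {
  sim <- make_slab_stack(nx = 4, ny = 4, nz = 10, height_um = 0, noise_sd = 0)
  expect_equal(sim$truth$true_metrics$biovolume, 0)
  expect_equal(sim$truth$true_metrics$max_thickness, 0)
  expect_true(all(sim$stack$intensities <= 20))
})

test_that("slab generator rejects invalid geometry and intensities", {
  expect_error(make_slab_stack(nz = 10, voxel = c(0.1, 0.1, 0.5),
                               height_um = 6), "depth")
  expect_error(make_slab_stack(nx = 0), "positive")
  expect_error(make_slab_stack(fg_intensity = 10, bg_intensity = 20),
               "exceed")
  expect_error(make_slab_stack(noise_sd = -1), "non-negative")
})

test_that("structured truth: two height populations give variance 25, gaps give continuity 0.8", {
  hm <- matrix(rep(c(10, 20), each = 32), 8, 8)   # equal counts of 10 and 20 um
  sim <- make_structured_stack(hm, nz = 50, noise_sd = 0)
  expect_equal(sim$truth$true_metrics$roughness_variance, 25)
  expect_equal(sim$truth$true_metrics$continuity_ratio, 1)

  gap <- make_structured_stack(matrix(10, 8, 8),
                               gaps = list(list(columns = NULL,
                                                from_um = 3, to_um = 5)),
                               nz = 25, noise_sd = 0)
  expect_equal(gap$truth$true_metrics$continuity_ratio, 0.8)  # (10 - 2) / 10
})

test_that("gaps at or above a column's top are rejected", {
  expect_error(
    make_structured_stack(matrix(5, 4, 4),
                          gaps = list(list(columns = NULL,
                                           from_um = 4, to_um = 5)),
                          nz = 12, noise_sd = 0),
    "top")
})

test_that("gap height never reaches column height in generated truth", {
  set.seed(3)
  hm <- matrix(sample(6:12, 36, replace = TRUE) * 0.5, 6, 6)
  sim <- make_structured_stack(hm,
                               gaps = list(list(columns = NULL,
                                                from_um = 0.5, to_um = 1.5)),
                               nz = 15, noise_sd = 0)
  has_gap <- sim$truth$true_gap_map > 0
  expect_true(all(sim$truth$true_gap_map[has_gap] <
                    sim$truth$true_height_map[has_gap]))
  expect_true(all(sim$truth$true_height_map >= 0))
})

test_that("generators are pure functions of their arguments including seed", {
  a <- make_slab_stack(nx = 8, ny = 8, nz = 10, height_um = 3,
                       noise_sd = 10, seed = 11)
  b <- make_slab_stack(nx = 8, ny = 8, nz = 10, height_um = 3,
                       noise_sd = 10, seed = 11)
  c <- make_slab_stack(nx = 8, ny = 8, nz = 10, height_um = 3,
                       noise_sd = 10, seed = 12)
  expect_identical(a$stack$intensities, b$stack$intensities)
  expect_false(identical(a$stack$intensities, c$stack$intensities))

  g1 <- make_growth_series(noise_sd = 0.05, seed = 4)
  g2 <- make_growth_series(noise_sd = 0.05, seed = 4)
  expect_identical(g1$curve$bca, g2$curve$bca)

  p1 <- make_gcms_samples(c(25, 250), noise_cv = 0.05, seed = 9)
  p2 <- make_gcms_samples(c(25, 250), noise_cv = 0.05, seed = 9)
  expect_identical(p1$areas, p2$areas)
})

test_that("generated intensities respect the declared bit depth", {
  sim8 <- make_slab_stack(nx = 8, ny = 8, nz = 10, height_um = 4,
                          fg_intensity = 250, noise_sd = 50, seed = 2)
  expect_true(all(sim8$stack$intensities >= 0))
  expect_true(all(sim8$stack$intensities <= 255))
  sim16 <- make_slab_stack(nx = 8, ny = 8, nz = 10, height_um = 4,
                           fg_intensity = 60000, bg_intensity = 100,
                           noise_sd = 5000, seed = 2, bit_depth = 16L)
  expect_true(all(sim16$stack$intensities <= 65535))
})

test_that("growth series has the designed sampling and noiseless slope", {
  sim <- make_growth_series(interval_min = 30, duration_min = 1440,
                            noise_sd = 0)
  expect_length(sim$curve$times, 49)   # every 30 min for 24 h
  # slope in the exponential window is log10(2)/doubling_time per minute
  w <- sim$truth$true_window
  sel <- sim$curve$times >= w[1] & sim$curve$times <= w[2]
  slopes <- diff(sim$curve$bca[sel]) / diff(sim$curve$times[sel])
  expect_equal(unique(round(slopes, 12)), log10(2) / 60)
  expect_error(make_growth_series(interval_min = 30, duration_min = 1000),
               "divisible")
  expect_error(make_growth_series(bca0 = 8, plateau_bca = 7), "plateau")
})

test_that("Ct tables encode folds as Ct shifts under the efficiency model", {
  sim <- make_ct_table(c(ctrl = 1, trt = 4), efficiency = 2, noise_sd = 0,
                       replicates = 3)
  expect_equal(nrow(sim$table), 12)   # 2 genes x 2 groups x 3 replicates
  ct_t <- function(g) unique(sim$table$ct[sim$table$group == g &
                                            sim$table$gene == "target"])
  expect_equal(ct_t("ctrl") - ct_t("trt"), 2)  # log2(4) cycles lower
  ref <- unique(sim$table$ct[sim$table$gene == "reference"])
  expect_length(ref, 1)                        # reference constant everywhere
  expect_error(make_ct_table(c(a = 0)), "positive")
  expect_error(make_ct_table(c(a = 1), efficiency = 2.5), "efficiency")
})

test_that("GC-MS blanks give zero analyte area but positive internal standard", {
  sim <- make_gcms_samples(c(0, 100), noise_cv = 0, seed = 1)
  expect_equal(sim$areas$area_245_348[1], 0)
  expect_gt(sim$areas$area_249_352[1], 0)
  # noiseless responses exactly proportional to concentration
  stds <- make_gcms_samples(c(25, 50, 100, 175, 250), noise_cv = 0)
  resp <- stds$areas$area_245_348 / stds$areas$area_249_352
  expect_equal(resp / resp[1], c(25, 50, 100, 175, 250) / 25, tolerance = 1e-12)
  expect_error(make_gcms_samples(c(-1)), "non-negative")
})
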