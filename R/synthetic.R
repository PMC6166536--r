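#' @title Synthetic data with known ground truth
#' @description Generators emulating the four instrument outputs of the
#'   co-culture phenotyping pipeline: confocal Z-stacks of slab-like
#'   biofilms, plate-reader growth series in BCA units, qPCR Ct tables under
#'   an explicit amplification-efficiency model, and GC-MS peak areas with a
#'   deuterated internal standard. Every generator returns both the data and
#'   a `ground_truth` object with the analytically known quantities, so each
#'   downstream stage can be tested against truth. All generators are pure
#'   functions of their arguments including `seed`.
#' @name synthetic
NULL

new_ground_truth <- function(...) {
  structure(list(...), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

# draw integer intensities around a mean, clipped to the bit-depth range
draw_intensities <- function(n, mean, sd, bit_depth) {
  v <- if (sd > 0) stats::rnorm(n, mean, sd) else rep(mean, n)
  pmin(pmax(round(v), 0), 2^bit_depth - 1)
}

# analytic metrics for a set of quantized column heights (um) and per-column
# gap heights (um), over biomass columns (height > 0)
truth_metrics <- function(L, gap, dx, dy, fg_intensity, dz) {
  keep <- L > 0
  Lb <- L[keep]; Mb <- Lb - gap[keep]
  bv <- sum(Mb) * dx * dy
  if (length(Lb) == 0L) {
    return(biofilm_metrics(0, 0, NA_real_, NA_real_, NA_real_,
                           provenance = list(source = "analytic")))
  }
  biofilm_metrics(
    max_thickness = max(Lb),
    biovolume = bv,
    compactness = fg_intensity / (dx * dy * dz),
    roughness_variance = mean((Lb - mean(Lb))^2),
    continuity_ratio = mean(Mb) / mean(Lb),
    provenance = list(source = "analytic")
  )
}

#' Generate a uniform slab biofilm stack
#'
#' Every column is occupied from the substratum (plane 1) up to
#' `round(height_um / dz)` planes; foreground and background intensities are
#' Gaussian around their means, clipped to the bit-depth range. The ground
#' truth stores the quantized height (`round(height_um/dz) * dz`), so
#' recovery tests are exact; a uniform slab has roughness 0 and continuity 1.
#'
#' @param nx,ny,nz Stack dimensions (columns in x, y; planes in z).
#' @param voxel Length-3 numeric `c(dx, dy, dz)` in micrometres.
#' @param height_um Requested slab height in micrometres
#'   (must not exceed `nz * dz`).
#' @param fg_intensity,bg_intensity Mean foreground/background intensity
#'   counts (`fg_intensity > bg_intensity`).
#' @param noise_sd Additive Gaussian noise SD in counts (`>= 0`).
#' @param seed Integer seed; generators are deterministic given it.
#' @param bit_depth 8 (default) or 16.
#' @return A list with elements `stack` (a [voxel_stack]) and `truth`
#'   (a `ground_truth` with `true_height_map`, `true_gap_map`,
#'   `true_metrics`, `seed`).
#' @export
make_slab_stack <- function(nx = 64L, ny = 64L, nz = 40L,
                            voxel = c(0.1, 0.1, 0.5),
                            height_um = 10,
                            fg_intensity = 200, bg_intensity = 20,
                            noise_sd = 0, seed = 1L, bit_depth = 8L) {
  if (nx <= 0 || ny <= 0 || nz <= 0) stop("stack dimensions must be positive")
  dx <- voxel[1]; dy <- voxel[2]; dz <- voxel[3]
  if (height_um < 0) stop("height_um must be non-negative")
  if (height_um > nz * dz + 1e-9)
    stop("height_um exceeds the stack depth nz * dz")
  if (fg_intensity <= bg_intensity)
    stop("fg_intensity must exceed bg_intensity")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  height_map <- matrix(height_um, ny, nx)
  make_structured_stack(height_map, gaps = list(), nz = nz, voxel = voxel,
                        fg_intensity = fg_intensity,
                        bg_intensity = bg_intensity,
                        noise_sd = noise_sd, seed = seed,
                        bit_depth = bit_depth)
}

#' Generate a structured biofilm stack from a height map and gap spec
#'
#' Builds a stack whose (x, y) column heights follow `height_map`
#' (micrometres, quantized to `round(h/dz)` planes) with optional internal
#' gaps: each entry of `gaps` names a set of columns and a z-interval (um)
#' whose occupied voxels are removed. Gaps must lie strictly below each
#' affected column's top plane (a gap at the top would change the height).
#' Ground-truth metrics are computed analytically from the quantized
#' heights: max thickness = max height, roughness = population variance of
#' heights, continuity = 1 - mean gap height / mean height over biomass
#' columns.
#'
#' @param height_map Numeric `ny x nx` matrix of column heights in um.
#' @param gaps List of entries `list(columns = , from_um = , to_um = )`;
#'   `columns` is a logical `ny x nx` matrix (or `NULL` for all columns).
#'   The interval `[from_um, to_um)` is quantized to planes
#'   `round(from_um/dz)+1 .. round(to_um/dz)`.
#' @param nz Number of Z planes; defaults to the minimum depth holding the
#'   tallest column.
#' @inheritParams make_slab_stack
#' @return As [make_slab_stack].
#' @export
make_structured_stack <- function(height_map, gaps = list(), nz = NULL,
                                  voxel = c(0.1, 0.1, 0.5),
                                  fg_intensity = 200, bg_intensity = 20,
                                  noise_sd = 0, seed = 1L, bit_depth = 8L) {
  dx <- voxel[1]; dy <- voxel[2]; dz <- voxel[3]
  ny <- nrow(height_map); nx <- ncol(height_map)
  planes <- round(height_map / dz)
  if (any(planes < 0)) stop("heights must be non-negative")
  if (is.null(nz)) nz <- max(planes, 1L)
  nz <- as.integer(nz)
  if (any(planes > nz)) stop("a column height exceeds the stack depth nz * dz")
  occ <- array(FALSE, dim = c(ny, nx, nz))
  zidx <- array(rep(seq_len(nz), each = ny * nx), dim = c(ny, nx, nz))
  occ <- zidx <= array(rep(planes, nz), dim = c(ny, nx, nz))
  gap_planes <- matrix(0L, ny, nx)
  for (g in gaps) {
    cols <- if (is.null(g$columns)) matrix(TRUE, ny, nx) else g$columns
    p_from <- round(g$from_um / dz) + 1L
    p_to <- round(g$to_um / dz)
    if (p_to < p_from) stop("empty gap interval after quantization")
    if (any(cols & (p_to >= planes)))
      stop("gap reaches or exceeds a column's top plane; gaps must be strictly internal")
    for (p in p_from:p_to) {
      sl <- occ[, , p]
      sl[cols] <- FALSE
      occ[, , p] <- sl
    }
    gap_planes[cols] <- gap_planes[cols] + (p_to - p_from + 1L)
  }
  set.seed(seed)
  v <- array(0, dim = c(ny, nx, nz))
  v[occ] <- draw_intensities(sum(occ), fg_intensity, noise_sd, bit_depth)
  v[!occ] <- draw_intensities(sum(!occ), bg_intensity, noise_sd, bit_depth)
  stack <- voxel_stack(v, dx, dy, dz, bit_depth = bit_depth)
  L <- planes * dz
  gap_um <- gap_planes * dz
  truth <- new_ground_truth(
    true_height_map = L,
    true_gap_map = gap_um,
    true_metrics = truth_metrics(L, gap_um, dx, dy, fg_intensity, dz),
    seed = seed
  )
  list(stack = stack, truth = truth)
}

#' Generate a growth series in BCA units
#'
#' Background-corrected absorbance follows a lag, then a log-linear rise
#' with slope `log10(2) / doubling_time_min` per minute, then a plateau;
#' additive Gaussian noise on top. Defaults mirror a 30-min sampling
#' interval over 24 h (49 points).
#'
#' @param bca0 Baseline BCA during lag.
#' @param doubling_time_min True doubling time in minutes (`> 0`).
#' @param lag_min Lag duration in minutes.
#' @param plateau_bca Plateau BCA (`> bca0`).
#' @param interval_min Sampling interval (min).
#' @param duration_min Total duration (min); must be divisible by
#'   `interval_min`.
#' @param noise_sd Additive noise SD in BCA units.
#' @param seed Integer seed.
#' @return List with `curve` (a [growth_curve]) and `truth` (a
#'   `ground_truth` with `true_doubling_time`, `true_window`, `seed`).
#' @export
make_growth_series <- function(bca0 = 5, doubling_time_min = 60,
                               lag_min = 120, plateau_bca = 7,
                               interval_min = 30, duration_min = 1440,
                               noise_sd = 0, seed = 1L) {
  if (bca0 >= plateau_bca) stop("bca0 must be below plateau_bca")
  if (doubling_time_min <= 0) stop("doubling_time_min must be positive")
  if (duration_min %% interval_min != 0)
    stop("duration_min must be divisible by interval_min")
  times <- seq(0, duration_min, by = interval_min)
  slope <- log10(2) / doubling_time_min
  bca <- pmin(bca0 + slope * pmax(times - lag_min, 0), plateau_bca)
  set.seed(seed)
  if (noise_sd > 0) bca <- bca + stats::rnorm(length(bca), 0, noise_sd)
  curve <- growth_curve(times, bca, blank_corrected = TRUE)
  truth <- new_ground_truth(
    true_doubling_time = doubling_time_min,
    true_window = c(lag_min, lag_min + (plateau_bca - bca0) / slope),
    seed = seed
  )
  list(curve = curve, truth = truth)
}

#' Generate a qPCR Ct table under an efficiency model
#'
#' For each group g with true fold `f_g` relative to the calibrator, the
#' target gene's expected Ct is
#' `target_ct_calibrator - log(f_g)/log(efficiency)`; the reference (16S)
#' gene's expected Ct is constant across groups. Additive Gaussian noise on
#' cycles.
#'
#' @param group_folds Named numeric vector of true fold changes per group;
#'   the calibrator group should carry fold 1.
#' @param ref_ct Expected reference-gene Ct (cycles).
#' @param target_ct_calibrator Expected target Ct in the calibrator group.
#' @param efficiency Amplification factor per cycle, in `(1, 2]`; 2 is
#'   perfect doubling.
#' @param noise_sd Ct noise SD (cycles).
#' @param replicates Replicates per group (`>= 1`).
#' @param seed Integer seed.
#' @return List with `table` (data frame: sample, group, gene, ct,
#'   replicate) and `truth` (`true_fold_change` named vector, `seed`).
#' @export
make_ct_table <- function(group_folds, ref_ct = 15,
                          target_ct_calibrator = 25, efficiency = 2,
                          noise_sd = 0, replicates = 3L, seed = 1L) {
  if (any(group_folds <= 0)) stop("fold changes must be positive")
  if (efficiency <= 1 || efficiency > 2)
    stop("efficiency must lie in (1, 2]")
  if (replicates < 1) stop("replicates must be >= 1")
  groups <- names(group_folds)
  if (is.null(groups)) stop("group_folds must be a named vector")
  set.seed(seed)
  rows <- do.call(rbind, lapply(groups, function(g) {
    tgt <- target_ct_calibrator - log(group_folds[[g]]) / log(efficiency)
    data.frame(
      sample = paste0(g, "_r", seq_len(replicates)),
      group = g,
      gene = rep(c("target", "reference"), each = replicates),
      ct = c(tgt + stats::rnorm(replicates, 0, noise_sd),
             ref_ct + stats::rnorm(replicates, 0, noise_sd)),
      replicate = rep(seq_len(replicates), 2L),
      stringsAsFactors = FALSE
    )
  }))
  rownames(rows) <- NULL
  truth <- new_ground_truth(true_fold_change = group_folds, seed = seed)
  list(table = rows, truth = truth)
}

#' Generate GC-MS peak areas with a deuterated internal standard
#'
#' Analyte area is `response_factor * conc * (1 + e)` and the internal
#' standard area `istd_response_factor * istd_conc * (1 + e')`, with
#' independent multiplicative noise of coefficient of variation `noise_cv`.
#' Each analyte area is split over the two quantifier channels (m/z 245 and
#' 348 for derivatized DPD; 249 and 352 for the deuterated standard) in a
#' fixed 60/40 ratio; downstream analysis sums the pair, so the split
#' cancels.
#'
#' @param true_conc Numeric vector of analyte concentrations (ng/mL, `>= 0`).
#' @param istd_conc Internal standard concentration (ng/mL, `> 0`);
#'   250 ng/mL by default.
#' @param response_factor Analyte detector response (area per ng/mL).
#' @param istd_response_factor Internal-standard response (area per ng/mL).
#' @param od600 Numeric vector of culture densities, recycled to
#'   `length(true_conc)`; use `NA` for cell-free standards.
#' @param noise_cv Multiplicative noise CV (fraction).
#' @param seed Integer seed.
#' @return List with `areas` (data frame: sample, area_245_348,
#'   area_249_352, od600, known_conc_ng_ml) and `truth`
#'   (`true_concentrations`, `seed`).
#' @export
make_gcms_samples <- function(true_conc, istd_conc = 250,
                              response_factor = 1000,
                              istd_response_factor = 800,
                              od600 = NA_real_, noise_cv = 0, seed = 1L) {
  if (any(true_conc < 0)) stop("concentrations must be non-negative")
  if (istd_conc <= 0) stop("istd_conc must be positive")
  n <- length(true_conc)
  od600 <- rep_len(od600, n)
  set.seed(seed)
  eps_a <- if (noise_cv > 0) stats::rnorm(n, 0, noise_cv) else numeric(n)
  eps_i <- if (noise_cv > 0) stats::rnorm(n, 0, noise_cv) else numeric(n)
  a_area <- response_factor * true_conc * (1 + eps_a)
  i_area <- istd_response_factor * istd_conc * (1 + eps_i)
  a_area <- pmax(a_area, 0)
  i_area <- pmax(i_area, 0)
  areas <- data.frame(
    sample = paste0("s", seq_len(n)),
    area_245_348 = a_area,
    area_249_352 = i_area,
    od600 = od600,
    known_conc_ng_ml = true_conc,
    stringsAsFactors = FALSE
  )
  truth <- new_ground_truth(true_concentrations = true_conc, seed = seed)
  list(areas = areas, truth = truth)
}
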