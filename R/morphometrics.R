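#' Segment a confocal stack into occupied and background voxels
#'
#' Replaces proprietary surface reconstruction with a documented, global
#' thresholding step: a voxel is occupied iff its intensity is greater than
#' or equal to the threshold. With `method = "otsu"` the threshold is chosen
#' to maximize the between-class variance of the global intensity histogram
#' (all candidate integer thresholds are scanned; ties resolve to the
#' smallest).
#'
#' @param stack A [voxel_stack].
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param threshold Required for `method = "fixed"`: an intensity in
#'   `[0, 2^bit_depth)`.
#' @param min_object_size Optional minimum 6-connected component size in
#'   voxels; components smaller than this are removed from the occupancy
#'   mask. Default `0` (no filtering).
#' @return A [binary_stack].
#' @export
segment_stack <- function(stack, method = c("otsu", "fixed"),
                          threshold = NULL, min_object_size = 0L) {
  stopifnot(inherits(stack, "voxel_stack"))
  method <- match.arg(method)
  v <- stack$intensities
  if (method == "fixed") {
    if (is.null(threshold))
      stop("`threshold` is required when method = \"fixed\"")
    if (threshold < 0 || threshold >= 2^stack$bit_depth)
      stop("fixed threshold must lie in [0, 2^bit_depth)")
    thr <- threshold
  } else {
    thr <- otsu_threshold(as.integer(round(v)), stack$bit_depth)
  }
  occ <- array(v >= thr, dim = dim(v))
  if (min_object_size > 0L && any(occ)) {
    lab <- label_components_3d(occ)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_object_size)
    occ <- array(lab %in% keep, dim = dim(v))
  }
  binary_stack(occ, stack$dx, stack$dy, stack$dz,
               threshold_used = thr, method = method)
}

# Global Otsu threshold on integer intensities in [0, 2^bit_depth - 1].
# Returns the threshold t (occupied iff intensity >= t) maximizing the
# between-class variance w0*w1*(mu1-mu0)^2; smallest t on ties.
otsu_threshold <- function(x, bit_depth) {
  nbins <- 2L^bit_depth
  h <- tabulate(x + 1L, nbins = nbins)
  levels <- 0:(nbins - 1L)
  n <- sum(h)
  if (sum(h > 0L) < 2L)
    stop("degenerate stack: all intensities identical, Otsu threshold undefined")
  # class 0 = intensities < t, class 1 = intensities >= t, for t in 1..max
  csum <- cumsum(h)                     # counts <= level
  cmean <- cumsum(h * levels)           # intensity mass <= level
  total_mean <- cmean[nbins] / n
  # candidate t corresponds to splitting after level t-1
  w0 <- csum[-nbins] / n
  mu0 <- ifelse(w0 > 0, cmean[-nbins] / csum[-nbins], 0)
  w1 <- 1 - w0
  mu1 <- ifelse(w1 > 0, (cmean[nbins] - cmean[-nbins]) / (n - csum[-nbins]), 0)
  bcv <- w0 * w1 * (mu1 - mu0)^2
  bcv[!is.finite(bcv)] <- -Inf
  which.max(bcv)                        # threshold t = index (split after level t-1)
}

# 6-connected component labelling of a 3D logical array by iterative
# minimum-label propagation (vectorized array shifts until fixpoint).
label_components_3d <- function(occ) {
  d <- dim(occ)
  lab <- array(0L, dim = d)
  lab[occ] <- seq_len(sum(occ))
  shift_min <- function(l) {
    m <- l
    n <- array(Inf, dim = d)
    l2 <- l; l2[l2 == 0L] <- Inf
    # six face neighbours
    n[-1, , ]  <- pmin(n[-1, , ],  l2[-d[1], , ])
    n[-d[1], , ] <- pmin(n[-d[1], , ], l2[-1, , ])
    n[, -1, ]  <- pmin(n[, -1, ],  l2[, -d[2], ])
    n[, -d[2], ] <- pmin(n[, -d[2], ], l2[, -1, ])
    n[, , -1]  <- pmin(n[, , -1],  l2[, , -d[3]])
    n[, , -d[3]] <- pmin(n[, , -d[3]], l2[, , -1])
    upd <- occ & is.finite(n) & n < l2
    m[upd] <- as.integer(n[upd])
    m
  }
  repeat {
    nxt <- shift_min(lab)
    if (identical(nxt, lab)) break
    lab <- nxt
  }
  # compact labels to 1..k
  u <- sort(unique(lab[lab > 0L]))
  lab[lab > 0L] <- match(lab[lab > 0L], u)
  lab
}

#' Per-column local and mask thickness of a segmented biofilm
#'
#' For every (x, y) column: the local biovolume thickness
#' `L = (top occupied plane index) * dz`, measured substratum to top and
#' including any internal gaps; and the surface-mask thickness
#' `M = (occupied plane count) * dz`, counting only occupied voxels. A voxel
#' in plane k (1-based) spans `[(k-1)*dz, k*dz)`, so a single-plane biofilm
#' has thickness `dz`, not 0.
#'
#' @param binary A [binary_stack].
#' @param column_policy `"biomass"` (default): only columns with at least
#'   one occupied voxel enter the profiles; `"all"`: every column, empty
#'   columns contributing `L = M = 0`.
#' @return A [thickness_profiles]; zero columns (empty stack under the
#'   biomass policy) yields an empty profile, and downstream metrics report
#'   0 or `NA` explicitly.
#' @export
thickness_profiles_from_binary <- function(binary,
                                           column_policy = c("biomass", "all")) {
  stopifnot(inherits(binary, "binary_stack"))
  column_policy <- match.arg(column_policy)
  d <- dim(binary$occupancy)
  nz <- d[3]
  occm <- matrix(binary$occupancy, ncol = nz)   # rows = columns (y,x), cols = z
  counts <- rowSums(occm)
  # top occupied plane index per column (0 when empty)
  top <- apply(occm, 1L, function(r) if (any(r)) max(which(r)) else 0L)
  L <- top * binary$dz
  M <- counts * binary$dz
  if (column_policy == "biomass") {
    keep <- counts > 0
    L <- L[keep]; M <- M[keep]
  }
  thickness_profiles(L, M, column_policy = column_policy)
}

#' Maximal biovolume thickness (height)
#'
#' The maximum over columns of the local biovolume thickness, in um.
#'
#' @param profiles A [thickness_profiles].
#' @return Height in micrometres; 0 with a warning on empty profiles.
#' @export
max_thickness <- function(profiles) {
  stopifnot(inherits(profiles, "thickness_profiles"))
  if (profiles$n_columns == 0L) {
    warning("empty profiles: no occupied columns, max thickness reported as 0")
    return(0)
  }
  max(profiles$local_thickness)
}

#' Biovolume of a segmented stack
#'
#' Total volume of occupied voxels: `count * dx * dy * dz`, in um^3.
#'
#' @param binary A [binary_stack].
#' @return Biovolume in cubic micrometres.
#' @export
biovolume <- function(binary) {
  stopifnot(inherits(binary, "binary_stack"))
  sum(binary$occupancy) * binary$dx * binary$dy * binary$dz
}

#' Compactness: total fluorescence per unit biovolume
#'
#' Sum of source intensities over occupied voxels divided by the biovolume,
#' in counts per um^3.
#'
#' @param stack The source [voxel_stack].
#' @param binary The congruent [binary_stack].
#' @return Compactness; `NA` when the biovolume is 0 (undefined).
#' @export
compactness <- function(stack, binary) {
  stopifnot(inherits(stack, "voxel_stack"), inherits(binary, "binary_stack"))
  bv <- biovolume(binary)
  if (bv == 0) return(NA_real_)
  sum(stack$intensities[binary$occupancy]) / bv
}

#' Biofilm roughness variance
#'
#' The population variance of the local thickness over the included
#' columns: `sum((L_i - mean(L))^2) / N`, in um^2. A perfectly uniformly
#' thick biofilm has roughness 0; larger values mean a rougher surface.
#'
#' @param profiles A [thickness_profiles].
#' @return Roughness variance in um^2; `NA` on empty profiles.
#' @export
roughness_variance <- function(profiles) {
  stopifnot(inherits(profiles, "thickness_profiles"))
  L <- profiles$local_thickness
  if (length(L) == 0L) return(NA_real_)
  mean((L - mean(L))^2)
}

#' Biofilm continuity ratio
#'
#' Mean surface-mask thickness divided by mean local biovolume thickness.
#' Equals 1 iff no column has an internal gap below its top occupied voxel;
#' values below 1 measure how much of the reconstructed surface is holes.
#'
#' @param profiles A [thickness_profiles].
#' @return Dimensionless ratio in `[0, 1]`; `NA` when the mean local
#'   thickness is 0 (undefined).
#' @export
continuity_ratio <- function(profiles) {
  stopifnot(inherits(profiles, "thickness_profiles"))
  L <- profiles$local_thickness
  if (length(L) == 0L || mean(L) == 0) return(NA_real_)
  mean(profiles$mask_thickness) / mean(L)
}

#' Compute all biofilm morphometrics of a stack
#'
#' Segments the stack, builds per-column thickness profiles, and assembles
#' the five summary metrics with provenance (threshold, method, column
#' policy) recorded in the result.
#'
#' @inheritParams segment_stack
#' @inheritParams thickness_profiles_from_binary
#' @return A [biofilm_metrics].
#' @export
compute_metrics <- function(stack, method = c("otsu", "fixed"),
                            threshold = NULL,
                            column_policy = c("biomass", "all"),
                            min_object_size = 0L) {
  method <- match.arg(method)
  column_policy <- match.arg(column_policy)
  binary <- segment_stack(stack, method = method, threshold = threshold,
                          min_object_size = min_object_size)
  profiles <- thickness_profiles_from_binary(binary, column_policy = column_policy)
  mt <- if (profiles$n_columns == 0L) 0 else max(profiles$local_thickness)
  biofilm_metrics(
    max_thickness = mt,
    biovolume = biovolume(binary),
    compactness = compactness(stack, binary),
    roughness_variance = roughness_variance(profiles),
    continuity_ratio = continuity_ratio(profiles),
    provenance = list(threshold = binary$threshold_used, method = method,
                      column_policy = column_policy,
                      min_object_size = min_object_size)
  )
}
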