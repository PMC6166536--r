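#' Construct a voxel stack
#'
#' A `voxel_stack` holds a 3D grid of non-negative integer fluorescence
#' intensities from a confocal Z-stack, together with the anisotropic voxel
#' dimensions in micrometres. The array is indexed `[y, x, z]` with `z = 1`
#' at the substratum.
#'
#' @param intensities 3D numeric array of non-negative integer intensities,
#'   dimension `c(ny, nx, nz)`.
#' @param dx,dy,dz Voxel edge lengths in micrometres. `dz` is the Z-slice
#'   spacing (confocal acquisitions in this system typically use
#'   0.35--0.70 um, but any positive value is accepted).
#' @param bit_depth Intensity bit depth, 8 or 16.
#' @return An object of class `voxel_stack`.
#' @export
voxel_stack <- function(intensities, dx, dy, dz, bit_depth = 8L) {
  if (length(dim(intensities)) != 3L)
    stop("`intensities` must be a 3D array indexed [y, x, z]")
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16")
  if (any(!is.finite(intensities)) || any(intensities < 0))
    stop("intensities must be finite and non-negative")
  if (any(intensities > 2^bit_depth - 1))
    stop("intensities exceed the declared bit depth")
  if (!all(c(dx, dy, dz) > 0)) stop("voxel dimensions must be positive")
  structure(
    list(intensities = intensities, dx = dx, dy = dy, dz = dz,
         bit_depth = as.integer(bit_depth)),
    class = "voxel_stack"
  )
}

#' @export
print.voxel_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "<voxel_stack> %d x %d columns, %d planes; voxel %.3g x %.3g x %.3g um; %d-bit\n",
    d[2], d[1], d[3], x$dx, x$dy, x$dz, x$bit_depth))
  invisible(x)
}

#' @export
dim.voxel_stack <- function(x) dim(x$intensities)

#' Construct a binary (segmented) stack
#'
#' Boolean occupancy grid congruent with its source [voxel_stack], plus the
#' threshold and method that produced it. A voxel is occupied iff its
#' intensity is greater than or equal to `threshold_used`.
#'
#' @param occupancy 3D logical array, same dimensions as the source stack.
#' @param dx,dy,dz Voxel dimensions in micrometres (copied from the source).
#' @param threshold_used Intensity threshold applied.
#' @param method Segmentation method, `"otsu"` or `"fixed"`.
#' @return An object of class `binary_stack`.
#' @export
binary_stack <- function(occupancy, dx, dy, dz, threshold_used, method) {
  if (!is.logical(occupancy) || length(dim(occupancy)) != 3L)
    stop("`occupancy` must be a 3D logical array")
  structure(
    list(occupancy = occupancy, dx = dx, dy = dy, dz = dz,
         threshold_used = threshold_used, method = method),
    class = "binary_stack"
  )
}

#' @export
print.binary_stack <- function(x, ...) {
  d <- dim(x$occupancy)
  cat(sprintf(
    "<binary_stack> %d x %d columns, %d planes; %d occupied voxels (%s, threshold %g)\n",
    d[2], d[1], d[3], sum(x$occupancy), x$method, x$threshold_used))
  invisible(x)
}

#' Per-column thickness profiles
#'
#' For each included (x, y) column of a segmented stack: the local biovolume
#' thickness `L` (substratum to the top of the highest occupied voxel,
#' internal gaps included) and the surface-mask thickness `M` (occupied
#' voxel count times `dz`, gaps excluded), both in micrometres.
#'
#' @param local_thickness Numeric vector of `L` values (um).
#' @param mask_thickness Numeric vector of `M` values (um), same length.
#' @param column_policy Inclusion policy used: `"biomass"` (columns with at
#'   least one occupied voxel) or `"all"`.
#' @return An object of class `thickness_profiles`.
#' @export
thickness_profiles <- function(local_thickness, mask_thickness,
                               column_policy = "biomass") {
  if (length(local_thickness) != length(mask_thickness))
    stop("profile vectors must have equal length")
  if (any(mask_thickness > local_thickness + 1e-9))
    stop("mask thickness cannot exceed local thickness")
  structure(
    list(local_thickness = local_thickness,
         mask_thickness = mask_thickness,
         n_columns = length(local_thickness),
         column_policy = column_policy),
    class = "thickness_profiles"
  )
}

#' @export
print.thickness_profiles <- function(x, ...) {
  cat(sprintf(
    "<thickness_profiles> %d columns (policy: %s); mean L %.3g um, mean M %.3g um\n",
    x$n_columns, x$column_policy,
    if (x$n_columns) mean(x$local_thickness) else NA_real_,
    if (x$n_columns) mean(x$mask_thickness) else NA_real_))
  invisible(x)
}

#' Summary morphometrics of one imaged biofilm
#'
#' The five summary metrics: maximal biovolume thickness (um), biovolume
#' (um^3), compactness (total fluorescence per um^3 of biovolume), roughness
#' variance (um^2, the population variance of local thickness), and the
#' continuity ratio (dimensionless, 1 = no internal gaps). Undefined metrics
#' (e.g. on an empty biofilm) are `NA`, never silently 0.
#'
#' @param max_thickness,biovolume,compactness,roughness_variance,continuity_ratio
#'   The metric values.
#' @param provenance Named list recording threshold, method and column policy.
#' @return An object of class `biofilm_metrics`.
#' @export
biofilm_metrics <- function(max_thickness, biovolume, compactness,
                            roughness_variance, continuity_ratio,
                            provenance = list()) {
  if (!is.na(continuity_ratio) &&
      (continuity_ratio < -1e-9 || continuity_ratio > 1 + 1e-9))
    stop("continuity_ratio must lie in [0, 1]")
  if (!is.na(roughness_variance) && roughness_variance < -1e-9)
    stop("roughness_variance must be non-negative")
  structure(
    list(max_thickness = max_thickness, biovolume = biovolume,
         compactness = compactness, roughness_variance = roughness_variance,
         continuity_ratio = continuity_ratio, provenance = provenance),
    class = "biofilm_metrics"
  )
}

#' @export
print.biofilm_metrics <- function(x, ...) {
  cat("<biofilm_metrics>\n")
  cat(sprintf("  max thickness:      %.4g um\n", x$max_thickness))
  cat(sprintf("  biovolume:          %.4g um^3\n", x$biovolume))
  cat(sprintf("  compactness:        %.4g counts/um^3\n", x$compactness))
  cat(sprintf("  roughness variance: %.4g um^2\n", x$roughness_variance))
  cat(sprintf("  continuity ratio:   %.4g\n", x$continuity_ratio))
  invisible(x)
}

#' @export
as.data.frame.biofilm_metrics <- function(x, ...) {
  data.frame(
    max_thickness_um = x$max_thickness,
    biovolume_um3 = x$biovolume,
    compactness = x$compactness,
    roughness_variance_um2 = x$roughness_variance,
    continuity_ratio = x$continuity_ratio,
    threshold = if (is.null(x$provenance$threshold)) NA_real_ else x$provenance$threshold,
    method = if (is.null(x$provenance$method)) NA_character_ else x$provenance$method,
    column_policy = if (is.null(x$provenance$column_policy)) NA_character_ else x$provenance$column_policy,
    stringsAsFactors = FALSE
  )
}

#' Construct a growth curve
#'
#' Time series of background-corrected absorbance (BCA) values. BCA is a
#' log10 quantity: the instrument reports `log10(sum of object pixel
#' intensities)` per frame.
#'
#' @param times Sampling times in minutes, strictly increasing, starting at 0.
#' @param bca BCA values, one per time point.
#' @param blank_corrected Logical; whether a blank has been subtracted.
#' @return An object of class `growth_curve`.
#' @export
growth_curve <- function(times, bca, blank_corrected = FALSE) {
  if (length(times) != length(bca)) stop("`times` and `bca` lengths differ")
  if (length(times) && times[1] != 0) stop("times must start at 0")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(
    list(times = times, bca = bca, blank_corrected = isTRUE(blank_corrected)),
    class = "growth_curve"
  )
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("<growth_curve> %d points over %g min%s\n",
              length(x$times), if (length(x$times)) max(x$times) else 0,
              if (x$blank_corrected) " (blank-corrected)" else ""))
  invisible(x)
}

#' Linear concentration-response calibration curve
#'
#' Ordinary least-squares line of normalized detector response on analyte
#' concentration (ng/mL), with its R^2 and the concentration range spanned
#' by the standards used. Quantification outside `range` is flagged as
#' extrapolated.
#'
#' @param slope,intercept Fitted coefficients (normalized response per ng/mL).
#' @param r_squared Coefficient of determination of the fit.
#' @param range Length-2 numeric, `c(min, max)` standard concentration.
#' @param n_standards Number of calibration points used.
#' @return An object of class `calibration_curve`.
#' @export
calibration_curve <- function(slope, intercept, r_squared, range,
                              n_standards) {
  if (n_standards < 3) stop("calibration requires at least 3 standards")
  structure(
    list(slope = slope, intercept = intercept, r_squared = r_squared,
         range = range, n_standards = n_standards),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> response = %.4g * conc + %.4g (R^2 = %.4f); range %g-%g ng/mL, n = %d\n",
    x$slope, x$intercept, x$r_squared, x$range[1], x$range[2], x$n_standards))
  invisible(x)
}
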