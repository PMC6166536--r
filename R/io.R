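#' Write a voxel stack to a multi-page TIFF with a JSON sidecar
#'
#' One grayscale page per Z plane, substratum first; intensities are stored
#' at the stack's bit depth so the round trip through [read_stack()] is
#' exact. Voxel sizes are recorded in `<path>.json`.
#'
#' @param stack A [voxel_stack].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "voxel_stack"))
  d <- dim(stack$intensities)
  maxval <- 2^stack$bit_depth - 1
  pages <- lapply(seq_len(d[3]), function(z) stack$intensities[, , z] / maxval)
  tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth)
  jsonlite::write_json(
    list(dx = stack$dx, dy = stack$dy, dz = stack$dz,
         bit_depth = stack$bit_depth),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF into a voxel stack
#'
#' Pages must share one size and bit depth (8 or 16). Voxel sizes come from
#' the `<path>.json` sidecar written by [write_stack()], or must be given
#' explicitly; there is no safe default for physical voxel size.
#'
#' @param path TIFF path.
#' @param voxel Optional `c(dx, dy, dz)` in micrometres, overriding the
#'   sidecar.
#' @param reversed If `TRUE`, the last page is treated as the substratum.
#' @return A [voxel_stack].
#' @export
read_stack <- function(path, voxel = NULL, reversed = FALSE) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1L)
    stop("mixed page sizes in ", path, ": all Z planes must be congruent")
  if (is.null(voxel)) {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar))
      stop("no voxel metadata: supply `voxel = c(dx, dy, dz)` or a ",
           sidecar, " sidecar")
    meta <- jsonlite::read_json(sidecar)
    voxel <- c(meta$dx, meta$dy, meta$dz)
    bit_depth <- if (is.null(meta$bit_depth)) NULL else meta$bit_depth
  } else bit_depth <- NULL
  if (length(voxel) != 3 || any(!is.finite(voxel)))
    stop("voxel metadata must provide finite dx, dy, dz")
  maxint <- max(vapply(pages, max, 0))
  if (is.null(bit_depth)) bit_depth <- if (maxint > 255) 16L else 8L
  if (maxint > 2^bit_depth - 1)
    stop("unsupported bit depth: intensities exceed 16-bit range")
  if (reversed) pages <- rev(pages)
  arr <- array(0, dim = c(dims[[1]], length(pages)))
  for (z in seq_along(pages)) arr[, , z] <- pages[[z]]
  voxel_stack(arr, voxel[1], voxel[2], voxel[3], bit_depth = as.integer(bit_depth))
}

#' Read a qPCR Ct table from CSV
#'
#' Expects columns `sample, group, gene, ct, replicate` as written by the
#' synthetic generator or exported from a thermocycler.
#'
#' @param path CSV path.
#' @return A validated data frame.
#' @export
read_ct_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample", "group", "gene", "ct", "replicate")
  if (!all(req %in% names(tab)))
    stop("Ct CSV must have columns: ", paste(req, collapse = ", "))
  tab
}

#' Read a growth series from CSV
#'
#' Expects columns `time_min, bca`.
#'
#' @param path CSV path.
#' @param blank_corrected Whether the series is already blank-corrected.
#' @return A [growth_curve].
#' @export
read_growth_csv <- function(path, blank_corrected = TRUE) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_min", "bca") %in% names(tab)))
    stop("growth CSV must have columns time_min, bca")
  growth_curve(tab$time_min, tab$bca, blank_corrected = blank_corrected)
}

#' Read pre-integrated GC-MS peak areas from CSV
#'
#' Expects columns `sample, area_245_348, area_249_352, od600` (optionally
#' `known_conc_ng_ml` for standards).
#'
#' @param path CSV path.
#' @return A validated data frame.
#' @export
read_peak_areas_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample", "area_245_348", "area_249_352", "od600")
  if (!all(req %in% names(tab)))
    stop("peak-area CSV must have columns: ", paste(req, collapse = ", "))
  tab
}
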