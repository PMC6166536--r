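#' BCA value of one imaging frame
#'
#' Background-corrected absorbance as reported by image-cytometry plate
#' readers: `log10` of the sum of object pixel intensities.
#'
#' @param object_pixel_intensities Non-negative pixel intensity counts of
#'   the detected objects in one frame.
#' @return BCA value; `NA` with a warning when the sum is zero (undefined).
#' @export
bca_from_frame <- function(object_pixel_intensities) {
  if (any(object_pixel_intensities < 0))
    stop("object pixel intensities must be non-negative")
  s <- sum(object_pixel_intensities)
  if (s == 0) {
    warning("zero total object intensity: BCA undefined, returning NA")
    return(NA_real_)
  }
  log10(s)
}

#' Subtract a blank curve from a raw growth curve
#'
#' Pointwise subtraction on a matching time grid.
#'
#' @param raw,blank [growth_curve] objects on identical time grids.
#' @return A blank-corrected [growth_curve].
#' @export
background_correct <- function(raw, blank) {
  stopifnot(inherits(raw, "growth_curve"), inherits(blank, "growth_curve"))
  if (!isTRUE(all.equal(raw$times, blank$times)))
    stop("raw and blank curves must share the same time grid")
  growth_curve(raw$times, raw$bca - blank$bca, blank_corrected = TRUE)
}

# Detect the exponential window: the longest run of consecutive intervals
# whose local slope exceeds 5% of the maximum local slope, capped away from
# the lag baseline and the plateau by restricting to the middle 10-90% band
# of the curve's dynamic range (under noise, baseline and plateau intervals
# would otherwise leak into the run and bias the fitted slope).
detect_exponential_window <- function(curve) {
  t <- curve$times; b <- curve$bca
  s <- diff(b) / diff(t)
  smax <- max(s)
  if (smax <= 0) return(NULL)
  rng <- max(b) - min(b)
  lo <- min(b) + 0.1 * rng
  hi <- max(b) - 0.1 * rng
  keep <- s > 0.05 * smax & b[-length(b)] >= lo & b[-1] <= hi
  if (!any(keep)) return(NULL)
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  i <- starts[best]; j <- ends[best]
  c(t[i], t[j + 1L])          # points i .. j+1 bracket the kept intervals
}

#' Estimate generation (doubling) time from a growth curve
#'
#' Fits the slope `m` of BCA against time by ordinary least squares over the
#' exponential window and returns `log10(2) / m` minutes. BCA is a log10
#' quantity, so a doubling adds `log10(2)` BCA units. The window is detected
#' automatically (longest run of near-maximal local slopes, capped away from
#' the plateau) unless given explicitly.
#'
#' @param curve A [growth_curve].
#' @param window Optional `c(t_start, t_end)` in minutes overriding window
#'   detection.
#' @return Doubling time in minutes, with attributes `slope` (BCA/min) and
#'   `window`; `NA` with attribute `no_growth = TRUE` (and a warning) when
#'   no positive-slope window exists.
#' @export
generation_time <- function(curve, window = NULL) {
  stopifnot(inherits(curve, "growth_curve"))
  if (is.null(window)) window <- detect_exponential_window(curve)
  if (is.null(window)) {
    warning("no growth detected: curve has no positive-slope window")
    return(structure(NA_real_, no_growth = TRUE))
  }
  sel <- curve$times >= window[1] & curve$times <= window[2]
  if (sum(sel) < 3)
    stop("exponential window contains fewer than 3 points")
  fit <- stats::lm(bca ~ t, data = data.frame(t = curve$times[sel],
                                              bca = curve$bca[sel]))
  m <- unname(stats::coef(fit)[2])
  if (!is.finite(m) || m <= 0) {
    warning("no growth detected: fitted slope is not positive")
    return(structure(NA_real_, no_growth = TRUE))
  }
  structure(log10(2) / m, slope = m, window = window)
}

#' Maximum BCA (plateau density) of a growth curve
#'
#' @param curve A non-empty [growth_curve].
#' @return The maximum BCA value, the analogue of maximum optical density.
#' @export
max_bca <- function(curve) {
  stopifnot(inherits(curve, "growth_curve"))
  if (!length(curve$bca)) stop("empty growth curve")
  max(curve$bca)
}
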