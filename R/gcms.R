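#' Integrate an extracted-ion chromatogram
#'
#' Trapezoidal area under the sum of the selected m/z channel traces within
#' a retention-time window. The quantifier channel pairs for derivatized
#' DPD are m/z 245 + 348 (analyte) and 249 + 352 (deuterated internal
#' standard).
#'
#' @param chromatogram List or data frame with a numeric `time` component
#'   (minutes, strictly increasing) and one numeric trace per channel named
#'   `mz<channel>` (e.g. `mz245`).
#' @param channels Integer vector of m/z channels to sum.
#' @param rt_window `c(start, end)` minutes; must overlap the time axis in
#'   at least two samples.
#' @return Integrated area (counts x minutes).
#' @export
integrate_eic <- function(chromatogram, channels, rt_window) {
  t <- chromatogram$time
  if (is.null(t) || any(diff(t) <= 0))
    stop("chromatogram must have a strictly increasing `time` component")
  nm <- paste0("mz", channels)
  missing <- setdiff(nm, names(chromatogram))
  if (length(missing))
    stop("missing channel trace(s): ", paste(missing, collapse = ", "))
  y <- Reduce(`+`, lapply(nm, function(m) chromatogram[[m]]))
  if (any(y < 0)) stop("intensities must be non-negative")
  sel <- t >= rt_window[1] & t <= rt_window[2]
  if (sum(sel) < 2)
    stop("retention-time window covers fewer than 2 samples of the time axis")
  pracma::trapz(t[sel], y[sel])
}

#' Internal-standard- and OD-normalized detector response
#'
#' `(analyte_area / istd_area) / od600`. The deuterated internal standard
#' cancels injection and derivatization variability; OD600 normalization
#' puts culture supernatants on a per-cell-density scale and is skipped
#' (pass `od600 = NA`) for cell-free calibration standards.
#'
#' @param analyte_area Analyte peak area (sum of m/z 245 + 348), `>= 0`.
#' @param istd_area Internal-standard peak area (sum of 249 + 352), `> 0`.
#' @param od600 Culture density; `NA` skips OD normalization.
#' @return Dimensionless normalized response.
#' @export
normalized_response <- function(analyte_area, istd_area, od600 = NA_real_) {
  if (any(istd_area <= 0))
    stop("internal-standard area must be positive (failed derivatization or injection?)")
  if (any(analyte_area < 0)) stop("analyte area must be non-negative")
  if (any(od600[!is.na(od600)] <= 0)) stop("od600 must be positive")
  r <- analyte_area / istd_area
  od <- rep_len(od600, length(r))
  ifelse(is.na(od), r, r / od)
}

#' Fit an external calibration curve
#'
#' Ordinary least-squares line (with intercept) of normalized response on
#' concentration, over at least 3 distinct standard concentrations.
#' Optionally weighted (`weights` passed to [stats::lm()]).
#'
#' @param conc Standard concentrations (ng/mL).
#' @param response Normalized responses, same length.
#' @param weights Optional fit weights.
#' @return A [calibration_curve].
#' @export
fit_calibration <- function(conc, response, weights = NULL) {
  if (length(conc) != length(response)) stop("length mismatch")
  if (length(unique(conc)) < 3)
    stop("calibration requires >= 3 distinct standard concentrations")
  fit <- stats::lm(response ~ conc,
                   data = data.frame(conc = conc, response = response),
                   weights = weights)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((response - mean(response))^2)
  calibration_curve(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
    range = range(conc),
    n_standards = length(conc)
  )
}

#' Quantify DPD from a normalized response
#'
#' Inverts the calibration line, `conc = (response - intercept) / slope`
#' in ng/mL, and converts to micromolar: ng/mL divided by the molar mass in
#' g/mol gives umol/L directly. Responses mapping outside the calibrated
#' concentration range are flagged as extrapolated.
#'
#' @param response Normalized response(s).
#' @param curve A [calibration_curve].
#' @param molar_mass Analyte molar mass in g/mol; default 132.12 for DPD
#'   ((S)-4,5-dihydroxy-2,3-pentanedione, C5H8O4).
#' @return Data frame with columns `conc_ng_ml`, `conc_uM`, `extrapolated`.
#' @export
quantify_dpd <- function(response, curve, molar_mass = 132.12) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope == 0) stop("calibration slope is zero: cannot invert")
  conc <- (response - curve$intercept) / curve$slope
  tol <- 1e-9 * max(abs(curve$range))   # boundary concentrations are in range
  data.frame(
    conc_ng_ml = conc,
    conc_uM = conc / molar_mass,
    extrapolated = conc < curve$range[1] - tol | conc > curve$range[2] + tol
  )
}
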