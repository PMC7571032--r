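#' Fit a calibration curve
#'
#' Ordinary least-squares line of detector response (peak-area ratio of the
#' analyte derivative to the internal standard) on concentration. The residual
#' standard deviation (n - 2 denominator) is the "standard deviation of the
#' response" used for detection limits; the alternative reading — the sd of
#' blank/lowest-level responses — can be supplied directly to [lod()] via
#' `sigma`.
#'
#' @param concentration Numeric vector of standard concentrations (ug/kg),
#'   at least 3 distinct values.
#' @param response Numeric vector of responses, same length.
#' @return An object of class `calibration_curve`: list with `slope`,
#'   `intercept`, `sigma` (residual sd), `n`, and the fitted `lm`.
#' @export
#' @examples
#' cc <- fit_calibration(c(25, 50, 100, 200), c(0.26, 0.49, 1.02, 1.98))
#' cc$slope
fit_calibration <- function(concentration, response) {
  if (length(concentration) != length(response)) {
    abort_bad_arg("concentration and response must have equal length.")
  }
  if (length(unique(concentration)) < 3L) {
    abort_bad_arg("calibration needs at least 3 distinct concentrations.")
  }
  fit <- stats::lm(response ~ concentration)
  out <- list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    sigma = sqrt(sum(stats::residuals(fit)^2) / stats::df.residual(fit)),
    n = length(concentration),
    fit = fit
  )
  if (out$slope == 0) abort_bad_arg("calibration slope is zero.")
  class(out) <- "calibration_curve"
  out
}

#' Limit of detection and quantification
#'
#' LOD = 3.3 sigma / S from the calibration curve's residual standard
#' deviation sigma and slope S; LOQ = 3 x LOD. Values are returned at full
#' precision — round for presentation only (note 3 x 8 = 24 rounds of a
#' full-precision LOD near 8.3 to the conventionally reported 25).
#'
#' @param curve A `calibration_curve` from [fit_calibration()].
#' @param sigma Optional override for the response standard deviation (e.g.
#'   the sd of blank responses instead of the residual sd).
#' @return LOD or LOQ in the concentration units of the calibration.
#' @export
#' @examples
#' cc <- fit_calibration(c(25, 50, 100), c(0.25, 0.50, 1.00))
#' lod(cc); loq(cc)
lod <- function(curve, sigma = NULL) {
  stopifnot(inherits(curve, "calibration_curve"))
  s <- sigma %||% curve$sigma
  3.3 * s / abs(curve$slope)
}

#' @rdname lod
#' @export
loq <- function(curve, sigma = NULL) {
  3 * lod(curve, sigma)
}

#' Spike recovery
#'
#' Percentage of a known spiked amount recovered by the analytical method.
#'
#' @param measured Measured concentration in the spiked sample (ug/kg).
#' @param spiked True spiked concentration (ug/kg), > 0.
#' @return Recovery in percent.
#' @export
#' @examples
#' recovery(460, 500)  # 92
recovery <- function(measured, spiked) {
  if (any(spiked <= 0)) abort_bad_arg("spiked concentration must be > 0.")
  100 * measured / spiked
}

#' Intra- and inter-day repeatability
#'
#' Relative standard deviations from replicate measurements grouped by day:
#' intra-day RSD is the mean over days of the within-day 100 x sd / mean;
#' inter-day RSD is 100 x sd / mean of the daily means. Both are invariant
#' under multiplicative rescaling of all measurements.
#'
#' @param value Numeric vector of replicate measurements.
#' @param day Grouping vector (one label per measurement); >= 2 replicates
#'   per day, and >= 2 days for the inter-day figure.
#' @return A list with `intra_day` and `inter_day`, both in percent.
#' @export
#' @examples
#' repeatability_rsd(c(98, 102, 99, 101), day = c(1, 1, 2, 2))
repeatability_rsd <- function(value, day) {
  if (length(value) != length(day)) abort_bad_arg("value and day must have equal length.")
  by_day <- split(value, day)
  if (any(lengths(by_day) < 2L)) abort_bad_arg("need >= 2 replicates per day.")
  daily_mean <- vapply(by_day, mean, numeric(1))
  if (any(daily_mean == 0)) abort_bad_arg("a daily mean of zero makes RSD undefined.")
  intra <- mean(vapply(by_day, function(v) 100 * stats::sd(v) / mean(v), numeric(1)))
  inter <- if (length(by_day) >= 2L) 100 * stats::sd(daily_mean) / mean(daily_mean) else NA_real_
  list(intra_day = intra, inter_day = inter)
}
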