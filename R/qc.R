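#' Fit a linear calibration curve
#'
#' Ordinary least-squares regression of instrument response on
#' concentration, as used for solvent and matrix-matched calibration in
#' quantitative LC-MS/MS work. R-squared is `1 - SSres/SStot`, identical to
#' the squared correlation between fitted and observed responses whenever
#' the slope is nonzero.
#'
#' @param concentration Numeric vector, mg/kg. At least two distinct
#'   values over at least three points.
#' @param response Numeric vector of instrument responses, same length.
#' @param matrix_id Optional label for the calibration matrix (solvent or
#'   matrix-matched).
#' @return An object of class `"calibration"`: list with `slope`,
#'   `intercept`, `r2`, `range_low`, `range_high`, `matrix_id`, `fit` (the
#'   underlying `lm`).
#' @examples
#' cal <- fit_calibration(c(0.01, 0.1, 0.4, 0.8), c(1343, 13424, 53688, 107374))
#' cal$slope
#' @export
fit_calibration <- function(concentration, response, matrix_id = "solvent") {
  stopifnot(is.numeric(concentration), is.numeric(response),
            length(concentration) == length(response))
  if (length(concentration) < 3L)
    stop("calibration needs at least 3 points", call. = FALSE)
  if (length(unique(concentration)) < 2L)
    stop("degenerate design: all concentrations identical", call. = FALSE)
  fit <- stats::lm(response ~ concentration)
  ss_tot <- sum((response - mean(response))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(list(matrix_id = matrix_id,
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r2 = r2,
                 range_low = min(concentration),
                 range_high = max(concentration),
                 fit = fit),
            class = "calibration")
}

#' @export
print.calibration <- function(x, digits = 6, ...) {
  cat(sprintf("Calibration (%s): y = %s x + %s\n", x$matrix_id,
              format(x$slope, digits = digits),
              format(x$intercept, digits = digits)))
  cat(sprintf("  R^2 = %s over %g-%g mg/kg\n",
              format(x$r2, digits = digits), x$range_low, x$range_high))
  invisible(x)
}

#' Matrix effect from calibration slopes
#'
#' ME = (matrix-matched slope / solvent slope - 1) x 100%. Positive values
#' indicate signal enhancement by the matrix, negative values suppression.
#' |ME| below 20% is classed weak, between 20% and 50% moderate, above 50%
#' strong; the boundary values 20 and 50 are assigned to the milder class.
#'
#' @param slope_matrix Slope of the matrix-matched calibration curve.
#' @param slope_solvent Slope of the solvent calibration curve (nonzero).
#' @return List with `matrix_effect_pct`, `me_class` (`"weak"`,
#'   `"moderate"`, `"strong"`) and `direction` (`"enhancement"`,
#'   `"suppression"` or `"none"`).
#' @examples
#' matrix_effect(2, 5)   # -60%: strong suppression
#' @export
matrix_effect <- function(slope_matrix, slope_solvent) {
  stopifnot(is.numeric(slope_matrix), is.numeric(slope_solvent))
  if (!is.finite(slope_solvent) || slope_solvent == 0)
    stop("solvent calibration slope must be nonzero", call. = FALSE)
  me <- (slope_matrix / slope_solvent - 1) * 100
  a <- abs(me)
  cls <- if (a <= 20) "weak" else if (a <= 50) "moderate" else "strong"
  dir <- if (me > 0) "enhancement" else if (me < 0) "suppression" else "none"
  list(matrix_effect_pct = me, me_class = cls, direction = dir)
}

#' Spiked recovery
#'
#' Mean measured concentration of spiked replicates relative to the spiked
#' level, as a percentage. Recoveries are averaged over replicates, not
#' computed per replicate.
#'
#' @param measured Numeric vector of measured concentrations, mg/kg.
#' @param spiked_level Spiked concentration, mg/kg, > 0.
#' @return Recovery in percent.
#' @examples
#' recovery_pct(c(0.015, 0.016), 0.02)
#' @export
recovery_pct <- function(measured, spiked_level) {
  if (!length(measured)) stop("no measured replicates", call. = FALSE)
  stopifnot(is.numeric(measured), is.numeric(spiked_level),
            length(spiked_level) == 1L)
  if (!is.finite(spiked_level) || spiked_level <= 0)
    stop("spiked_level must be > 0", call. = FALSE)
  mean(measured) / spiked_level * 100
}

#' Relative standard deviation
#'
#' Sample standard deviation (n - 1 denominator) over the mean, percent.
#'
#' @param values Numeric vector, length >= 2, nonzero mean.
#' @return RSD in percent.
#' @examples
#' rsd_pct(c(1, 2, 3))  # 50
#' @export
rsd_pct <- function(values) {
  stopifnot(is.numeric(values))
  if (length(values) < 2L) stop("RSD needs at least 2 values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("RSD undefined: mean is zero", call. = FALSE)
  stats::sd(values) / m * 100
}

#' Apply detection and quantitation limits to a raw value
#'
#' Classifies raw concentrations against the limit of detection (LOD,
#' signal-to-noise 3) and limit of quantitation (LOQ, signal-to-noise 10):
#' below the LOD the value is a non-detect (censored); at or above the LOD
#' but below the LOQ it counts as detected but not quantifiable (the value
#' is retained and annotated); at or above the LOQ it is quantified. The
#' LOD boundary is inclusive on the detected side.
#'
#' @param raw Numeric vector of raw concentrations, mg/kg.
#' @param lod,loq Detection and quantitation limits, mg/kg, `lod <= loq`.
#'   Scalars or vectors matching `raw`.
#' @return Data frame with columns `concentration_mg_per_kg` (`NA` when
#'   censored), `censored` and `status`
#'   (`"nd"`, `"detected_below_loq"`, `"quantified"`).
#' @examples
#' apply_censoring(c(0, 0.002, 0.5), lod = 0.001, loq = 0.003)
#' @export
apply_censoring <- function(raw, lod, loq) {
  stopifnot(is.numeric(raw), is.numeric(lod), is.numeric(loq))
  n <- length(raw)
  lod <- rep_len(lod, n); loq <- rep_len(loq, n)
  if (any(lod > loq)) stop("lod must be <= loq", call. = FALSE)
  status <- ifelse(raw < lod, "nd",
                   ifelse(raw < loq, "detected_below_loq", "quantified"))
  data.frame(concentration_mg_per_kg = ifelse(status == "nd", NA_real_, raw),
             censored = status == "nd",
             status = status,
             lod = lod, loq = loq,
             stringsAsFactors = FALSE)
}

#' Assemble a method-validation report table
#'
#' Combines per-analyte calibration fits, detection limits and per-level
#' recovery/RSD results into one delimited-text-ready table (one row per
#' analyte and spike level) mirroring the usual validation table layout:
#' linear equation, range, R^2, LOD, LOQ, recovery, RSD.
#'
#' @param calibrations Named list of `"calibration"` objects (names =
#'   analyte ids).
#' @param limits Data frame with `analyte_id`, `lod`, `loq` (mg/kg).
#' @param spikes Data frame with `analyte_id`, `spiked_level` (mg/kg) and
#'   list-able replicate columns, or precomputed `recovery_pct`, `rsd_pct`.
#' @param path Optional path; when given the table is written as CSV.
#' @return The report data frame, invisibly when written.
#' @export
qc_report <- function(calibrations, limits, spikes, path = NULL) {
  stopifnot(is.list(calibrations), is.data.frame(limits),
            is.data.frame(spikes))
  eqn <- vapply(calibrations, function(cal)
    sprintf("y = %.1f x + %.1f", cal$slope, cal$intercept), character(1))
  rng <- vapply(calibrations, function(cal)
    sprintf("%g-%g", cal$range_low, cal$range_high), character(1))
  r2 <- vapply(calibrations, function(cal) cal$r2, numeric(1))
  cal_df <- data.frame(analyte_id = names(calibrations),
                       linear_equation = eqn, range_mg_per_kg = rng,
                       r2 = r2, stringsAsFactors = FALSE)
  out <- merge(merge(cal_df, limits, by = "analyte_id"), spikes,
               by = "analyte_id")
  out <- out[order(out$analyte_id, out$spiked_level), ]
  rownames(out) <- NULL
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  out
}
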