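# Marker-protein quantification: calibration-curve fitting, band
# quantification, recovery bookkeeping, and the volume-weighted
# cross-contamination estimator for fraction-purity assessment.

#' Geometry of the outer and inner segment compartments
#'
#' The inner segment of a carp cone has roughly 6 times the volume of its
#' outer segment; contamination estimates weight inner-segment membranes by
#' this ratio to convert percent-of-compartment recoveries into protein-mass
#' ratios (assuming equal membrane and protein density per volume across
#' compartments).
#'
#' @param is_os_volume_ratio inner:outer segment volume ratio, > 0.
#' @return a `geometry_config` object.
#' @export
geometry_config <- function(is_os_volume_ratio = 6) {
  if (is_os_volume_ratio <= 0) stop("is_os_volume_ratio must be positive")
  structure(list(is_os_volume_ratio = is_os_volume_ratio),
            class = "geometry_config")
}

#' Fit a linear calibration curve
#'
#' Ordinary least squares of signal on standard amount; the intercept is
#' unconstrained by default (densitometry baselines are rarely exactly zero)
#' but can be forced through the origin.
#'
#' @param standard_amounts known standard amounts (pmol or ng).
#' @param signals measured signals (fluorescence / immunoblot units).
#' @param force_origin if `TRUE`, fit without an intercept.
#' @return a `calibration` object: list with `slope`, `intercept`,
#'   `r_squared`, and the input series.
#' @export
fit_calibration <- function(standard_amounts, signals, force_origin = FALSE) {
  if (length(standard_amounts) != length(signals)) {
    stop("standard_amounts and signals must have equal length")
  }
  if (length(unique(standard_amounts)) < 2) {
    stop("need at least 2 distinct standard amounts to fit a calibration")
  }
  fit <- if (force_origin) lm(signals ~ standard_amounts + 0)
         else lm(signals ~ standard_amounts)
  slope <- unname(coef(fit)[["standard_amounts"]])
  intercept <- if (force_origin) 0 else unname(coef(fit)[["(Intercept)"]])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((signals - mean(signals))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  if (slope <= 0) {
    cf_log("WARN", "calibration slope is non-positive; ",
           "quantification with this curve is unreliable")
  }
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 standard_amounts = standard_amounts, signals = signals,
                 force_origin = force_origin),
            class = "calibration")
}

#' Quantify a band from its signal
#'
#' Inverts the calibration line and divides by the loading-volume multiplier
#' (e.g. 4 when a 4x volume lane was loaded to lift a faint band above the
#' detection limit). Signals below the fitted intercept clamp to 0 with a
#' warning — the band is below detection, not negative.
#'
#' @param signal measured band signal.
#' @param calibration a fitted [fit_calibration()] object.
#' @param volume_multiplier loading-volume multiple, > 0.
#' @return amount in the calibration's standard units (per 1x volume).
#' @export
quantify_band <- function(signal, calibration, volume_multiplier = 1) {
  stopifnot(inherits(calibration, "calibration"))
  if (volume_multiplier <= 0) stop("volume_multiplier must be positive")
  amount <- (signal - calibration$intercept) / calibration$slope
  if (any(amount < 0)) {
    cf_log("WARN", "signal below calibration intercept: ",
           "amount clamped to 0 (below detection)")
    amount <- pmax(amount, 0)
  }
  amount / volume_multiplier
}

#' Recovery of a marker in a fraction
#'
#' The content of a protein in a separated fraction as a percentage of its
#' content in the initial membranes from the same number of cells.
#'
#' @param amount_fraction amount measured in the fraction.
#' @param amount_initial amount in the initial membranes, > 0.
#' @return percent (vectorized over `amount_fraction`).
#' @export
recovery_percent <- function(amount_fraction, amount_initial) {
  if (amount_initial <= 0) stop("amount_initial must be positive")
  100 * amount_fraction / amount_initial
}

#' Volume-weighted cross-contamination ratio
#'
#' Estimates the ratio of contaminant protein mass to target protein mass in
#' a membrane fraction from marker recoveries, under the assumption that
#' membrane and protein density per volume are equal across compartments.
#' Recoveries are percent-of-compartment figures, so the inner-segment terms
#' are weighted by the inner:outer segment volume ratio. For an OS-rich
#' fraction (target = outer segment, contaminant = inner segment):
#' `ratio = (contaminant_recovery * V_IS/V_OS) / target_recovery`; for an
#' IS-rich fraction the volume weight moves to the denominator.
#'
#' @param target_marker_recovery recovery fraction in `[0, 1]` of the target
#'   compartment's marker in the fraction, > 0.
#' @param contaminant_marker_recovery recovery fraction in `[0, 1]` of the
#'   contaminating compartment's marker in the same fraction.
#' @param geometry a [geometry_config()].
#' @param fraction_type `"OS_rich"` when the target compartment is the outer
#'   segment, `"IS_rich"` when it is the inner segment.
#' @return dimensionless contaminant:target protein-mass ratio.
#' @examples
#' # cone OS-rich fraction: 54.5% pigment recovery vs 6.9% mitochondrial marker
#' cross_contamination_ratio(0.545, 0.069, geometry_config(6), "OS_rich")
#' @export
cross_contamination_ratio <- function(target_marker_recovery,
                                      contaminant_marker_recovery,
                                      geometry = geometry_config(),
                                      fraction_type = c("OS_rich", "IS_rich")) {
  fraction_type <- match.arg(fraction_type)
  if (any(target_marker_recovery <= 0)) {
    stop("target marker recovery must be positive")
  }
  if (any(contaminant_marker_recovery < 0)) {
    stop("contaminant marker recovery must be non-negative")
  }
  v <- geometry$is_os_volume_ratio
  if (fraction_type == "OS_rich") {
    (contaminant_marker_recovery * v) / target_marker_recovery
  } else {
    contaminant_marker_recovery / (target_marker_recovery * v)
  }
}
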