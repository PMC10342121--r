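# Mixture-series calibration of the resonance bias and its inversion.

estimate_raw_fraction <- function(spectrum, estimator, basis = NULL,
                                  nu1_constraints = list(), references = NULL,
                                  multi_start = TRUE) {
  if (estimator == "nu1") {
    fit <- fit_nu1_gaussians(spectrum, constraints = nu1_constraints,
                             multi_start = multi_start)
    list(raw = fit$raw_fraction_zea, area = fit$area_lut + fit$area_zea)
  } else {
    refs <- references %||% basis_references(basis, spectrum$laser_nm)
    fit <- cls_fit(spectrum, refs)
    list(raw = fit$raw_fraction_zea,
         area = sum(fit$coefficients[c("lut", "zea")]))
  }
}

#' Build a validation (calibration) curve from a mixture series
#'
#' Estimates the zeaxanthin fraction of every spectrum in a mixture
#' dilution series, aggregates per true-fraction level (mean +/- SD over
#' replicates, as validation dependencies are reported), and fits an
#' ordinary least-squares line through the level means. Deviation of the
#' line from identity quantifies the resonance bias of the chosen
#' estimator/laser combination. The per-level mean nu1 signal per unit
#' concentration is also recorded as the response curve used to convert
#' band areas into concentrations when mapping.
#'
#' @param series Output of [synth_mixture_series()] (or a measured
#'   equivalent with the same structure).
#' @param estimator `"nu1"` or `"cls"`.
#' @param basis `pigment_basis` used for CLS references (and optional
#'   cross-section bookkeeping).
#' @param nu1_constraints Constraints passed to [fit_nu1_gaussians()].
#' @param multi_start Passed to [fit_nu1_gaussians()].
#' @return A `calibration_curve`: `levels` (true fractions),
#'   `mean_estimated`, `sd_estimated`, `n_reps`, `response` (mean signal
#'   area per unit concentration per level), `slope`, `intercept`,
#'   `r_squared` (on the level means), `estimator`, `laser_nm`.
#' @export
build_calibration <- function(series, estimator = c("nu1", "cls"),
                              basis = NULL, nu1_constraints = list(),
                              multi_start = TRUE) {
  estimator <- match.arg(estimator)
  truth <- series$truth
  if (length(unique(truth$f_zea)) < 2) stop_domain("need >= 2 fraction levels")
  references <- if (estimator == "cls") {
    basis_references(basis %||% make_default_basis(), series$laser_nm)
  } else NULL
  est <- rep(NA_real_, length(series$spectra))
  area <- rep(NA_real_, length(series$spectra))
  for (i in seq_along(series$spectra)) {
    r <- tryCatch(
      estimate_raw_fraction(series$spectra[[i]], estimator, basis,
                            nu1_constraints, references, multi_start),
      error = function(e) NULL)
    if (!is.null(r)) { est[i] <- r$raw; area[i] <- r$area }
  }
  levels <- sort(unique(truth$f_zea))
  agg <- lapply(levels, function(f) {
    idx <- which(truth$f_zea == f & !is.na(est))
    if (length(idx) == 0) {
      stop_data("calibration failed: no successful fits at level f_zea = ", f)
    }
    c(mean = mean(est[idx]), sd = stats::sd(est[idx]), n = length(idx),
      response = mean(area[idx] / truth$total_concentration[idx]))
  })
  agg <- do.call(rbind, agg)
  line <- stats::lm(agg[, "mean"] ~ levels)
  ss_tot <- sum((agg[, "mean"] - mean(agg[, "mean"]))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(line)^2) / ss_tot else 1
  structure(list(levels = levels,
                 mean_estimated = unname(agg[, "mean"]),
                 sd_estimated = unname(agg[, "sd"]),
                 n_reps = unname(agg[, "n"]),
                 response = unname(agg[, "response"]),
                 slope = unname(stats::coef(line)[2]),
                 intercept = unname(stats::coef(line)[1]),
                 r_squared = r2,
                 estimator = estimator, laser_nm = series$laser_nm),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(paste0("<calibration_curve> %s estimator, %g nm, %d levels\n",
                     "  mean-estimated = %.3f + %.3f * true, R^2 = %.4f\n"),
              x$estimator, x$laser_nm, length(x$levels),
              x$intercept, x$slope, x$r_squared))
  invisible(x)
}

#' Invert a calibration curve
#'
#' Maps a raw (biased) fraction estimate back to the true-fraction scale
#' by monotone piecewise-linear interpolation of the empirical
#' (mean estimated -> true) relation - the empirical mean curve is used
#' rather than the fitted line so any curvature of the validation
#' dependency is preserved. Output is clamped to \[0, 1\] and the
#' endpoints map to the endpoints.
#'
#' @param raw_fraction Raw fraction estimate(s) in \[0, 1\].
#' @param curve A `calibration_curve`.
#' @param laser_nm Optional laser check; applying a curve to data from a
#'   different laser line is an error.
#' @return Corrected fraction(s) in \[0, 1\].
#' @export
invert_calibration <- function(raw_fraction, curve, laser_nm = NULL) {
  if (!is.null(laser_nm) && laser_nm != curve$laser_nm) {
    stop_data("calibration curve is for ", curve$laser_nm,
              " nm, data are ", laser_nm, " nm")
  }
  if (any(raw_fraction < 0 | raw_fraction > 1, na.rm = TRUE)) {
    stop_domain("raw_fraction must lie in [0, 1]")
  }
  xs <- curve$mean_estimated
  ys <- curve$levels
  if (any(diff(xs) <= 0)) {
    stop_data("non-monotone mean-estimated curve; pool replicates or ",
              "re-estimate with more levels before inverting")
  }
  # anchor the interpolant at the exact endpoints of the fraction scale
  if (xs[1] > 0) { xs <- c(0, xs); ys <- c(0, ys) }
  if (xs[length(xs)] < 1) { xs <- c(xs, 1); ys <- c(ys, 1) }
  out <- stats::approx(xs, ys, xout = raw_fraction, rule = 2)$y
  pmin(pmax(out, 0), 1)
}

# Interpolated signal response (area per unit concentration) at a given
# corrected fraction; used to turn band areas into concentrations.
calibration_response <- function(curve, fraction) {
  stats::approx(curve$levels, curve$response, xout = fraction, rule = 2)$y
}
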