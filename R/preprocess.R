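# Spectral preprocessing: cosmic-ray removal, baseline correction,
# cropping. Single-spectrum operations; map-level preprocessing iterates
# pixel-wise with shared settings.

#' Remove cosmic-ray spikes from a spectrum
#'
#' Detects single-bin spikes with a modified z-score of the centered
#' second difference `D_i = y_i - (y_{i-1} + y_{i+1}) / 2` (z = 0.6745
#' (D - median D) / MAD D). Detection is greedy and iterative: the bin
#' with the largest z above `z_threshold` is replaced by the local median
#' of its unflagged neighbors and the statistic is recomputed, so pairs
#' of adjacent spikes are caught one after the other. A bin is only
#' flagged when its excess also exceeds the local median level, which
#' keeps smooth noiseless bands untouched (cosmic rays are multiples of
#' the local signal, band curvature is not). Unflagged bins pass through
#' bit-exactly; flagged bin indices are recorded in the metadata.
#'
#' @param spectrum A `raman_spectrum`.
#' @param z_threshold Modified z-score threshold (> 0, default 8).
#' @param window Odd window (bins) for the local replacement median,
#'   default 5.
#' @param max_pass Safety cap on greedy iterations.
#' @return The despiked `raman_spectrum`; `metadata$cosmic_ray_bins`
#'   lists the replaced bins.
#' @export
remove_cosmic_rays <- function(spectrum, z_threshold = 8, window = 5,
                               max_pass = 50) {
  if (z_threshold <= 0) stop_domain("z_threshold must be > 0")
  if (window %% 2 != 1 || window < 3) stop_domain("window must be odd and >= 3")
  y <- spectrum$intensity
  n <- length(y)
  if (n < window) stop_domain("spectrum shorter than the despiking window")
  half <- (window - 1L) / 2L
  flagged <- integer(0)
  second_diff_z <- function(y) {
    d <- y - (c(y[1], y[-n]) + c(y[-1], y[n])) / 2
    med <- stats::median(d)
    mad <- stats::median(abs(d - med))
    scale <- max(mad / 0.6745, 1e-12 * max(abs(y), 1))
    list(d = d, z = (d - med) / scale)
  }
  local_median <- function(y, i, exclude) {
    idx <- setdiff(max(1L, i - half):min(n, i + half), exclude)
    if (length(idx) == 0) idx <- setdiff(seq_len(n), exclude)
    stats::median(y[idx])
  }
  for (pass in seq_len(max_pass)) {
    st <- second_diff_z(y)
    cand <- which(abs(st$z) > z_threshold)
    if (length(cand) == 0) break
    # spike-magnitude guard: excess over the local level must itself
    # exceed that level (true cosmic rays are many-fold the signal)
    ok <- vapply(cand, function(i) {
      lm <- local_median(y, i, exclude = i)
      abs(y[i] - lm) > abs(lm)
    }, logical(1))
    cand <- cand[ok]
    if (length(cand) == 0) break
    worst <- cand[which.max(abs(st$z[cand]))]
    y[worst] <- local_median(y, worst, exclude = c(flagged, worst))
    flagged <- sort(union(flagged, worst))
  }
  out <- spectrum
  out$intensity <- y
  out$metadata$cosmic_ray_bins <- flagged
  out
}

# Asymmetric penalized least-squares baseline (Eilers-style): minimize
# sum w_i (y_i - z_i)^2 + lambda ||D2 z||^2 with asymmetric weights,
# then re-smooth through the identified baseline-only points so strong
# bands exert no residual pull. The pentadiagonal solve is compiled.
als_baseline <- function(y, lambda, p, max_iter, tol = 1e-8) {
  w <- rep(1, length(y))
  z <- y
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    z_new <- .als_solve_banded(w, y, lambda)
    w <- ifelse(y > z_new, p, 1 - p)
    if (max(abs(z_new - z)) < tol * max(1, max(abs(y)))) {
      z <- z_new
      converged <- TRUE
      break
    }
    z <- z_new
  }
  # masked re-smoothing: repeatedly refit through baseline-only points
  # (residual below 3x the noise scale) until the point set stabilizes,
  # so strong bands and their tails exert no residual pull
  prev_mask <- NULL
  for (k in seq_len(10)) {
    noise <- stats::mad(diff(y - z)) / sqrt(2)
    thr <- 3 * max(noise, 1e-12 * max(abs(y), 1))
    mask <- (y - z) <= thr
    if (sum(mask) < 10 || identical(mask, prev_mask)) break
    z <- .als_solve_banded(as.numeric(mask), y, lambda)
    prev_mask <- mask
  }
  list(baseline = z, iterations = it, converged = converged)
}

#' Subtract the spectral baseline
#'
#' Estimates and removes a smooth baseline. The default estimator is
#' asymmetric penalized least squares (smoothness penalty on the second
#' difference, asymmetric weights pressing the baseline under the
#' bands); a robust polynomial fit is available as an alternative.
#'
#' @param spectrum A `raman_spectrum`.
#' @param method `"asymmetric_penalized"` (default) or `"polynomial"`.
#' @param params Method parameters: for `asymmetric_penalized`,
#'   `lambda` (smoothness, > 0, default 1e5), `p` (asymmetry, default
#'   0.01), `max_iter` (default 30); for `polynomial`, `degree`
#'   (<= 5, default 3) and `max_iter` of iterative reweighting.
#' @return Baseline-subtracted `raman_spectrum`; the estimated baseline
#'   is stored in `metadata$baseline`.
#' @export
correct_baseline <- function(spectrum,
                             method = c("asymmetric_penalized", "polynomial"),
                             params = list()) {
  method <- match.arg(method)
  y <- spectrum$intensity
  x <- spectrum$wavenumber
  if (method == "asymmetric_penalized") {
    lambda <- params$lambda %||% 1e5
    p <- params$p %||% 0.01
    max_iter <- params$max_iter %||% 30
    if (lambda <= 0) stop_config("field 'lambda' must be > 0")
    if (p <= 0 || p >= 1) stop_config("field 'p' must be in (0, 1)")
    fit <- als_baseline(y, lambda, p, max_iter)
    if (!fit$converged && isTRUE(params$strict)) {
      stop_numeric("baseline estimator did not converge",
                   diagnostics = list(iterations = fit$iterations))
    }
    baseline <- fit$baseline
  } else {
    degree <- params$degree %||% 3
    if (degree > 5) stop_config("field 'degree' must be <= 5")
    max_iter <- params$max_iter %||% 20
    xs <- (x - mean(x)) / stats::sd(x)
    X <- cbind(1, stats::poly(xs, degree, raw = TRUE))
    w <- rep(1, length(y))
    baseline <- y
    for (it in seq_len(max_iter)) {
      fit <- stats::lm.wfit(X, y, w)
      baseline_new <- y - fit$residuals
      # next pass fits only points at or below the current trend (plus
      # a noise margin), excluding band regions entirely
      r <- y - baseline_new
      margin <- 3 * max(stats::mad(diff(r)) / sqrt(2),
                        1e-12 * max(abs(y), 1))
      w_new <- as.numeric(r <= margin)
      if (sum(w_new) <= degree + 1) w_new <- as.numeric(r <= 2 * margin)
      if (max(abs(baseline_new - baseline)) < 1e-9 * max(1, max(abs(y)))) {
        baseline <- baseline_new
        break
      }
      baseline <- baseline_new
      w <- w_new
    }
  }
  out <- spectrum
  out$intensity <- y - baseline
  out$metadata$baseline <- baseline
  out$metadata$baseline_method <- method
  out
}

#' Crop a spectrum to a wavenumber interval
#'
#' @param spectrum A `raman_spectrum`.
#' @param lo_cm1,hi_cm1 Interval bounds (inclusive); defaults 800/1800,
#'   the analysis region.
#' @return Cropped `raman_spectrum`.
#' @export
crop_region <- function(spectrum, lo_cm1 = 800, hi_cm1 = 1800) {
  if (lo_cm1 >= hi_cm1) stop_domain("crop bounds must satisfy lo < hi")
  keep <- spectrum$wavenumber >= lo_cm1 & spectrum$wavenumber <= hi_cm1
  if (!any(keep)) stop_domain("crop interval does not overlap the axis")
  out <- spectrum
  out$wavenumber <- spectrum$wavenumber[keep]
  out$intensity <- spectrum$intensity[keep]
  out
}

#' Preprocess one spectrum
#'
#' Standard chain: cosmic-ray removal, baseline subtraction, crop.
#'
#' @param spectrum A `raman_spectrum`.
#' @param config List with optional sections `z_threshold`, `window`,
#'   `baseline` (list: `method`, params) and `crop` (length-2 numeric).
#' @return Preprocessed `raman_spectrum`.
#' @export
preprocess_spectrum <- function(spectrum, config = list()) {
  sp <- remove_cosmic_rays(spectrum,
                           z_threshold = config$z_threshold %||% 8,
                           window = config$window %||% 5)
  bl <- config$baseline %||% list()
  sp <- correct_baseline(sp, method = bl$method %||% "asymmetric_penalized",
                         params = bl)
  crop <- config$crop %||% c(800, 1800)
  crop_region(sp, crop[1], crop[2])
}

#' Preprocess every pixel of a spectral map
#'
#' Applies [preprocess_spectrum()] pixel-wise with shared configuration.
#'
#' @param map A `spectral_map`.
#' @param config As in [preprocess_spectrum()].
#' @return The preprocessed `spectral_map`.
#' @export
preprocess_map <- function(map, config = list()) {
  crop <- config$crop %||% c(800, 1800)
  keep <- map$wavenumber >= crop[1] & map$wavenumber <= crop[2]
  if (!any(keep)) stop_domain("crop interval does not overlap the axis")
  out <- map
  out$wavenumber <- map$wavenumber[keep]
  out$intensity <- matrix(0, nrow = nrow(map$intensity), ncol = sum(keep))
  for (i in seq_len(nrow(map$intensity))) {
    sp <- raman_spectrum(map$wavenumber, map$intensity[i, ], map$laser_nm)
    sp <- preprocess_spectrum(sp, config)
    out$intensity[i, ] <- sp$intensity
  }
  out$metadata$preprocessed <- TRUE
  out
}
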