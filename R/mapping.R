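# Retina mapping: per-pixel unmixing into pigment images, radial
# profiles, region segmentation, cross-sections and Z-scan profiles.

#' Per-pixel pigment estimation over a spectral map
#'
#' Runs the chosen unmixing estimator on every pixel of a (preprocessed)
#' spectral map and assembles the pigment images: total nu1 signal,
#' zeaxanthin fraction (raw and calibration-corrected), lutein and
#' zeaxanthin concentrations, and the observed nu1 band FWHM. When a
#' calibration curve is supplied, raw fractions are inverted through the
#' empirical bias curve and band areas are divided by the calibrated
#' signal response at the corrected fraction, putting concentrations on
#' the calibration's concentration scale. Pixels whose fit fails are
#' masked, not interpolated.
#'
#' @param map A preprocessed `spectral_map`.
#' @param estimator `"nu1"` (default) or `"cls"`.
#' @param calibration Optional `calibration_curve` (laser must match).
#' @param basis `pigment_basis` for CLS references.
#' @param nu1_constraints Constraints for [fit_nu1_gaussians()].
#' @param multi_start Start-grid policy for the nu1 fit; default `FALSE`
#'   (single moment-based start) for speed on large maps.
#' @param max_failure_fraction Error if more than this fraction of
#'   pixels fails (default 0.2).
#' @return A `pigment_map`: list with `images` (named list of `nx x ny`
#'   matrices: `lut`, `zea`, `total`, `fwhm`, `fraction_zea`,
#'   `raw_fraction_zea`), `mask` (TRUE = valid), geometry fields and
#'   provenance.
#' @export
map_pixelwise <- function(map, estimator = c("nu1", "cls"), calibration = NULL,
                          basis = NULL, nu1_constraints = list(),
                          multi_start = FALSE, max_failure_fraction = 0.2) {
  estimator <- match.arg(estimator)
  if (!is.null(calibration) && calibration$laser_nm != map$laser_nm) {
    stop_data("calibration curve laser (", calibration$laser_nm,
              " nm) does not match map laser (", map$laser_nm, " nm)")
  }
  references <- if (estimator == "cls") {
    basis_references(basis %||% make_default_basis(), map$laser_nm)
  } else NULL
  npx <- nrow(map$intensity)
  raw <- total_area <- fwhm <- rep(NA_real_, npx)
  for (i in seq_len(npx)) {
    sp <- raman_spectrum(map$wavenumber, map$intensity[i, ], map$laser_nm)
    res <- tryCatch({
      if (estimator == "nu1") {
        fit <- fit_nu1_gaussians(sp, constraints = nu1_constraints,
                                 multi_start = multi_start)
        list(raw = fit$raw_fraction_zea,
             area = fit$area_lut + fit$area_zea,
             fwhm = fit$observed_band_fwhm)
      } else {
        fit <- cls_fit(sp, references)
        list(raw = fit$raw_fraction_zea,
             area = sum(fit$coefficients[c("lut", "zea")]),
             fwhm = tryCatch(measure_nu1_fwhm(sp), error = function(e) NA_real_))
      }
    }, error = function(e) NULL)
    if (!is.null(res)) {
      raw[i] <- res$raw; total_area[i] <- res$area; fwhm[i] <- res$fwhm
    }
  }
  mask <- !is.na(raw)
  fail_frac <- 1 - mean(mask)
  if (fail_frac > max_failure_fraction) {
    stop_data(sprintf("map quality: %.1f%% of pixels failed to fit",
                      100 * fail_frac))
  }
  if (!is.null(calibration)) {
    corrected <- rep(NA_real_, npx)
    corrected[mask] <- invert_calibration(pmin(pmax(raw[mask], 0), 1), calibration)
    conc_total <- total_area / calibration_response(calibration, corrected)
  } else {
    corrected <- raw
    conc_total <- total_area
  }
  as_img <- function(v) matrix(v, nrow = map$nx, ncol = map$ny)
  images <- list(lut = as_img(conc_total * (1 - corrected)),
                 zea = as_img(conc_total * corrected),
                 total = as_img(conc_total),
                 fwhm = as_img(fwhm),
                 fraction_zea = as_img(corrected),
                 raw_fraction_zea = as_img(raw))
  structure(list(images = images, mask = as_img(mask),
                 nx = map$nx, ny = map$ny,
                 x_um = map$x_um, y_um = map$y_um,
                 pixel_size_um = map$pixel_size_um, plane = map$plane,
                 laser_nm = map$laser_nm, estimator = estimator,
                 calibrated = !is.null(calibration)),
            class = "pigment_map")
}

#' @export
print.pigment_map <- function(x, ...) {
  cat(sprintf("<pigment_map> %d x %d px, %s estimator%s, %.1f%% valid\n",
              x$nx, x$ny, x$estimator,
              if (x$calibrated) " (calibrated)" else "",
              100 * mean(x$mask)))
  invisible(x)
}

#' Locate the macula center on a pigment map
#'
#' Intensity-weighted centroid of the pixels above the 95th percentile
#' of the total image.
#'
#' @param pigment_map A `pigment_map`.
#' @param quantile Threshold quantile (default 0.95).
#' @return Length-2 numeric `(x, y)` in um.
#' @export
find_center <- function(pigment_map, quantile = 0.95) {
  tot <- as.numeric(pigment_map$images$total)
  ok <- as.numeric(pigment_map$mask) > 0 & !is.na(tot)
  if (!any(ok) || diff(range(tot[ok])) == 0) {
    stop_data("total image is constant; center undefined")
  }
  thr <- stats::quantile(tot[ok], quantile, names = FALSE)
  sel <- ok & tot >= thr
  w <- tot[sel]
  c(x = sum(pigment_map$x_um[sel] * w) / sum(w),
    y = sum(pigment_map$y_um[sel] * w) / sum(w))
}

#' Radial profile of the pigment images
#'
#' Bins pixels into annuli around a center and reports the pixel-count
#' weighted mean, SD and n per annulus for every image in the map.
#'
#' @param pigment_map A `pigment_map`.
#' @param center Length-2 `(x, y)` in um, e.g. from [find_center()].
#' @param bin_width_um Annulus width (um, > 0; default = pixel pitch).
#' @return A data frame with `r_um` (bin centers), `n`, and
#'   `mean_<image>` / `sd_<image>` columns, plus a `ratio` column
#'   (mean zea / mean lut per annulus). Class `radial_profile`.
#' @export
radial_profile <- function(pigment_map, center = NULL, bin_width_um = NULL) {
  center <- center %||% find_center(pigment_map)
  bin_width_um <- bin_width_um %||% pigment_map$pixel_size_um[1]
  if (bin_width_um <= 0) stop_domain("bin_width_um must be > 0")
  if (center[1] < min(pigment_map$x_um) - bin_width_um ||
      center[1] > max(pigment_map$x_um) + bin_width_um ||
      center[2] < min(pigment_map$y_um) - bin_width_um ||
      center[2] > max(pigment_map$y_um) + bin_width_um) {
    stop_domain("center lies outside the map")
  }
  r <- sqrt((pigment_map$x_um - center[1])^2 + (pigment_map$y_um - center[2])^2)
  nbin <- ceiling(max(r) / bin_width_um)
  bin <- pmin(floor(r / bin_width_um) + 1L, nbin)
  ok <- as.numeric(pigment_map$mask) > 0
  out <- data.frame(r_um = (seq_len(nbin) - 0.5) * bin_width_um,
                    n = as.integer(tabulate(bin[ok], nbin)))
  for (nm in names(pigment_map$images)) {
    v <- as.numeric(pigment_map$images[[nm]])
    means <- sds <- rep(NA_real_, nbin)
    use <- ok & !is.na(v)
    if (any(use)) {
      means[sort(unique(bin[use]))] <-
        vapply(split(v[use], bin[use]), mean, numeric(1))
      sds[sort(unique(bin[use]))] <-
        vapply(split(v[use], bin[use]), stats::sd, numeric(1))
    }
    out[[paste0("mean_", nm)]] <- means
    out[[paste0("sd_", nm)]] <- sds
  }
  out$ratio <- out$mean_zea / out$mean_lut
  attr(out, "center_um") <- center
  attr(out, "bin_width_um") <- bin_width_um
  class(out) <- c("radial_profile", "data.frame")
  out
}

# Boundary radii (um) from the radial total profile: minima of the
# second derivative of the Gaussian-smoothed log profile.
data_driven_boundaries <- function(profile, n_boundaries = 3, smooth_sd_bins = 2) {
  g <- profile$mean_total
  ok <- !is.na(g) & profile$n > 0
  r <- profile$r_um[ok]
  g <- log(pmax(g[ok], 1e-12))
  if (diff(range(g)) < 1e-6) stop_data("flat profile: no segmentation boundaries")
  # Gaussian smoothing on the log profile
  half <- ceiling(3 * smooth_sd_bins)
  kern <- stats::dnorm(-half:half, sd = smooth_sd_bins)
  kern <- kern / sum(kern)
  gpad <- c(rep(g[1], half), g, rep(g[length(g)], half))
  gs <- stats::filter(gpad, kern, sides = 2)[(half + 1):(half + length(g))]
  d2 <- c(NA, diff(diff(gs)), NA)
  is_min <- rep(FALSE, length(d2))
  for (i in 2:(length(d2) - 1)) {
    if (!any(is.na(d2[(i - 1):(i + 1)])) && d2[i] < 0 &&
        d2[i] <= d2[i - 1] && d2[i] <= d2[i + 1]) {
      is_min[i] <- TRUE
    }
  }
  cand <- which(is_min)
  if (length(cand) == 0) stop_data("no curvature minima found in the profile")
  cand <- cand[order(d2[cand])][seq_len(min(n_boundaries, length(cand)))]
  # refine each detected drop to its onset: smoothing and
  # discretization push the curvature minimum into the transition, so
  # walk from the steepest-descent point of the drop back to where the
  # slope has decayed to 10% of its peak
  d1 <- c(NA, (gs[-(1:2)] - gs[1:(length(gs) - 2)]) / 2, NA)
  n_pts <- length(gs)
  refine <- vapply(cand, function(i) {
    # steepest point of THIS drop: first local minimum of the slope
    mid <- i
    while (mid < n_pts - 1 && is.finite(d1[mid + 1]) && d1[mid + 1] < d1[mid]) {
      mid <- mid + 1
    }
    slope_peak <- d1[mid]
    if (!is.finite(slope_peak) || slope_peak >= 0) return(r[i])
    j <- mid
    while (j > 2 && is.finite(d1[j - 1]) && d1[j - 1] <= 0.1 * slope_peak) {
      j <- j - 1
    }
    # linear interpolation of the 10%-slope crossing between j-1 and j
    if (j > 1 && is.finite(d1[j - 1]) && d1[j] < 0.1 * slope_peak) {
      frac <- (0.1 * slope_peak - d1[j - 1]) / (d1[j] - d1[j - 1])
      r[j - 1] + frac * (r[j] - r[j - 1])
    } else r[j]
  }, numeric(1))
  sort(refine)
}

#' Segment a pigment map into macular regions
#'
#' Labels pixels as foveola / fovea / parafovea / outside. In `fixed`
#' mode the region boundaries are the standard disk diameters (0.35, 1,
#' 2 mm). In `data_driven` mode boundaries are placed where the total
#' concentration profile changes most sharply: at the largest-magnitude
#' minima of the second derivative of the smoothed log radial profile,
#' sorted by radius.
#'
#' @param pigment_map A `pigment_map`.
#' @param center Length-2 `(x, y)` um; computed when `NULL`.
#' @param mode `"fixed"` or `"data_driven"`.
#' @param fixed_diameters_mm Region disk diameters (mm) for fixed mode.
#' @param profile Optional precomputed [radial_profile()] (data-driven
#'   mode).
#' @param smooth_sd_bins Gaussian smoothing sd (in profile bins) applied
#'   to the log profile before differentiation (default 2; pick it so
#'   the physical window stays well under the transition width).
#' @return A `region_segmentation`: `center_um`, `radii_um` (named
#'   foveola/fovea/parafovea boundary radii), `labels` (`nx x ny` factor
#'   matrix), `mode`.
#' @export
segment_regions <- function(pigment_map, center = NULL,
                            mode = c("fixed", "data_driven"),
                            fixed_diameters_mm = c(0.35, 1, 2),
                            profile = NULL, smooth_sd_bins = 2) {
  mode <- match.arg(mode)
  center <- center %||% find_center(pigment_map)
  if (mode == "fixed") {
    if (any(diff(fixed_diameters_mm) <= 0)) {
      stop_domain("fixed diameters must be strictly increasing")
    }
    radii <- fixed_diameters_mm * 1000 / 2
  } else {
    profile <- profile %||% radial_profile(pigment_map, center)
    radii <- data_driven_boundaries(profile, smooth_sd_bins = smooth_sd_bins)
    while (length(radii) < 3) radii <- c(radii, max(radii) * 1.05 + 1)
  }
  names(radii) <- c("foveola", "fovea", "parafovea")
  r <- sqrt((pigment_map$x_um - center[1])^2 + (pigment_map$y_um - center[2])^2)
  lab <- cut(r, breaks = c(-Inf, radii, Inf),
             labels = c("foveola", "fovea", "parafovea", "outside"))
  structure(list(center_um = center, radii_um = radii,
                 labels = matrix(lab, nrow = pigment_map$nx),
                 mode = mode),
            class = "region_segmentation")
}

#' @export
print.region_segmentation <- function(x, ...) {
  cat(sprintf("<region_segmentation> %s mode, boundaries %.0f / %.0f / %.0f um\n",
              x$mode, x$radii_um[1], x$radii_um[2], x$radii_um[3]))
  invisible(x)
}

#' Regional pigment statistics
#'
#' Per region: Zea:Lut concentration ratio computed as the ratio of the
#' regional mean zeaxanthin to the regional mean lutein image (ratio of
#' means - pixel-wise division would amplify noise at low signal), a
#' descriptive SD of the pixel-wise ratios, pixel count, and mean total
#' concentration. A center-to-periphery contrast (mean total inside the
#' fovea boundary over mean total outside the parafovea boundary) is
#' attached as attribute `central_peripheral_contrast`.
#'
#' @param pigment_map A `pigment_map`.
#' @param segmentation A `region_segmentation` on the same grid.
#' @return Data frame with one row per region (`region`, `n`,
#'   `mean_ratio`, `sd_ratio`, `mean_total`, `mean_fraction`); regions
#'   with no valid pixels are reported with `n = 0` and `NA` statistics.
#' @export
region_ratios <- function(pigment_map, segmentation) {
  if (!all(dim(segmentation$labels) == dim(pigment_map$mask))) {
    stop_data("segmentation grid does not match the pigment map")
  }
  labs <- factor(as.character(segmentation$labels),
                 levels = c("foveola", "fovea", "parafovea", "outside"))
  ok <- as.numeric(pigment_map$mask) > 0
  lut <- as.numeric(pigment_map$images$lut)
  zea <- as.numeric(pigment_map$images$zea)
  tot <- as.numeric(pigment_map$images$total)
  frac <- as.numeric(pigment_map$images$fraction_zea)
  rows <- lapply(levels(labs), function(rg) {
    sel <- ok & labs == rg & !is.na(lut) & !is.na(zea)
    n <- sum(sel)
    if (n == 0) {
      return(data.frame(region = rg, n = 0L, mean_ratio = NA_real_,
                        sd_ratio = NA_real_, mean_total = NA_real_,
                        mean_fraction = NA_real_))
    }
    px_ratio <- zea[sel][lut[sel] > 0] / lut[sel][lut[sel] > 0]
    data.frame(region = rg, n = n,
               mean_ratio = mean(zea[sel]) / mean(lut[sel]),
               sd_ratio = if (length(px_ratio) > 1) stats::sd(px_ratio) else NA_real_,
               mean_total = mean(tot[sel]),
               mean_fraction = mean(frac[sel]))
  })
  out <- do.call(rbind, rows)
  central <- ok & labs %in% c("foveola", "fovea") & !is.na(tot)
  periph <- ok & labs == "outside" & !is.na(tot)
  attr(out, "central_peripheral_contrast") <-
    if (any(central) && any(periph)) mean(tot[central]) / mean(tot[periph]) else NA_real_
  out
}

#' In-plane cross-section through a pigment map
#'
#' Samples every image along the segment from `start_um` to `end_um` at
#' pixel pitch, averaging `width_px` nearest-pixel samples taken
#' perpendicular to the segment.
#'
#' @param pigment_map A `pigment_map`.
#' @param start_um,end_um Segment endpoints `(x, y)` in um, inside the
#'   map.
#' @param width_px Perpendicular averaging width in pixels (odd;
#'   `1` = nearest-pixel sampling).
#' @return Data frame: `distance_um` plus one column per image.
#' @export
line_cross_section <- function(pigment_map, start_um, end_um, width_px = 1) {
  dvec <- c(end_um[1] - start_um[1], end_um[2] - start_um[2])
  len <- sqrt(sum(dvec^2))
  if (len == 0) stop_domain("zero-length cross-section segment")
  inside <- function(p) {
    p[1] >= min(pigment_map$x_um) - pigment_map$pixel_size_um[1] &&
      p[1] <= max(pigment_map$x_um) + pigment_map$pixel_size_um[1] &&
      p[2] >= min(pigment_map$y_um) - pigment_map$pixel_size_um[2] &&
      p[2] <= max(pigment_map$y_um) + pigment_map$pixel_size_um[2]
  }
  if (!inside(start_um) || !inside(end_um)) stop_domain("endpoints outside map")
  pitch <- pigment_map$pixel_size_um[1]
  u <- dvec / len
  v <- c(-u[2], u[1])
  steps <- seq(0, len, by = pitch)
  offs <- (seq_len(width_px) - (width_px + 1) / 2) * pitch
  nearest_px <- function(x, y) {
    ix <- pmin(pmax(round(x / pigment_map$pixel_size_um[1] + 0.5), 1), pigment_map$nx)
    iy <- pmin(pmax(round(y / pigment_map$pixel_size_um[2] + 0.5), 1), pigment_map$ny)
    (iy - 1) * pigment_map$nx + ix
  }
  out <- data.frame(distance_um = steps)
  for (nm in names(pigment_map$images)) {
    img <- as.numeric(pigment_map$images[[nm]])
    ok <- as.numeric(pigment_map$mask) > 0
    img[!ok] <- NA
    out[[nm]] <- vapply(steps, function(s) {
      px <- vapply(offs, function(o) {
        p <- c(start_um[1], start_um[2]) + s * u + o * v
        nearest_px(p[1], p[2])
      }, numeric(1))
      mean(img[px], na.rm = TRUE)
    }, numeric(1))
  }
  out
}

#' Depth profiles from a Z-scan map
#'
#' Unmixes an XZ spectral map pixel-wise and averages the lutein and
#' zeaxanthin concentration over the lateral (X) direction per depth,
#' reporting the layer peak depth and FWHM of each pigment.
#'
#' @param map A preprocessed XZ `spectral_map` (depth in `y_um`).
#' @param ... Passed to [map_pixelwise()] (estimator, calibration, ...).
#' @return List with `profile` (data frame: `z_um`, `lut`, `zea`,
#'   `total`) and `layers` (data frame per pigment: `peak_z_um`,
#'   `fwhm_um`, `amplitude`).
#' @export
zscan_profile <- function(map, ...) {
  if (map$plane != "XZ") stop_data("zscan_profile expects an XZ map")
  pm <- map_pixelwise(map, ...)
  z_levels <- sort(unique(map$y_um))
  per_depth <- function(img) {
    v <- as.numeric(img)
    v[as.numeric(pm$mask) == 0] <- NA
    vapply(z_levels, function(z) mean(v[map$y_um == z], na.rm = TRUE), numeric(1))
  }
  prof <- data.frame(z_um = z_levels,
                     lut = per_depth(pm$images$lut),
                     zea = per_depth(pm$images$zea),
                     total = per_depth(pm$images$total))
  layer_stats <- function(y) {
    ok <- !is.na(y)
    if (sum(ok) < 5) return(c(NA_real_, NA_real_, NA_real_))
    z <- z_levels[ok]; yy <- y[ok]
    c(z[which.max(yy)], half_max_width(z, yy), max(yy))
  }
  layers <- rbind(lut = layer_stats(prof$lut), zea = layer_stats(prof$zea))
  layers <- data.frame(pigment = rownames(layers), peak_z_um = layers[, 1],
                       fwhm_um = layers[, 2], amplitude = layers[, 3],
                       row.names = NULL)
  list(profile = prof, layers = layers)
}
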