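# Synthetic polarized FLIM data: axon cross-sections with oriented
# transmembrane dipoles and biexponential decays.

#' Construct a FLIM dataset
#'
#' Per-pixel photon-arrival histograms in two polarization detection
#' channels on a uniform time axis.
#'
#' @param time_ps Bin-start times (ps), uniform pitch.
#' @param parallel,perpendicular Count arrays `nx * ny` rows (pixels,
#'   x-major) by `nt` columns (time bins).
#' @param nx,ny Image dimensions.
#' @param g_factor Instrumental correction factor G (> 0).
#' @param laser_power Relative excitation power.
#' @param metadata Free-form list.
#' @return A `flim_dataset` object.
#' @export
flim_dataset <- function(time_ps, parallel, perpendicular, nx, ny,
                         g_factor = 1, laser_power = 1, metadata = list()) {
  parallel <- as.matrix(parallel); perpendicular <- as.matrix(perpendicular)
  if (!all(dim(parallel) == dim(perpendicular))) {
    stop_data("channel arrays must have identical dimensions")
  }
  if (nrow(parallel) != nx * ny) stop_data("channel arrays must have nx*ny rows")
  if (ncol(parallel) != length(time_ps)) {
    stop_data("channel arrays must have one column per time bin")
  }
  if (g_factor <= 0) stop_config("field 'g_factor' must be > 0")
  bin_ps <- if (length(time_ps) > 1) diff(time_ps)[1] else 16
  structure(list(time_ps = as.numeric(time_ps), parallel = parallel,
                 perpendicular = perpendicular, nx = as.integer(nx),
                 ny = as.integer(ny), g_factor = g_factor,
                 laser_power = laser_power, bin_ps = bin_ps,
                 metadata = metadata),
            class = "flim_dataset")
}

#' @export
print.flim_dataset <- function(x, ...) {
  cat(sprintf(
    "<flim_dataset> %d x %d px, %d bins @ %g ps, G = %g, power = %g, %d photons\n",
    x$nx, x$ny, length(x$time_ps), x$bin_ps, x$g_factor, x$laser_power,
    sum(x$parallel) + sum(x$perpendicular)))
  invisible(x)
}

# Draw a binned arrival-time histogram for n photons from the
# two-exponential mixture with amplitude fraction f_short. Arrival times
# are sampled from the exponentials truncated to the recorded range so
# every drawn photon lands in a bin (photon conservation).
draw_decay_histogram <- function(n, tau_short, tau_long, f_short, time_ps, bin_ps) {
  nt <- length(time_ps)
  if (n == 0) return(integer(nt))
  t_max <- nt * bin_ps
  # amplitude fraction -> photon-number fraction of the short component
  p_short <- f_short * tau_short / (f_short * tau_short + (1 - f_short) * tau_long)
  n_short <- stats::rbinom(1, n, p_short)
  rexp_trunc <- function(m, tau) {
    -tau * log(1 - stats::runif(m) * (1 - exp(-t_max / tau)))
  }
  t <- c(rexp_trunc(n_short, tau_short), rexp_trunc(n - n_short, tau_long))
  idx <- pmin(floor(t / bin_ps) + 1L, nt)
  tabulate(idx, nbins = nt)
}

#' Simulate polarized FLIM images of an axon cross-section
#'
#' Pixels lie on an annulus (the membrane of an axon seen end-on). At
#' each pixel the xanthophyll transition dipole lies in the image plane
#' along the radial (transmembrane pigment) or tangential direction.
#' With horizontal excitation polarization, photoselection excites each
#' pixel with probability proportional to cos^2(theta) of its dipole
#' angle, and the fixed emission dipole splits detected photons between
#' the parallel (cos^2) and perpendicular (sin^2) channels; the
#' perpendicular channel detection efficiency is 1/G. Photon arrival
#' times follow the biexponential mixture with amplitude fraction
#' `f_short`; counts are Poisson. One dataset is generated per entry of
#' `power_series`, with expected counts proportional to power.
#'
#' @param orientation `"radial"` or `"tangential"` dipole orientation.
#' @param ring_radius_px,ring_width_px Annulus center radius and radial
#'   width in pixels.
#' @param counts_per_pixel Expected photons at unit power for a pixel
#'   with dipole parallel to the excitation polarization.
#' @param tau_short_ps,tau_long_ps Lifetimes (ps, > 0).
#' @param f_short Amplitude fraction of the short component in \[0, 1\].
#' @param power_series Relative excitation powers (non-empty).
#' @param g_factor Instrumental G factor embedded in the data.
#' @param n_bins Number of 16 ps time bins.
#' @param image_px Image side length (pixels); default fits the ring.
#' @param f_short_per_power Optional vector overriding `f_short` per
#'   power entry (to simulate power-dependent photoswitching).
#' @param seed Optional seed.
#' @return List with `datasets` (one `flim_dataset` per power) and
#'   `truth` (list: per-pixel dipole angles `theta`, `f_short` per power,
#'   lifetimes, ring parameters).
#' @export
synth_axon_flim <- function(orientation = c("radial", "tangential"),
                            ring_radius_px = 12, ring_width_px = 4,
                            counts_per_pixel = 2000,
                            tau_short_ps = 70, tau_long_ps = 2500,
                            f_short = 0.6, power_series = c(1, 2, 4),
                            g_factor = 1, n_bins = 512, image_px = NULL,
                            f_short_per_power = NULL, seed = NULL) {
  orientation <- match.arg(orientation)
  if (length(power_series) == 0) stop_domain("power_series must be non-empty")
  if (tau_short_ps <= 0 || tau_long_ps <= 0) stop_domain("lifetimes must be > 0")
  if (f_short < 0 || f_short > 1) stop_domain("f_short must be in [0, 1]")
  if (counts_per_pixel <= 0) stop_domain("counts_per_pixel must be > 0")
  f_power <- f_short_per_power %||% rep(f_short, length(power_series))
  if (length(f_power) != length(power_series)) {
    stop_domain("f_short_per_power must match power_series length")
  }
  n_img <- image_px %||% (2 * ceiling(ring_radius_px + ring_width_px) + 5)
  bin_ps <- 16
  time_ps <- (seq_len(n_bins) - 1) * bin_ps
  cx <- (n_img + 1) / 2
  ix <- rep(seq_len(n_img), times = n_img)
  iy <- rep(seq_len(n_img), each = n_img)
  rr <- sqrt((ix - cx)^2 + (iy - cx)^2)
  on_ring <- abs(rr - ring_radius_px) <= ring_width_px / 2
  phi <- atan2(iy - cx, ix - cx)                  # angle of the radial direction
  theta <- if (orientation == "radial") phi else phi + pi / 2
  # fraction of decay photons landing inside the recorded time range
  p_short <- f_power * tau_short_ps /
    (f_power * tau_short_ps + (1 - f_power) * tau_long_ps)
  t_max <- n_bins * bin_ps
  datasets <- with_seed(seed, {
    lapply(seq_along(power_series), function(k) {
      p <- power_series[k]
      exc <- counts_per_pixel * p * cos(theta)^2 * on_ring
      lam_par <- exc * cos(theta)^2
      lam_perp <- exc * sin(theta)^2 / g_factor
      n_par <- stats::rpois(length(lam_par), lam_par)
      n_perp <- stats::rpois(length(lam_perp), lam_perp)
      par_mat <- matrix(0L, nrow = n_img * n_img, ncol = n_bins)
      perp_mat <- matrix(0L, nrow = n_img * n_img, ncol = n_bins)
      for (i in which(n_par + n_perp > 0)) {
        if (n_par[i] > 0) {
          par_mat[i, ] <- draw_decay_histogram(n_par[i], tau_short_ps,
                                               tau_long_ps, f_power[k],
                                               time_ps, bin_ps)
        }
        if (n_perp[i] > 0) {
          perp_mat[i, ] <- draw_decay_histogram(n_perp[i], tau_short_ps,
                                                tau_long_ps, f_power[k],
                                                time_ps, bin_ps)
        }
      }
      flim_dataset(time_ps, par_mat, perp_mat, n_img, n_img,
                   g_factor = g_factor, laser_power = p,
                   metadata = list(synthetic = TRUE, orientation = orientation,
                                   excitation_nm = 470,
                                   emission_band = "550/88",
                                   drawn_par = n_par, drawn_perp = n_perp))
    })
  })
  truth <- list(orientation = orientation, theta = theta, on_ring = on_ring,
                nx = n_img, ny = n_img, ring_radius_px = ring_radius_px,
                ring_width_px = ring_width_px, tau_short_ps = tau_short_ps,
                tau_long_ps = tau_long_ps, f_short = f_power,
                p_short = p_short, t_max_ps = t_max,
                power_series = power_series, g_factor = g_factor, seed = seed)
  list(datasets = datasets, truth = truth)
}
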