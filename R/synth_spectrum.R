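# Synthetic single spectra and mixture dilution series.

# Noiseless expected intensity of a lut/zea mixture (no baseline).
expected_mixture <- function(basis, f_zea, laser_nm, total_concentration) {
  total_concentration *
    (f_zea * cross_section(basis, "zea", laser_nm) * basis_profile(basis, "zea") +
     (1 - f_zea) * cross_section(basis, "lut", laser_nm) * basis_profile(basis, "lut"))
}

#' Simulate one mixture Raman spectrum
#'
#' Draws a resonance Raman spectrum of a lutein/zeaxanthin mixture: the
#' expected trace is `total_concentration * [f_zea * s(zea, L) * B_zea +
#' (1 - f_zea) * s(lut, L) * B_lut] + baseline`, with additive Gaussian
#' read noise and optional Poisson photon statistics, plus single-bin
#' cosmic-ray spikes at a configurable per-bin rate. The simulated
#' analogue of dilution-series measurements on chromatographically pure
#' pigment solutions.
#'
#' @param basis A `pigment_basis`.
#' @param f_zea Zeaxanthin mole fraction in \[0, 1\].
#' @param laser_nm 488 or 514.
#' @param total_concentration Total pigment concentration (arbitrary
#'   units > 0); the noiseless spectrum scales linearly with it.
#' @param noise_sd Additive Gaussian noise standard deviation (counts).
#' @param baseline Optional additive baseline: numeric vector on the
#'   basis axis, or a function of wavenumber.
#' @param cosmic_ray_rate Expected number of spikes per bin (e.g. 2e-3).
#' @param poisson If `TRUE`, intensities are drawn as Poisson counts of
#'   the expected trace before adding Gaussian noise.
#' @param seed Optional seed; identical arguments and seed give
#'   bit-identical output.
#' @return List with elements `spectrum` (`raman_spectrum`) and `truth`
#'   (list recording `f_zea`, `total_concentration`, noise settings,
#'   spike positions and `seed`).
#' @export
synth_spectrum <- function(basis, f_zea, laser_nm, total_concentration = 1,
                           noise_sd = 0.02, baseline = NULL,
                           cosmic_ray_rate = 0, poisson = FALSE, seed = NULL) {
  if (!is.numeric(f_zea) || length(f_zea) != 1L || is.na(f_zea) ||
      f_zea < 0 || f_zea > 1) {
    stop_domain("f_zea must be a single value in [0, 1]")
  }
  if (noise_sd < 0) stop_domain("noise_sd must be >= 0")
  if (total_concentration <= 0) stop_domain("total_concentration must be > 0")
  wn <- basis$wavenumber
  mu <- expected_mixture(basis, f_zea, laser_nm, total_concentration)
  base_vec <- numeric(length(wn))
  if (!is.null(baseline)) {
    base_vec <- if (is.function(baseline)) baseline(wn) else as.numeric(baseline)
    if (length(base_vec) != length(wn)) {
      stop_data("baseline vector must match the wavenumber axis length")
    }
  }
  out <- with_seed(seed, {
    y <- if (poisson) stats::rpois(length(mu), mu) else mu
    y <- y + base_vec
    if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
    spikes <- integer(0)
    if (cosmic_ray_rate > 0) {
      n_spikes <- stats::rpois(1, cosmic_ray_rate * length(wn))
      if (n_spikes > 0) {
        spikes <- sample.int(length(wn), min(n_spikes, length(wn)))
        amp <- stats::runif(length(spikes), 20, 100) * max(abs(y), 1e-6)
        y[spikes] <- y[spikes] + amp
      }
    }
    list(y = y, spikes = sort(spikes))
  })
  truth <- list(f_zea = f_zea, total_concentration = total_concentration,
                laser_nm = laser_nm, noise_sd = noise_sd,
                cosmic_ray_bins = out$spikes, poisson = poisson, seed = seed)
  list(spectrum = raman_spectrum(wn, out$y, laser_nm,
                                 metadata = list(synthetic = TRUE, f_zea = f_zea)),
       truth = truth)
}

#' Simulate a mixture dilution series
#'
#' Generates the synthetic analogue of a pigment-mixture validation
#' series: `n_levels` true zeaxanthin fractions equally spaced on
#' \[0, 1\], each measured `n_reps` times; replicates differ only in the
#' noise realization.
#'
#' @inheritParams synth_spectrum
#' @param n_levels Number of fraction levels (>= 2).
#' @param n_reps Replicates per level (>= 1).
#' @return List with `spectra` (list of `raman_spectrum`, level-major
#'   order) and `truth` (data frame: `level`, `rep`, `f_zea`,
#'   `total_concentration`).
#' @export
synth_mixture_series <- function(basis, laser_nm, n_levels = 11, n_reps = 10,
                                 noise_sd = 0.02, total_concentration = 1,
                                 seed = NULL) {
  if (n_levels < 2) stop_domain("n_levels must be >= 2")
  if (n_reps < 1) stop_domain("n_reps must be >= 1")
  fractions <- seq(0, 1, length.out = n_levels)
  spectra <- vector("list", n_levels * n_reps)
  truth <- data.frame(level = rep(seq_len(n_levels), each = n_reps),
                      rep = rep(seq_len(n_reps), times = n_levels),
                      f_zea = rep(fractions, each = n_reps),
                      total_concentration = total_concentration)
  with_seed(seed, {
    k <- 0L
    for (i in seq_len(n_levels)) {
      for (j in seq_len(n_reps)) {
        k <- k + 1L
        spectra[[k]] <- synth_spectrum(basis, fractions[i], laser_nm,
                                       total_concentration = total_concentration,
                                       noise_sd = noise_sd)$spectrum
      }
    }
  })
  list(spectra = spectra, truth = truth, laser_nm = laser_nm,
       noise_sd = noise_sd, seed = seed)
}
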