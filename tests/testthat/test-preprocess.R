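# Cosmic-ray removal, baseline correction, cropping.

smooth_band <- function() {
  wn <- seq(800, 1800, by = 1)
  raman_spectrum(wn, gauss_band_test(wn, 1526, 14), 488)
}
gauss_band_test <- function(x, center, fwhm, amp = 1) {
  amp * exp(-(x - center)^2 / (2 * (fwhm / (2 * sqrt(2 * log(2))))^2))
}

# independent brute-force spike oracle: the smallest set of candidate
# bins whose removal (deletion from the series) brings every modified
# second-difference z below the threshold
oracle_spikes <- function(y, thr) {
  zstat <- function(y) {
    n <- length(y)
    d <- y - (c(y[1], y[-n]) + c(y[-1], y[n])) / 2
    abs((d - stats::median(d)) /
          max(stats::mad(d, constant = 1) / 0.6745, 1e-12))
  }
  cand <- which(zstat(y) > thr)
  if (length(cand) == 0) return(integer(0))
  for (k in 1:length(cand)) {
    subsets <- utils::combn(cand, k, simplify = FALSE)
    for (s in subsets) {
      if (max(zstat(y[-s])) <= thr || (k > 0 && length(y[-s]) < 5)) {
        return(sort(s))
      }
    }
  }
  sort(cand)
}

test_that("a single injected spike is replaced and nothing else changes", {
  sp <- smooth_band()
  spiked <- sp
  i <- 300
  spiked$intensity[i] <- 50 * max(stats::median(sp$intensity[i + (-2:2)]), 0.01)
  out <- remove_cosmic_rays(spiked)
  expect_equal(out$metadata$cosmic_ray_bins, i)
  expect_identical(out$intensity[-i], spiked$intensity[-i])
  expect_lt(out$intensity[i], spiked$intensity[i] / 10)
})

test_that("a spike-free noiseless band passes through untouched", {
  sp <- smooth_band()
  out <- remove_cosmic_rays(sp)
  expect_identical(out$intensity, sp$intensity)
  expect_length(out$metadata$cosmic_ray_bins, 0)
})

test_that("adjacent spikes are both flagged, matching the brute-force oracle", {
  set.seed(31)
  wn <- seq(800, 1800, by = 1)
  y <- gauss_band_test(wn, 1526, 14) + rnorm(length(wn), 0, 0.01)
  y[c(450, 451)] <- y[c(450, 451)] + c(30, 22)
  sp <- raman_spectrum(wn, y, 488)
  out <- remove_cosmic_rays(sp)
  expect_true(all(c(450, 451) %in% out$metadata$cosmic_ray_bins))
  expect_setequal(out$metadata$cosmic_ray_bins, oracle_spikes(y, 8))
})

test_that("despiking is idempotent", {
  set.seed(32)
  wn <- seq(800, 1800, by = 1)
  y <- gauss_band_test(wn, 1526, 14) + rnorm(length(wn), 0, 0.02)
  y[c(100, 600, 601)] <- y[c(100, 600, 601)] + c(45, 25, 40)
  once <- remove_cosmic_rays(raman_spectrum(wn, y, 488))
  twice <- remove_cosmic_rays(once)
  expect_identical(twice$intensity, once$intensity)
  expect_length(twice$metadata$cosmic_ray_bins, 0)
  expect_error(remove_cosmic_rays(raman_spectrum(1000:1002, c(1, 2, 1), 488),
                                  window = 5),
               class = "xm_domain_error")
})

test_that("baseline correction recovers a band on a linear ramp within 1%", {
  wn <- seq(800, 1800, by = 1)
  band <- gauss_band_test(wn, 1526, 14)
  ramp <- 0.5 + 0.001 * (wn - 800)
  out <- correct_baseline(raman_spectrum(wn, band + ramp, 488))
  expect_lt(abs(sum(out$intensity) - sum(band)) / sum(band), 0.01)
  # the estimated baseline is stored for inspection
  expect_equal(out$metadata$baseline, ramp, tolerance = 1e-3)
})

test_that("zero-baseline input is a no-op and positive baselines only subtract", {
  wn <- seq(800, 1800, by = 1)
  band <- gauss_band_test(wn, 1526, 14)
  out0 <- correct_baseline(raman_spectrum(wn, band, 488))
  expect_lt(max(abs(out0$intensity - band)) / max(band), 1e-6)
  y <- band + 0.4 + 5e-4 * (wn - 800)
  out <- correct_baseline(raman_spectrum(wn, y, 488))
  expect_true(all(out$intensity <= y + 1e-8))
})

test_that("polynomial baseline method handles a curved background", {
  wn <- seq(800, 1800, by = 1)
  band <- gauss_band_test(wn, 1526, 14)
  curved <- 0.3 + 1e-6 * (wn - 1300)^2
  out <- correct_baseline(raman_spectrum(wn, band + curved, 488),
                          method = "polynomial", params = list(degree = 3))
  expect_lt(abs(sum(out$intensity) - sum(band)) / sum(band), 0.05)
  expect_error(correct_baseline(smooth_band(), method = "polynomial",
                                params = list(degree = 7)),
               class = "xm_config_error")
})

test_that("cropping keeps the inclusive interval and rejects bad bounds", {
  wn <- seq(700, 1900, by = 1)
  sp <- raman_spectrum(wn, gauss_band_test(wn, 1526, 14), 488)
  cr <- crop_region(sp)
  expect_equal(range(cr$wavenumber), c(800, 1800))
  full <- crop_region(sp, 700, 1900)
  expect_identical(full$intensity, sp$intensity)
  expect_error(crop_region(sp, 1500, 1200), class = "xm_domain_error")
  expect_error(crop_region(sp, 2000, 2100), class = "xm_domain_error")
})

test_that("preprocessing never changes the axis except by cropping", {
  set.seed(33)
  sim <- synth_spectrum(default_basis, 0.5, 514, noise_sd = 0.01,
                        baseline = function(w) 0.2 + 2e-4 * (w - 800),
                        cosmic_ray_rate = 2e-3, seed = 41)
  out <- preprocess_spectrum(sim$spectrum)
  expect_true(all(out$wavenumber %in% sim$spectrum$wavenumber))
  expect_equal(range(out$wavenumber), c(800, 1800))
})

test_that("end-to-end preprocessing recovers the noiseless nu1 area within 2%", {
  sim <- synth_spectrum(default_basis, 0.4, 514, noise_sd = 0,
                        baseline = function(w) 0.3 + 5e-4 * (w - 800),
                        cosmic_ray_rate = 3e-3, seed = 11)
  pp <- preprocess_spectrum(sim$spectrum)
  fit <- fit_nu1_gaussians(pp)
  s <- xs_at(514)
  truth_area <- (0.4 * s[["zea"]] + 0.6 * s[["lut"]]) *
    (14 / (2 * sqrt(2 * log(2)))) * sqrt(2 * pi)
  expect_lt(abs(fit$area_lut + fit$area_zea - truth_area) / truth_area, 0.02)
})
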