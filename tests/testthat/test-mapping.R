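# Pigment mapping, radial profiles, segmentation, region statistics,
# cross-sections and Z-scan profiles. Maps are scaled down (1.5 mm at
# coarse pitch) so the suite stays fast.

uniform_map <- function(f_zea, n = 6, noise_sd = 0, conc = 1, laser = 514,
                        seed = 1) {
  wn <- default_basis$wavenumber
  base <- synth_spectrum(default_basis, f_zea, laser, total_concentration = conc,
                         noise_sd = 0)$spectrum$intensity
  inten <- matrix(rep(base, each = n * n), nrow = n * n)
  if (noise_sd > 0) {
    inten <- inten + with_seed_test(seed, matrix(rnorm(length(inten), 0, noise_sd),
                                                 nrow = n * n))
  }
  g <- expand.grid(ix = seq_len(n), iy = seq_len(n))
  spectral_map(wn, inten, (g$ix - 0.5) * 5, (g$iy - 0.5) * 5, n, n, 5,
               "XY", laser)
}
with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed); expr
}

# one fitted noiseless scaled-down retina map shared by several tests
fitted_test_map <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- synth_retina_map(default_basis, test_geometry(37.5), 514,
                              noise_sd = 0, seed = 55)
      pm <- map_pixelwise(preprocess_map(sim$map),
                          calibration = small_calibration())
      cache <<- list(sim = sim, pm = pm)
    }
    cache
  }
})

test_that("a uniform 50:50 map yields a constant fraction image", {
  m <- uniform_map(0.5)
  pm <- map_pixelwise(m, calibration = small_calibration())
  fr <- as.numeric(pm$images$fraction_zea)
  expect_true(all(abs(fr - 0.5) < 0.015))
  expect_true(all(pm$mask))
  # mass consistency: lut + zea recompose the total exactly
  expect_equal(pm$images$lut + pm$images$zea, pm$images$total, tolerance = 1e-12)
})

test_that("FWHM image of a pure-pigment map is constant at the component width", {
  pm <- map_pixelwise(uniform_map(0), calibration = NULL)
  fw <- as.numeric(pm$images$fwhm)
  expect_true(all(abs(fw - fw[1]) < 0.1))
  expect_equal(fw[1], 14, tolerance = 0.1)
})

test_that("the FWHM image peaks where the mixture is closest to 50:50", {
  tm <- fitted_test_map()
  # dense-grid oracle: the two-Gaussian sum is broadest at equal signal split
  raw <- as.numeric(tm$pm$images$raw_fraction_zea)
  fw <- as.numeric(tm$pm$images$fwhm)
  ok <- !is.na(raw) & !is.na(fw)
  expect_equal(raw[ok][which.max(fw[ok])], 0.5, tolerance = 0.05)
})

test_that("find_center locates the macula and rejects degenerate input", {
  tm <- fitted_test_map()
  ctr <- find_center(tm$pm)
  expect_lt(max(abs(ctr - 750)), 37.5)
  single <- uniform_map(0.5, n = 5)
  pm1 <- map_pixelwise(single)
  pm1$images$total[] <- 0
  pm1$images$total[3, 4] <- 1
  expect_equal(unname(find_center(pm1)), c(12.5, 17.5))
  pm1$images$total[] <- 1
  expect_error(find_center(pm1), class = "xm_data_error")
})

test_that("radial profiles are flat on uniform maps and hit the truth plateaus", {
  pm_u <- map_pixelwise(uniform_map(0.4, n = 8))
  prof_u <- radial_profile(pm_u, center = c(20, 20))
  ok <- prof_u$n > 0
  expect_lt(max(abs(prof_u$mean_total[ok] - mean(prof_u$mean_total[ok]))), 1e-6)

  tm <- fitted_test_map()
  prof <- radial_profile(tm$pm, center = c(750, 750))
  inner <- prof$r_um < 100 & prof$n > 0
  outer <- prof$r_um > 1030 & prof$n > 0
  expect_true(any(inner) && any(outer))
  expect_equal(mean(prof$ratio[inner]), 2.0, tolerance = 0.05)
  expect_equal(mean(prof$ratio[outer]), 0.3, tolerance = 0.05 / 0.3)
  expect_error(radial_profile(tm$pm, center = c(-4000, 750)),
               class = "xm_domain_error")
})

test_that("fixed segmentation uses the standard disk radii and partitions", {
  tm <- fitted_test_map()
  seg <- segment_regions(tm$pm, center = c(750, 750), mode = "fixed")
  expect_equal(unname(seg$radii_um), c(175, 500, 1000))
  expect_true(all(!is.na(seg$labels)))
  expect_setequal(as.character(unique(as.vector(seg$labels))),
                  c("foveola", "fovea", "parafovea", "outside"))
})

test_that("data-driven segmentation recovers the foveola boundary", {
  tm <- fitted_test_map()
  # the profile pitch here is a coarse 37.5 um, so a 1-bin kernel keeps
  # the smoothing window well below the 150 um transition width
  seg <- segment_regions(tm$pm, center = c(750, 750), mode = "data_driven",
                         smooth_sd_bins = 1)
  # at this pitch one profile bin is 37.5 um; the onset estimate is
  # resolution-limited to about 1.5 bins
  expect_lt(abs(seg$radii_um[["foveola"]] - 175), 1.5 * 37.5)
  expect_lt(abs(seg$radii_um[["fovea"]] - 500), 1.5 * 37.5)
  flat <- map_pixelwise(uniform_map(0.5, n = 8))
  expect_error(segment_regions(flat, center = c(20, 20), mode = "data_driven"),
               class = "xm_data_error")
})

test_that("region statistics recover the generator's ratios and contrast", {
  tm <- fitted_test_map()
  seg <- segment_regions(tm$pm, center = c(750, 750), mode = "fixed")
  rr <- region_ratios(tm$pm, seg)
  expect_equal(rr$mean_ratio[rr$region == "foveola"], 2.0, tolerance = 0.05)
  expect_equal(rr$mean_ratio[rr$region == "outside"], 0.3,
               tolerance = 0.05 / 0.3)
  expect_equal(attr(rr, "central_peripheral_contrast"), 100, tolerance = 0.1)
})

test_that("region ratios are rotation-robust (radial symmetry)", {
  tm <- fitted_test_map()
  rot <- tm$pm
  # rotate every image (and the mask) by 90 degrees on the square grid
  rot90 <- function(m) t(m[nrow(m):1, , drop = FALSE])
  rot$images <- lapply(tm$pm$images, rot90)
  rot$mask <- rot90(tm$pm$mask)
  seg <- segment_regions(tm$pm, center = c(750, 750), mode = "fixed")
  rr0 <- region_ratios(tm$pm, seg)
  rr1 <- region_ratios(rot, seg)
  expect_equal(rr1$mean_ratio, rr0$mean_ratio, tolerance = 0.01)
})

test_that("masked pixels are excluded from regional statistics", {
  tm <- fitted_test_map()
  seg <- segment_regions(tm$pm, center = c(750, 750), mode = "fixed")
  rr0 <- region_ratios(tm$pm, seg)
  masked <- tm$pm
  kill <- which(as.character(seg$labels) == "foveola")[1:5]
  masked$mask[kill] <- FALSE
  rr1 <- region_ratios(masked, seg)
  expect_equal(rr1$n[rr1$region == "foveola"],
               rr0$n[rr0$region == "foveola"] - 5L)
})

test_that("line cross-sections track the map and honor their contracts", {
  tm <- fitted_test_map()
  cs <- line_cross_section(tm$pm, c(25, 750), c(1475, 750))
  # the total profile must peak on the central plateau
  peak_x <- cs$distance_um[which.max(cs$total)] + 25
  expect_lt(abs(peak_x - 750), 175)
  # uniform map: constant profile
  pm_u <- map_pixelwise(uniform_map(0.5, n = 8))
  cs_u <- line_cross_section(pm_u, c(5, 20), c(35, 20), width_px = 3)
  expect_lt(diff(range(cs_u$total)), 1e-6)
  # width 1 equals nearest-pixel sampling
  cs1 <- line_cross_section(pm_u, c(5, 20), c(35, 20), width_px = 1)
  expect_equal(cs1$total[1], pm_u$images$total[1, 4])
  expect_error(line_cross_section(tm$pm, c(100, 100), c(100, 100)),
               class = "xm_domain_error")
})

test_that("Z-scan profiles co-localize the pigments and match the truth", {
  zs <- synth_zscan(default_basis, layer_center_um = 20, layer_fwhm_um = 8,
                    f_zea_profile = 0.4, noise_sd = 0, nx = 4)
  zp <- zscan_profile(zs$map, calibration = small_calibration())
  peaks <- zp$layers$peak_z_um
  expect_lt(abs(peaks[1] - 20), 1)
  expect_lt(abs(peaks[1] - peaks[2]), 1)
  # amplitude ratio matches the generator fraction within 10%
  ratio <- zp$layers$amplitude[zp$layers$pigment == "zea"] /
    zp$layers$amplitude[zp$layers$pigment == "lut"]
  expect_equal(ratio, 0.4 / 0.6, tolerance = 0.1)
  expect_error(zscan_profile(uniform_map(0.5)), class = "xm_data_error")
})

test_that("excessive fit failures raise a map-quality error", {
  m <- uniform_map(0.5, n = 4)
  m$intensity[1:10, ] <- 0  # flat spectra cannot be located
  expect_error(map_pixelwise(m, max_failure_fraction = 0.2),
               class = "xm_data_error")
})
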