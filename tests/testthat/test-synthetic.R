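# Synthetic-data generator: basis invariants, mixture model, retina
# geometry truth, Z-scan co-localization, FLIM photoselection.

test_that("default basis carries the pure-pigment band structure", {
  b <- default_basis
  # nu1 is the dominant band of each pigment, at the pigment-specific center
  expect_equal(b$bands$lut$center[1], 1526)
  expect_equal(b$bands$zea$center[1], 1521)
  for (p in c("lut", "zea")) {
    expect_true(all(b$bands[[p]]$amplitude[1] > b$bands[[p]]$amplitude[-1]))
    # secondary carotenoid bands present so full-spectrum CLS is non-degenerate
    expect_true(all(c(1157, 1008) %in% b$bands[[p]]$center))
  }
  # resonance conditions at 514 nm favor zeaxanthin
  expect_gt(cross_section(b, "zea", 514) / cross_section(b, "lut", 514), 1)
})

test_that("invalid basis configuration is rejected with the field named", {
  expect_error(make_default_basis(list(bands = list(lut = data.frame(
    center = 1526, fwhm = -2, amplitude = 1)))), "fwhm")
  expect_error(make_default_basis(list(bands = list(zea = data.frame(
    center = 300, fwhm = 10, amplitude = 1)))), "center")
  expect_error(make_default_basis(list(cross_sections = list(
    lut = c("488" = -1, "514" = 1)))), "cross_sections")
})

test_that("pure synthetic spectra peak at the pigment nu1 positions", {
  s_lut <- pure_spectrum(0, 488)
  s_zea <- pure_spectrum(1, 514)
  expect_equal(s_lut$wavenumber[which.max(s_lut$intensity)], 1526)
  expect_equal(s_zea$wavenumber[which.max(s_zea$intensity)], 1521)
})

test_that("synth_spectrum validates the mixture fraction", {
  expect_error(synth_spectrum(default_basis, -0.1, 514), class = "xm_domain_error")
  expect_error(synth_spectrum(default_basis, 1.3, 514), class = "xm_domain_error")
})

test_that("generators are bit-identical under a fixed seed", {
  a <- synth_spectrum(default_basis, 0.4, 514, noise_sd = 0.05,
                      cosmic_ray_rate = 1e-3, seed = 7)
  b <- synth_spectrum(default_basis, 0.4, 514, noise_sd = 0.05,
                      cosmic_ray_rate = 1e-3, seed = 7)
  expect_identical(a$spectrum$intensity, b$spectrum$intensity)
  m1 <- synth_retina_map(default_basis, test_geometry(150), 514, seed = 3)
  m2 <- synth_retina_map(default_basis, test_geometry(150), 514, seed = 3)
  expect_identical(m1$map$intensity, m2$map$intensity)
  f1 <- synth_axon_flim(counts_per_pixel = 100, power_series = 1, n_bins = 64,
                        seed = 5)
  f2 <- synth_axon_flim(counts_per_pixel = 100, power_series = 1, n_bins = 64,
                        seed = 5)
  expect_identical(f1$datasets[[1]]$parallel, f2$datasets[[1]]$parallel)
})

test_that("noiseless spectrum integral is exactly linear in concentration", {
  conc <- c(0.5, 2, 8)
  integral <- vapply(conc, function(k) {
    sum(synth_spectrum(default_basis, 0.3, 514, total_concentration = k,
                       noise_sd = 0)$spectrum$intensity)
  }, numeric(1))
  fit <- stats::lm(integral ~ conc)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((integral - mean(integral))^2)
  expect_equal(r2, 1, tolerance = 1e-12)
  expect_equal(unname(stats::coef(fit)[1]), 0, tolerance = 1e-9)
})

test_that("mixture series has the prescribed level grid and replicates", {
  ser <- synth_mixture_series(default_basis, 514, n_levels = 11, n_reps = 10,
                              noise_sd = 0, seed = 1)
  expect_length(ser$spectra, 110)
  expect_equal(sort(unique(ser$truth$f_zea)), seq(0, 1, by = 0.1))
  # noiseless replicates at one level are identical
  i1 <- which(ser$truth$level == 4)
  expect_identical(ser$spectra[[i1[1]]]$intensity, ser$spectra[[i1[2]]]$intensity)
  expect_error(synth_mixture_series(default_basis, 514, n_levels = 1),
               class = "xm_domain_error")
})

test_that("retina truth follows the stated central/peripheral plateaus", {
  prof <- retina_truth_profile(c(0, 0.05, 0.16, 1.05, 1.2, 1.4))
  expect_equal(prof$ratio[1:3], rep(2, 3))
  expect_equal(prof$ratio[4:6], rep(0.3, 3))
  expect_equal(prof$total[1] / prof$total[6], 100)
  # smooth monotone decline in between
  mid <- retina_truth_profile(seq(0, 1.3, by = 0.01))
  expect_true(all(diff(mid$ratio) <= 1e-12))
  expect_true(all(diff(mid$total) <= 1e-12))
})

test_that("retina map truth is radially symmetric by construction", {
  sim <- synth_retina_map(default_basis, test_geometry(75), 514,
                          noise_sd = 0, seed = 1)
  r_mm <- sim$truth$r_mm
  recomputed <- retina_truth_profile(r_mm)$ratio
  expect_equal(sim$truth$ratio, recomputed, tolerance = 0)
})

test_that("retina map validates its geometry", {
  expect_error(retina_geometry(pixel_size = -5), class = "xm_config_error")
  expect_error(retina_geometry(map_extent = 0.8), class = "xm_config_error")
  expect_error(retina_geometry(foveola_diameter = 1.5), class = "xm_config_error")
})

test_that("Z-scan co-localizes the two pigments in one Gaussian layer", {
  zs <- synth_zscan(default_basis, layer_center_um = 20, layer_fwhm_um = 8,
                    f_zea_profile = 0.4, noise_sd = 0, nx = 4)
  expect_equal(zs$map$pixel_size_um, c(1, 1))   # 1 um voxel pitch default
  per_z <- function(col) {
    z <- sort(unique(zs$truth$z_um))
    vapply(z, function(zz) mean(col[zs$truth$z_um == zz]), numeric(1))
  }
  tot <- per_z(zs$truth$total)
  z_levels <- sort(unique(zs$truth$z_um))
  expect_lt(abs(z_levels[which.max(tot)] - 20), 1)
  # lut and zea truth profiles peak at the same depth
  lut_prof <- per_z(zs$truth$total * (1 - zs$truth$f_zea))
  zea_prof <- per_z(zs$truth$total * zs$truth$f_zea)
  expect_equal(which.max(lut_prof), which.max(zea_prof))
  expect_error(synth_zscan(default_basis, layer_fwhm_um = 0),
               class = "xm_domain_error")
})

test_that("axon photoselection produces the expected sector anisotropy", {
  sim <- synth_axon_flim("radial", counts_per_pixel = 3000, power_series = 1,
                         n_bins = 128, seed = 9)
  d <- sim$datasets[[1]]
  # radial dipoles + horizontal polarization: left/right sectors bright
  ss <- sector_statistics(d)
  expect_gt(ss$lr_tb_intensity_ratio, 1)
  # tangential orientation is the 90-degree rotation of the radial case
  simt <- synth_axon_flim("tangential", counts_per_pixel = 3000,
                          power_series = 1, n_bins = 128, seed = 9)
  sst <- sector_statistics(simt$datasets[[1]])
  expect_lt(sst$lr_tb_intensity_ratio, 1)
  # noiseless expectation at theta = 0: perpendicular intensity 0 => r = 1
  theta0 <- which(abs(sim$truth$theta) < 1e-9 & sim$truth$on_ring)
  expect_true(length(theta0) > 0)
  expect_equal(sum(d$perpendicular[theta0, ]), 0)
  expect_equal(anisotropy(sum(d$parallel[theta0, ]), 0, 1), 1)
})

test_that("every drawn photon lands in the histogram (conservation)", {
  sim <- synth_axon_flim(counts_per_pixel = 500, power_series = c(1, 3),
                         n_bins = 256, seed = 13)
  for (d in sim$datasets) {
    expect_identical(unname(rowSums(d$parallel)), as.numeric(d$metadata$drawn_par))
    expect_identical(unname(rowSums(d$perpendicular)),
                     as.numeric(d$metadata$drawn_perp))
  }
  expect_error(synth_axon_flim(power_series = numeric(0)),
               class = "xm_domain_error")
})
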