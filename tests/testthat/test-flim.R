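# TCSPC decay fitting, anisotropy, photoselection sectors, power trend.

test_that("anisotropy follows the printed formula exactly", {
  expect_equal(anisotropy(100, 100, 1), 0)
  expect_equal(anisotropy(300, 100, 1), 0.4)
  expect_equal(anisotropy(100, 0, 1), 1)
  expect_equal(anisotropy(100, 0, 2.7), 1)
  expect_equal(anisotropy(100, 200, 0.5), 0)
  expect_error(anisotropy(0, 0, 1), class = "xm_domain_error")
  expect_error(anisotropy(10, 5, 0), class = "xm_domain_error")
  expect_error(anisotropy(-1, 5, 1), class = "xm_domain_error")
})

test_that("anisotropy stays in [-0.5, 1] for random non-negative pairs", {
  set.seed(3)
  i_par <- runif(1e4, 0, 100)
  i_perp <- runif(1e4, 0, 100)
  r <- anisotropy(i_par, i_perp, 1)
  expect_true(all(r >= -0.5 & r <= 1))
  # channel-swap consistency, evaluated directly from the formula
  r_sw <- anisotropy(i_perp, i_par, 1)
  expect_equal(r_sw, (i_perp - i_par) / (i_perp + 2 * i_par))
})

test_that("a noiseless single exponential is recovered to 1 ps", {
  t_ps <- (0:511) * 16
  mu <- 500 * exp(-t_ps / 2500)
  h <- structure(list(time_ps = t_ps, counts_parallel = mu,
                      counts_perpendicular = mu * 0, g_factor = 1,
                      laser_power = 1, bin_ps = 16),
                 class = "decay_histogram")
  fit <- fit_decay(h, n_components = 1, channel = "parallel")
  expect_lt(abs(fit$tau_long - 2500), 1)
  expect_equal(fit$f_short, 0)
})

test_that("the biexponential amplitude fraction is recovered from 1e6 photons", {
  sim <- synth_axon_flim(counts_per_pixel = 25000, power_series = 1, seed = 3,
                         ring_radius_px = 10, ring_width_px = 3)
  d <- sim$datasets[[1]]
  expect_gt(sum(d$parallel) + sum(d$perpendicular), 1e6)
  fit <- fit_decay(d)
  expect_lt(abs(fit$f_short - 0.6), 0.02)
  expect_equal(fit$tau_short, 70, tolerance = 0.1)
  expect_equal(fit$tau_long, 2500, tolerance = 0.02)
  expect_lt(fit$tau_short, fit$tau_long)  # relabeling contract
})

test_that("a spurious second component is negligible or flagged degenerate", {
  t_ps <- (0:511) * 16
  set.seed(6)
  mu <- rpois(512, 800 * exp(-t_ps / 2500))
  h <- structure(list(time_ps = t_ps, counts_parallel = mu,
                      counts_perpendicular = mu * 0, g_factor = 1,
                      laser_power = 1, bin_ps = 16),
                 class = "decay_histogram")
  fit <- fit_decay(h, n_components = 2, channel = "parallel")
  expect_true(fit$f_short < 0.05 || isTRUE(fit$degenerate))
})

test_that("short_fraction reports the amplitude fraction with guards", {
  f <- structure(list(tau_short = 70, tau_long = 2500, amp_short = 3,
                      amp_long = 1, f_short = 0.75, degenerate = FALSE),
                 class = "biexp_fit")
  expect_equal(short_fraction(f), 0.75)
  f$amp_short <- 0; f$f_short <- 0
  expect_equal(short_fraction(f), 0)
  f$f_short <- 0.5
  expect_equal(short_fraction(f), 0.5)
  f$tau_short <- NA_real_
  expect_error(short_fraction(f), class = "xm_data_error")
  f$tau_short <- 2400; f$degenerate <- TRUE
  expect_warning(short_fraction(f), "10%")
})

test_that("insufficient counts are refused", {
  t_ps <- (0:127) * 16
  h <- structure(list(time_ps = t_ps, counts_parallel = rep(0.1, 128),
                      counts_perpendicular = rep(0, 128), g_factor = 1,
                      laser_power = 1, bin_ps = 16),
                 class = "decay_histogram")
  expect_error(fit_decay(h, channel = "parallel"), class = "xm_data_error")
})

test_that("sector statistics expose the photoselection contrast", {
  sim <- synth_axon_flim("radial", counts_per_pixel = 4000, power_series = 1,
                         n_bins = 128, seed = 9)
  ss <- sector_statistics(sim$datasets[[1]])
  expect_gt(ss$lr_tb_intensity_ratio, 1)
  # left/right sectors carry positive anisotropy (dipoles near horizontal)
  lr <- ss$sectors$anisotropy[ss$sectors$sector %in% c("left", "right")]
  tb <- ss$sectors$anisotropy[ss$sectors$sector %in% c("top", "bottom")]
  expect_true(all(lr > 0))
  expect_true(all(tb < lr))
})

test_that("an isotropic-emitter ring has four statistically equal sectors", {
  # isotropic: equal expected counts at every angle, equal channel split
  set.seed(10)
  n <- 25
  ix <- rep(1:n, times = n); iy <- rep(1:n, each = n)
  rr <- sqrt((ix - 13)^2 + (iy - 13)^2)
  on_ring <- abs(rr - 8) <= 2
  lam <- 500 * on_ring
  nt <- 8
  par_m <- matrix(rpois(n * n * nt, lam / nt), ncol = nt)
  perp_m <- matrix(rpois(n * n * nt, lam / nt), ncol = nt)
  d <- flim_dataset((0:(nt - 1)) * 16, par_m, perp_m, n, n)
  ss <- sector_statistics(d, center = c(13, 13), inner_px = 6, outer_px = 10)
  m <- ss$sectors$mean_intensity
  se <- sqrt(m / ss$sectors$n_pixels) * sqrt(2)
  for (k in 2:4) expect_lt(abs(m[k] - m[1]), 3 * (se[k] + se[1]))
})

test_that("fitted f_short is independent of the dipole angle", {
  sim <- synth_axon_flim(counts_per_pixel = 20000, power_series = 1,
                         n_bins = 256, seed = 17, ring_radius_px = 9,
                         ring_width_px = 3)
  d <- sim$datasets[[1]]
  tot <- rowSums(d$parallel) + rowSums(d$perpendicular)
  px <- which(sim$truth$on_ring & tot > 3000)
  f_px <- vapply(px, function(i) {
    h <- decay_histogram(d, i)
    fit_decay(h, min_counts = 1000)$f_short
  }, numeric(1))
  theta <- abs(cos(sim$truth$theta[px]))
  fit <- stats::lm(f_px ~ theta)
  ci <- stats::confint(fit, "theta")
  expect_true(ci[1] <= 0 && ci[2] >= 0)
})

test_that("doubling the counts shrinks the f_short scatter like sqrt(n)", {
  scatter <- vapply(c(4000, 16000), function(cpp) {
    fs <- vapply(1:6, function(s) {
      sim <- synth_axon_flim(counts_per_pixel = cpp, power_series = 1,
                             n_bins = 256, seed = 500 + s,
                             ring_radius_px = 8, ring_width_px = 2)
      fit_decay(sim$datasets[[1]])$f_short
    }, numeric(1))
    stats::sd(fs)
  }, numeric(1))
  # factor 4 in counts: expect the SE to halve, within generous MC slack
  expect_lt(scatter[2], scatter[1])
})

test_that("power trends distinguish constant from drifting fractions", {
  powers <- c(1, 2, 4, 8)
  sim <- synth_axon_flim(counts_per_pixel = 6000, power_series = powers,
                         n_bins = 256, seed = 5)
  fs <- vapply(sim$datasets, function(d) fit_decay(d)$f_short, numeric(1))
  tr <- power_trend(powers, fs)
  expect_true(tr$ci[1] <= 0 && tr$ci[2] >= 0)
  # linearly increasing truth: the CI must exclude zero with positive sign
  sim2 <- synth_axon_flim(counts_per_pixel = 6000, power_series = powers,
                          f_short_per_power = c(0.3, 0.4, 0.5, 0.6),
                          n_bins = 256, seed = 6)
  fs2 <- vapply(sim2$datasets, function(d) fit_decay(d)$f_short, numeric(1))
  tr2 <- power_trend(powers, fs2)
  expect_gt(tr2$ci[1], 0)
  expect_error(power_trend(c(1, 2), c(0.5, 0.5)), class = "xm_data_error")
})
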