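# Shared fixtures, built in code at test time.

default_basis <- make_default_basis()

# cross-sections of the default basis at a given laser, as the named
# vector the estimators expect
xs_at <- function(laser_nm, basis = default_basis) {
  c(lut = cross_section(basis, "lut", laser_nm),
    zea = cross_section(basis, "zea", laser_nm))
}

# a quick noiseless mixture spectrum on the default basis
pure_spectrum <- function(f_zea, laser_nm = 514, ...) {
  synth_spectrum(default_basis, f_zea, laser_nm, noise_sd = 0, ...)$spectrum
}

# small calibration curve reused by mapping tests (coarse but accurate
# enough at noise 0.02); built once per test run
small_calibration <- local({
  curve <- NULL
  function() {
    if (is.null(curve)) {
      ser <- synth_mixture_series(default_basis, 514, n_levels = 11,
                                  n_reps = 5, noise_sd = 0.02, seed = 101)
      curve <<- build_calibration(ser, "nu1", multi_start = FALSE)
    }
    curve
  }
})

# scaled-down retina geometry used throughout the mapping tests
test_geometry <- function(pixel_um = 37.5) {
  retina_geometry(map_extent = 1.5, pixel_size = pixel_um)
}
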