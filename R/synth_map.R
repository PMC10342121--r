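# Synthetic retina maps (XY) and Z-scans (XZ).

#' Retina map geometry parameters
#'
#' Holds the radial geometry the synthetic retina generator emulates:
#' foveola/fovea/parafovea disk diameters, the central and peripheral
#' zeaxanthins-to-lutein ratios, the central-to-peripheral total pigment
#' contrast, and sampling parameters. Defaults are the anatomy of a
#' healthy macula: 0.35 / 1 / 2 mm disks, Zea:Lut about 2 in the center
#' falling to about 0.3 in the periphery, and an approximately 100-fold
#' concentration contrast between the macula and the peripheral retina.
#'
#' @param foveola_diameter,fovea_diameter,parafovea_diameter Disk
#'   diameters in mm, strictly increasing.
#' @param central_zea_lut_ratio,peripheral_zea_lut_ratio Zea:Lut
#'   concentration ratios at the center and in the periphery.
#' @param central_to_peripheral_total_ratio Total-concentration contrast.
#' @param transition_width Raised-cosine transition width (mm).
#' @param map_extent Side length of the simulated square field (mm).
#' @param pixel_size Pixel pitch (um).
#' @return A `retina_geometry` object.
#' @export
retina_geometry <- function(foveola_diameter = 0.35, fovea_diameter = 1,
                            parafovea_diameter = 2,
                            central_zea_lut_ratio = 2,
                            peripheral_zea_lut_ratio = 0.3,
                            central_to_peripheral_total_ratio = 100,
                            transition_width = 0.15,
                            map_extent = 3, pixel_size = 5) {
  g <- list(foveola_diameter = foveola_diameter, fovea_diameter = fovea_diameter,
            parafovea_diameter = parafovea_diameter,
            central_zea_lut_ratio = central_zea_lut_ratio,
            peripheral_zea_lut_ratio = peripheral_zea_lut_ratio,
            central_to_peripheral_total_ratio = central_to_peripheral_total_ratio,
            transition_width = transition_width,
            map_extent = map_extent, pixel_size = pixel_size)
  if (!(foveola_diameter < fovea_diameter && fovea_diameter < parafovea_diameter)) {
    stop_config("field 'diameters' must satisfy foveola < fovea < parafovea")
  }
  ratios <- c(central_zea_lut_ratio, peripheral_zea_lut_ratio,
              central_to_peripheral_total_ratio)
  if (any(!is.finite(ratios)) || any(ratios <= 0)) {
    stop_config("all geometry ratios must be positive")
  }
  if (transition_width <= 0) stop_config("field 'transition_width' must be > 0")
  if (pixel_size <= 0) stop_config("field 'pixel_size' must be > 0")
  if (map_extent < fovea_diameter) {
    stop_config("field 'map_extent' (", map_extent,
                " mm) must cover at least the fovea diameter (",
                fovea_diameter, " mm)")
  }
  structure(g, class = "retina_geometry")
}

# Raised-cosine step: 1 for r <= r0, 0 for r >= r0 + w.
rc_step <- function(r, r0, w) {
  s <- rep(1, length(r))
  s[r >= r0 + w] <- 0
  mid <- r > r0 & r < r0 + w
  s[mid] <- (1 + cos(pi * (r[mid] - r0) / w)) / 2
  s
}

# Radial staircase in log space between a central and a peripheral level.
# The foveola and fovea drops START at their boundary radii (the plateaus
# fill each disk and the curvature extremum sits exactly on the boundary);
# the outermost drop ENDS at the parafovea radius so everything beyond it
# is a pure peripheral plateau. `shares` splits the log contrast over the
# three steps.
radial_staircase <- function(r, central, peripheral, geometry, shares) {
  w <- geometry$transition_width
  r1 <- geometry$foveola_diameter / 2
  r2 <- geometry$fovea_diameter / 2
  r3 <- geometry$parafovea_diameter / 2
  s <- shares / sum(shares)
  frac <- s[1] * rc_step(r, r1, w) + s[2] * rc_step(r, r2, w) +
    s[3] * rc_step(r, r3 - w, w)
  exp(log(peripheral) + (log(central) - log(peripheral)) * frac)
}

#' Ground-truth radial profiles of the synthetic retina
#'
#' @param r_mm Radial distance(s) from the map center in mm.
#' @param geometry A `retina_geometry`.
#' @return Data frame with `r_mm`, `ratio` (true Zea:Lut), `f_zea`
#'   (true zeaxanthin fraction), `total` (true total concentration,
#'   peripheral level = 1).
#' @export
retina_truth_profile <- function(r_mm, geometry = retina_geometry()) {
  ratio <- radial_staircase(r_mm, geometry$central_zea_lut_ratio,
                            geometry$peripheral_zea_lut_ratio, geometry,
                            shares = c(1, 1, 1) / 3)
  total <- radial_staircase(r_mm, geometry$central_to_peripheral_total_ratio,
                            1, geometry, shares = c(0.02, 0.68, 0.30))
  data.frame(r_mm = r_mm, ratio = ratio, f_zea = ratio / (1 + ratio),
             total = total)
}

#' Construct a spectral map object
#'
#' @param wavenumber Shared wavenumber axis (cm^-1).
#' @param intensity Matrix `n_pixels x n_bins` of intensity traces.
#' @param x_um,y_um Pixel-center coordinates (um), length `n_pixels`.
#'   For XZ maps `y_um` holds the depth coordinate.
#' @param nx,ny Grid dimensions (pixels are in x-major order:
#'   pixel index = `(iy - 1) * nx + ix`).
#' @param pixel_size_um Pixel pitch (um), length 1 or 2.
#' @param plane `"XY"` or `"XZ"`.
#' @param laser_nm 488 or 514.
#' @param metadata Free-form list.
#' @return A `spectral_map` object.
#' @export
spectral_map <- function(wavenumber, intensity, x_um, y_um, nx, ny,
                         pixel_size_um, plane = c("XY", "XZ"), laser_nm,
                         metadata = list()) {
  plane <- match.arg(plane)
  intensity <- as.matrix(intensity)
  if (nrow(intensity) != nx * ny) stop_data("intensity must have nx*ny rows")
  if (ncol(intensity) != length(wavenumber)) {
    stop_data("intensity must have one column per wavenumber bin")
  }
  if (any(pixel_size_um <= 0)) stop_config("field 'pixel_size_um' must be > 0")
  structure(list(wavenumber = as.numeric(wavenumber), intensity = intensity,
                 x_um = as.numeric(x_um), y_um = as.numeric(y_um),
                 nx = as.integer(nx), ny = as.integer(ny),
                 pixel_size_um = rep(as.numeric(pixel_size_um), length.out = 2),
                 plane = plane, laser_nm = as.numeric(laser_nm),
                 metadata = metadata),
            class = "spectral_map")
}

#' @export
print.spectral_map <- function(x, ...) {
  cat(sprintf("<spectral_map %s> %d x %d px @ %g um, %d bins, laser %g nm\n",
              x$plane, x$nx, x$ny, x$pixel_size_um[1],
              length(x$wavenumber), x$laser_nm))
  invisible(x)
}

# Pixel-center coordinate grid: origin at the lower-left pixel corner,
# centers at (i - 0.5) * pitch.
pixel_grid <- function(nx, ny, pitch_um) {
  ix <- rep(seq_len(nx), times = ny)
  iy <- rep(seq_len(ny), each = nx)
  list(x = (ix - 0.5) * pitch_um, y = (iy - 0.5) * pitch_um)
}

#' Simulate a macular Raman map
#'
#' Generates an XY spectral map whose per-pixel true Zea:Lut ratio and
#' total concentration follow the radial plateau-and-transition profiles
#' of [retina_truth_profile()]: central plateau at the configured central
#' ratio, peripheral plateau beyond the parafovea radius, and a total
#' concentration contrast of `central_to_peripheral_total_ratio` between
#' the macula and the periphery. Per-pixel spectra follow the same
#' mixture model as [synth_spectrum()].
#'
#' @param basis A `pigment_basis`.
#' @param geometry A `retina_geometry`.
#' @param laser_nm 488 or 514.
#' @param noise_sd Additive Gaussian noise sd (counts; 0 for noiseless).
#' @param concentration_scale Total concentration assigned to the
#'   peripheral plateau (the central plateau is `concentration_scale *
#'   central_to_peripheral_total_ratio`).
#' @param seed Optional seed.
#' @return List with `map` (`spectral_map`) and `truth` (data frame per
#'   pixel: `x_um`, `y_um`, `r_mm`, `f_zea`, `ratio`, `total`).
#' @export
synth_retina_map <- function(basis, geometry = retina_geometry(), laser_nm = 514,
                             noise_sd = 0.02, concentration_scale = 1,
                             seed = NULL) {
  pitch <- geometry$pixel_size
  n <- max(2L, round(geometry$map_extent * 1000 / pitch))
  grid <- pixel_grid(n, n, pitch)
  cx <- n * pitch / 2
  r_mm <- sqrt((grid$x - cx)^2 + (grid$y - cx)^2) / 1000
  prof <- retina_truth_profile(r_mm, geometry)
  total <- prof$total * concentration_scale
  f <- prof$f_zea
  s_l <- cross_section(basis, "lut", laser_nm)
  s_z <- cross_section(basis, "zea", laser_nm)
  B_l <- basis_profile(basis, "lut")
  B_z <- basis_profile(basis, "zea")
  # outer-product form of the synth_spectrum mixture model, all pixels at once
  inten <- (total * (1 - f) * s_l) %o% B_l + (total * f * s_z) %o% B_z
  if (noise_sd > 0) {
    inten <- inten + with_seed(seed, matrix(stats::rnorm(length(inten), 0, noise_sd),
                                            nrow = nrow(inten)))
  }
  map <- spectral_map(basis$wavenumber, inten, grid$x, grid$y, n, n,
                      pitch, "XY", laser_nm,
                      metadata = list(synthetic = TRUE, seed = seed,
                                      noise_sd = noise_sd,
                                      center_um = c(cx, cx)))
  truth <- data.frame(x_um = grid$x, y_um = grid$y, r_mm = r_mm,
                      f_zea = f, ratio = prof$ratio, total = total)
  list(map = map, truth = truth, geometry = geometry)
}

#' Simulate a Z-scan through the pigmented layer
#'
#' Generates an XZ spectral map in which both pigments share one Gaussian
#' depth profile (they occupy the same retinal structures); the local
#' zeaxanthin fraction along depth is set by `f_zea_profile`.
#'
#' @param basis A `pigment_basis`.
#' @param layer_center_um Depth of the layer maximum (um).
#' @param layer_fwhm_um Layer thickness as FWHM (um, > 0).
#' @param f_zea_profile Single fraction in \[0, 1\] or a function of
#'   depth (um) returning fractions.
#' @param laser_nm 488 or 514.
#' @param nx Number of lateral positions.
#' @param z_range_um Depth range scanned (um).
#' @param voxel_um Voxel pitch (um, default 1).
#' @param amplitude Peak total concentration of the layer.
#' @param noise_sd Additive Gaussian noise sd.
#' @param seed Optional seed.
#' @return List with `map` (`spectral_map`, plane XZ; `y_um` is depth)
#'   and `truth` (per-pixel data frame).
#' @export
synth_zscan <- function(basis, layer_center_um = 20, layer_fwhm_um = 8,
                        f_zea_profile = 0.5, laser_nm = 514, nx = 20,
                        z_range_um = 40, voxel_um = 1, amplitude = 1,
                        noise_sd = 0.01, seed = NULL) {
  if (layer_fwhm_um <= 0) stop_domain("layer_fwhm_um must be > 0")
  if (layer_center_um < 0) stop_domain("layer_center_um must be >= 0")
  if (voxel_um <= 0) stop_config("field 'voxel_um' must be > 0")
  nz <- max(2L, round(z_range_um / voxel_um))
  grid <- pixel_grid(nx, nz, voxel_um)
  z <- grid$y
  total <- amplitude * gauss_band(z, layer_center_um, layer_fwhm_um)
  f <- if (is.function(f_zea_profile)) f_zea_profile(z) else rep(f_zea_profile, length(z))
  if (any(f < 0 | f > 1)) stop_domain("f_zea_profile must stay in [0, 1]")
  s_l <- cross_section(basis, "lut", laser_nm)
  s_z <- cross_section(basis, "zea", laser_nm)
  inten <- (total * (1 - f) * s_l) %o% basis_profile(basis, "lut") +
    (total * f * s_z) %o% basis_profile(basis, "zea")
  if (noise_sd > 0) {
    inten <- inten + with_seed(seed, matrix(stats::rnorm(length(inten), 0, noise_sd),
                                            nrow = nrow(inten)))
  }
  map <- spectral_map(basis$wavenumber, inten, grid$x, z, nx, nz, voxel_um,
                      "XZ", laser_nm,
                      metadata = list(synthetic = TRUE, seed = seed,
                                      layer_center_um = layer_center_um,
                                      layer_fwhm_um = layer_fwhm_um))
  truth <- data.frame(x_um = grid$x, z_um = z, f_zea = f, total = total)
  list(map = map, truth = truth)
}
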