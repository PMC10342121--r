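# xanthomap

Quantitative mapping of the macular xanthophylls — lutein (Lut) and the
zeaxanthins (Zea + *meso*-Zea) — from two-laser resonance Raman
spectral images and polarized fluorescence-lifetime (FLIM) data, for
spectroscopists and retina researchers who need bias-corrected pigment
maps rather than raw band intensities.

The human macula concentrates xanthophylls ~100-fold relative to the
peripheral retina, with Zea:Lut ≈ 2 in the central foveola falling to
≈ 0.3 in the periphery. The pigments are distinguishable by their ν₁
C=C stretch Raman band (1526 cm⁻¹ for Lut, 1521 cm⁻¹ for the
zeaxanthins) and by their different resonance conditions under 488 nm
vs 514 nm excitation — but resonance enhancement biases the apparent
pigment fractions, so mapping requires calibration.

## What the package does

* **ν₁ deconvolution** — two-Gaussian fit of the ν₁ band; fractions
  from component areas:
  `raw = A_zea / (A_zea + A_lut)`, corrected by relative Raman
  cross-sections `s`: `(A_zea/s_zea) / (A_zea/s_zea + A_lut/s_lut)`.
* **CLS unmixing** — non-negative classical least squares of whole
  spectra onto pure references.
* **Calibration** — Fig-4-style validation dependencies from mixture
  dilution series (per-level mean ± SD, OLS line through level means)
  and empirical inversion of the resonance bias.
* **Mapping** — per-pixel pigment images, FWHM (mixture broadening)
  images, radial profiles, fixed or data-driven
  foveola/fovea/parafovea segmentation, in-plane cross-sections and
  Z-scan layer profiles.
* **FLIM** — Poisson-MLE biexponential TCSPC fitting (16 ps bins),
  short-lifetime amplitude fraction, anisotropy
  `r = (I∥ − G·I⊥)/(I∥ + 2G·I⊥)`, photoselection sector statistics of
  axon cross-sections, laser-power trends.
* **Synthetic data** — generators for basis spectra, mixture series,
  radially structured macular maps, Z-scans and oriented-dipole axon
  images, each with ground-truth records, so the entire pipeline is
  testable without instrument data.
* **I/O + CLI** — plain-text spectrum/map formats, text FLIM
  containers, JSON calibration curves, a YAML-configured
  `run_pipeline()` with a checksummed manifest, and a thin
  `inst/cli/xanthomap` command-line wrapper
  (`simulate | preprocess | unmix | calibrate | map | flim | run`).

## Worked example

```r
library(xanthomap)

basis <- make_default_basis()

# 1. calibrate the 514 nm resonance bias from a simulated mixture series
series <- synth_mixture_series(basis, laser_nm = 514, n_levels = 11,
                               n_reps = 10, seed = 1)
curve <- build_calibration(series, estimator = "nu1")
print(curve)

# 2. simulate a 1.5 x 1.5 mm macular map at 25 um pixels and unmix it
geometry <- retina_geometry(map_extent = 1.5, pixel_size = 25)
sim <- synth_retina_map(basis, geometry, laser_nm = 514, seed = 7)
pigments <- map_pixelwise(preprocess_map(sim$map), calibration = curve)

# 3. segment the macula and report regional statistics
center <- find_center(pigments)
seg <- segment_regions(pigments, center, mode = "fixed")
stats <- region_ratios(pigments, seg)
```

Output:

```
<calibration_curve> nu1 estimator, 514 nm, 11 levels
  mean-estimated = 0.129 + 0.950 * true, R^2 = 0.9656
<pigment_map> 60 x 60 px, nu1 estimator (calibrated), 100.0% valid
     region    n mean_ratio mean_total
1   foveola  154  2.0716533 99.3086413
2     fovea 1112  1.1260438 92.9241668
3 parafovea 2310  0.8318269 13.4369977
4   outside   24  0.3039646  0.9668568
center-to-periphery concentration contrast: 96.9
```

The validation line shows the zeaxanthin overrepresentation at 514 nm
(intercept 0.13: even pure-lutein mixtures read as partly zeaxanthin
before correction) with R² = 0.97 on the level means. After inversion
through the empirical curve, the mapped regional ratios recover the
generator's truth — 2.07 vs 2 in the foveola, 0.30 vs 0.3 outside the
parafovea — and the mean concentration inside the fovea is ~97× the
peripheral level.

The methods vignette (`vignettes/xanthophyll-mapping.Rmd`) documents
the spectral model, the calibration and its inversion, the synthetic
retina's geometry, all tunable parameters with their defaults, and the
package's design decisions and limitations.

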