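---
title: "Mapping macular xanthophylls: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping macular xanthophylls: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xanthomap)
```

## The problem

The human macula concentrates the xanthophylls lutein (Lut) and the
zeaxanthins (Zea and its *meso* isomer, treated jointly throughout this
package) roughly a hundred-fold relative to the peripheral retina, with
the Zea:Lut concentration ratio around 2 in the central foveola and
around 0.3 in the periphery. Resonance Raman microscopy can map both
pigments because their strongest band — the ν₁ C=C stretch — sits at
1526 cm⁻¹ for Lut and 1521 cm⁻¹ for the zeaxanthins, and because the
two standard argon laser lines sample different resonance conditions:
488 nm lies in Lut's 0-0 absorption band, while 514 nm is essentially
outside Lut's absorption but still inside the zeaxanthin absorption.
The price of resonance enhancement is a *resonance bias*: the share of
the Raman signal attributable to each pigment is not its concentration
share. xanthomap implements the full chain needed to go from raw
spectral maps to bias-corrected pigment images, plus the polarized FLIM
analysis used to interrogate xanthophyll orientation in single axon
membranes.

## Spectral model and unmixing

Each pigment contributes a sum of Gaussian bands
$G(\nu) = A\,e^{-(\nu-c)^2/2\sigma^2}$ with
$\mathrm{FWHM} = 2\sqrt{2\ln 2}\,\sigma$. A mixture spectrum at laser
$L$ is

$$ y(\nu) = C\,[\,f\,s_{zea,L}\,B_{zea}(\nu) + (1-f)\,s_{lut,L}\,B_{lut}(\nu)\,] $$

where $C$ is total concentration, $f$ the zeaxanthin mole fraction,
$s_{p,L}$ the relative resonance Raman cross-sections and $B_p$ the
unit band profiles. Two estimators recover $f$:

* **ν₁ deconvolution** (`fit_nu1_gaussians()`): a two-Gaussian fit in a
  ±40 cm⁻¹ window around the band maximum. Fractions come from
  component *areas* ($A\sigma\sqrt{2\pi}$), the
  concentration-meaningful quantity, not peak heights.
* **CLS** (`cls_fit()`): the whole spectrum regressed onto pure
  reference spectra with non-negative coefficients (concentrations
  cannot be negative) and an optional flat/linear nuisance background.
  The constrained solve is an exact active-set on top of the QR
  solution.

The raw fraction $A_{zea}/(A_{zea}+A_{lut})$ is resonance-biased; the
cross-section-corrected form divides each area by $s_{p,L}$ first.

**Center constraints.** The two ν₁ components sit only 5 cm⁻¹ apart
with ~14 cm⁻¹ widths. If the component centers are left free (even
within ±3 cm⁻¹ bounds), the model is practically unidentifiable at
realistic noise: in a 200-replicate simulation at 2% noise and
$f = 0.3$ the free-center fit returns a corrected fraction of
0.35 ± 0.34 (fits collapse onto a single component), while fixing the
centers at the pure-component positions — which are known exactly from
pure references — returns 0.2998 ± 0.027. The package therefore fixes
the centers by default (`center_tol = 0`); bounded centers remain one
argument away for instruments with wavenumber drift.

## Calibration of the resonance bias

`build_calibration()` reproduces the validation-dependency protocol: a
dilution series of known mixtures is measured repeatedly, the estimated
fraction is averaged per level, and an ordinary least-squares line is
fit through the level means (R² is reported on the means, matching how
averaged validation points are presented). `invert_calibration()` then
maps raw fractions back to the true-fraction scale by monotone
piecewise-linear interpolation of the *empirical* mean curve — not the
fitted line — so any curvature of the dependency survives the
inversion. Curves are tagged with their estimator and laser; applying a
curve to data from another laser is an error, and mixtures measured in
solvent are not assumed to transfer to tissue (curves carry provenance
metadata instead).

The calibration also records the mean ν₁ signal per unit concentration
at each level (the *response curve*). During mapping, each pixel's band
area is divided by the response interpolated at its corrected fraction,
which converts signal to concentration without assuming the
cross-sections are known — only that the calibration mixtures are on a
known concentration scale.

## The synthetic retina

Because donor-retina data cannot be regenerated at desk scale, every
stage is exercised against a synthetic generator whose truth records
make recovery measurable.

* **Basis** (`make_default_basis()`): ν₁ at 1526/1521 cm⁻¹ (FWHM
  14 cm⁻¹), plus the literature-typical secondary carotenoid bands ν₂
  (1157 cm⁻¹) and ν₃ (1008 cm⁻¹) so full-spectrum CLS is
  non-degenerate. Cross-section defaults
  ($s_{lut} = 1.0/0.5$ and $s_{zea} = 1.15/1.0$ at 488/514 nm) were
  chosen once so that simulated validation curves reproduce the
  observed behavior: zeaxanthin overrepresented at both lasers,
  strongest at 514 nm, with validation R² inside the reported
  0.93–0.99 range (they come out at 0.998 and 0.966). A 14 cm⁻¹
  component width against a 5 cm⁻¹ center separation produces the
  visible mixture broadening of the ν₁ band that the FWHM map exploits.
* **Radial geometry** (`retina_geometry()`): foveola/fovea/parafovea
  disks of 0.35/1/2 mm. Both the Zea:Lut ratio (2 → 0.3) and the total
  concentration (100 → 1) follow log-space staircases with
  raised-cosine transitions of width 0.15 mm. The foveola and fovea
  steps *start* at their boundary radii — so each disk is a clean
  plateau and the curvature extremum used by data-driven segmentation
  sits exactly on the boundary — while the outermost step *ends* at the
  parafovea radius, so everything beyond it is a pure peripheral
  plateau. The total-concentration contrast is split (2%, 68%, 30% of
  the log contrast) across the three steps: the ~100-fold figure
  describes the macula (the fovea disk) against the periphery, so the
  high plateau spans the fovea and the foveola boundary appears as a
  subtle but detectable shoulder. Ratio steps use equal log shares.
* **Noise**: additive Gaussian with `noise_sd = 0.02` by default (2% of
  the unit-concentration ν₁ peak), a realistic EMCCD read-noise level
  for 50 ms acquisitions; Poisson photon statistics are available as an
  option. Cosmic rays are injected as single-bin spikes of 20–100× the
  signal maximum.
* **Z-scans** (`synth_zscan()`): both pigments share one Gaussian layer
  profile along depth at 1 µm voxel pitch — the pigments occupy the
  same retinal structures and differ only in amount.
* **FLIM axons** (`synth_axon_flim()`): an annulus of pixels whose
  transition dipoles lie in the image plane along the radial
  (transmembrane) or tangential direction. Horizontal excitation
  selects dipoles with probability ∝ cos²θ and the fixed emission
  dipole splits detection cos²θ : sin²θ between polarization channels.
  This fixed-in-plane model is a deliberate simplification — with no
  3D wobble or depolarization the anisotropy reaches 1 at the poles
  instead of the 0.4 limit of isotropic 3D photoselection — which makes
  the sector contrast maximally legible while leaving the formula
  arithmetic untouched. Decays are two-exponential mixtures with
  amplitude fraction `f_short`; the defaults τ = 70/2500 ps and
  `f_short = 0.6` are plausible values for carotenoid-dominated versus
  matrix fluorescence (no lifetimes are printed for the original
  system, so these are free generator parameters and only qualitative
  claims — power invariance, sector contrast — are meaningfully
  testable). Counts are Poisson, binned at 16 ps, with arrival times
  drawn from the range-truncated exponentials so every drawn photon
  lands in the histogram.

What the generator does *not* emulate: instrument optics (pinhole PSF,
spectrograph dispersion), instrument response convolution in time,
wavenumber miscalibration, detector saturation, tissue autofluorescence
backgrounds, or a separate *meso*-zeaxanthin component (the two
zeaxanthins are never separated spectroscopically here). Passing tests
therefore demonstrate correctness of the estimators under the stated
statistical model, not robustness to every artifact of real tissue
data.

## Preprocessing

* **Cosmic rays** (`remove_cosmic_rays()`): modified z-score of the
  centered second difference, applied greedily (largest spike first,
  replaced by the local median of unflagged neighbors, statistic
  recomputed) so adjacent spikes are caught sequentially. A flagged bin
  must also exceed the local median level by more than 100% — cosmic
  rays are many-fold the local signal — which keeps smooth noiseless
  bands untouched. Threshold 8, window 5 bins; the procedure is
  idempotent.
* **Baseline** (`correct_baseline()`): asymmetric penalized least
  squares (second-difference penalty λ = 1e5, asymmetry p = 0.01)
  followed by an iterated masked re-smoothing: points more than 3 noise
  SDs above the current baseline are excluded and the penalized smooth
  is refit until the mask stabilizes. The refinement removes the
  residual upward pull that band tails exert on the plain asymmetric
  solution (band-area error on a ramp background drops from ~3% to
  <0.01%). The pentadiagonal solve is O(n) compiled code. A robust
  polynomial alternative (degree ≤ 5) is provided.
* **Crop**: analysis is restricted to 800–1800 cm⁻¹.

## Mapping and segmentation

`map_pixelwise()` fits every pixel independently (failures are masked,
never interpolated; >20% failures abort with a map-quality error) and
assembles lutein, zeaxanthin, total, fraction and FWHM images.
Coordinates are continuous µm with the origin at the lower-left pixel
corner and centers at $(i-0.5)\cdot\text{pitch}$. Regional Zea:Lut
ratios are ratios of regional means — dividing pixel-wise would amplify
noise where lutein is weak. Radial profiles are pixel-count-weighted
annulus means.

Data-driven segmentation detects boundaries at the largest-magnitude
minima of the second derivative of the Gaussian-smoothed log radial
total profile, then refines each detected drop to its *onset*: the
point where the slope has decayed to 10% of its peak within that drop,
found by walking back from the steepest-descent point. The refinement
matters because smoothing and discretization displace the raw curvature
minimum into the transition by roughly the kernel width (~30 µm at
10 µm pitch with the earlier 3-bin kernel — enough to misplace the
0.35 mm foveola by ~0.06 mm); with onset refinement and the default
2-bin kernel the noiseless analytic error is under 0.01 mm while
detection stays robust to 1% profile noise. At coarse profile pitches
the kernel should be reduced so the physical smoothing window stays
well under the 0.15 mm transition width; the boundary estimate is
resolution-limited to roughly one bin.

The "relative zeaxanthin distribution" view of a map is the FWHM image
itself (in cm⁻¹): mixture broadening of ν₁ is monotone in the signal
split between the components, so the image is exported as-is rather
than rescaled into concentration units, for which no published mapping
exists.

## FLIM analysis

Decays are tail-fit (window starting two bins after the peak; no IRF
deconvolution, as no IRF is available) by Poisson maximum likelihood
with deterministic initialization from log-linear tail slopes. Fitted
per-bin count amplitudes are converted to continuous amplitudes at the
histogram origin — undoing the window offset and bin integration —
before the short-lifetime fraction
$f_{short} = a_s/(a_s + a_l)$ is formed; without that conversion the
tail fit underestimates the short amplitude by
$e^{-t_{start}/\tau_s}$, a ~25% effect at the defaults. `f_short` is
the *amplitude* (population) fraction, the conventional reading of "the
fraction of the short-lifetime component"; the intensity-weighted
variant is computable from the returned amplitudes and lifetimes. A
two-component fit is flagged degenerate when the lifetimes are within
10% or the short lifetime falls below the 16 ps bin width
(sub-resolution components have meaningless extrapolated amplitudes).

Anisotropy is $r = (I_\parallel - G I_\perp)/(I_\parallel + 2 G
I_\perp)$, computed from time-integrated per-pixel channel counts
(time-resolved $r(t)$ is out of scope); $G$ is an instrument input,
embedded in synthetic datasets. Sector statistics pool photons in four
axis-centered quadrant sectors of an annulus and report the
left+right : top+bottom mean-intensity contrast, the photoselection
signature of transmembrane pigment orientation. `power_trend()` fits a
weighted least-squares line of `f_short` against laser power; a 95%
slope CI containing zero is the quantitative form of "scanning
intensity does not reorient the probed pool".

## Numerical choices and degenerate inputs

* ν₁ fit: deterministic 3 widths × 3 amplitude-split start grid
  (seedless); best SSE wins, ties break toward the smaller zeaxanthin
  amplitude. Single moment-based starts (`multi_start = FALSE`) are the
  mapping default — on windows of ~80 bins they agree with the grid to
  numerical precision on clean data and are ~10× faster.
* Flat spectra fail band location with an explicit error; both-zero
  areas raise an undefined-fraction error; empty regions are reported
  missing rather than as zeros.
* Calibration inversion requires a monotone mean curve and instructs
  pooling otherwise; endpoints map to endpoints and output is clamped
  to [0, 1].
* Map problem sizes used in the package's own end-to-end checks: a
  1.5 × 1.5 mm field at 10 µm pixels (150 × 150 ≈ 22,500 spectra) for
  regional recovery, coarser 40 × 40 fields for unit tests — both carry
  the full radial structure, only sampled at different pitch.

## Known limitations

* Calibration transfers across matrices (solvent → tissue) are tagged,
  not modeled.
* The two-reference CLS cannot separate *meso*-zeaxanthin from
  zeaxanthin; adding a third reference is mechanically possible but
  untested against truth.
* Region ratio accuracy near the periphery of small fields rests on few
  pixels (the corners of a 1.5 mm field beyond the 1 mm parafovea
  radius); larger fields sharpen it.
* The FLIM dipole model omits 3D orientation distributions; measured
  anisotropies in tissue will not reach the synthetic extremes.
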