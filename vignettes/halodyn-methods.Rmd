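---
title: "halodyn: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{halodyn: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halodyn)
```

halodyn is an analysis chain for quantitative live-cell fluorescence
microscopy of haloarchaeal cells expressing a GFP-tagged DNA-repair
protein, built around four measurement models — focus quantification in
wide-field images, FRAP kinetics, number-and-brightness (N&B) fluctuation
analysis, and sedimentation-derived hydrodynamics — plus a synthetic-data
generator that emulates the acquisitions with known ground truth. This
vignette explains each model, its assumptions, the tunable parameters, and
the design choices made where the underlying workflow left the design open.

## The synthetic world

Every quantitative claim the test suite makes is conditional on the
generator's stated world, so its defaults are fixed once and documented
here.

**Cell geometry.** Cells are pleiomorphic: each is a randomly deformed
ellipse (axis ratio uniform on 1–2.2, plus Fourier boundary harmonics of
orders 2–5 with s.d. 0.06) whose pixelised area is calibrated to a Gaussian
target distribution, by default 28 ± 6 µm² — the population mean and s.d.
of untreated rod/disc-shaped *Haloferax volcanii* cells. The recorded
ground-truth area is the rasterised pixel area (exact by construction,
within one pixel of the Gaussian draw). Cells are placed without overlap
and with a PSF-radius margin from the field border; a field that cannot
hold the request reports the shortfall, and an impossible request is an
error.

**Imaging model.** A frame is a Poisson draw of
`background + PSF * (pool molecules + foci)`. Pool molecules (default
2000/cell at 5 photons/molecule/frame) are binned to their nearest pixel
and blurred with a truncated, renormalised Gaussian PSF (sigma 0.15 µm), so
a noiseless frame conserves photons exactly — the basis of a conservation
test. Molecules perform Brownian steps of per-axis variance `2 D dt`
(default D = 1 µm²/s, inside the 0.8–2.3 µm²/s apparent range measured for
the tagged protein); steps ending outside the cell are mirrored across the
current position, and a molecule whose mirrored step is also outside stays
put for that frame — an approximation to reflecting boundaries that is
exact to first order in step length. Foci are immobile single-PSF point
sources of `focus_brightness_multiple` (default 100) molecule-equivalents;
counts per cell are Poisson (default mean 2.0, the untreated-condition
average), and foci within one cell keep a minimum mutual distance of one
spot diameter (0.75 µm) because the focus *count* being emulated refers to
optically resolvable spots — two emitters inside one diffraction-limited
spot are one focus in principle, not a detection failure.

**What the generator does not emulate**: 3-D optics (single-plane PSF
only), detector afterpulsing or read noise (photon counting assumed),
autofluorescence texture, cell motility and division, anomalous diffusion.
A green recovery test therefore establishes correctness of the estimators
under shot noise and diffusion, not robustness to every real-world
artifact.

**FRAP traces** are simulated at trace level (the fits being emulated
operate on normalized traces): `n_prebleach` frames at unity, then
`F(t) = F_inf − sum_i a_i exp(−k_i t)` with `t = 0` at the first
post-bleach frame, Gaussian noise, and optionally a slow exponential
acquisition-bleaching envelope applied to the raw-scale trace. The bleach
depth is `sum(a_i)/(1 − immobile_fraction)`; the default world uses a full
bleach (depth 1) since the emulated experiments do not report their depth.

**N&B stacks** use the fast-diffusion limit: per frame and pixel the
occupancy is Poisson(`n_true`) and detected counts are
Poisson(`occupancy × epsilon_true + background`), frames independent. The
resulting counts are compound-Poisson with mean `n ε` and variance
`n ε (1 + ε)` plus background, so the apparent brightness at zero
background is exactly `1 + ε` — the analytic oracle used by the moment
tests.

## Segmentation and focus quantification

The pipeline mirrors a parameterised commercial workflow: Gaussian
smoothing (the 1.5 µm "smooth filter width" is taken as twice the Gaussian
sigma — the sigma convention is fixed here and matters only as a
definition), suppression of sub-sphere structure with a 1 µm disc
(morphological opening), Otsu thresholding, connected components, and
seeded watershed splitting with seeds at local maxima separated by at
least one seed diameter (2 µm; 4 µm is appropriate for enlarged
replication-arrested cells).

Two choices deserve emphasis:

* **The background ball.** A classic rolling-ball *residual* (image minus
  opening) with a 1 µm ball erases every object larger than 1 µm —
  including all cells. Whatever the original proprietary implementation
  did, the only reading of "1 µm background subtraction sphere" consistent
  with detecting ~6 µm cells is that the sphere sets the scale of
  *removed* small structure; the opened image is therefore what gets
  thresholded. Focus detection, as specified, uses no background
  subtraction at all.
* **Per-cell boundary refinement.** Cells carrying the same fluorophore
  pool in different areas have different interior brightness, and a single
  global threshold misplaces the boundary of atypically bright or dim
  cells (>10% area error in testing). Each label is therefore
  re-thresholded at the half-maximum between the field background and its
  own interior (75th percentile) level, within its own territory; a
  refinement never annexes another cell's pixels, so watershed splits
  survive. With this step, recovered areas match ground truth to a few
  percent.

Foci are detected on the unsmoothed image with a scale-normalised
difference-of-Gaussians band-pass tuned to the 0.75 µm spot diameter
(`sigma = d/(2*sqrt(2))`, DoG ratio 1.6); the "quality" of a focus is the
filter response at its maximum. There is deliberately **no automatic
threshold**: the emulated workflow used a manually chosen quality cutoff,
so `detect_foci()` requires one, and `calibrate_quality_threshold()`
reproduces the manual choice objectively by placing the cutoff between the
weakest true-spot responses and the strongest spurious responses on a
held-out synthetic field. Population statistics are totals-over-totals
ratios (not means of per-cell ratios), which makes
`mean_intensity_per_surface × average_cell_surface =
mean_intensity_per_cell` an exact identity.

## FRAP normalization and fitting

The ROI trace is background-corrected and divided by a reference trace:
an exponential `c0 + a·exp(−λt)` fitted to the background-corrected
pre-bleach frames and extrapolated over the acquisition, which removes
slow acquisition bleaching and makes the pre-bleach level exactly one.
`(I_raw − I_b)/I_sb` is the unique normalization consistent with a
background-corrected reference and unit pre-bleach intensity. If the
pre-bleach fit fails (flat segment) the pre-bleach mean is used and the
trace flagged. Normalization is scale-invariant, so fitted parameters do
not depend on detector gain.

Recovery is fitted on the post-bleach segment as
`F(t) = plateau − sum a_i exp(−k_i t)` by bounded nonlinear least squares
(`nls`, port algorithm; log-linear start for the mono rate, fast/slow
split start for the bi model). The time origin is the first post-bleach
frame and the plateau is free (recovery percentages are reported at finite
time, implying an unconstrained plateau). 95% CIs come from the asymptotic
covariance; a seeded residual bootstrap is available as a cross-check
because the emulated analysis does not state its CI method. Bi-exponential
components are ordered fast-then-slow; the slow fraction
`a_slow/(a_fast + a_slow)` is defined over the mobile (recovering)
amplitudes only and its CI uses the delta method. Fits with an amplitude
CI crossing zero, or with `k_fast/k_slow < 3` (where exponential
components are notoriously non-identifiable), are flagged ambiguous.
Derived quantities: `tau_1/2 = ln(2)/k` and `D = β·A/(4·tau_1/2)` with
β = 1 (confocal) and the bleached area A = 3.72 µm² by default.

One known inconsistency in the emulated source is documented rather than
reproduced: its printed slow-phase diffusion range does not follow from
`D = A·k/(4 ln 2)` applied to its printed slow-rate CI with A = 3.72 µm²;
the discrepancy is consistent with propagating the ±1.95 µm² uncertainty
in A. halodyn computes D from whatever k and A it is given and takes no
position on that range.

## Number and brightness

Per-pixel temporal mean and *population* variance (divide by the number of
frames — the fluctuation-spectroscopy convention) feed the photon-counting
N&B maps: apparent number `N = ⟨I⟩²/σ²`, apparent brightness
`B = σ²/⟨I⟩`, molecular number `n = ⟨I⟩²/(σ² − ⟨I⟩)` and molecular
brightness `ε = (σ² − ⟨I⟩)/⟨I⟩`. There are no detector offset or readout
terms because the acquisitions being emulated used avalanche photodiodes
in single-photon-counting mode. Pixels at or below the shot-noise floor
(`σ² ≤ ⟨I⟩`, e.g. empty or immobile-only pixels) carry no molecular
signal: they are masked `NA`, never silently zero. `B = 1 + ε` and
`n·ε = ⟨I⟩` hold to machine precision on valid pixels, and scaling counts
by a gain g scales B by g — asserted in the tests as a documented hazard,
since it is why uncalibrated analog detection cannot be fed to these
formulas. ROI summaries report mean ± SEM over valid pixels (ROIs with
fewer than 4 valid pixels are excluded with a flag) and brightness
normalized to a reference ROI, the per-cell diffuse-pool region, since the
original normalizer is unstated. A drift screen (cross-correlation of the
first- versus last-quartile average images) automates the exclusion of
visibly moving cells; no detrending is applied before the moments, as none
is stated in the emulated method.

## Hydrodynamics

Small closed-form calculators: oligomer stoichiometry
(measured/monomer mass, flagged if >0.15 from an integer),
`R_h = (f/f0)·(3Mv̄/(4πN_A))^(1/3)`, the s20,w buffer correction
`s·(η_b/η_20,w)·(1 − v̄ρ_20,w)/(1 − v̄ρ_b)` with a flotation guard, and the
Stokes–Einstein size factor `m^(1/3)`. The partial specific volume v̄ is a
required input with documented default 0.73 ml/g (the canonical protein
average): the emulated study computed v̄ from sequence but does not print
it, and its printed quantities are internally consistent only with
different v̄ values (its s20,w pair implies ≈0.788 ml/g, its hydrodynamic
radius ≈0.73 ml/g) — so no single value is hard-coded as truth, and the
tests carry a root-finding oracle for the implied v̄ instead.

## Numerical choices

* Otsu's threshold is computed on a 256-bin histogram of the image's own
  range, making segmentation invariant under uniform intensity scaling.
* Connected components and the seeded watershed are iterative label
  propagations (4-neighbourhood); the watershed floods in 64 quantised
  intensity levels from high to low, which splits touching cells along
  intensity valleys deterministically (ties resolved by the highest
  neighbouring label, a fixed raster-order convention).
* The exponential fits bound all rates and amplitudes below by zero;
  non-convergence is an explicit error carrying the optimizer message, not
  a silent NA.
* TIFF I/O is a deliberately minimal baseline implementation
  (little/big-endian, uncompressed, grayscale, 8/16/32-bit unsigned and
  32-bit float, multi-page) written for this package because no TIFF
  reader exists in the supported R stack; it rejects RGB and compressed
  input with explicit messages and was cross-validated against an
  independent Python TIFF library.
* All simulation entry points take a single integer seed, recorded in the
  emitted ground truth; identical configuration and seed reproduce
  bit-identical stacks.

## Limitations

Segmentation assumes a bimodal intensity histogram (cells on a darker
field) and will mis-threshold fields that are empty except for noise; the
focus detector's quality scale depends on the image's intensity units, so
thresholds calibrated on one acquisition setting do not transfer to
another; the FRAP model is the semiquantitative sum-of-exponentials
description, not a reaction–diffusion PDE; and the N&B implementation
deliberately omits analog-detector corrections and cross-correlation
variants.
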