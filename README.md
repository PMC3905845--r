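# halodyn

Quantitative analysis of live-cell fluorescence microscopy for archaeal
DNA-repair dynamics under replication arrest — and the synthetic data to
test every stage of it.

## The problem

When DNA replication forks stall, repair endonucleases such as Hef in
*Haloferax volcanii* concentrate into diffraction-limited fluorescent
foci. Quantifying that response from microscopy takes four measurement
models, each with its own statistics:

* **Focus quantification** — segment pleiomorphic cells in calibrated
  wide-field images, detect sub-resolution foci, and summarise a
  population (foci per cell, intensity fraction in foci, 0–20 foci
  histogram) with totals-over-totals ratios.
* **FRAP kinetics** — normalize recovery traces so the pre-bleach level is
  unity, fit `F(t) = plateau − Σ aᵢ e^(−kᵢt)` (mono or bi-exponential)
  with 95% CIs, and derive `τ₁/₂ = ln 2 / k` and the apparent diffusion
  coefficient `D = βA/(4τ₁/₂)` for a bleached area A.
* **Number & brightness (N&B)** — from the per-pixel temporal mean ⟨I⟩ and
  variance σ² of a photon-counting time series: apparent brightness
  `B = σ²/⟨I⟩`, molecular brightness `ε = B − 1` (shot noise removed) and
  molecular number `n = ⟨I⟩/ε`, distinguishing oligomerisation at foci
  from the diffusing pool.
* **Hydrodynamics** — the downstream arithmetic of sedimentation velocity:
  oligomer stoichiometry, `s₂₀,w` buffer correction,
  `R_h = (f/f₀)·(3Mv̄/4πN_A)^{1/3}` and Stokes–Einstein size scaling.

Because the underlying experiments deposited no raw data, the package
ships a first-class simulator (`sim_config()`, `make_cell_geometry()`,
`simulate_timelapse()`, `simulate_frap_traces()`, `simulate_nandb_stack()`)
that emulates the acquisitions — Poisson photon statistics, Brownian pool,
immobile PSF-sized foci — with recorded ground truth, so every estimator
is tested by parameter recovery.

## Worked example

```r
library(halodyn)

cfg  <- sim_config(image_shape = c(300, 300))     # 207 nm px, 28±6 um^2 cells
geom <- make_cell_geometry(cfg, n_cells = 12, seed = 42)
img  <- get_frame(simulate_timelapse(geom, cfg, n_frames = 1, seed = 42)$stack, 1)

labels <- segment_cells(img, pixel_size_um = cfg$pixel_size_um)
thr    <- calibrate_quality_threshold(img, geom$foci,
                                      pixel_size_um = cfg$pixel_size_um)
foci   <- detect_foci(img, labels, pixel_size_um = cfg$pixel_size_um,
                      quality_threshold = thr)
population_summary(per_cell_metrics(img, labels, foci,
                                    pixel_size_um = cfg$pixel_size_um))
#> population of 12 cells
#>   average cell surface      25.56 um^2
#>   mean intensity per cell   1.606e+04
#>   mean intensity / surface  628.2 per um^2
#>   mean foci per cell        1.75
#>   mean focus intensity      691.7
#>   intensity fraction in foci 0.075
```

The detected 1.75 foci/cell compares with the generator's truth of 1.67
for these 12 cells (20 foci drawn from Poisson(2)). A replication-arrest
FRAP ensemble, fitted bi-exponentially:

```r
ens <- simulate_frap_traces(c(2.75, 0.24), c(0.3195, 0.1698),
                            immobile_fraction = 0.5107,
                            noise_sd = 0.03 * sqrt(26), n_traces = 26,
                            config = sim_config(), seed = 42)
fit_recovery(average_traces(ens$traces), model = "bi")
#> bi-exponential FRAP fit (100 post-bleach samples, rmse 0.0275)
#>   fast k = 2.324 s^-1 [95% CI 0.869-3.779], a = 0.303, tau1/2 = 0.298 s, D = 3.12 um^2/s
#>   slow k = 0.339 s^-1 [95% CI 0.114-0.563], a = 0.151, tau1/2 = 2.046 s, D = 0.45 um^2/s
#>   plateau = 0.477
#>   slow fraction of mobile pool = 33.2% [95% CI 10.5-55.9]
```

Both simulated rates (2.75 and 0.24 s⁻¹) and the slow fraction (34.7%)
are recovered within their intervals. The hydrodynamics calculator
reproduces the sedimentation-derived radius of the Hef dimer:

```r
hydrodynamic_radius(mass_kda = 184.5, f_ratio = 1.76, vbar = 0.73)
#> [1] 6.62734   # nm
```

A command-line front end covers the same stages:

```sh
Rscript inst/scripts/halodyn foci --input field.tif --pixel-size-um 0.207 --quality 10
Rscript inst/scripts/halodyn hydro --monomer-mass 93.95 --measured-mass 184.5
```

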