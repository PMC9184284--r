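# nanoscatter

Label-free single-molecule characterization in nanofluidic channels, in R.

Nanofluidic scattering microscopy images unlabeled biomolecules while they
diffuse inside a nanochannel etched in silica: the interference between the
light scattered by the channel and by the molecule turns each molecule into
a dark, diffraction-limited dip travelling along a kymograph (a time ×
position map of relative contrast). Two numbers characterize every tracked
molecule:

- **Molecular weight** from the *integrated optical contrast* (iOC), the
  dip's contrast integrated along the channel axis (units of nm):

  MW = iOC · A / (n̄ · a)

  with A the channel cross-section (nm²),
  n̄ = (1.5 n_m² + 0.5 n_w²)/(n_m² − n_w²) the contrast factor of the
  filled channel (≈ −10.25 for water in silica) and a = 0.46 Å³/Da the mass
  polarizability constant of proteins.

- **Hydrodynamic (Stokes) radius** from the diffusivity D estimated with
  the covariance-based estimator (CVE)

  D = ⟨Δx²⟩/(2Δt) + ⟨Δxₙ Δxₙ₊₁⟩/Δt,

  inverted through the confinement-corrected Stokes–Einstein relation
  R_s = K(R_s/r) · k_B T / (6πη D), where K(λ) is the hindrance factor of
  a sphere in a pore of equivalent radius r = √(A/π). Because K depends on
  R_s, the inversion solves an implicit equation by bisection.

The package provides both directions of this analysis:

- a **forward simulator** — Brownian dynamics (optionally with drift and
  transient wall binding) rendered into kymographs with the correct
  contrast physics, line-spread blur, motion blur, pixelation and camera
  noise, with full ground truth;
- the **inverse pipeline** — background estimation and normalization,
  multi-scale matched-filter detection with subpixel localization,
  trajectory linking with transient-binding exclusion, per-trajectory
  (iOC, D) → (MW, R_s) conversion, and population statistics (N-weighted
  histograms, Gaussian fits, FWHM resolution).

It is aimed at anyone developing or teaching kymograph-based
single-particle analysis: the simulator defines controlled truth, the
pipeline measures how well it can be recovered.

## Worked example

Simulate thirty independent recordings of BSA (66 kDa, literature
R_s = 3.5 nm) in a 100 × 27 nm channel at 200 frames per second and
0.005 % noise, run the full analysis, and fit the populations:

```r
library(nanoscatter)

st <- nsm_study(species_spec("BSA", mw = 66, r_s = 3.5),
                channel_geometry("I"), n_traj = 30, n_frames = 500,
                seed = 7)
fit_population(population_histogram(st$estimates, "mw_kDa"))
#>     center     sigma     fwhm     area
#> 1 66.87183 0.5835495 1.374154 0.889168
fit_population(population_histogram(st$estimates, "rs_nm"))
#>    center    sigma      fwhm      area
#> 1 3.50782 0.421902 0.9935034 0.9665302
```

The fitted mass population is centered at 66.9 kDa (truth 66) with a FWHM
resolution of 1.4 kDa under these idealized conditions, and the radius
population at 3.51 nm (truth 3.5). `st$estimates` holds the per-trajectory
values (`ioc_nm`, `D_um2_s`, `mw_kDa`, `rs_nm`, statistical weight
N/ΣN and quality flags); `scatter_report()` draws the MW–R_s scatter with
population ellipses and the globular scaling line R_s = 0.88·MW^(1/3).

A YAML-driven run producing TIFF/CSV/JSON artifacts:

```r
run_pipeline(read_run_config(system.file("examples", "channel1_bsa.yaml",
                                         package = "nanoscatter")),
             out_dir = "results")
```

and the same stages are scriptable from a shell via
`Rscript inst/cli/nsm.R simulate|preprocess|track|estimate|report|run`.

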