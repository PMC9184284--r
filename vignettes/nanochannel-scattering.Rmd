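---
title: "Models and methods behind nanoscatter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nanoscatter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(nanoscatter)
```

This vignette documents the physical models, the estimators, the numerical
choices and the known limitations of the package — the information a
maintainer or a careful user needs to judge what the package's results do
and do not mean.

## The measurement principle

A biomolecule diffusing inside a water-filled nanochannel in silica
scatters light coherently with the channel itself. In a dark-field image
the molecule appears as a *negative* diffraction-limited dip riding on the
channel's scattering background, because the channel (water groove in
silica) has negative optical contrast relative to the wall while the
molecule's polarizability is positive, so the cross term of the two
scattered fields reduces the collected intensity. Collapsing each movie
frame across the channel's short axis gives a kymograph: one row of
relative differential contrast per frame, one column per position along
the channel.

Two per-molecule quantities carry all the information the package
extracts:

* the **integrated optical contrast** (iOC), the dip's relative contrast
  integrated along the channel axis, with units of length. It is
  proportional to molecular weight,

  $$\mathrm{MW} = \mathrm{iOC}\cdot\frac{A}{\bar n a},\qquad
    \bar n = \frac{1.5\,n_m^2 + 0.5\,n_w^2}{n_m^2 - n_w^2},$$

  with $A$ the channel cross-section, $n_m = 1.33$ (water),
  $n_w = 1.46$ (silica), and $a = 0.46\ \mathrm{Å^3/Da}$ the
  mass-polarizability constant of proteins. Both $\bar n$ (≈ −10.25) and
  iOC are negative in this configuration, so a positive mass emerges from
  signed quantities; user-facing reports show magnitudes. A dimensional
  check: nm · nm² / (nm³ Da⁻¹) = Da.

* the **diffusivity** $D$, converted to a hydrodynamic (Stokes) radius
  through the confinement-corrected Stokes–Einstein relation

  $$R_s = K(\lambda)\,\frac{k_B T}{6\pi\eta D},\qquad
    \lambda = R_s / r,\quad r = \sqrt{A/\pi},$$

  where $K$ is the hindrance factor of a sphere in a pore,

  $$K(\lambda) = \frac{1 + \tfrac98\lambda\ln\lambda - 1.56\lambda
     + 0.53\lambda^2 + 1.92\lambda^3 - 2.81\lambda^4 + 0.27\lambda^5
     + 1.1\lambda^6 - 0.44\lambda^7}{(1-\lambda)^2}.$$

  $K(0) = 1$ exactly (the $\lambda\ln\lambda$ limit is handled
  explicitly) and $K$ decreases monotonically over the range the package
  accepts. Because $K$ depends on $R_s$, the radius is the root of an
  implicit equation; `stokes_radius_from_diffusivity()` brackets it on
  $(0, 0.8\,r)$ and bisects to $10^{-4}$ nm. We accept $\lambda < 0.8$
  and warn above $0.6$: the $(1-\lambda)^{-2}$ factor makes the
  correlation diverge toward $\lambda = 1$, far outside the regime
  (λ ≲ 0.3) it was established in. A diffusivity too small to yield any
  radius below the cap raises an explicit "unresolvable confinement"
  error rather than returning a clamped value.

Defaults: $T = 294.15$ K and $\eta = 0.978$ mPa·s (water at 21 °C).
Forward and inverse conversions always use the same context, so round
trips are insensitive to this choice.

The empirical globular-protein scaling $R_s \approx b\,\mathrm{MW}^{1/3}$
uses $b = 0.88$ in units of nm·kDa$^{-1/3}$. We interpret the prefactor
in kDa units because only then does it reproduce the literature radii the
package ships (0.88·66^{1/3} = 3.56 nm vs 3.5 nm for BSA;
0.88·669^{1/3} = 7.70 nm vs 8.6 nm for thyroglobulin, which is known to
sit above the globular line); in Da units it would predict radii an
order of magnitude too large.

An `intensity_model()` exposes the absolute intensity picture
($I_c \propto |\alpha_c|^2$, $I_m \propto |\alpha_m|^2$,
$\Delta I_t = -2\sqrt{I_c I_m}$) for consistency checks — it demonstrates
that the interference term exceeds the bare molecular scattering by more
than two orders of magnitude for molecule-scale polarizabilities, which
is the reason the method works at all. The analysis path never depends on
absolute intensities; only relative contrast enters the mass
calibration. The default
channel polarizability magnitude is a slab-contrast surrogate
$A\,|n_w^2-n_m^2|/(n_w^2+n_m^2)$, a deliberate order-of-magnitude stand-in
since absolute radiometry is out of scope.

## The forward simulator

`simulate_experiment()` composes three steps, all seeded once from the
plan's `rng_seed` (bit-identical reruns are a tested contract):

1. **Dynamics.** Overdamped 1-D Brownian motion,
   $x_{i+1} = x_i + v\,\delta t + \sqrt{2D\,\delta t}\,\xi$, at 20
   substeps per 5 ms frame by default, with $D$ from the hindrance
   relation above. The simulated domain is twice the field of view
   (default 15 µm), centered, with reflecting ends; the field of view
   itself is open, so molecules wander in and out of sight exactly as in
   a channel much longer than the camera's footprint. Optional binding
   events freeze the position for a specified frame interval, emulating
   transient wall sticking on non-passivated surfaces.

2. **Rendering.** Each substep contributes a Gaussian line profile
   (σ = 100 nm by default, consistent with a diffraction-limited FWHM of
   about 240 nm at 600 nm wavelength and NA 1.27) whose spatial integral
   is the species' iOC; substep profiles are averaged within the frame.
   This *is* the motion blur of a camera integrating over the exposure —
   for the faster species the within-frame excursion (hundreds of nm)
   dominates the optical width, and any analysis that ignores it fails
   quantitatively (see below). Profiles are sampled at the 30 nm pixel
   pitch; frame sums times the pitch reproduce the iOC to 0.1%
   (a tested conservation law), except for profiles truncated by the
   field-of-view edge.

3. **Noise.** Additive zero-mean Gaussian contrast noise with
   s.d. 5×10⁻⁵ (0.005%) per pixel at 200 frames per second — the
   processed-kymograph noise level of the instrument being emulated. The
   underlying multi-kilohertz acquisition and frame averaging are not
   modeled separately; the pipeline consumes processed kymographs.
   Occupancy can be sampled from a molar concentration via
   `expected_count()` (28 nM ↔ 0.7 molecules per 15 µm field of view in
   a 100 × 27 nm channel).

What the simulator does **not** emulate: shot-noise statistics and
illumination drift beyond a global per-frame gain, axial/transverse
motion (the channel keeps molecules in focus; an optional contrast-jitter
parameter exists but defaults to 0), non-Gaussian point-spread tails,
spatial drift of the sample, and lipid-bilayer formation kinetics.
Passing tests on simulated data therefore demonstrate the correctness of
the estimators under the stated model, not robustness to every
instrumental artifact.

## Preprocessing

Raw movies are collapsed across the transverse axis (unweighted mean),
the empty-channel background is estimated as the pixel-wise temporal
median, and contrast is formed as
$(\mathrm{raw}/(g_t\,\mathrm{bg}) - 1)$ with a per-frame global gain
$g_t$ (median of raw/background) absorbing source drift. The median is
the standard robust estimator at sparse occupancy; a molecule parked at
one position for most of the movie leaks into it, which is flagged by an
occupancy check (median far below the upper decile) and is a documented
failure mode — a dip present in *every* frame is indistinguishable from
background structure by any temporal estimator.

Two second-order biases matter quantitatively, and both were found by
closing the loop against simulator ground truth:

* the dip itself drags the per-frame gain median down by a fraction of
  the noise level. An offset that small is invisible pixel-wise but
  integrates to a large error over the wide window used for the iOC
  (~100 pixels × 2×10⁻⁵ × 30 nm ≈ half the iOC of BSA). The detector
  therefore re-estimates a per-frame residual offset from pixels far from
  any detection and subtracts it before summing.
* the temporal median absorbs part of the dip wherever the molecule
  lingers. `nsm_study()` runs a second pass: detections from the first
  pass mask the molecule's footprint, the background is re-estimated from
  unmasked frames only (`estimate_background(mask = ...)`), and the
  kymograph is re-normalized. Without this pass the BSA mass comes out
  several percent low; with it, recovery is within ~1%.

## Detection, localization, linking

Frames are screened with a multi-scale matched filter: Gaussian
templates at 1×, 2× and 4× the optical line-spread width, each
normalized to unit L2 norm so the filtered noise keeps the per-pixel
noise level (estimated robustly by MAD on a strided subsample; all
scales share one forward FFT). Local minima below κ·noise (κ = 5 by
default, giving a tested false-positive rate below 10⁻² per line) are
candidates; candidates from different scales within 2.5 template widths
of each other are the same dip and the strongest normalized response
wins. The multi-scale design is forced by motion blur: a 44 µm²/s
protein's within-frame occupation profile is several times wider than
the optical line-spread function, and a single-width template misses it
entirely.

Subpixel positions come in two stages. A fixed-width least-squares
Gaussian fit (Gauss–Newton on position, amplitude in closed form)
refines the candidate; then an iterative windowed centroid (center of
mass of the background-corrected contrast in a wide window, re-centered
three times) gives the final position. The centroid matters: it
estimates the *frame-averaged* position, which is exactly the quantity
whose statistics the covariance-based diffusivity estimator corrects
for. Using the profile mode instead (what a narrow fixed-width fit
returns for a blurred, often multi-lobed occupation profile) produced
apparent jumps between lobes and a ~50% negative bias in D before this
was diagnosed. The per-frame iOC is the windowed sum of corrected
contrast times the pixel pitch (window: 10 line-spread widths or 4
template widths, whichever is larger) — insensitive to blur
redistributing the profile, unlike the fitted-amplitude estimate
`ioc_fit_nm`, which is also reported and agrees with the sum for slow or
static molecules (a tested equivalence). Frames whose window is clipped
by the field-of-view edge carry an `edge` flag: their truncated sums
would bias the trajectory mean low by 1–2%, so they are excluded from
the iOC average (but kept for linking and diffusivity).

Linking is greedy nearest-neighbor with a gate of
$4\sqrt{2 D_{max}\Delta t} + |v|\Delta t$ (default $D_{max}$ = 30 µm²/s;
`nsm_study()` sizes it from the fastest declared species with 50%
headroom), gap tolerance of 3 missed frames, and ties broken by smaller
displacement then larger |iOC|. At the occupancy this instrument class
operates at (≲ 2 molecules per field of view) ambiguous assignments are
rare and globally optimal assignment is not warranted. In flow mode the
per-frame drift (median nearest-neighbor displacement) is subtracted
before gating so drifting particles link correctly.

Transient binding is excised, not merely flagged: segments where the
rolling standard deviation of position over 50 frames falls below 3× the
median localization uncertainty are cut out, and the flanking free
segments are re-emitted when still ≥ 50 frames (`min_N`, also the
threshold below which trajectories are dropped outright). The thresholds
are package decisions validated on simulation; the instrument papers in
this area do not state theirs.

## Per-trajectory and population estimation

The molecule's iOC is the arithmetic mean of its per-frame values over
free, non-edge frames; mass follows from the calibration above.
Diffusivity uses the
covariance-based estimator

$$\hat D = \frac{\overline{(\Delta x_n)^2}}{2\Delta t}
  + \frac{\overline{\Delta x_n \Delta x_{n+1}}}{\Delta t},$$

whose covariance term cancels the bias from static localization noise
*and* from motion blur when positions are frame averages — the reason
the detector reports centroids. Displacements across linking gaps are
excluded, as are the displacement pairs that touch them. Negative
estimates (possible for noise-dominated trajectories) are preserved and
flagged `invalid_negative_D` rather than truncated; truncation would
bias population means upward. In flow mode the per-trajectory mean
displacement is subtracted first. No blur-correction term is added to
the estimator itself; with centroid positions none is needed (tested
bias < 2% at N = 10⁴).

One bias is *inherent to the measurement geometry* rather than to any
estimator: a trajectory is only observed while the molecule stays in the
field of view, and conditioning a random walk on remaining inside a
window truncates the largest displacements. On simulation this depresses
the CVE by ~15% for observation runs shorter than ~50 frames but by
< 3% for runs of ≥ 50 frames at BSA-like diffusivity in a 15 µm field of
view. The default `min_N = 50` and the N-weighting of population
statistics keep the surviving effect at the percent level; it shrinks
further for slower species and longer fields of view. This affects any
finite-field-of-view tracking experiment, not just the simulation.

Population statistics weight each trajectory by $N_i/\sum N$ — a
trajectory's evidence is proportional to its length, and peak masses
then reflect relative concentrations. Histograms use Freedman–Diaconis
bin widths capped at one tenth of the data range (so small studies still
spread over enough bins to fit); a sum of Gaussians is fitted by
Levenberg–Marquardt (`minpack.lm`), with the single-component fit
initialized from the histogram mode and the weighted standard deviation,
and σ parameterized on the log scale to stay positive. The population
mean is the fitted center; the resolution is the FWHM,
$2\sqrt{2\ln 2}\,\sigma$. Multi-component fits (e.g. a dimer shoulder)
require user-supplied initialization; no automatic model selection is
attempted. When all mass lands in ~one bin the FWHM floor is the bin
width, and the fit refuses histograms with fewer than five populated
bins per component.

## Problem sizes and validation

The test suite and the acceptance script validate the closed loop at
study sizes chosen to give comfortable statistical margins on one CPU:
the radius recovery uses 100 trajectories of 1000 steps (the CVE's
per-trajectory s.d. is ~8%, so the mean is determined to well under 1%);
mass recoveries use 100–200 simulated recordings of 500 frames (fitted
centers reproducible to ~1%); the thyroglobulin resolution run uses
60–300 recordings with lengths drawn uniformly between 500 and 1100
frames. Measured outcomes under the default conditions: BSA in the
100 × 27 nm channel recovers 66.8 kDa and R_s 3.6 nm (truths 66 and
3.5); aldolase in the 82 × 40 nm channel recovers 158.5 kDa (truth 158);
the idealized thyroglobulin mass FWHM is ~1.6 kDa, far inside the
30 kDa experimental resolution it is checked against — as it should be,
since the simulation includes only the stated noise source.

## Known limitations

* The hindrance correlation treats the channel as a circular pore of
  equal area; rectangular-section corrections, wall slip and
  electrostatic wall interactions are not modeled.
* Elongated molecules (DNA) violate the hard-sphere assumption behind
  the radius conversion; their recovered $R_s$ is an equivalent-sphere
  radius, expected to sit below the globular line at a given mass.
* The tracker is greedy and single-hypothesis; it is not intended for
  occupancies far above ~2 molecules per field of view.
* Two molecules closer than ~2.5 template widths merge into one
  detection and their contrast sums; at the design occupancy this is a
  rare transient.
* Axial position is neither simulated nor estimated.
* The iOC windowed sum assumes the background-corrected baseline is flat
  across the window; structured stray-light backgrounds would need
  flat-fielding upstream, which is out of scope.
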