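---
title: "Methods: simulating and classifying THz-TDS corneal scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and classifying THz-TDS corneal scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The corneal endothelium is the monolayer that pumps fluid out of the stroma;
when it is damaged, the cornea swells (edema) and its terahertz reflectivity
changes, because liquid water dominates the dielectric response of tissue in
the 0.1–2 THz band. `thzcornea` implements a complete analysis chain for
reflection-mode THz time-domain spectroscopy (THz-TDS) of the cornea under a
controlled intraocular-pressure (IOP) protocol:

1. a **physics-based simulator** that generates cohorts of per-pixel THz
   pulses from layered-tissue hydration models, together with per-sample
   endothelial cell density (ECD) labels;
2. **signal processing** that turns each pulse into a deconvolved frequency
   response and a band-limited spectral slope;
3. **feature extraction** into three per-sample predictors, `S_Start`,
   `S_Elev` and `S_Phys` — the mean slope over the last 30 min of the
   acclimation, elevated-IOP and recovery periods;
4. **classification** of endothelial integrity (intact: ECD > 3000
   cells/mm²) with linear SVMs evaluated over repeated randomized 70/30
   splits, reporting vertically averaged ROC curves and AUC mean ± SD.

The experimental design being emulated scans each sample every 4 min over a
9-h protocol (1 h acclimation at 15 mmHg, 4 h at 25/35/45 mmHg, 4 h back at
15 mmHg), on a 9 × 9 angular grid, with a metallic-sphere reference scan for
deconvolution.

## Dielectric and layered-media model

**Time convention.** Everything uses `exp(-i*omega*t)`: lossy media have
`Im(eps) >= 0` and `Im(n) >= 0`. The convention is declared once and enforced
in the Debye model, the Bruggeman root selection, the principal square root
in `index_from_permittivity()`, and the transfer-matrix phase. Sign
inconsistencies are the classic failure mode of layered-media code, which is
why the transfer matrix is cross-checked against an independently coded
Airy multiple-reflection series in the test suite (agreement ≤ 1e-10).

**Water.** Liquid water is modeled with the standard two-relaxation-time
Debye form
\[
\varepsilon(f) = \varepsilon_\infty
 + \frac{\Delta\varepsilon_1}{1 - i\,2\pi f\,\tau_1}
 + \frac{\Delta\varepsilon_2}{1 - i\,2\pi f\,\tau_2},
\]
with the literature room-temperature parameter set
`eps_inf = 3.48`, `delta_eps1 = 73.43`, `tau1 = 8.24 ps`,
`delta_eps2 = 1.45`, `tau2 = 0.18 ps` (static permittivity 78.36). These
values are a configuration entry, not a fit: any published water set can be
substituted through `default_config()$dielectric$water`.

**Tissue mixing.** Hydrated stroma is treated as a two-phase composite of
water in a nondispersive biological background (`eps_background = 4.0`,
configurable). The effective permittivity is the physical root of the
symmetric Bruggeman mixing rule, which reduces to a quadratic; the root with
positive real part and nonnegative imaginary part is selected and the
residual of the mixing equation is verified to ≤ 1e-12 at every call.

**Hydration profile.** Water entering at a boundary diffuses into the
stroma following Fick's second law for a semi-infinite medium with fixed
boundary concentration,
\( C(z,t) = C_0 + (C_1 - C_0)\,\mathrm{erfc}\!\big(z / 2\sqrt{Dt}\big) \).
A slab eigenfunction series was deliberately not used: the probed depth is
small compared with corneal thickness, and the erfc form is the simplest
solution consistent with a stratified-diffusion description. The profile is
discretized into 20 equal-thickness layers over 500 µm (both configurable)
on top of a bulk half-space, and the reflection coefficient at normal
incidence is computed by the characteristic (transfer) matrix method.

**Why the slope works as a hydration biomarker.** Raising the water volume
fraction raises `|r|` at 0.4 THz and, because the Debye dispersion makes
water's permittivity fall steeply across the band, makes the least-squares
slope of `|r(f)|` over 0.4–0.8 THz more negative. Both monotonicities are
asserted over a fraction sweep of 0.5→0.9 in the test suite; they are a
property of the physical model, not an imposed calibration.

## Hydration dynamics of the synthetic cohort

The study design needs two archetypes: intact samples whose spectral slope
barely moves under elevated IOP and recovers fully, and damaged samples
whose slope tracks the pressure insult and stays depressed after release.
No quantitative IOP-to-influx law is available for this system, so the
surface water fraction `C1(t)` follows a deliberately phenomenological
two-rate model,
\[
\frac{dC_1}{dt} = k_{in}\,\frac{\mathrm{IOP}-15}{10}\,(C_{1,max} - C_1)
 - k_{out}\,p\,(C_1 - C_0),
\]
integrated with a 1-min Euler step and bounded in `[C0, C1_max]`. The pump
efficacy `p` is a logistic map of ECD centered at the 3000 cells/mm²
integrity threshold (scale 300 cells/mm²). With the defaults
(`C0 = 0.75`, `C1_max = 0.95`, `k_in = 0.004 /min per 10 mmHg`,
`k_out = 0.05 /min`):

* an intact sample (`p ≈ 1`) at 45 mmHg equilibrates ~0.04 above baseline
  with a ~20-min time constant and relaxes back within the first recovery
  hour — a flat, reversible slope series;
* a damaged sample (`p ≈ 0`) rises ~0.14 with an hour-scale time constant
  and decays with a ~200-min time constant, so it remains swollen at the
  end of the 4-h recovery — a slope series that follows the IOP insult.

The rates were chosen once, from these time-constant considerations, to
reproduce the two archetypes; they are free parameters of the generator and
make no claim about the real ex vivo system. Because efflux scales with
pump efficacy, pressure magnitude matters less than endothelial state —
the design's central qualitative feature.

ECDs are drawn from a two-component lognormal mixture (intact mode 5000
cells/mm², log-SD 0.15; damaged mode 1600 cells/mm², log-SD 0.2; weight
0.5), consistent with the healthy porcine range of roughly 3500–6500
cells/mm² and with severely decellularized damaged layers. Class labels are
always re-derived from the drawn ECD by the strict `> 3000` rule, never
stored independently.

## Forward model and signal processing

The reference pulse is an analytic first-derivative-of-Gaussian wavelet
(width 0.25 ps, spectral peak ≈ 0.64 THz, energy concentrated 0.1–2 THz),
2048 samples at 0.0333 ps. Each pixel's trace is the inverse transform of
(reference spectrum × reflectance) plus white detector noise
(`noise_sd = 0.01` of the unit pulse peak per pixel). The simulator
evaluates the layer-stack reflectance up to 4 THz and treats the response
as zero above, where the wavelet carries no energy (relative spectral
amplitude < 1e-4); this is a property of the band-limited source, not an
approximation of the tissue model. Sphere-curvature and alignment effects
are not modeled: deconvolution against a same-geometry reference cancels
geometry to first order, so all pixels are statistically exchangeable up to
noise.

Processing mirrors the standard instrument chain:

* **High-pass Gaussian filter**, gain `1 - exp(-f²/(2σ_f²))` with `σ_f`
  calibrated so the gain is exactly 0.5 at the 0.1 THz cutoff. It is applied
  to sample and reference alike, so it cancels in the transfer spectrum and
  matters only for trace-level displays and DC rejection.
* **FFT** with no window and no zero-padding by default (a window generator
  and padding are configuration options); frequency resolution is
  `1/(N·Δt)` ≈ 14.7 GHz at the defaults.
* **Wiener-regularized deconvolution**
  `H = S·conj(R) / (|R|² + λ²)` with `λ = 1e-3 · max|R|`. Bare spectral
  division amplifies out-of-band noise without bound; the small floor leaves
  the in-band bias at the 1e-6 level while keeping out-of-band bins finite.
* **Spectral slope**: OLS slope of `|H(f)|` — *linear* amplitude, not dB —
  against frequency over `0.4 ≤ f ≤ 0.8` THz, both edges inclusive
  (27 bins at the defaults). Dimensionless amplitude per THz gives the
  slope its units of picoseconds. The band is configurable; 0.4–0.8 THz is
  the default bandwidth of interest (a 0.4–1 THz variant appears in some
  displays of this kind of data and is reachable through
  `signal$band$f_high`).

A noiseless end-to-end round trip (synthesize → filter → FFT → deconvolve →
slope) reproduces the slope computed directly from the model `|r(f)|` to
better than 1%, which is the pipeline's core self-consistency property.

## Feature extraction

Per frame, the slope is averaged over the central 5 × 5 block of the 9 × 9
grid (the central 25 pixels). Pixels with failed deconvolution (`NaN`) are
dropped if they are ≤ 20% of the ROI, otherwise the frame errors out — the
source data give no guidance here, so the rule is conservative and loud.
`S_Start`, `S_Elev`, `S_Phys` are the means of the ROI slope over the
**half-open** windows `(30, 60]`, `(270, 300]`, `(510, 540]` min: the frame
landing exactly at `T_end - 30` is excluded, which makes frame counting
unambiguous at 4-min sampling (exactly 8 frames per window). Whether the
boundary frame belongs to the window is genuinely underdetermined; the
half-open choice is recorded here and fixed everywhere.

## Classification

"Bootstrapping" in this design is read operationally as repeated randomized
70/30 train/test splits — Monte Carlo cross-validation — not resampling with
replacement; with n = 19 samples, resampling with replacement would make
single-class test sets common, while the split reading matches "new training
and testing datasets formed in each iteration". Splits are stratified by
class by default (a non-stratified mode exists) to avoid degenerate test
sets at this sample size.

Each of the 300 iterations: z-score the predictors with training-split
statistics (SVM penalty grids are scale-sensitive; this also makes the
per-iteration AUCs exactly invariant to any positive rescaling of the
features), grid-search the margin-penalty parameter over `10^(-3..3)` by
5-fold CV on the training split scored by accuracy (ties to the smallest
cost), fit a linear SVM, and score the test split with the decision
function oriented so that larger means intact. The per-iteration ROC/AUC is
computed by `pROC`; curves are vertically averaged on a fixed 101-point FPR
grid by linear interpolation with the origin pinned at (0, 0) — the usual
mean-ROC convention; threshold averaging is not implemented. The grid
search runs inside every iteration on that iteration's training split;
running it once globally would leak test information across iterations.
Four predictor sets are evaluated (`S_Start`, `S_Elev`, `S_Phys`,
`S_Elev + S_Phys`); no multiple-testing correction is applied across them —
the AUCs are reported raw. Only the linear kernel is exercised by default;
the kernel argument passes through to `e1071::svm` for the standard
alternatives.

## What the generator does and does not emulate

The generator reproduces the statistical structure the analysis relies on:
per-pixel pulses with realistic band-limited spectra, hydration-driven
slope dynamics that differ between intact and damaged endothelium, a 7/6/6
allocation of 19 samples across 25/35/45 mmHg, and a deterministic archive
keyed to a single master seed. With the default settings the two classes
separate in `S_Elev` by more than 3 pooled standard deviations, so the SVM
stage is exercised in a regime where recovery of the class structure is
expected, and a permuted-label control stays at chance.

It does **not** emulate: sphere-alignment and curvature artifacts,
time-of-arrival jitter between pixels, drift or 1/f detector noise,
biological variability beyond the ECD→pump map (e.g. thickness variation,
epithelial state), or any quantitative IOP–hydration coupling. Passing
tests therefore demonstrate the correctness and determinism of the
*analysis*, and the internal consistency of the physics, not expected
classifier performance on real scans — real cohorts are noisier and the
class separation materially smaller.

## Numerical choices and problem sizes

* Transfer matrices are accumulated elementwise over the frequency grid;
  Bruggeman roots come from the closed-form quadratic with an explicit
  residual check, so no iterative root-finding is involved anywhere.
* All RNG flows from a single master seed: cohort-level draws use it
  directly, each sample gets a derived seed, and each frame's noise seed is
  a fixed function of the sample seed and frame index, so streamed
  processing, archived processing and partial re-synthesis are
  bit-identical.
* The default full run processes 19 samples × 136 frames × 81 pixels of
  2048-sample traces (about 210k pulses) in a few minutes on one core;
  frames that share a hydration state share one reflectance evaluation.
  Unit tests run on reduced fixtures (512-sample traces, 3 × 3 grids,
  96-min protocols) that exercise identical code paths.
* The scan archive is a plain-directory format (per-frame CSV trace tables
  plus a JSON manifest with the configuration hash). As text, a full
  default cohort is several gigabytes, so `run_all()` streams frames
  through the processing stage instead of materializing them;
  `write_archive()` exists for small cohorts and interoperability.

## Known limitations

* The IOP→influx rates are free parameters; none of the generator's
  dynamic constants are estimates of porcine physiology.
* Normal incidence only; no oblique propagation, scattering or
  polarization effects.
* The Fick profile uses a fixed effective diffusion time as a shape
  parameter rather than co-evolving with the surface dynamics; depth
  structure is therefore quasi-static between frames.
* With n = 19 the per-iteration AUC distribution is strongly discrete
  (test sets of ~6), which inflates the AUC standard deviation for any
  classifier — a property of the evaluation design, not of the features.
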