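---
title: "Methods: quantitative MRI of maternal-placental-fetal haemodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative MRI of maternal-placental-fetal haemodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decidemri)
```

`decidemri` quantifies maternal, placental and fetal haemodynamics from
three MRI modalities acquired in the pregnant sheep — a multi-compartment
diffusion-relaxation series of the placentomes, T2-prepared vessel series,
and phase-contrast (PC) cine flow acquisitions — and combines them into
oxygen delivery/consumption estimates and repeated-measures cohort
statistics across a basal state and two post-treatment windows (TAD1,
TAD2). This vignette documents the models, the defaults and why they were
chosen, the synthetic-data generator that makes the whole pipeline testable
without scanner data, and the numerical decisions that matter.

## The placentome signal model

The placentome (the sheep equivalent of a cotyledon-caruncle unit) is
modelled as three water compartments, each with its own diffusion and
transverse-relaxation behaviour:

$$
S(b, TE) = S_0\left[
  f\, e^{-b d^{*}} e^{-TE\,R_{2fb}}
  + v\, e^{-TE\,R_{2mb}}
  + (1 - f - v)\, e^{-b d} e^{-TE\,R_{2ts}}
\right]
$$

* `f` — feto-placental blood volume fraction; this compartment decays with
  the fast pseudo-diffusivity `d_star` (incoherent capillary flow, the
  IVIM effect) and the blood relaxation rate `R2fb = 1/T2fb`. Since blood
  T2 depends on oxygen saturation, the fitted `T2fb` converts to a
  feto-placental SO2 through the same calibration used for vessel
  oximetry.
* `v` — maternal blood volume fraction. Maternal blood percolates slowly
  through the intervillous sinuses; the model assigns it no diffusion
  attenuation, only relaxation at the fixed, highly saturated maternal
  blood rate `R2mb`.
* `1 - f - v` — trophoblast/tissue fraction with true diffusivity `d` and
  fixed tissue relaxation `R2ts`.

One typographic ambiguity deserves a note: in compressed print the
equation's grouping can be read as if the diffusion factor
`exp(-b d_star)` multiplied all three terms. We adopt the three-additive-
compartment reading above — fetal blood carries `d_star`, tissue carries
`d`, maternal blood carries no `b` dependence — which is the form used
throughout the model's lineage and the only physically sensible one (the
maternal pool is not flowing coherently enough to dephase with the fetal
pseudo-diffusion coefficient).

The fixed constants for maternal blood and tissue are sometimes quoted
in the literature with rate-like units (150 and 42 "ms^-1"). Read
literally as rates these are impossible
(a R2 of 150/ms means T2 of 7 µs); we interpret them as T2 values,
`T2mb = 150 ms` and `T2ts = 42 ms` at 3 T, and both are overridable via
`decide_constants()`.

The forward model is evaluated with `expm1` so that the compartment
fractions sum to one exactly in floating point: `decide_signal(p, k, 0, 0)`
is bitwise equal to `S0`.

## Fitting

`fit_decide_roi()` fits the six free parameters
(`S0, f, v, d, d_star, T2fb`) to the in-mask mean signal curve;
`fit_decide_voxelwise()` then fits every voxel independently, initialised
at the ROI estimate — the two-stage scheme used in the model's published
applications. The solver is Levenberg-Marquardt with box projection
(`minpack.lm::nls.lm`) and an analytic Jacobian. The boxes are those used
to stabilise the published fits: `0 < f, v, d, d_star < 1` and
`0 < T2fb < 150 ms`. An alternative route fitting logit/log-transformed
parameters without boxes is available (`decide_fit_control(transform =
"logit")`); the bounded natural-unit route is the default because the
boxes are then honoured exactly as printed, with no transform-induced
gradient pathology at a boundary.

Numerical choices:

* Joint constraint `f + v < 1` is not part of the printed boxes but is
  required for a physical tissue fraction; it is enforced as a soft
  penalty residual, weighted by `penalty_weight` (default 10) times the
  signal amplitude, active only when `f + v >= 1`.
* Default initialisation: `f = v = 0.2`, `d = 1.5e-3 mm²/s`,
  `d_star = 0.03 mm²/s`, `T2fb = 75 ms` (mid-box), `S0 =` maximum
  observed signal. Cost tolerance `1e-10`, at most 400 iterations.
* Two safeguards against local minima, both verified by the noiseless
  two-block phantom test: every voxel is also fitted from the default
  mid-box start (the better solution wins), and a solution with
  `d >= d_star` — tissue diffusing faster than pseudo-diffusing blood,
  i.e. the two diffusive compartments having swapped roles — triggers a
  restart from the exchanged point.
* Degenerate input (a flat curve, which carries no decay information) is
  flagged, not fitted; per-voxel optimiser failures are flagged in the
  diagnostic volumes and never abort the map.
* Ordinary unweighted least squares on magnitude data; no Rician bias
  correction is applied, the standard practice for this model family.
* The acquisition grid must contain at least 6 distinct points spanning
  at least 2 b-values and 2 echo times, otherwise the six-parameter fit
  is non-identifiable and the fit functions refuse to run. The package
  default (`default_grid()`) is the full cross of
  b ∈ {0, 50, 100, 200, 400, 600} s/mm² with
  TE ∈ {72, 96, 120, 144, 192} ms; acquisitions of this type vary in their
  b/TE sampling, so the grid is fully configurable.

### How well are the fractions identified?

With the default grid and noise at SNR 50 (referenced to the b = 0,
minimum-TE volume), the Cramér-Rao bound computed from the analytic
Jacobian puts the relative standard deviation of `v` around 5-7% but that
of `f` around 17-31% for mid-physiological truths: the feto-placental
term is a small, fast-decaying share of the total signal and trades off
against `T2fb`. The voxelwise estimator reaches this bound (median
absolute relative errors ≈ 4% for `v` and ≈ 15% for `f` in the seeded
acceptance simulations), so per-voxel `f` at this SNR is variance-limited
by the experiment design, not by the optimiser; `f` recovered from the
ROI-average curve is far more precise because averaging raises the
effective SNR by the square root of the mask size. The estimator's bias
for `v` shrinks monotonically as SNR doubles (Rician floor effects fade);
for `f` the bias is statistically indistinguishable from zero at every
tested SNR.

## Vessel T2 oximetry

`fit_t2_decay()` fits the two-parameter mono-exponential
`S(τ) = S0 exp(-τ/T2)` to a T2-prepared series (default preparation
times 32-192 ms in 32 ms steps) by nonlinear least squares
initialised from the log-linear regression. No offset/noise-floor term is
included by default, matching the acquisition's description; non-decaying
series are flagged failures. ROI signals are aggregated by the mean
(median was the other candidate; mean matches the usual vendor analysis).

Saturation conversion uses the Luz-Meiboom-type quadratic
`R2 = A + B (1 - Y)^2` (`R2` in s^-1). Calibration constants are specific to
species, haematocrit, field strength and preparation timing, so they are
**required configuration**;
the named preset `sheep_3T` (`A = 4 s^-1`, `B = 60 s^-1`) ships as a
representative value for sheep blood at 3 T and haematocrit ≈ 0.30, in
the range reported by T2-prep calibrations of ovine and human blood at
this field strength. Both the placentome `T2fb` and the vessel T2s go
through the same inversion, `so2_from_t2()`: `Y = 1 - sqrt((R2 - A)/B)`,
clamped to [0, 1] with a clamp flag, and erroring when T2 exceeds the
fully-saturated limit beyond tolerance.

The manual "central 60% of the vessel" ROI placement is operationalised
deterministically by `central_fraction_roi()`: pixels ranked by descending
exact Euclidean distance to the mask boundary (image border counts as
background), ties broken by ascending distance to the mask centroid, then
row-major order; the top `ceiling(0.6 N)` pixels are kept. The
deterministic tie-break makes tests exact.

## Phase-contrast flow

Velocity is `v = VENC · φ/π`; aliased phase (|φ| > π) is rejected rather
than unwrapped — unwrapping is out of scope and silent unwrapping would
hide acquisition errors. Per-cardiac-phase flow is the ROI sum of
velocity × pixel area, and the reported flow is the unweighted mean over
phases (uniform phase sampling; an RR-weighted integral gives identical
results under uniform sampling). Maternal cardiac output (LVCO) is the
ascending-aorta flow; total uterine artery flow is left + right;
`normalize_flow()` indexes to maternal weight (mL/min/kg) or to LVCO (%).
No background-phase or eddy-current correction is applied: phase input is
assumed pre-corrected.

## Oxygen transport

With Hb in g/L, saturations as fractions and flows in mL/min:

* fetal DO2 = 1.36 × Hb × Y_UV × Q_UV
* fetal V̇O2 = 1.36 × Hb × (Y_UV − Y_DAo) × Q_UV
* uterine artery DO2 = 1.36 × Hb × Y_UtA × Q_UtA

1.36 mL O2 binds per gram of haemoglobin; haemoglobin is converted to
g/mL internally, so the outputs are mL O2/min. Dissolved oxygen is
omitted (the equations carry no solubility term). The oxygen extraction
fraction `(Y_UV − Y_DAo)/Y_UV` equals V̇O2/DO2 and is independent of Hb
and flow. Uterine DO2 as a percentage of available DO2 divides by
`1.36 × Hb × Y_arterial × LVCO`. In protocols of this design the uterine *vein* is what
is practical to measure by T2 oximetry while the delivery equation needs
the arterial `Y_UtA`; the
generator and pipeline use the maternal arterial saturation for both
`Y_UtA` and `Y_arterial`, and the mapping is configurable.

## The synthetic-data generator

`simulate_cohort()` generates the complete study with known ground truth:
`n_animals` ewes (default 7) × three states. Between-animal variability
is modelled as lognormal multipliers on flows and additive normal shifts
on fractions and saturations (clamped to their valid ranges);
within-animal state-to-state fluctuation is additive normal. The default
injected effects encode the physiological pattern the generator is built
to emulate — a vasodilator that lowers maternal pressure and
redistributes cardiac output away from the uterus while fetal
oxygenation is maintained: `v` raised by
+0.08 at TAD2, the UtA share of LVCO lowered by 4 percentage points at
TAD1 and TAD2, maternal arterial pressure lowered at both TAD windows,
and **no** true effect on `f`, `d`, `d_star`, `T2fb`, umbilical flow or
any fetal oxygen endpoint. Default magnitudes are mid-physiological
values for the anaesthetised pregnant ewe: LVCO ≈ 8 L/min, UtA ≈ 16% of
LVCO, UV ≈ 700 mL/min, maternal Hb 80 g/L and fetal 95 g/L, Y_UV 0.80,
Y_DAo 0.55, maternal arterial 0.95. `T2fb` defaults to 90 ms for
consistency with the shipped calibration: a feto-placental saturation of
about 0.65 — between the fetal arterial and umbilical-vein values — maps
to T2 ≈ 90 ms.

At `level = "images"` each animal-state receives a placentome volume
(6×6×1 voxels, Rician noise at SNR 50), three vessel T2-prep series
(Rician, SNR 100) and four parabolic-profile PC cine simulations (AAo,
both UtAs, UV) whose peak velocity is set from the true flow; the VENC
defaults to typical protocol values (150 cm/s maternal vessels,
100 cm/s umbilical vein) and is raised when an
unusually high simulated flow would otherwise alias, as a scanner
operator would do. Placentome volumes are deliberately small and the
cohort pipeline summarises each placentome by its ROI-average fit — the
placentome-level summary such cohort analyses report — which keeps a
100-replicate end-to-end simulation under a minute; voxelwise maps remain
available for phantom studies.

Noise: magnitude images get Rician noise (magnitude of a
complex-Gaussian perturbation), with Gaussian available for analytic
bias checks. The noise SD is referenced to the least-attenuated volume
(minimum b, then minimum TE), so the requested SNR is what an analyst
would measure on that volume.

What the generator does **not** emulate: anatomically realistic
placentome shapes, motion (the registration steps of the real protocol
are out of scope; synthetic data are motion-free), cardiac waveform
physiology beyond a sinusoidal modulation, partial-volume effects at
vessel edges, background phase offsets, and pharmacokinetics (tadalafil
concentrations are sampled covariates only). Passing tests therefore
demonstrate correctness of the estimators on data satisfying the models'
assumptions, not robustness to motion or segmentation error.

## Cohort statistics

`rm_anova()` is the classical within-subject one-way decomposition
(SS condition / subject / error; `F = MS_cond/MS_err`), cross-checked in
the tests against `aov(y ~ state + Error(animal))`. No sphericity
correction is applied by default (the plain decomposition is the default of the
analysis software this layer mirrors); pairwise comparisons are paired t-tests with the Bonferroni
cap `p_adj = min(1, m·p)`, and TAD1-vs-TAD2 tadalafil uses a plain paired
t-test. Pairwise comparisons via ANOVA-MSE contrasts were the alternative;
paired t was adopted as the more common convention. Letters are assigned by a greedy insert-and-absorb pass over
the significant pairs, deterministic in the state order, so groups
sharing a letter are not significantly different. Degenerate cases
(zero error variance, zero-variance differences) are flagged rather than
producing spurious statistics. `bin_time_average()` supports the 5-min
binning used for continuously logged pressure/heart-rate traces.

## Problem sizes used in validation

The shipped tests and the acceptance script use: 1000 random parameter
draws for the normalization property; a 10×10×2 two-block noiseless
phantom; 500 voxels at SNR 50 (and 4000 voxels per SNR for the bias
trend over SNR 25/50/100); 1000 replicate T2-prep fits at SNR 100; 500
record-level null cohorts for the type-I rate; and 100 replicate
image-level cohorts (n = 7) for the end-to-end detection rates. These
sizes make the Monte-Carlo error small relative to each quantity checked
while keeping a full run to a few minutes on one core.

## Known limitations

* Per-voxel `f` at SNR 50 is variance-limited (see the Cramér-Rao
  analysis above); placentome-level conclusions should rest on ROI fits
  or on voxel-median summaries.
* The sheep-blood calibration constants are a documented preset, not a
  bench calibration; absolute SO2 values shift with `A` and `B`, though
  state *contrasts* within an animal are far less sensitive.
* Magnitude fitting ignores the Rician noise floor; at SNRs well below
  those simulated here the high-b/long-TE points would bias `d` and the
  fractions.
* The statistics layer implements complete-case repeated-measures ANOVA
  only; mixed-effects models for unbalanced designs are out of scope.
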