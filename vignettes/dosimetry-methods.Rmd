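---
title: "Dosimetry methods in dynodose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dosimetry methods in dynodose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynodose)
```

`dynodose` estimates the absorbed radiation dose delivered by a short-lived
PET tracer from a dynamic whole-body acquisition, by two independent routes:
an organ-level MIRD computation built on fitted kinetics, and a voxel-level
computation built on numerical time integration. This vignette is the
package's own account of the models, the numerical choices, and what the
synthetic validation does and does not establish.

## The measurement problem

Rubidium-82 chloride decays with a 76 s half-life, so the physical decay
constant λ = ln2/76 ≈ 0.00912 s⁻¹ dominates every aspect of the analysis:
whatever the biology does, no voxel can accumulate more than
1/λ = 0.030457 MBq·h of decays per MBq injected, and after seven minutes
(5.5 half-lives) the signal is essentially gone. A long axial field-of-view
scanner covering all major organs in one bed position can reconstruct the
whole 0–420 s history into a handful of frames; the bundled schedule uses
seven (0–30, 30–60, 60–90, 90–120, 120–180, 180–270, 270–420 s).

Scanners report activity concentration *decay-corrected to scan start*:
the frame value is the frame average of the physically decaying signal
multiplied by the correction factor

f = λΔt · e^{λ(s − t_ref)} / (1 − e^{−λΔt})

for a frame [s, s+Δt). The package keeps this factor in one function
(`frame_decay_correction_factor()`), derives λ from the half-life everywhere
(never stores it), and carries an explicit `decay_corrected` flag on every
image and TAC container so a stage cannot silently double-correct. The
decay-correction reference is scan start, which coincides with injection
start for a tracer infused as the scan begins; a `reference_time_s` field
covers protocols with an offset. The 20 s infusion duration is not modelled
in the decay arithmetic — it is a property of the input function, which the
synthetic kinetics can represent, not of the correction.

## Organ branch: biexponential kinetics and closed-form TIA

Decay-corrected organ curves from perfusion tracers rise quickly within the
first minute and plateau after about two; the package models them as
c(t) = a₁e^{−μ₁t} + a₂e^{−μ₂t} with μ₁, μ₂ ≥ 0 and amplitudes free in sign,
so uptake-then-plateau (a₂ < 0) is a special case rather than a forced
washout form — curves that plateau rather than return to zero are fitted
without bias. The normalized time-integrated activity restores physical
decay analytically inside the integral:

∫₀^∞ c(t)e^{−λt} dt = a₁/(λ+μ₁) + a₂/(λ+μ₂),

scaled by organ volume, converted to hours and normalized per MBq injected.
No numerical decay-multiplication step exists, and extrapolation beyond the
last frame is by the fitted model plus physical decay; at this half-life the
tail beyond 420 s contributes under 3% of the integral, so fit instability
there is tolerable.

Numerical choices in the fitter:

* **Multi-start, no RNG.** Rate pairs are seeded from a fixed grid of nine
  rates (0 to 0.25 s⁻¹, 36 ordered pairs); amplitudes are solved linearly
  per start (variable projection) and all four parameters are polished by
  Levenberg–Marquardt with μ ≥ 0 bounds. Lowest residual wins; ties break
  toward the smaller fast rate. Unweighted least squares is the default,
  with optional per-point weights.
* **Frame-aware prediction.** A frame value is an average over 30–150 s of
  a curve that moves substantially within early frames. Fitting the model
  *at frame midpoints* against frame-averaged data biases the recovered
  integral by about −2% for typical uptake kinetics; when a schedule is
  supplied, the model therefore predicts exactly what the scanner reports
  (the decay-corrected frame average), which removes the discretization bias
  identically. `tia_table()` always fits in this mode; point mode remains
  for bare (t, y) data.
* **Non-negativity.** Starts whose fitted curve goes negative on
  [0, 2·t_last] are rejected. Noisy curves rising from zero can push the
  best free fit slightly negative at t = 0; a second pass refits with the
  t = 0 value pinned non-negative. If every start fails, the organ falls
  back to the trapezoid-plus-tail estimator and the output's `method`
  column says so.
* **Physical bounds as errors.** Every TIA must lie in [0, 1/λ] and the
  table total must not exceed 1/λ; violations stop the pipeline and name
  the offending organs rather than propagating impossible numbers.

The total-body remainder row is the whole-body activity minus the summed
organ activities (floored at zero, with a warning beyond a −0.1% tolerance),
fitted with the identical biexponential procedure. Frame values are
attributed to frame midpoints for fitting and integration — the convention
that minimizes first-order bias for smooth curves. Organ mass defaults to
volume × 1 g/mL, overridable per organ where density matters (lung).

## MIRD doses and effective dose

Organ absorbed dose is the standard source-sum D(r_T) = Σ_S Ã(r_S)·S(r_T←r_S),
with S-values supplied as CSV (`phantom,source,target,s_mGy_per_MBq_h`).
All organ-name joins go through one normalizer with an explicit alias map
("Heart content" → `heart_contents`, "Total body" → `remainder`, content
sources vs wall targets). Two deliberate policies:

* An unresolved source organ — including a missing `remainder` source row —
  is an error, never a silent drop: dropping a source silently drops dose.
* The remainder row is already organ-subtracted by construction, so no
  workstation-style remainder rescaling is applied. This is the largest
  source of discrepancy between MIRD implementations and is stated here
  prominently.

Commercial reference-phantom S-values are proprietary and are not bundled;
the package ships a small synthetic toy table and a generator
(`synthetic_svalue_table()`) that make the arithmetic fully testable while
carrying no claim about any real phantom. Consequently the absolute organ
doses of the bundled reference study are *fixtures for summary statistics*
(ranges, rest/stress differences), not a reproduction target.

Effective dose applies the ICRP-103 tissue weighting factors (bundled CSV,
validated to sum to exactly 1) with radiation weighting 1 for photons and
electrons; the 0.12 remainder weight is applied to the mean equivalent dose
of the remainder organs present, and named tissues absent from a report
(sex-specific organs of the other phantom) contribute zero with a warning.
Effective dose is computed per phantom, with no male/female averaging.

## Voxel branch: trapezoid plus mono-exponential tail

Cumulated activity is an integral of the *physically decaying* signal, so
the voxel integrator first removes the decay correction at the frame
midpoints and then integrates:

* trapezoid between the first and last midpoints;
* a left-edge piece from injection (t = 0) to the first midpoint. The
  default is a **triangle ramp from zero**, because the true activity rises
  from zero at injection; holding the first value constant back to t = 0
  (the `rectangle` option) overestimates rising curves by 4–5% at this
  frame width — more than the entire discrepancy budget between the two
  branches — while the triangle keeps the bias near +1%. The rectangle
  remains the right choice for signals already at speed in the first frame,
  and both are exposed as flags with the choice recorded in the output.
* a mono-exponential tail A_last/k with k fitted from the last two time
  points, k = ln(A₆/A₇)/(t₇−t₆). Rising, flat or empty voxels fall back to
  k = λ: after decay-uncorrection nothing decays slower than physics, and a
  fitted k ≤ 0 would diverge. The fallback fraction is reported as a QC
  metric, counted among voxels that actually have a tail (A₇ > 0).

Dose conversion is local energy deposition by default — appropriate for a
positron emitter whose betas have millimetre range against multi-millimetre
voxels — using the locally deposited mean energy per decay from the nuclide
configuration (for Rb-82: ≈1.41 MeV/decay, the ~1.48 MeV mean positron
energy at 95.4% yield; annihilation photons are excluded from local
deposition). Kernel mode convolves the energy-release map with a
user-supplied dose kernel by zero-padded FFT; a delta kernel reproduces
local mode to machine precision, and only a programmatically generated
Gaussian toy kernel ships — packaging a transport kernel would imply a
provenance it does not have.

## The synthetic phantom: what it emulates, what it does not

The generator lays out 12 labelled structures (the 11 segmented source
organs of a rubidium perfusion study, with the heart split into wall and
ventricular content, the wall wrapped around the content to exercise
segmentation adjacency) plus background body tissue inside a body box that
leaves a 3-voxel air margin — without the margin, kernel convolution loses
energy off the grid edge and energy-conservation checks conflate image
truncation with kernel truncation. Default kinetics rise rapidly within the
first minute and stabilize after about two (a₂ = −a₁, rise rates
0.02–0.08 s⁻¹, washout ~10⁻⁴ s⁻¹), with plateau amplitudes graded across
organs; geometry is schematic because organ shape is irrelevant to the
dosimetry arithmetic. Noise is scaled-Poisson on the decay-corrected values
weighted by frame duration — the right sufficient statistic for estimator
testing, but *not* a model of tomographic noise: reconstructed images have
spatially correlated noise, and no point-spread blur is applied by default
(an optional Gaussian kernel can probe partial-volume sensitivity).
Passing tests therefore demonstrate correctness of the estimators under
count-limited noise, not robustness to reconstruction artefacts or
segmentation error on real images.

Two spec-level physical properties hold only in restricted regimes and are
tested there: whole-body activity is non-increasing only for a closed
system (the phantom's rising curves model tracer arrival, so constant
-biology phantoms are used for that check), and the per-voxel TIA bound
"first-midpoint concentration extrapolated to t = 0 over λ" holds only for
curves non-increasing from injection.

## Validation design and problem sizes

The test-suite and acceptance checks run, by design, at sizes a laptop
handles in minutes: a 40×40×60 grid at 4 mm voxels for end-to-end scans,
1000 randomized parameter sets for the closed-form-vs-quadrature oracle,
and 200 seeded replicates at 5% frame-level noise for recovery calibration
(median TIA error ≈1.3%, 95th percentile ≈4.5%; noiseless recovery is exact
to machine precision because the frame-aware fit inverts the simulator's
forward model exactly). The voxel and kinetic branches agree within 2.5%
on noiseless data, the residual being trapezoid discretization of the
early peak.

## Known limitations

* No partial-volume correction, cardiac gating, or scatter/attenuation
  modelling — label maps and reconstructed activity images are inputs.
* The biexponential is an empirical description, not a compartment model;
  it cannot separate delivery from retention.
* Absolute organ doses depend entirely on the S-value table supplied;
  bundled synthetic tables are for testing only.
* The voxel branch's first-frame handling is the dominant systematic at
  this frame width; both edge rules are provided and flagged because the
  truth depends on the input function, which a 30 s first frame cannot
  resolve.
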