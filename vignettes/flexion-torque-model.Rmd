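---
title: "Methods: a circumference-driven model of elbow flexion torque"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a circumference-driven model of elbow flexion torque}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexitorque)
```

## The model and its assumptions

The elbow is treated as a single-flexor system: the biceps dominates
flexion, triceps co-contraction is neglected, and the forearm-weight torque
is assumed removed by the dynamometer's self-weight calibration, so the
measured torque is attributed entirely to the contractile element. In
Hill-type models the contractile force is the product of a maximum force,
an activation level, a force–length factor and a force–velocity factor.
Two further assumptions turn this into a circumference-driven model:

1. **Strain as activation.** The voluntary circumferential strain
   `s = (ĉ(θ) − C₀(θ)) / C₀(θ)` — the relative increase of the upper-arm
   circumference over its passive ("connatural") value at the same elbow
   angle — is proportional to the activation level, with an
   angle-dependent and a velocity-dependent slope factor.
2. **Merged factors.** All angle-dependent terms (force–length factor,
   moment arm, strain–activation slope, maximum torque) merge into one
   torque–angle factor, and all velocity-dependent terms into one
   torque–velocity gain.

The working model is then

\[ T = s \cdot \eta(\theta,\dot\theta), \qquad
   \eta = \hat G_l(\theta)\,G_v(\dot\theta), \qquad
   \ln \eta = a_1\theta + a_2 \ \text{ on } [50^\circ, 100^\circ] . \]

`η = T/s` diverges at the range-of-motion (ROM) limits where the strain
vanishes, which is why the log-linear fit and all error evaluation are
restricted to the stable 50–100° range, and why η samples with strain below
a threshold are masked. The individual Hill quantities are deliberately
*not* identifiable: only the merged `(a₁, a₂)` and the gain are estimated.

The empirical claim at the heart of the analysis is that `G_v` is constant
over 60–120 °/s. Under that null, η curves measured at different velocities
coincide, an averaged `η̄(θ)` can be trained from first-set isokinetic
flexions, and torque in any later flexion (isokinetic or isotonic) is
predicted as `T = s·η̄(θ)`.

## What the synthetic generator states

No raw subject data accompany the study this package replicates, so the
generator *is* the stated world, with known ground truth for recovery
tests. Its defaults are fixed once and not tuned against test outcomes:

| Parameter | Default | Why |
|---|---|---|
| ROM | 30–120° | protocol constant |
| Velocities | 60/90/120 °/s, 4 cycles/set, 2 sets | protocol constants |
| Isotonic impedance | 30%, 40% of the subject's peak torque at 120 °/s | protocol constant (e.g. a 32 N·m subject gets 10/15 N·m) |
| `a₁` | U(−0.018, −0.008) /° | η declines with angle; spread gives visible between-subject heterogeneity |
| `a₂` | U(6.0, 7.0) | with the strain peak below, peak torques land at ≈25–55 N·m, typical of healthy adult elbow flexion |
| `s_max` | U(0.08, 0.25) | inside the inclusion rule: subjects under 5% peak strain are excluded, strain stays within 0–30% |
| strain profile | `s_max·[4u(1−u)]^p`, `u=(θ−30)/90`, `p=1` | only the endpoint behaviour is stated (zero at both ROM limits); this is the simplest smooth unimodal bump with one shape knob |
| `C₀(θ)` | linear, `c0_mid` U(270, 320) mm at 90°, slope U(0.12, 0.30) mm/° | passive shortening thickens the flexors, so C₀ increases with flexion; a linear profile is within measurement error over 90° |
| torque noise | 0.5 N·m (Gaussian, iid) | ≈1–2% of peak torque, a plausible dynamometer noise floor |
| circumference noise | 0.4 mm (Gaussian, iid) | ≈0.13% of circumference; sensor noise is unreported, this is a placeholder, not a device claim |
| drift | `2 mm·(1−e^{−t/60s})` | emulates fabric-sensor resistance relaxation: slow, saturating, monotone — the phenomenon rectification exists to remove |
| sampling | 100 Hz | unreported; ample for 60–120 °/s motions and makes 60/90/120 °/s flexions hit the ROM apexes on exact samples |
| inertia, damping | 0.08 kg·m², 0.10 N·m·s/° | forearm-scale inertia; damping sets isotonic peak speeds near 250–300 °/s |

η is log-linear over the *whole* ROM (not just 50–100°) so the fitting
stage's model is exactly realizable and parameter recovery is a sharp
test. Extensions carry zero voluntary strain ("rest during extensions");
drift accumulates over the whole trial, which is what the 2nd-flexion
selection rule mitigates. Each trial draws all its randomness from one
integer seed; the study driver fans a single top-level seed out to
per-trial seeds through one `sample.int` draw, making whole studies
byte-reproducible.

**What the generator does not emulate:** triceps co-contraction, sEMG,
cuff-pressure effects on soft tissue, pennation-angle changes, sensor
electronics beyond additive drift, angle-channel noise, or any
subject-level correlation between parameters. A green test therefore
establishes that the *pipeline* is correct and calibrated under the stated
world — not that the model is physiologically validated.

### The isotonic strain command

The stated isotonic dynamics are a rigid forearm,
`I·θ̈ = T_muscle − impedance − c·θ̇`, clipped to the ROM with velocity
zeroed at the limits. Taken literally with `T_muscle = s(θ)·η(θ)` and the
endpoint-zero strain profile, the flexion can never leave the lower stop
(zero strain ⇒ zero torque at 30°). Real subjects contract isometrically
against the resistance until the lever yields. The generator therefore
drives the muscle with a strain *command*: the maximum-effort profile, or,
where that is insufficient, a drive floor `(1+0.1)·impedance/η(θ)` — just
enough strain to keep the lever moving — with a 0.3 s activation ramp at
the standstill start. The floor tapers linearly to zero over the last 8°
so strain and torque still vanish toward ROM-high; the flexion ends where
the arm stalls at the taper equilibrium (typically ≈7° short of ROM-high)
or at the stop. Torque, strain and circumference remain mutually
consistent (`T = s·η` exactly), so the prediction stage sees a fair test.

## Numerical choices

- **Calibration.** Passive samples are averaged in 1° angle bins; each
  grid point is stored at the bin's *mean sample angle* (not the bin
  centre) and evaluation interpolates linearly with *linear* edge
  extrapolation. Both choices make calibration exact for locally linear
  profiles; flat edge extrapolation would bias `C₀(30°)` by half a bin
  times the profile slope (≈0.1 mm) and measurably bias the fitted slope.
- **Segmentation.** Flexions are rising sweeps found by an
  alternating-extremum scan with 2° hysteresis on a 50 ms-smoothed angle
  signal, refined to the raw-signal extrema — so on noiseless triangular
  trajectories the boundaries equal the brute-force argmin/argmax exactly.
  A sweep must cover ≥70% of the ROM (isotonic flexions stall early).
- **Rectification.** Each flexion is mapped affinely onto the fixed frame
  `[C₀(30°), C̄(top)]`, where `C̄` averages the measured circumference at
  all flexion-to-extension turnarounds of the trial. The map is invariant
  to additive offsets of the measured channel (the drift it removes); its
  real benefit is *consistency across flexions* — rectified cycles of a
  drifting trial agree ≈40× better than raw ones. Endpoint circumferences
  are read from a ±1° window by default; `endpoint_window = 0` uses the
  single apex sample, which is exactly unbiased and is what the noiseless
  recovery and ANOVA-calibration tests use (the window's discretisation
  bias, ~10⁻⁴ in fit units, differs across velocities because the sample
  spacing does, and a homogeneous-null ANOVA is sensitive enough to see
  it).
- **η masking.** `min_strain = 0.005` (0.5% strain) excludes
  division blow-ups near the ROM limits while keeping nearly all of
  50–100°; samples with non-positive ratios are masked, so `ln η` is
  always defined on the mask.
- **Log base.** The fit uses the natural log by default; base is a
  configuration option because `η̄`, the ANOVA conclusions and all
  predictions are invariant to it (only `(a₁, a₂)` rescale by `1/ln 10`).
- **η̄ training.** Raw η curves (not fitted lines) are interpolated to a
  common 1° grid and averaged pointwise; a grid point is valid only where
  every training curve contributes. For a single curve the grid defaults
  to the curve's own angles, which makes train-on-self prediction the
  exact algebraic inverse of `η = T/s`. Prediction never extrapolates:
  out-of-range samples are masked (or rejected with `strict = TRUE`).
- **ANOVA.** Classical fixed-effects one-way ANOVA with
  `η² = SS_between/SS_total` effect sizes (Cohen bands 0.01/0.06/0.14 —
  the only effect-size measure consistent with the study's printed
  magnitudes and "medium-high" label). When the total variance is
  floating-point dust (noiseless simulations produce bit-near-identical
  fits), the groups are reported as identical (`F = 0, p = 1`) instead of
  an unstable 0/0 ratio; exactly zero variance remains an error.
- **Error indicators.** `r_mr` divides by the measured torque, so samples
  with `|T_m|` below 0.5 N·m are excluded from it; zero-variance
  correlations and zero-mean `r_m` report `NA` rather than erroring.

## The unit of replication in the velocity ANOVA

The replicated study reports per-subject p-values near 0.99 for both
parameters. With the one-way layout used here — velocity groups each
containing the same subjects' fitted parameters — that behaviour is
expected: between-subject spread inflates the within-group variance while
cancelling out of the between-group differences, so the unpaired F test is
severely conservative under the null. The cohort-level replica
(`run_study`, acceptance target) shows exactly this: p ≈ 0.93–0.99. The
package's type-I calibration test therefore uses a *homogeneous* cohort
(identical true parameters across subjects), which makes the groups
exchangeable and recovers the nominal 5% rejection rate; the power test
injects a 2× velocity-gain spread across 60–120 °/s and rejects in
essentially every replicate. Per-subject ANOVA tables (2 fits per velocity
from the two sets) are produced for structural fidelity; no
multiple-testing correction is applied across subjects, matching the
replicated analysis.

## Known limitations

- The generator's noise magnitudes are placeholders; at the defaults the
  cohort mean relative errors come out near 3–6%, lower than the 15–22%
  the original study reports on real subjects, whose error budget includes
  physiological and device effects not modelled here. The structure of the
  reports, not their absolute error level, is the replication target.
- Rectification re-anchors each flexion to the trial's average top
  circumference: monotone within-trial drift is compressed, not removed in
  absolute terms (the paired drift test documents the residual).
- The isotonic drive floor is a modelling device to make the stated
  dynamics traversable; real isotonic effort profiles are unknown.
- Only flexion (loading) phases are analysed; extensions are treated as
  rest, and no statistical validation of the model beyond the replicated
  analyses is attempted.
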