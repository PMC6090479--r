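---
title: "Models and methods: simulating and analyzing error-related potentials in a virtual throwing task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: simulating and analyzing error-related potentials in a virtual throwing task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the scientific models inside `skittlesERP`, the
parameters that matter, the design choices made where the design was
genuinely open, and the limits of what the synthetic data can show.

## 1. The task and its physics

In the semi-virtual Skittles task a participant rotates a lever
(length 0.4 m, pivot at (0, −1.5) m) in the horizontal plane and releases a
ball that travels around a central post (radius 0.25 m at the origin) toward
a target (radius 0.05 m at (0.35, 1.0) m). The outcome is fixed at release
by two numbers: the lever angle and the angular velocity.

**Angle convention.** All functions share one convention, defined in
`lever_config()`: at 0° the lever tip lies on the negative-x side of the
pivot (the start circle); the angle increases in the clockwise sense of the
screen frame (target toward +y), so at 90° the tip points toward +y. The
ball leaves the tip tangentially with speed `|ω_rad| × 0.4 m`. Whether a
real lever would add a radial velocity component at release is unknowable
from the task description; we model the release as purely tangential and
expose the release state so users can construct alternatives.

**Flight model.** The original task's ball dynamics come from a physics
model whose equations are not reproduced in task descriptions beyond "an
elliptic path around the post". We therefore model the flight as a
two-dimensional isotropic damped harmonic restoring force about the post
center — the simplest dynamics with exactly that phenomenology. Per axis,

$$x(t) = A\,\sin(\omega t + \varphi)\,e^{-t/\tau},$$

with $A, \varphi$ solved from the release position and velocity. This is the
closed-form solution of $\ddot x = -(\omega^2 + 1/\tau^2)\,x - (2/\tau)\,\dot x$,
and the test suite verifies the closed form against an independent
Runge–Kutta integration of that equation to better than $10^{-6}$ m over a
2 s flight.

**Parameter defaults** (all config-exposed in `oscillator_params()`):

| parameter | default | unit | rationale |
|---|---|---|---|
| ω | 3.0 | rad/s | see below |
| τ | 10 | s | mild damping; orbits visibly shrink but do not collapse |
| flight duration | 2 | s | one-plus orbit; scoring horizon |
| dt | 0.002 | s | matches the 500 Hz recording clock |

ω was chosen by grid search so that a near-optimal throw (release near 80°,
300°/s) reaches the closest point to the target about 0.87 s after release —
consistent with the task's outcome feedback being delayed by 850 ms because
that is roughly when the ball reaches the target's vicinity.

**Scoring.** `score_trajectory()` records the minimal center-to-center
ball–target distance *d*, scanning only samples before the first post
contact (contact radius = post radius + ball radius = 0.30 m, circles
touching). Classification (`classify_trial()`) is: hit iff *d* ≤ 0.10 m and
no post contact; for ERP averaging, clear hit iff *d* ≤ 0.07 m, clear error
iff *d* ≥ 0.12 m, everything else excluded. All three boundaries are
inclusive, matching how the cut-offs are stated; the movement-onset rule in
`detect_movement_onset()` is strict (> 50°/s) because it is phrased as
"exceeded".

**Release-parameter model.** Trials are drawn with Gaussian scatter around a
participant aim point. The defaults (aim 80°, 300°/s; SDs 8°, 40°/s) were
calibrated once on the *d* landscape so a session lands at ≈73% hits, ≈18%
clear errors, and almost no post contacts — inside the 50–80% hit-rate band
of trained cohorts. A per-participant lognormal skill factor (σ = 0.35)
multiplies the scatter, giving between-participant hit-rate SDs of roughly
10–15 percentage points; practice sessions shrink the scatter by fixed
multipliers (1.38, 1.12, 0.95, 0.80), reproducing improvement from the
mid-60s to around 80% across four sessions. In the observation condition the
trial list is balanced to 50% hits / 50% misses by selection from an
oversampled pool, mirroring replayed observation blocks.

## 2. The synthetic EEG generator

The generator exists so that every downstream stage is testable without the
original recordings. It emulates:

- 500 Hz sampling, a small montage around FCz plus two mastoids;
- event markers for trial start, ball release, outcome feedback (exactly
  `round(0.850 × fs)` samples after release), and outcome class;
- Ne/ERN- and FRN-shaped components injected on error trials, time-locked to
  release (window 200–350 ms) and feedback (150–350 ms) respectively. The
  default shape is a raised-cosine arch whose window mean is analytically
  `peak × 2/π`; a truncated Gaussian (±3σ, σ = width/6, window mean
  `peak × √(2π)/6 × (2Φ(3)−1)`) is available. Design-point peaks default to
  −0.6 (ERN) and −3.4 μV (FRN) for the observation condition and 0.05 and
  −5.6 μV for the active occluded condition, with per-participant true
  amplitudes drawn around those points (SDs 1.6 and 4.0 μV on the peak
  scale);
- background noise as a sum of spectrally shaped 1/f^α (α = 1) and white
  Gaussian noise. The shaping weights are deterministic, so the noise is
  exactly Gaussian with total variance `pink_sd² + white_sd²` (defaults 8
  and 3 μV). The pink spectrum is flat below 0.25 Hz — real scalp spectra
  flatten toward 0 Hz, and an unbounded 1/f pole would make long-recording
  variance estimates dominated by a single random low-frequency mode. FFT
  lengths are padded to highly composite sizes for speed.

Noise and between-participant SDs were calibrated so that group confidence
intervals at the study's cohort sizes have half-widths of roughly 0.5–2.5 μV
across windows, which makes power behavior realistic. These are design
choices: the original study reports no noise statistics of its recordings.

**What the generator does not emulate:** ocular and movement artifacts
(blinks are out of scope along with ICA correction; the ±100 μV rejection
proxy is exercised with synthetic square pulses in tests), electrode drift
and impedance changes, topographic detail beyond fixed attenuation weights,
and any trial-to-trial coupling between behavior and neural amplitude (the
injected amplitude is constant within a participant). Passing tests
therefore demonstrate that the *pipeline* is correct and calibrated, not
that it would be robust to every artifact class in real data.

**Seeding.** A master seed yields per-participant substreams by drawing one
integer seed per participant from the seeded generator; cohorts are
reproducible participant by participant, and two runs with the same
`(config, seed)` produce bit-identical results.

## 3. The ERP pipeline

Processing per participant: band-pass filter, re-reference, segment, reject,
baseline-correct, average by outcome class, subtract, window.

- **Filter:** Butterworth 0.2–30 Hz. The order is a free design choice; we
  use order 2 applied forward–backward (zero phase) — standard ERP practice
  that preserves component latency.
- **Reference:** average of the two mastoids, subtracted from every scalp
  channel.
- **Segments:** observation condition anchored at trial start
  (−600…+2800 ms, covering trial start, replayed release, and feedback);
  active condition anchored at release (−600…+2200 ms). Epochs overlapping a
  recording edge are dropped and counted.
- **Artifact proxy:** manual inspection is not reproducible, so an
  amplitude-threshold rejection (±100 μV, configurable) stands in.
- **Baseline:** the 0–200 ms interval after the epoch's own release marker —
  the gap between release and the Ne/ERN window — subtracted from the whole
  epoch. Whether feedback-locked activity was baselined separately is not
  stated in the paradigm's descriptions; we use the single release-locked
  baseline everywhere and document it here.
- **Marker-relative windows:** all window math is relative to the per-epoch
  release/feedback markers, not the cutting anchor. In the observation
  condition the replayed release latency varies from trial to trial, so
  averaging re-aligns epochs to the markers (release-locked and
  feedback-locked variants of every curve).
- **Window edges:** half-open `[start, end)` on the 2 ms grid, so the shared
  350 ms edge of the two windows is never double-counted.
- **Statistics per window:** mean amplitude, and peak amplitude defined as
  the window *minimum* (the components are negativities). The per-window
  minimum of a grand average is never below the mean of per-participant
  minima — the package tests this Jensen-type inequality, which is why
  averaged peak amplitudes can differ from the peak of the grand-average
  curve.

## 4. Group inference

Window mean amplitudes are tested against zero with a one-sample t-test,
**one-tailed in the hypothesized (negative) direction** by default: the
potentials under study are negativities, so the hypotheses are inherently
directional (note that a directional test can yield p-values above 0.5, e.g.
p = 0.55 at t = +0.13, which a two-sided test never produces). The tail is
configurable. Confidence intervals are always two-sided 95%. Effect size is
Cohen's d = |mean|/SD.

Bayes factors use the JZS default prior — a Cauchy distribution with scale
0.707 on the standardized effect size, the default of the analysis software
version this paradigm reports — with the prior restricted to the
hypothesized half-line for directional tests. The marginal likelihood is
computed by quadrature over the prior quantile (`δ = r·tan(π(u−½))`,
u ∈ (0,1)), which keeps the integrand bounded on a finite domain; the
implementation satisfies `BF₋ + BF₊ = 2·BF₂` to 10⁻⁶ relative and matches an
independent JZS implementation to four decimals. Evidence labels follow the
1 / 3 / 20 / 150 cut points (weak / positive / strong / very strong; below 1
favors the null).

The between-condition contrast uses the pooled-variance independent t-test
(df = n₁ + n₂ − 2 = 33 at the study's cohort sizes), directional per window:
the prediction-related window is expected more negative in the observation
condition, the feedback-related window more negative in the occluded-active
condition. Welch's variant is available. Hit rates across practice sessions
are compared with a one-way between-groups ANOVA; note that a
repeated-measures decomposition would be the more faithful model for four
sessions of the same participants, but the between-groups form is the
package default (its F is conservative when participants differ in skill),
and both are standard `stats` calls.

## 5. Numerical choices and degenerate inputs

- Flight coefficients: `A sinφ = p₀`, `A(ω cosφ − sinφ/τ) = v₀` per axis; a
  release at the post center with zero velocity is rejected as degenerate.
- A trajectory whose first sample already contacts the post scores `d = ∞`
  and counts as a post hit.
- Markers are placed on integer samples; the feedback marker is defined as
  release sample + `round(0.850 fs)`, so the 425-sample spacing is exact by
  construction rather than subject to floating-point rounding.
- Zero-variance samples (noise-free cohorts) abort group inference with a
  clear error; `run_pipeline()` excludes participants lacking clear-hit or
  clear-error epochs from group statistics with a logged message.
- Quadrature failures in the Bayes factor raise a numerical error naming the
  integrator message rather than returning a value.

## 6. Problem sizes used in validation

The packaged validation (test suite and `scripts/acceptance.R`) uses
deliberately scaled problem sizes, chosen to exercise every code path at
desk scale: 100 random releases for the oracle comparison; a 200×200 release
grid for the classification partition; noise-free cohorts of 4 participants
with 24–40 trials for exact recovery (recovery is exact per participant, so
cohort size adds nothing); 1000 null cohorts of n = 18 for type-I
calibration and 400 cohorts for bias, simulated at the epoch level (the
epoch-level shortcut is proven equal to the full pipeline route in a unit
test); and a noisy end-to-end run at the study's participant counts (18/17)
with 80–120 trials per participant. The full-scale defaults (280/430 trials)
run in a few minutes and produce the same qualitative pattern; they are the
package defaults precisely so that `run_pipeline(default_config(), seed)`
reproduces the study-scale design.

## 7. Known limitations

- The flight dynamics are a stand-in with the correct qualitative geometry;
  absolute *d* landscapes (and hence which release strategies are optimal)
  will differ from the original task model.
- The noise model has no physiological structure (no alpha rhythm, no
  evoked variability, no artifacts), so statistical power estimates
  transfer to real data only to first order.
- Between-participant amplitude variability is Gaussian around the design
  points and independent of behavior; real Ne/ERN amplitudes correlate with
  prediction ability, which this generator does not model.
- The between-groups ANOVA treats sessions as independent groups; with the
  same participants across sessions it is conservative in spirit but not a
  repeated-measures analysis.
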