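---
title: "Methods: synergy extraction and kinetics for balance-recovery lunges"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synergy extraction and kinetics for balance-recovery lunges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungesyn)
```

This vignette documents the models and procedures the package
implements, the tunable parameters and their defaults, the numerical
choices made where the design was genuinely open, what the synthetic
generator does and does not emulate, and the known limitations.

## The task and the data

A balance-recovery lunge is a step reaction: the subject leans until
balance is lost, steps onto a force plate with the right leg, and holds
the lunge until stable. One repetition produces multirate streams:
3-D marker trajectories (nominally 250 Hz, mm), 13 channels of surface
EMG of the stepping limb and a triaxial ground reaction force (GRF), the
latter two at 1 kHz. The interval of interest runs from the lift-off of
the stepping foot, through touchdown, to the post-touchdown steady
state. All event indices are stored on the 1 kHz analog timebase;
kinematic indices are converted by rate ratio with round-half-up.

## Cycle segmentation

**Touchdown** is the first sample whose Euclidean GRF norm exceeds a
threshold (default 0 N, appropriate for synthetic traces that are
exactly zero during swing; ~10 N is the practical choice for real
plates, which never read exactly zero).

**Lift-off** uses the foot acceleration-and-jerk algorithm: the fifth
metatarsal's vertical trajectory is low-pass filtered (zero-phase
4th-order Butterworth, 50 Hz default), acceleration and jerk are taken
as 2nd/3rd central finite differences (filter-then-differentiate), the
lift-off estimate (LOe) is the global acceleration maximum in the 800 ms
preceding touchdown, and the refined event is the jerk zero-crossing
marking a local acceleration minimum within (−50, +200) ms of LOe. A
jerk zero is operationalized as a sign change between adjacent samples;
when several qualify, the candidate nearest LOe wins, ties broken toward
the earlier sample. If none qualifies the estimate is returned with a
warning rather than failing the trial.

**Steady state**: the knee angle after touchdown settles once the lunge
is stabilized. The detector finds maximum knee flexion after touchdown
(plateau ties broken toward the earliest sample — the angle convention
feeding this step is the 180°-at-full-extension inter-segment knee
angle, so maximum flexion is the angle minimum), differentiates the
angle from that point on, and segments the slope series with a divisive
energy-statistic change-point procedure: within each segment the split
maximizing `Q = mk/(m+k) · E(X, Y)` (energy distance, exponent 1) is
tested by permutation and significant splits are recursed into. The
returned event is the start of the first segment whose mean slope does
not significantly differ from zero (one-sample sign-flip permutation
test at the same alpha). A trial whose slope never settles raises a
"no steady state" error, mirroring the practice of repeating invalid
attempts. Since no reference implementation of the energy-based
procedure is relied upon, the in-package detector is cross-checked in
the tests against an O(n³) brute-force single-split energy scan.

Defaults for the change-point step — significance level 0.05, 199
permutations, minimum segment 30 kinematic samples (120 ms at 250 Hz) —
are exposed in `event_config()` rather than hard-coded, because the
literature that introduced the procedure leaves them to the user. 199
permutations bounds the smallest attainable p-value at 1/200, enough to
call a split at alpha 0.05 while keeping the detector fast.

## EMG processing

Envelopes are computed channel-wise: zero-phase 4th-order Butterworth
high-pass at 50 Hz, full-wave rectification, zero-phase 4th-order
low-pass at 20 Hz, and a final clip at zero (a zero-phase low-pass can
undershoot). "4th order" is the order per pass; the forward–backward
application doubles the effective attenuation, which is the convention
in this literature. The zero-phase filter extends the signal by odd
reflection and starts each pass from the constant-history steady state
of its first sample; the pad is sized from the slowest filter pole so
the operation is symmetric under time reversal to float tolerance.

Each cycle is time-normalized to 200 points — swing resampled to 50,
stance to 150, linear interpolation — so touchdown always falls on the
50/51 boundary, and cycles are concatenated.

Two normalizations serve different purposes:

* **Synergy normalization** (`normalize_for_synergies()`): each muscle's
  concatenated envelope is min–max scaled so every row of **V** spans
  exactly [0, 1]. Scaling to the trial maximum followed by subtraction
  of the minimum, taken literally, would leave the row maximum at
  1 − min; the package rescales once more so the row is exactly [0, 1],
  which is what "ranging between zero and unity" requires and what the
  factorization expects. The min–max range is computed on the
  concatenated, time-normalized signal (rather than the raw trace) so
  the unit bounds hold exactly in the matrix actually factorized.
* **Per-direction normalization** (`normalize_per_direction()`): each
  muscle is divided by its maximum over all of a participant's trials in
  one lunge direction, no min subtraction. This is the scale on which
  EMG amplitudes and coactivation are compared; it is invariant to
  uniform rescaling of the inputs.

Coactivation indices are per-point antagonist/agonist ratios —
hip `(FL+RF)/2 : (ME+MA)/2`, knee `(BF+ST)/2 : (RF+VM+VL)/3`, ankle
`TA : (GM+GL+SO)/3`. Points with a zero denominator are propagated as
missing values, never as zeros, because a zero would bias averaged
ratios downward.

## Synergy extraction

`synergy_nmf()` implements the classical Gaussian NMF multiplicative
updates with an epsilon (1e-12) guarding the denominators; the W update
uses the already-updated H. Convergence is declared when the relative
change of R² over a 20-iteration window drops below 0.01%; a 10⁴
iteration cap (with warning) bounds the worst case. Ten restarts from
uniform-random non-negative matrices are seeded `seed + restart − 1`, so
a single master seed reproduces the whole computation. The best-R²
solution is kept, and the scale indeterminacy of the factorization is
fixed by rescaling each primitive row to unit maximum with the scale
folded into the module — metrics are therefore always computed on a
fixed normalization, matching the convention of plotting
amplitude-normalized primitives and 0–1 modules.

`select_rank()` runs the factorization for ranks 1…round(0.75 m) (10 for
13 muscles), fits a straight line to the (rank, R²) points, and drops
the lowest rank until the fit MSE falls below 10⁻⁵ or two points remain;
the chosen order is the smallest rank still in the window. Two read-offs
are not pinned down by the stop rule alone and are fixed here: a curve
that is linear from the start selects rank 1, and an exhausted loop
returns the lower of the last two ranks.

**CoA** maps the cycle onto the unit circle (θ_t = 2π(t−1)/n), sums the
primitive as a circular mass distribution (A = Σ cosθ·H, B = Σ sinθ·H)
and returns the resultant angle as cycle points. The mapping is 1-based:
a unit impulse at point t has CoA exactly t. A uniform primitive has no
resultant and raises an error. **FWHM** subtracts the cycle minimum and
counts points strictly above half the resulting maximum. Both are
computed on the mean 200-point cycle of each primitive by default, with
per-cycle values available through `cycle_metrics()` (used for the
early/late repetition summaries).

**Classification** clusters mean-cycle primitives by shape
(agglomerative, average linkage, cosine distance, cut at 1 − 0.80).
Clusters whose medoid shows a single peak above half maximum are
fundamental and are labelled swing → touchdown → weight acceptance →
stabilization in ascending CoA order; primitives outside every
fundamental cluster are combined, and no CoA/FWHM is reported for them.
The unsupervised classifier of the original synergy literature is not
fully specified in public sources, so the clustering algorithm and its
0.80 similarity threshold are this package's configurable choices. With
fewer than four fundamental clusters the label prefix in CoA order is
used; this is correct when the missing synergy is the last one and is a
documented approximation otherwise (identifying *which* synergy is
absent in general requires reference shapes that only real data can
provide).

**Overlaps** binarize each fundamental primitive at half maximum
(consistent with the FWHM definition) and count, per time point, the
number of simultaneously active primitives minus one, floored at zero,
then average across trials.

## Kinematics and inverse dynamics

Joint angles are sagittal-plane (x–z) inter-segment angles: knee between
thigh (trochanter→epicondyle) and shank (epicondyle→malleolus) vectors
with 180° at full extension; ankle between shank and foot
(calcaneus→fifth metatarsal) vectors, 90° at the anatomical reference;
hip as thigh inclination from the downward vertical (anterior positive).
Inter-segment angles are invariant to rigid rotations; the inclination
is not, by construction. The published conventions for lunge kinematics
are not stated precisely enough to guarantee matching offsets, so the
conventions here are fixed, documented, and configurable downstream.

Resultant moments come from a bottom-up planar Newton–Euler recursion:
the foot balances the GRF applied at the center of pressure (zero during
swing), its weight and inertial load; the ankle reaction is propagated
to shank and thigh. Segment masses, CoM locations and gyration radii are
Winter-style fractions of body mass and segment length, shipped as an
editable list (`winter_parameters()`, YAML-overridable) because they are
external literature constants. Accelerations are 2nd central differences
of 50 Hz-low-passed marker positions. Moments are reported with
extension/plantarflexion positive. The 2-D simplification is deliberate:
only sagittal-plane moments are analysed in this task family, and
frontal/transverse inverse dynamics is out of scope. When no measured
CoP is available it defaults to the fifth metatarsal's ground-plane
position, a documented approximation.

## The synthetic generator

The generator is the package's verification instrument; its defaults are
the study conditions used throughout the tests.

* **Envelopes** (`simulate_envelopes()`): V = clip₀(W·H + ε) with
  Gaussian-bump primitives (default centers 25/60/85/120 points, σ = 6,
  unit amplitude) through a fixed plausible 13×4 module matrix, 25
  cycles, additive Gaussian noise (sd 0.05, truncated at zero so V stays
  non-negative — a deliberately simple noise model that keeps the NMF
  assumptions transparent), per-cycle jitter of centers (sd 2 points)
  and amplitudes (5%) emulating repetition-to-repetition variability.
  The jitter magnitudes are engineering choices — no published per-cycle
  variability statistics exist for this task to estimate them from.
* **Events** (`simulate_trial()`): the fifth-metatarsal trajectory is a
  quintic-smoothstep rise (200 ms), hold, and slower descent (≤300 ms);
  the rise places a unique jerk-zero acceleration minimum at the known
  lift-off with the global acceleration maximum shortly before it. The
  GRF is exactly zero during swing and rises as a half-sine impact
  (peak 1.2 body weight at 100 ms) so the first loaded sample is sharp.
  The knee angle flexes during swing, then settles monotonically with a
  decaying 2.5 Hz ripple to an exact plateau at the known steady state.
  A smoothly vanishing symmetric oscillation was rejected: it leaves no
  distribution change at the plateau onset for any change-point method
  to find, and its full-cycle segments have zero-mean slope, which makes
  the stated detection rule return early. Default timing: 350 ms swing,
  800 ms stance, in line with reported lunge durations (~1.1 s total,
  ~0.8 s to steady state).
* **EMG** channels are amplitude-modulated white noise following the
  truth envelopes, so the full envelope chain (high-pass, rectify,
  low-pass) recovers the modulation up to a constant factor that the
  normalizations remove.
* **Statics** (`simulate_static_case()`): a motionless posture with
  constant GRF at a fixed CoP; expected joint moments are computed by
  static equilibrium (each joint balances the GRF and all distal segment
  weights), an exact oracle for the inverse-dynamics stage.

What the generator does **not** emulate: soft-tissue artefact,
marker-labeling errors, plate resonance, EMG crosstalk, electrode lift,
or biomechanically consistent whole-body dynamics (marker streams are
kinematically plausible but not dynamically consistent with the GRF).
Passing the recovery tests therefore shows the algorithms are correctly
implemented and identifiable under clean conditions — not that they are
robust to every laboratory artefact.

## Repetition bookkeeping

Per condition the first and last repetitions are dropped and up to 50
central cycles kept (`run_config(central_max = 50)`); with the study's
52 valid lunges this is exactly the central 50. CoA/FWHM summaries split
the kept cycles into early and late blocks of up to 25
(`early_late_size`), generalized to `min(25, floor(n/2))` for smaller
runs. Conditions lacking a fundamental synergy produce `n.a.` cells in
the summary; a single-cycle block reports sd 0.

## Problem sizes and determinism

The test suite and the acceptance script run entirely on generated data:
the reference recovery problem is 13 × 5000 (25 cycles), rank search
1–10 with 10 restarts; pipeline-level tests use 5–7 cycles per condition
with 2 restarts, sizes chosen to exercise every code path at desk scale.
Every stochastic step — generator draws, NMF restarts, permutation
tests — derives from explicit seeds, and `run_pipeline()` seeds the RNG
from its config, so identical inputs give identical bundles.

## Known limitations

* Classification labels rely on CoA ordering; with missing fundamentals
  the prefix-labelling can misname synergies (see above).
* The steady-state detector inherits the granularity of the minimum
  change-point segment (120 ms at defaults); events closer than that to
  the trace end are not detectable.
* Inverse dynamics is 2-D; out-of-plane loading is projected away.
* Group-level inferential statistics (statistical parametric mapping,
  repeated-measures ANOVA and post-hocs) are intentionally out of scope;
  the summary tables are descriptive only.
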