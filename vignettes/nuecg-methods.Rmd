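---
title: "Interpreting non-uniformly sampled ECGs: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpreting non-uniformly sampled ECGs: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nuecg)
```

`nuecg` treats the electrocardiogram as a quasi-periodic signal whose local
bandwidth is predictable from electrophysiology: atrial depolarization
(P wave), ventricular depolarization (QRS) and repolarization (T wave)
occupy known phases of each cycle, and only the QRS carries appreciable
energy above ~40 Hz.  This makes an *arbitrary non-uniform representation*
— explicit `{t, v}` pairs whose local rate follows the expected bandwidth —
an efficient storage form, and the package provides both the sampling model
that produces such records and a full interpretation chain (beat detection,
beat classification, wave delineation) that reads them without ever
reconstructing a uniform signal.

All times in the package are milliseconds from record start and
real-valued; amplitudes are 16-bit integer counts with a gain in µV/LSB.
All leads of a record share one time grid — a deliberate simplification
that matches how the sampling model is driven (one set of wave borders per
beat across leads).

## The sampling model

An SLB (*standardized local bandwidth*) profile maps the normalized beat
cycle — 0 at the midpoint of the preceding RR interval, 1 at the midpoint
of the following one — to a local sampling frequency.  The default template
(`slb_profile()`) is parametric:

| segment | rate | rationale |
|---|---|---|
| iso-electric baseline | 100 Hz (`f_min`) | no diagnostic content above ~40 Hz there |
| P wave | 180 Hz (`f_p`) | low-frequency wave, borders still matter |
| QRS complex | 500 Hz (`f_max`) | full source rate; steep slopes, amplitudes are diagnostic |
| T wave | 130 Hz (`f_t`) | the slowest wave; its end point is the critical measurement |

with linear ramps (1.4 % of the cycle) at transitions.  The published
perceptual-relevance profile this emulates is not itself public; the chain
is explicitly sampling-model-agnostic, and arbitrary profiles load from
JSON.  `project_slb()` warps the template so that its five anchors land on
a concrete beat's borders — piecewise-linearly by default, or through a
monotone cubic warp (`warp = "spline"`, the three-step scaling-transform
variant).  Waves of premature beats may overrun the RR midpoint; the
projection then extends its segment and `slb_series_fun()` resolves
overlaps between adjacent beats by keeping the denser requirement.
Beats without usable borders are sampled at the full source rate, so
nothing is lost on unusual morphologies.

`sample_nonuniform()` integrates the local interval forward,
`t[k+1] = t[k] + 1000/f(t[k])`, with no jitter — deterministic and
testable.  Anti-aliasing is a bank of zero-phase 4th-order Butterworth
low-passes (cutoffs at 45 % of a small grid of design rates, applied to
the whole record; the per-sample value picks the nearest design rate in
log frequency).  Filtering is skipped wherever the local rate reaches the
source rate, which makes constant-full-rate sampling an exact identity.
`uniformize()` spline-interpolates onto the regular target grid and then
applies the same density-matched smoothing wherever the source grid is
sparser than the target — so interpolation at the knots of a
pseudo-non-uniform record returns the original samples exactly, while
genuinely sparse stretches are smoothed to their local Nyquist.  The
zero-phase filters produce the expected transients at both record ends;
fidelity statements therefore always refer to the interior (the first and
last second are excluded).

Out-of-band noise is deliberately *not* preserved by this round trip: a
record sampled at 100 Hz locally cannot, and should not, reproduce
broadband noise above its local Nyquist.  Round-trip PRD is accordingly
assessed on low-noise material (below).

## The QRS detector

The detection function is evaluated on its own regular grid
(`df_step = 2` ms) regardless of how the ECG is sampled — the property
that makes the detector grid-independent.  At each instant, four
regression lines are fitted to the raw sample cloud: long legs over
±61 ms and short legs over ±20 ms, by weighted least squares with a
Gaussian window over each leg (σ = leg length / 4; a flat window is
available).  The printed ratio-form kernel estimator is kept as
`slope_estimator = "eq7"` for comparison, but its denominator vanishes on
symmetric windows and it cannot recover the slope of an exact line, so the
covariance/variance form is the default — the tests pin both behaviours.

Angles are taken between the legs: `L = π − |atan(m₊) − atan(m₋)|`, near π
on flat or monotone stretches and small where the signal folds sharply.
Two normalizations matter here.  Amplitudes are first divided by the
lead's median absolute deviation — a robust scale dominated by baseline
activity, so QRS slopes saturate the arctangent while baseline slopes do
not, and detection is invariant to common amplitude scaling.  Slopes are
then multiplied by a time constant before the arctangent
(`time_scale = 61` ms, the long-leg span).  This constant sets the
contrast of the detection function: with it, the DF peaks at beats exceed
the baseline by two to three orders of magnitude, which the adaptive
threshold recursion needs — the recursion equilibrates at a level
proportional to the peak mass it sees per adaptation interval, and with
weak contrast it would settle among the T-wave responses.

The threshold is initialized from the first 2 s of DF values (geometric
mean of the median and the maximum — a scale-free point between floor and
peaks) and updated unconditionally every 120 ms;
an optional mode additionally updates at strict 3-point local DF maxima.
Each upward crossing contributes one detection, timed at the DF maximum of
the supra-threshold excursion: the raw crossing instant depends on the
threshold height, while the excursion peak is a stable per-beat landmark.
Detections are landmarks, not fiducials — the delineator refines them.  A
DF with zero dynamic range (flat record) yields no detections.

## The beat classifier

Beats are compared as graphs of `(τ, value)` nodes over [−200, +400] ms
around the detection point.  The distance interpolates each graph at the
other's node instants, sums absolute value differences weighted by a
time-dependent factor, averages the two directions (making the distance
symmetric), and divides by the mean absolute amplitude of the two graphs
(making it scale-invariant).  The weight is proportional to the class
kernel grid density at τ, normalized to mean 1 — samples near the fiducial
point dominate the likelihood assessment.  Node values are
baseline-corrected (median of the window) on extraction: without this,
slow baseline wander contributes an offset term comparable to genuine
morphology differences and the intra/inter-class distance distributions
overlap (measured during calibration).

Class kernels live on a fixed, beat-independent quantization pattern:
0.25 ms spacing for |τ| ≤ 50 ms (8× the densest 500 Hz signal grid),
then 1, 2 and 4 ms out to ±200/400 ms — monotone density decay away from
the fiducial point.  Kernels hold per-point running means with per-point
member counts.

Clustering is multipass: the first pass applies the founding threshold
(join and update the nearest kernel if within `new_class_threshold`, else
found a new class, with early abort of a comparison once the cumulative
score exceeds the threshold); later passes freeze kernels, assign every
beat to its nearest kernel (ties to the lowest class index), then rebuild
kernels from members; the process stops when two consecutive passes agree
or after `max_iter = 10` passes.  Classes that lose all members are
dropped, so over-founding in the first pass self-heals.  The default
threshold (850) was calibrated once on the synthetic suite as the midpoint
between the upper envelope of intra-class beat-to-kernel distances and the
lower envelope of cross-class ones — beat-to-*kernel*, not beat-to-beat,
because the kernel grid roughly doubles the node count entering the sum.
Beats truncated by a record edge are excluded (`NA` assignments).

## The NUTS transform and the delineator

The slotted estimator correlates the non-uniform signal with regularly
sampled analyzing atoms: a pair (signal sample *i*, atom tap *j*) enters
the double sum when their lag is within half a tap spacing
(`slot_kernel()`, closed boundary), and the sum of paired products is
normalized by the number of selected pairs.  On a uniform grid this
reduces to an ordinary discrete correlation; on sparse stretches the
count normalization keeps the estimate unbiased.  The transform is exact
by construction — the tests compare every coefficient against an
independent brute-force double sum and require agreement to 1e−12.

The atom is the Coiflet-5 mother wavelet averaged over each of the 30
unit cells of its support, at unit energy, with tap spacing `2^a`·2 ms at
scale *a* (equal to the dyadic shift step).  Two alternatives were
measured and rejected during design: point-sampling ψ at the cell centres
aliases badly (the wavelet is sharply peaked, and two taps absorb nearly
all energy), and the raw 30-tap highpass filter carries side ripples of
3–10 % of the main lobe up to eight taps out, which leak QRS energy into
the P-wave search band.  The cell-averaged atom's tails decay below 0.1 %
of the main lobe within four taps.  With this construction the wave bands
map to scales as: QRS at scale 2, P at scale 3, T at scales 4 then 5 — one
dyadic level away from some published delineator configurations, which is
expected whenever the atom geometry differs.

Delineation reads the per-scale coefficient series (3-point smoothed,
[1 2 1]/4) through qualified landmarks:

* **QRS** (scale 2, ±110 ms around the detection): significant extrema are
  those above 8 % of the dominant extremum, floored at 3.5× the
  coefficient noise; the first and last bracket the complex, and onset/end
  are the outward decay crossings of |c| at 6 % of the bracketing
  extremum (floored at 2.5× noise), plus a small symmetric offset
  (−2.37 ms).  The construction is mirror-symmetric, so a symmetric
  complex delineates symmetrically.
* **P** (scale 3, window from 35 % of the local RR before QRS onset to
  24 ms before it — a full shift step clear of the QRS response): a
  present P shows a dominant extremum interior to the window; its flanking
  zero crossings give a lobe centre and half-span, and the borders are the
  centre ∓ calibrated multiples of the half-span (2.30/2.13).  Dominants
  at the window edge are tails of neighbouring waves and are rejected.
* **T** (scale 4, then 5; window from 80 ms after QRS end to 60 % of the
  local RR): T-end is the outward decay crossing of the dominant extremum
  at 30 % of its height plus a calibrated offset (66.5 ms).  The window
  reaches 40 ms further back so the T lobe forms an interior extremum, but
  only extrema past the nominal start may dominate.  Qualification is
  sign-agnostic, so inverted T waves delineate identically.  The fallback
  scale must show twice the relative evidence before accepting a wave.

Literal outward zero crossings do not exist for this near-symmetric atom
(the response decays without changing sign beyond the side lobes), and
decay crossings chased to very small fractions sit below the noise floor;
the landmark geometry above keeps every border anchored to steep, stable
features.  Zero crossings and decay crossings are linearly interpolated
between shifts, so all borders are real-valued ms that may fall between
samples.  Presence gates combine an analytic noise floor with a small
fraction of the record-wide coefficient magnitude at the wave's scale
(computed over well-supported shifts only), which rejects residual tails
of neighbouring complexes even on noise-free fixtures.

The coefficient noise floor is propagated analytically: the per-sample
noise σ is estimated from scaled second differences (median
|Δ²v|/0.6745/√6 — linear trends cancel, the QRS minority does not move a
median), and the floor at a scale is σ·√(Σg²·n̄)/N̄ times the smoothing
gain, where n̄ is the mean pair count per tap.  A fraction-of-window-RMS
rule was tried first and fails structurally: the wave under measurement
dominates its own search window's RMS.

Multilead fusion averages per-lead borders (a wave is present if any lead
finds it); averaging was preferred over earliest-onset/latest-end
combination because extreme-value fusion biases borders outward under
noise.

All delineator constants were calibrated once, on the synthetic suite at
its study conditions, against the generator's ±3σ border convention, and
frozen in `delineator_config()`; only width-like biases were calibrated
away — the small common shift of both QRS borders is morphology-driven and
cancels in every reported duration.

The orthogonal periodized Coiflet-5 analysis/synthesis pair
(`dwt_coif5()`/`idwt_coif5()`) documents the reversibility of the chosen
wavelet family on uniform grids; it is a reference, not part of the
non-uniform path.

## The synthetic generator and what passing tests mean

`generate_record()` builds multilead records from sum-of-Gaussian beat
morphologies — five components (P, Q, R, S, T) with amplitude, centre and
width — because analytic ground truth matters more here than physiological
realism: borders are defined at ±3σ of the outermost contributing
component, exactly.  Three presets cover a normal beat, a ventricular
ectopic (wide QRS, no P, discordant T, premature with compensatory pause)
and an atrial ectopic (inverted P, deep S).  RR intervals jitter normally
(σ 25 ms, truncated), beat amplitudes by 5 %, and baseline wander
(80 µV, 0.33 Hz) plus white noise are added after ground truth is
recorded.  A single seed makes records bit-reproducible.

Two noise regimes define the study conditions: the detection suite runs at
SNR 20 dB (60 s, two leads, ~80 beats), while the delineation and
round-trip suites run at SNR 30 dB with repeated near-identical beats —
emulating averaged conformance-testing material, where delineators are
customarily evaluated; white noise at 20 dB contains substantial energy
above every local Nyquist, which no bandwidth-matched representation can
or should reproduce.  Problem sizes in the shipped tests (10 s × 10
records for estimator exactness, 60 s for detection, 240 s for
clustering, 2 × 45 s for delineation) were chosen so the whole suite runs
in about a minute while every criterion still rests on ≥ 100 beats or
≥ 40 000 coefficients.

What passing tests do show: exactness of the slotted estimator,
grid-independence of detection, separability of distinct morphologies,
and border accuracy against a known truth under the declared noise.  What
they do not show: performance on real recordings with muscle artifact,
electrode motion, atrial fibrillation or conduction disease — Gaussian
bumps have no notches, slurs or fragmentation, the noise is white, and the
morphology mixture is far cleaner than a real arrhythmia record.  The
WFDB reader and the evaluation harness exist precisely so the chain can be
run against user-supplied database records.

## Known limitations

* One shared time grid across leads; per-lead grids would need a
  different class-kernel update and border fusion.
* The classifier's founding threshold is a single global constant; records
  mixing very large and very small beats may need it re-calibrated.
* T-end inherits the largest uncertainty (a calibrated offset from a decay
  crossing at a coarse 32 ms shift grid); its tolerance budget is
  correspondingly the widest.
* Paced rhythms are out of scope (the sampling model presumes the
  P-QRS-T cycle), as are compressed-sensing or level-crossing acquisition
  models and verbose diagnostic statement generation.
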