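---
title: "Reverse-correlation analysis of jittered interception movements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reverse-correlation analysis of jittered interception movements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When people reach for a moving target while watching a cursor that tracks
their unseen finger, they correct their trajectory online using visual
information about both the target and the hand. How vigorously they
respond to an error, and how that vigour changes as time runs out, can be
measured by perturbing what they see and averaging their reactions.
`reachrc` implements a reverse-correlation (step-triggered averaging)
analysis of such experiments: on every display frame (60 Hz) a lateral
step of fixed amplitude (2.5 mm) and random sign is added either to the
target's position or to the offset between the cursor and the finger, so
that the perturbation accumulates as a random walk. Because the signs of
the steps are mutually independent, grouping trials by the direction of
the step at one chosen frame and differencing the group means isolates
the average response to a step at that moment: at every other moment the
steps average out. A 2.5 mm step at 60 Hz is a substantial perturbation
in velocity terms (150 mm/s equivalent) while individual steps remain
nearly invisible.

## The estimator

For each trial, lateral acceleration is obtained by least-squares fitting
a second-order polynomial to the 500 Hz lateral finger positions within a
40 ms window centred on the moment of interest and taking twice the
quadratic coefficient — simultaneous smoothing and double
differentiation with a Savitzky–Golay filter. At 500 Hz the 40 ms window
is taken as 21 samples (centre ± 10), the symmetric odd-length window
spanning the stated width; windows that would be incomplete are dropped,
never padded or shrunk, because padding biases acceleration estimates
near the end of the movement, exactly where the responses of interest
are largest. Since the quadratic coefficient of a least-squares
polynomial fit is invariant under shifts of the time axis, the estimate
at a moment between samples equals the filter output at the nearest
sample; ties exactly halfway between samples follow R's `round()`.

Trials are synchronised not on the clock but on display frames counted
backward from the *end of the movement*, defined as the interpolated
first moment the finger crosses the target's path. Movements that stop
short of the path still receive an end (the moment of maximal distance
from the start point) provided their closest approach to the path is
within 2 cm; anything further is excluded, explicitly, never silently.
The last synchronised frame (`k = 0`) therefore falls 0–17 ms before the
end. Step moments are analysable only when they occur strictly more than
100 ms before the end — no visuomotor response is faster — and the
filter is evaluated on actual times per trial, not on the frame-from-end
index, because the 0–17 ms synchronisation offset differs across trials.
Whether the interpolated crossing or the nearest 500 Hz sample defines
the end is an open choice at the 2 ms level; interpolation is used here.

The response kernel for a perturbation type and step moment `k` is the
difference between the unweighted group-mean accelerations
(rightward-step group minus leftward-step group) at each lag from 0 to
250 ms after the step, sign-flipped for cursor steps so that
*compensatory* responses — toward a shifted target, away from a shifted
cursor — are positive for both types. Accelerations are computed per
trial and then averaged (not computed on averaged positions): the two
orders agree for this linear estimator only when every trial contributes
to every lag, which truncation breaks. Lags past the end of a trial's
movement drop that trial from that lag's mean (per-lag dropping keeps
the most data and matches the synchronised design); a curve whose
direction groups cannot both be populated is undefined, not zero. The
two direction groups are differenced without size weighting.

## The vigour comparison

Kernels are reduced to read-outs at fixed lags after the step (160, 170,
180 ms by default, where responses are clearly developed but not yet
truncated for most step moments). Plotting the cursor read-out against
the target read-out across step moments tests whether response vigour
grows in the same way during the movement for both sources of visual
information: if it does, the points lie on a straight line through the
origin whose slope is the cursor/target vigour ratio; if reliance on the
cursor grows disproportionately late, the points bend upward. The
package quantifies the visual impression with the through-origin
least-squares slope `sum(t*c) / sum(t^2)` and a curvature index — the
quadratic coefficient of the through-origin fit `c ~ a*t + b*t^2` — with
a seeded bootstrap (2,000 replicates by default, resampling step-moment
pairs) giving a confidence interval for the curvature and a standard
error for the slope.

Step moments whose kernels rest on very few trials at a lag — moments
later than most movements lasted, or truncated in most trials — produce
noise-dominated read-outs that can dominate the through-origin fit. A
pair therefore enters the comparison only if, for both perturbation
types, the contributing trial count at that lag is at least half the
per-lag maximum across moments (`min_count_frac = 0.5`). This is the
package's operationalisation of comparing responses at the moments where
they are clearly estimable.

Two caveats belong with the slope. First, the through-origin estimator
has a classical errors-in-variables attenuation: noise in the
target-response abscissa biases the slope toward zero by the factor
`sum(t_true^2) / (sum(t_true^2) + n*var(noise))`. Averaging kernels
across sessions (`aggregate_kernels()`, the analogue of
across-participant averaging) shrinks the noise term; the bias is
negligible only when per-point kernel noise is small relative to the
kernel values. Second, no formal test compares the *overall* cursor
versus target vigour: that difference is confounded by what a cursor is
and how much kinaesthetic information dilutes it, so only the shape of
the relationship across the movement is interpreted.

## The synthetic-trial generator

The analysis makes no generative assumptions, but validating it requires
data with known ground truth. The simulator produces interception trials
under an explicit, invented feedback-control law — every parameter of
`feedback_model()` is a modelling choice of this package, not an
estimate from data:

* **Task geometry** (all in `session_config()`): target appears 300 mm
  left and 200 mm beyond the start point, moves rightward at 500 mm/s,
  27 mm target / 10 mm cursor / 20 mm start discs, 60 Hz display,
  500 Hz sampling, ±2.5 mm per-frame jitter on the target position or
  the cursor offset (never both).
* **Baseline reach**: minimum jerk from the start point to a point 15 mm
  beyond the target path (the finger slides through the target), planned
  so the path is crossed at the trial's nominal time — drawn per trial
  as Normal(0.58 s, 0.04 s), truncated — at the target's predicted
  position at that moment. Movement begins after a 0.15 s reaction time;
  nothing moves before onset.
* **Feedback law**: after a 110 ms latency, a step of size `d` mm
  injects lateral acceleration `d * gain(t_rem) * h(t)`, with `h` a
  gamma-density impulse response (mode 90 ms, 99th percentile 300 ms
  after response onset) of unit time-integral, so each step produces a
  persistent velocity change — consistent with corrective acceleration
  outlasting 200 ms in this kind of task. The gain schedule
  `gain_scale / max(t_rem, gain_floor)` (default scale 1, floor 0.1 s)
  makes responses more vigorous as remaining time shrinks; its units are
  1/s — the velocity change per millimetre of step needed to cancel the
  step within the remaining time. Cursor-step responses are sign-flipped
  (compensation moves the finger away from the displayed displacement)
  and scaled by `cursor_weight` (default 0.6), representing the
  jitter-free kinaesthetic information that dilutes visual information
  about the hand.
* **Motor noise**: white acceleration noise on both axes from movement
  onset, doubly integrated into position. The default SD of
  1600 mm/s^2 per sample was calibrated once so that default sessions
  are hit on roughly 70% of trials (about the success rate typical of
  this task), with end-of-movement times near 580 ms.
* **Seeding**: one master seed per session; per-trial child seeds are
  drawn from it, so sessions are reproducible and trials independent.

What the generator does *not* emulate: biomechanics, muscle dynamics or
friction; eye movements and any effect of jitter visibility; reaction to
jitter before movement onset; learning or fatigue across trials; the
heavy-tailed end-time distributions and occasional recording artefacts
of real motion capture. Passing parameter-recovery tests therefore shows
that the *analysis* is correct and well-calibrated under a plausible
response law, not that the law describes human controllers.

## Validation design and problem sizes

The test suite validates each stage against an independent oracle: the
Savitzky–Golay output against `lm()` quadratic fits; hit detection
against 10 kHz brute-force resampling; reverse-correlation curves on toy
sessions against an explicit group-means re-implementation; random-walk
conditioning against the binomial closed form (20,000 sequences: the
conditional group means separate by exactly twice the step amplitude,
5 mm, from the selected frame onward, and by 0 before it); and the full
pipeline by parameter recovery.

Recovery runs use 6 sessions of 400 trials per condition with
`cursor_weight` in {0.3, 0.6, 1.0}, kernels averaged across sessions —
comparable in volume to, though smaller than, a multi-participant study
— and reduced motor noise (400 mm/s^2): at the realism default the
attenuation bias described above is comparable to the Monte-Carlo error
at this volume, so the recovery study is run where the estimator's bias
is negligible and its stochastic error honestly measured. The recovered
through-origin slopes match the generating cursor weights within
bootstrap error, are monotone in the weight, and the curvature intervals
cover zero (the generator gives both channels the same gain schedule).
A zero-gain simulation (400 trials) yields kernels statistically
indistinguishable from zero; with roughly 9,000 kernel read-outs,
individual cells exceed a 3-standard-error bound at the expected chance
rate, so consistency with zero is asserted on the exceedance fraction
and on a family-wise bound rather than cell by cell.

## Numerical choices

* Frame times are exact multiples of 1/60 s from target appearance;
  finger samples are an independent 1/500 s grid. Display quantities are
  held between frames; the hit rule interpolates cursor and target
  linearly between sample points and solves each segment's closest
  approach in closed form.
* Movement-end crossing takes the *first* crossing of the path;
  re-crossings are ignored. Distance to the path is perpendicular
  (`|y - y_path|`); "distance from the start" is Euclidean.
* Degenerate inputs fail loudly: empty groups give undefined curves, not
  zeros; all-zero target responses make the slope undefined; collinear
  calibration points, non-monotone timestamps, jitter on the wrong
  display channel and orphan trial ids are all rejected with the
  offending trial and row.
* On-disk tables serialise doubles with 17 significant digits and are
  parsed with exact rounding, so write–read–write cycles are
  byte-identical.

## Worked example

```{r, eval = FALSE}
library(reachrc)

cfg <- session_config()
mdl <- feedback_model(cursor_weight = 0.6, motor_noise_sd = 400)

kernels <- aggregate_kernels(lapply(1:4, function(i) {
  ses <- annotate_session(simulate_session(cfg, mdl, 400, seed = 200 + i))
  kernel_matrix(ses)
}))
vig <- vigour_summary(kernels, seed = 1)
vig$fits
plot_kernels(kernels)
plot_vigour_pairs(vig)
```

The recovered `origin_slope` column sits near the generating cursor
weight of 0.6 at all three lags, and the curvature intervals cover zero.
The same analysis applied to real trial tables (via `read_session()`)
requires only that the data be coerced into the three-file dialect
documented in `write_session()`.

## Known limitations

* The conditional-averaging estimator is the only kernel estimator
  provided; no ridge/Wiener or frequency-domain alternative.
* The through-origin slope is attenuated by abscissa noise (see above);
  users comparing conditions should equalise kernel noise first or
  aggregate enough sessions.
* `session_config()` assumes a rightward-moving target and a horizontal
  target path; other geometries require mapping into this frame.
* The movement-end definition needs the finger to approach the target
  path; tasks without a crossing-like event need a different anchor.
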