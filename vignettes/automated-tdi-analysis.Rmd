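---
title: "ECG-free segmentation of fetal myocardial velocity traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ECG-free segmentation of fetal myocardial velocity traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetaltdi)
```

## The problem

Color tissue-Doppler imaging (TDI) of the fetal heart records the
longitudinal velocity of the myocardium - usually sampled by a small
region of interest (ROI) placed at the atrioventricular (AV) plane in the
septum or a ventricular wall. The trace over one heartbeat contains the
three classic peaks (systolic Sm, early-diastolic Em, atrial-contraction
Am) and, between them, the time intervals of the cardiac cycle. In adults
these intervals are anchored to a simultaneous ECG; a fetal ECG of adequate
quality is not routinely available, so fetal work needs a way to find the
cycle's time events from the velocity signal alone.

`fetaltdi` implements such an ECG-free analysis. The premise is mechanical
rather than electrical: each transition of myocardial work (atrial
contraction, pre-ejection, ejection, post-ejection, rapid filling, slow
filling) produces an abrupt change - a *shift* - in myocardial
acceleration. The package detects these shifts in the differentiated
velocity trace and assigns them to the six phase onsets. Atrial contraction
is taken as the start of the cycle, consistent with viewing the heart as a
piston pump driven by its inflow; "pre-ejection" and "post-ejection" are
used instead of isovolumic contraction/relaxation because the boundaries
are defined by shifts in myocardial work, not valve events.

## The analysis pipeline

`analyze_trace()` runs, per trace:

1. **Pre-smoothing** - a centered 3-point moving average
   (`smooth.default_window`), mirroring the smoothing that clinical export
   chains apply.
2. **Filter bank** - four settings of increasing strength (moving averages
   of width 3, 5, 7, 9 samples; `filter.windows`). The published method
   mentions four filter settings without describing them, so the widths
   here are a declared reconstruction and are configurable. Settings are
   tried in order; the first that segments at least half of the cycles
   wins.
3. **Differentiation** - central differences (symmetric, so event timing is
   not biased by the derivative stencil), one-sided at the edges.
4. **Period estimation** (`estimate_period()`) - the highest peak of the
   autocorrelation within lags corresponding to 80-220 bpm, refined to
   sub-sample precision by parabolic interpolation. The normalized peak
   value is the confidence; below `cycle.min_confidence` (default 0.5) the
   trace is declared non-periodic.
5. **Cycle anchoring** (`locate_cycle_starts()`) - candidate atrial onsets
   are downward departures of acceleration from a near-zero band
   (`cycle.onset_band`, default 0.1 x max |a|). Candidates are scored by
   the quietness of the preceding velocity (a true atrial onset follows the
   diastasis lull), the quietest anchors a chain extended beat by beat
   (acceptance window +/- 20 % of the period), and each onset is refined to
   the vertex of the local jerk peak. Onsets whose pre-onset window is
   clipped by the record edge are dropped: they cannot be verified against
   a diastasis and risk anchoring a cycle mid-phase.
6. **Shift detection and template matching** (`detect_shifts()`,
   `segment_cycle()`) - within each cycle, candidates are collected as
   acceleration zero crossings, near-zero band events, prominent
   acceleration extrema, and acceleration *steps* (prominent, sharp local
   extrema of the jerk - the literal "shifts"). One candidate per phase
   onset is then chosen by minimizing the summed squared deviation of
   candidate cycle-fractions from template priors, under strict ordering,
   per-event tolerance windows (+/- 0.08 cycle) and allowed candidate
   kinds - a small dynamic program whose optimum is verified against
   exhaustive enumeration in the tests. The atrial onset is fixed to the
   cycle start.
7. **Measurement** - Sm/Em/Am as the extreme velocities inside their phase
   windows (taken from the minimally smoothed trace, since the stronger
   filter settings would attenuate the narrow A-wave peak), phase durations
   as onset differences, both aggregated across cycles by median, which is
   robust to a single bad beat.

Failures never raise errors: the result carries `success = FALSE` and one
of four reasons (`no_periodicity`, `insufficient_shifts`,
`template_mismatch`, `degenerate_input`). The original study could not
analyze 22 % of clinical traces; the failure taxonomy here is a
reconstruction, since those criteria were not published.

## The synthetic heart

No raw fetal echo recordings are publicly available, so the package ships
a generator whose output carries exact ground truth
(`build_waveform()`, `generate_field()`, `sample_roi()`,
`generate_dataset()`).

**Waveform.** One cycle is a fixed sequence of lobes, one per phase:
A-wave (negative), biphasic pre-ejection transient, S-wave (positive),
biphasic post-ejection transient, E-wave (negative), flat diastasis. The
main waves are arched lobes `A sin(pi u) (1 + gamma cos^2(pi u))` that
reach exactly their configured peak at mid-phase; the transients are
full-sine wiggles of amplitude `transient_amp`. Two properties of this
shape family are deliberate:

* *Every phase boundary carries an acceleration step.* Arched lobes meet
  their neighbors with a velocity-slope break, so the acceleration jumps at
  each onset - exactly the "shift" the detector looks for. (Lobes with
  tangent-zero edges, e.g. raised cosines, were tried first and fail: after
  smoothing, their boundary features melt into the neighboring lobe and two
  of the six onsets become unlocalizable at ~190 Hz.)
* *Zero net displacement is exact by construction.* The AV-plane returns to
  its position every beat, so the velocity must integrate to zero over a
  cycle. The transients are area-free; the `gamma` factor fattens the
  lighter of the positive/negative main-wave sides (and if necessary slims
  the heavier one) so the areas cancel analytically while peaks stay put.

**Defaults** (synthetic conventions, not measured claims): heart rate
140 bpm (generated batches draw 110-160 bpm, the normal fetal range), frame
rate 190 Hz (the typical color-TDI cine-loop rate, range ~179-219), peaks
Sm +5.0, Em -6.0, Am -4.5 cm/s, transients 1.5 cm/s, phase fractions
0.15 / 0.05 / 0.35 / 0.05 / 0.25 / 0.15 in cycle order, noise 0.5 cm/s.
Velocity is positive toward the apex during systole; opposite probe
orientation is handled by `analyze_trace(invert = TRUE)`.

**Space.** The field extends from the AV-plane to the apex with a linear
apex-ward decay of velocity (1 at the AV-plane, 0 at the apex) - the
standard base-to-apex gradient of AV-plane motion. Geometry defaults per
gestational-age group: septal length 15.6 / 23.3 / 32.5 mm and wall
thickness 1.8 / 2.9 / 3.6 mm for GA I (18-24 wk), II (25-32 wk), III
(33-41 wk). An ROI trace is the unweighted mean over the depths the ROI
covers; ROI width is metadata (the 1-D field has no across-wall
variation). With linear decay, a taller ROI averages deeper, slower
myocardium - which reproduces the attenuation of measured peak velocities
with ROI length, while leaving event *timing* untouched. That separation
(velocities fall, intervals stay) is precisely the behavior reported for
clinical ROI-size comparisons, and `roi_study()` reproduces it:

```{r roi-study, eval = FALSE}
roi_study(ga_weeks = 38, seed = 1, noise_sd = 0)
# median Sm/Em/Am difference vs the 2 mm ROI:
#   -1.6 % (3 mm), -3.2 % (4 mm), -6.3 % (6 mm), -9.5 % (8 mm)
# every phase-duration difference: 0 %
```

**What the generator does not emulate:** speckle, angle-dependence, fetal
movement and breathing artifacts, beat-to-beat heart-rate variability,
across-wall velocity gradients, and valve clicks. Noise is additive white
Gaussian only. A green test on synthetic data therefore establishes that
the algorithm recovers the stated morphology under additive noise - not
that it reaches the published clinical feasibility rates, which depend on
recording quality the simulator does not model. Recordings start at a
random phase of the cycle (drawn from the seed): a trace that conveniently
starts exactly at an atrial onset would hide a real anchoring difficulty.

## The quality score

The 1-3 acceleration score grades how distinct the shifts are: 3 = clear
and well defined, 2 = less well defined, often biphasic, 1 = indistinct
and flat. The published score is a human visual judgment; this package's
`acceleration_score()` is a quantitative surrogate built from three
scale-free features - flatness (median/95th-percentile contrast of |a|),
shift prominence (jerk at the matched events relative to the cycle
maximum), and a biphasic count (prominent jerk peaks near an event that no
matched boundary explains). Thresholds live under `quality.*` and were
calibrated on the generator's fixture classes (clean, flat, constructed
double-lobed); the surrogate has not been validated against human raters,
and no attempt is made to reproduce the published per-wall averages, which
depend on the unavailable recordings.

## Numerical choices and degenerate inputs

* Sub-sample localization everywhere: interpolated zero crossings,
  parabolic vertices for extrema and jerk peaks, linear flank extrapolation
  for band-run edges. At 190 Hz a cycle is ~80 samples and the isovolumic
  phases ~4 samples, so sample-level bias is visible in every downstream
  interval.
* Smoothing edge policy is window truncation (output length = input
  length, no reflected transients near record edges).
* Quantiles are type-7 (linear interpolation); integer percentages round
  half away from zero - both reproduce every printed table value from its
  printed numerator/denominator, and both are configurable where they
  matter.
* Degenerate inputs (constant traces, < 8 samples) yield
  `degenerate_input`; a trace shorter than two expected cycles or without
  an autocorrelation peak above the confidence threshold yields
  `no_periodicity`; cycles with fewer than six candidates yield
  `insufficient_shifts`; candidate sets violating the template's order or
  tolerance windows yield `template_mismatch`.
* All randomness flows from explicit integer seeds; batch generation fans
  a master seed into per-trace seeds with a counter scheme, so any subset
  of a batch reproduces independently.

## Known limitations

* The four filter settings, the event template, the failure taxonomy and
  the quality thresholds are reconstructions of unpublished internals; all
  are exposed as configuration for recalibration against real data.
* The template priors default to the generator's phase fractions. On real
  traces whose phase proportions differ substantially (e.g. marked
  tachycardia changing diastolic proportions), the priors should be refit.
* Event localization assumes the six-lobed morphology; arrhythmic beats,
  fusion of E and A waves at high heart rates, and severely low frame
  rates will degrade the assignment before the period estimate fails.
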