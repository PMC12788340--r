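---
title: "Validating foot-mounted IMU sprint metrics against motion capture: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating foot-mounted IMU sprint metrics against motion capture: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strideval)
```

## The problem

Foot-mounted inertial measurement units (IMUs) estimate spatiotemporal gait
metrics — stride length, stride duration, stride cadence — and whole-body
velocity and acceleration during overground sprinting. Before such a device
is used for athlete monitoring, its outputs need to be compared against a
criterion system: 3D motion capture (markers at 100 Hz) synchronized with
in-ground force plates (vertical ground reaction force, GRF, at 1000 Hz),
over a measured "10 m fly" — a maximal sprint segment entered at speed after
a 10 m approach.

`strideval` implements that comparison chain end to end, and pairs it with a
synthetic trial generator with a known error structure, so that every stage
— event detection, filtering, synchronization, stride matching, and the
agreement statistics — can be verified against ground truth without any
proprietary data.

## The synthetic trial model

`simulate_criterion_trial()` builds one trial from `sprint_params()`:

* **COM kinematics.** Forward velocity follows a mono-exponential rise
  $v(t) = v_{peak}\,(1 - e^{-t/\tau})$, the standard sprint-acceleration
  model; the COM oscillates vertically at twice the stride frequency (once
  per step) with amplitude `com_vert_amp` (default 0.025 m). Lateral COM
  motion is zero. The *resultant* COM speed, the quantity both systems
  report, is the magnitude of this velocity vector.
* **Gait.** Each foot is in stance for `duty_factor` x stride period,
  feet offset by half a period. During stance the foot-mounted device marker
  is stationary at its plant position (the COM position at mid-stance);
  during swing it translates to the next plant with a cosine-eased profile
  and a sine vertical arc. Toe markers sit `toe_offset` ahead of the device
  markers.
* **GRF.** Each stance produces a vertical-force bump
  $F(u) = 2.2\,BW\,\sqrt{\sin(\pi u)}$, $u \in (0,1)$ the stance phase:
  positive, exactly zero outside stance, peaking at 2.2 body weights. The
  square-root sharpening of the half-sine mimics the steep loading rates of
  sprint impacts, so the force passes a 50 N detection threshold within a
  fraction of a millisecond of true stance onset and threshold-based event
  detection can be validated at 1 ms resolution. Vertical impulse balance is
  *not* enforced — the generator targets event and stride geometry, not
  kinetic realism.
* **Defaults** (peak velocity 8.2 m/s, tau 1.2 s, stride frequency
  2.15 Hz, duty factor 0.24, body weight 700 N) describe a trained adult
  sprinting through a 10 m fly after a 10 m approach. They are simulator
  choices representative of the setting, not estimates of any study
  population, which is why the packaged per-participant fixture carries only
  counts, never kinematics.

`device_error_model()` describes the emulated IMU export: velocity scale and
additive bias, white noise on the 10 Hz velocity and acceleration samples, a
device clock lag, Gaussian jitter on stride-event timestamps, and bias plus
noise on stride lengths. The default sample noise (0.05 m/s) is deliberately
small: commercial foot-IMU velocity outputs are already smoothed by the
vendor's state estimator, so their short-term noise is far below their
systematic error. `generate_cohort()` jitters *kinematics only* (participant
level, from two RNG streams derived from one seed), and applies the error
model identically to every trial: changing the error model never changes the
underlying gait, which keeps parameter-recovery experiments clean. The flip
side, worth remembering when reading synthetic limits of agreement: the
generator does not model between-trial error drift, so synthetic LoA widths
reflect injected sample noise only, whereas real devices also vary from
trial to trial.

## Event detection and stride metrics

Foot strike is called at the first GRF sample at or above 50 N after at
least `min_contact` (20 ms) below it, toe-off at the first subsequent sample
below the threshold sustained equally long. The 20 ms debounce suppresses
threshold chatter and is far below any plausible sprint contact time.
Strides are consecutive ipsilateral foot strikes; stride length is the
straight-line horizontal displacement of the device marker between the two
strike frames (nearest 100 Hz frame to each 1000 Hz event) — not an
integrated path length, which would systematically exceed step geometry over
the swing arc; cadence is 60/duration. Zone entry is the first frame the
leading toe marker reaches the zone start, exit the first frame the trailing
toe reaches the zone end. Note that this event rule makes the COM cover
slightly *more* than the nominal zone (it trails the lead toe at entry and
leads the trail toe at exit, each by a positive sub-stride distance); that
is a property of the protocol, not an implementation artifact.

## Signal derivation and filtering

Criterion velocity is the resultant of the central-differenced COM marker
axes; acceleration is the central difference of the filtered velocity.
Endpoints use one-sided differences so series keep their length and time
base for synchronization. Filtering is zero-phase (forward-backward)
Butterworth: the nominal order (4) is achieved as a double pass of a
half-order design whose cutoff is raised by $(\sqrt{2}-1)^{-1/4} \approx
1.247$, placing the -3 dB point of the cascade at the requested frequency.
The input is extended by odd reflection before filtering, and the mean is
removed and restored around the filter, so edge transients are suppressed
and constants pass through exactly. Phase distortion would corrupt event
timing, hence the zero-phase choice; whether the original laboratory chain
filtered zero-phase is not knowable from its outputs, and a config flag
(`filter$cutoff_velocity` / `cutoff_acceleration`) allows fixed cutoffs for
sensitivity analysis.

Cutoffs default to Winter-style residual analysis over 4-20 Hz: RMS
residuals between raw and filtered signal are computed on a candidate grid,
a straight line is fitted over the noise-dominated upper quarter of the
range and extrapolated to 0 Hz as the noise floor, and the smallest
candidate whose residual does not exceed that intercept is selected. Two
caveats are documented deliberately. First, the procedure presumes a noise
floor: on a noise-free signal the intercept is near zero and the selection
drifts to the top of the candidate range — a constant signal is special-cased
to the lower bound, but clean periodic signals select a cutoff just above
their own bandwidth (which is also the sensible answer). Second, whether
cutoffs should be chosen per trial or globally is left to the caller; the
pipeline default is per trial.

Marker gaps of up to five frames are filled by local least-squares quintic
polynomials through up to six valid frames per side — a practical substitute
for generalized cross-validated quintic smoothing splines that reproduces
polynomial trajectories through degree five exactly; longer or boundary gaps
are left missing and flagged, and strides that depend on them are excluded.

## Synchronization

Device velocity (10 Hz) is linearly upsampled to 100 Hz (original samples
preserved bit-exactly) and aligned to the criterion velocity by exhaustive
integer-sample lag search minimizing RMSE, +-2 s by default, ties broken
toward the smallest then the negative lag. Two estimator details matter in
practice and are exposed as arguments:

* **Centering.** Plain RMSE alignment of a *biased* stream against a rising
  velocity ramp trades the bias against the slope and converges to a wrong
  lag by roughly bias/slope (a second or more at sprint slopes). The
  pipeline therefore removes the overlap-window means before computing the
  RMSE (`center = TRUE`), making the search insensitive to constant
  between-device offsets. On curvature-poor windows this costs precision —
  alignment information then comes only from slope variation — so recovered
  lags on a 1.5 s zone window are good to a few tens of milliseconds, not
  to one sample. With no systematic bias (or after bias correction), plain
  RMSE over the full trial recovers lags to about one 100 Hz sample.
* **Overlap.** Lags whose overlap window falls below a minimum (the
  pipeline requires 90% of the zone window) are excluded: short partial
  overlaps otherwise fit spuriously well.

Stride events are matched greedily by nearest completion time, same foot,
within a 100 ms tolerance (about a quarter stride). The original laboratory
workflow matched these events manually; any automatic rule is a design
choice, so the tolerance is a config entry and unmatched counts are
reported.

## Agreement battery

All differences are `device - criterion`, so negative bias means device
underestimation. The battery per variable:

* MAE, RMSE, mean bias with 95% limits of agreement `bias +- 1.96 sd(d)`
  (sample SD, multiplier fixed at 1.96, no small-sample correction);
* LoA in two modes: `first_trial` keeps each participant's earliest trial to
  remove repeated-measures dependency, `pooled` keeps everything;
* Spearman rank correlation with the conventional magnitude bands (trivial
  < 0.1 <= small < 0.3 <= moderate < 0.5 <= large < 0.7 <= very large <
  0.9 <= nearly perfect);
* log-ratio Bland-Altman: mean and limits of `ln(device/criterion)`
  back-transformed to percent; pairs with either value below a positivity
  floor (1e-6 in the variable's units) are excluded and counted, and
  variables dominated by near-zero or negative values (instantaneous
  acceleration) should not be analysed on this scale at all;
* a Kolmogorov-Smirnov normality screen, Lilliefors-corrected by default
  because the normal parameters are estimated from the sample (the
  uncorrected variant, which is badly conservative in that situation, is
  available behind a flag);
* a heteroscedasticity screen: Spearman correlation of |difference| against
  pair means, two-sided at alpha = 0.05.

No multiplicity correction is applied across variables. Instantaneous
velocity and acceleration are paired at the device's *native* 10 Hz sample
times inside the zone (after alignment): each exported device sample enters
the comparison exactly once, and interpolated pseudo-samples never shrink
the apparent noise — important because the battery doubles as a
parameter-recovery instrument for the injected error model. Peak velocity is
defined as each system's per-trial maximum inside the zone.

## Numerical and testing choices

Problem sizes in the test suite are chosen to keep the full run around half
a minute: unit tests use an 8 m approach, cohort-level checks use the full
23 x 4 study-sized cohort (about 2700 velocity pairs), LoA coverage uses
1e5 differences, and the normality-screen calibration uses 2000 replicates
of n = 100. Determinism is part of the contract: the same seed reproduces
cohorts byte-identically through the CSV writers, and `run_validation()`
reports are checksum-stable.

What passing these tests shows — and what it does not: the synthetic
generator exercises the chain under a known, well-behaved error structure
(white sensor noise, constant lag, constant bias, Gaussian event jitter).
Real device errors drift within and between trials, real mocap
trajectories contain labelling noise and soft-tissue artifact, and real GRF
baselines wander; agreement numbers from synthetic runs therefore
demonstrate correctness of the *method*, not expected field performance of
any particular device.
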