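---
title: "Measurement methods behind gaitfga"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement methods behind gaitfga}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitfga)
```

`gaitfga` converts 3D body-keypoint trajectories into clinical gait measures
and automated Functional Gait Assessment (FGA) scores. This vignette explains
the measurement model, the parameters that matter, what the synthetic
simulator does and does not emulate, and the numerical choices the package
makes. It states no empirical result that the test suite does not itself
compute.

## Coordinate frame and calibration

All measurement happens in a walkway frame: x anterior-posterior (forward),
y mediolateral (+ toward the subject's left), z up. `fit_walkway_frame()`
builds the frame from three standing calibration points — at the walkway
origin, a known distance forward (default 5 m) and a known distance to the
right (default 1 m). The forward axis is taken directly from the forward
point (it is the measurement-critical axis for step length and speed); the ML
axis is the right-point direction orthogonalized against it. Because both
calibration distances are known, each horizontal axis receives a
multiplicative bias correction; capture systems of this class typically show
a few percent of scale error, so `axis_scale` outside [0.8, 1.2] triggers a
warning. Whether the vertical axis needs the same correction is not
determinable from a flat calibration walk; the package defaults the z scale
to the mean of the two horizontal scales.

## Event detection

Foot speed is the absolute AP velocity of a heel keypoint, smoothed at
`foot_speed_cutoff` (default 3 Hz, zero phase). Stance is any maximal region
with foot speed below `speed_threshold` (default 0.15 m/s); regions shorter
than `min_stance` (0.15 s) are dropped and above-threshold gaps shorter than
`min_swing_gap` (0.10 s) are merged away. The *midstance* instant is the
temporal midpoint of the stance region, and the footstep location is the mean
heel position over the region — averaging over the stance is more robust to
keypoint jitter than reading a single sample; the single-sample alternative
is available as `footstep_location = "midpoint"`.

Walking bouts are found by normalized cross-correlation of the summed
left+right foot speed against a synthetic gait-initiation template (0.5 s
quiet plateau, then a half-amplitude first swing pulse and a full steady
pulse — the first swing of a walk that starts from standing necessarily
advances only one step length) and its time reverse for termination.
Normalized (Pearson-per-window) correlation makes the match insensitive to
overall amplitude, so a slow walker does not bias the boundaries. The
template's cadence and speed can be given in the configuration; when absent,
`find_footsteps()` estimates them from the detected stances (median
midstance interval and median AP displacement per step), which makes the
pipeline self-calibrating on straight walks. Footsteps are the stances that
begin after the bout start (stances beginning earlier are the initial quiet
standing); the final footstep's stance extends into terminal quiet standing
and is attributed to the bout with a `bout_end_margin` (0.2 s) allowance.

### Why speed signals use a Gaussian smoother

The generic `lowpass()` operation is a forward-backward 4th-order
Butterworth — the field's default, with an 8th-order effective roll-off and
no phase lag. For the *threshold-crossing* speed signals, however, the
package uses a zero-phase Gaussian smoother with the same −3 dB cutoff
convention. The reason is numerical, and measurable with the simulator: a
Butterworth's impulse response oscillates, and the superposed sidelobes of
two adjacent swing pulses can create a spurious bump of up to ~0.19 m/s in
the middle of a stance plateau at fast gaits (cadence 2.5 steps/s, 0.8 m
steps) — above the 0.15 m/s stance threshold, which splits one stance into
two. A Gaussian's response is strictly monotone, so smoothing can narrow a
stance but never split it. The Butterworth remains available (and tested)
as `lowpass()`; `smooth_keypoints()` uses it for position smoothing, where
no threshold crossing is involved.

## Spatiotemporal measures and FGA scoring

Step length and signed step width are the AP and ML displacements between
consecutive footstep locations; the step period is the midstance-time
difference. Head speed is the derivative of the mean AP position of the
available head keypoints (two ears and nose, or a single head marker),
signed so that the return leg of a pivot trial is negative. The bout summary
reports movement duration, mean and maximum |head speed|, the maximum
lateral footstep deviation outside the walkway edge (half-width default
0.1524 m, i.e. a 30.48 cm lane), and step-width statistics.

Conditions 2–6 are scored by explicit threshold rules; all thresholds live
in `scoring_thresholds()` / `analysis_config()` and are embedded in every
report. The printed score bins share endpoints, so bins are applied
highest-score-first with inclusive bounds on the higher bin: a fast-walk
ratio of exactly 1.25 scores 2, exactly 1.10 scores 2, exactly 1.05 scores
1. Decisions the rules leave open, resolved here:

* **Baseline flavor.** Condition 2 compares *mean* bout speeds; Conditions
  3/4 compare the trial's *maximum* speed against the baseline's *maximum*
  (like-for-like — comparing a maximum to a mean would score an identical
  walk as abnormal, since max/mean of one bout is ≈ 1.2 once the
  acceleration and deceleration phases are included). Both baselines are
  embedded in the report.
* **Ratios above 110 %** in Conditions 3/4 fall outside every printed bin;
  a completed but non-qualifying trial scores 1.
* **Lateral placements** beyond the 15.24 cm limit cap Conditions 3/4 at
  score 1, mirroring the deduction structure of the observational rules.
* **Turn measurement** (Condition 5): the turn is bracketed at the global
  maximum of AP head position by the last `+0.2` m/s and first `−0.2` m/s
  crossings of signed head speed (`v_turn` configurable); a missing
  crossing marks the turn incomplete (score 0).
* **Obstacle clearance** (Condition 6): the swing apex of each step is the
  maximum heel height between consecutive midstances; the obstacle step is
  the highest apex, and its clearance is that apex minus the median apex of
  the other steps. "High clearance" has no published numeric definition;
  the default cutoff `clearance_high = 0.10` m is a configuration parameter,
  not a claim.
* Conditions 1 and 7–10 carry metrics but no automated score — no published
  quantitative rules exist for them.

## Two-system agreement validation

To validate a markerless stream against a marker-based reference, the
summed-foot-speed series are cross-correlated after linearly resampling the
markerless stream to the reference rate (default 240 Hz); the correlation
argmax gives the inter-system lag. The markerless stream is then translated
so the left-foot positions coincide at the first sample, footsteps are
extracted per system, and steps are paired greedily by nearest midstance
time within 0.3 s (orphans are reported, never dropped). Agreement is
summarized by OLS of the markered measure on the markerless one (t-based
95 % CIs, n−2 df) and Bland–Altman statistics of markerless − markered
differences with 1.96·SD limits of agreement. Deming or mixed-effects
agreement models are out of scope.

## The synthetic gait simulator

The simulator exists to give every stage exact ground truth. Heel
trajectories are piecewise closed forms: exactly stationary in stance and
raised-cosine in swing (a C¹, bell-shaped swing-speed pulse); step *i* lands
at `i × step_length` on alternating sides of the centerline, the first swing
advancing one step length and later swings two. Steady speed is always
`step_length × cadence` — speed is derived, never free. Vertical heel motion
is a half-sine bump per swing (`swing_apex_height`, default 0.05 m; an
optional obstacle step raises one apex). Head keypoints ride a smooth
closed-form progression profile (cosine speed ramps of one step period
around a constant-speed plateau) with rigid ear/nose offsets. The head is
deliberately *not* produced by discretely filtering the mid-feet trajectory:
closed forms are rate-independent, which is what makes a 240 Hz and a 30 Hz
stream of the same walk agree exactly at common sample instants — the
property the two-system validation tests rely on.

Pivot trials define their turn interval kinematically: head AP speed passes
±0.2 m/s exactly at the interval boundaries, decelerating from steady speed
just before the interval and re-accelerating just after, with a small
(±0.05 m/s) drift inside so the AP position maximum is unique. Quiet-standing
pads of 1.5 s surround every trial so bout detection has a non-trivial job.
Noise is i.i.d. Gaussian per axis per sample (`noise_sd`).

Defaults mirror the intended use conditions: a 6 m walkway, 30 Hz markerless
sampling (240 Hz for the simulated reference system), and two step-width
conditions (normal ≈ 0.10–0.12 m, wide ≈ 0.25 m) in the validation studies.
Cadence (2.0 steps/s) and stance fraction (0.6 of the stride) are
conventional round numbers for healthy adult walking; no source dictates
them, and they are exposed as parameters.

What the simulator does **not** emulate: joint-angle realism, double-support
weight transfer, heel rocking during stance (real stance speed is not
exactly zero), occlusion/dropout, heavier-tailed keypoint error, curved
paths, or soft-tissue artifact. Passing tests therefore demonstrate that the
*algorithms* recover known kinematics under Gaussian jitter — not that any
camera system achieves a particular accuracy on real gait.

## Numerical choices and degenerate inputs

* Zero-phase filtering uses odd-reflection padding (~`9 fs / cutoff`
  samples), which keeps DC gain 1 to ≈1e−9 and symmetric pulse peaks fixed;
  series shorter than three filter orders are refused.
* A requested cutoff at or above 0.9 × Nyquist is clamped with a warning;
  `smooth_keypoints()` treats a request above 0.45 × the sampling rate
  (e.g. 25 Hz smoothing of a 30 Hz stream) as a no-op, since the data
  cannot contain such content.
* Derivatives are central differences (exact for quadratics at interior
  samples) with one-sided ends.
* Cross-correlation windows with near-zero variance get correlation 0; a
  peak below `min_peak_corr` (0.5) raises a low-confidence error naming the
  failing template rather than returning a guess.
* Constant-zero speed yields one stance spanning the series; all-fast speed
  yields none; fewer than two footsteps yield an empty step table; a trial
  whose analysis fails inside a session becomes a flagged, unscored
  condition rather than an error.
* Broken left/right alternation raises a data-quality *flag*, not an error —
  real pathological gait can do this legitimately.

## Problem sizes used in the test suite

The suite simulates walks of 4–6 m at 30 Hz (a few hundred samples each):
a 27-point noiseless grid over cadence 1.5–2.5 steps/s, step length
0.3–0.8 m and width 0.05–0.25 m for exact parameter recovery; 50 noisy seeds
(3 mm keypoint noise) for footstep localization; and a 50-seed paired
30/240 Hz study for end-to-end agreement. These sizes keep the full suite
around ten seconds while leaving no stage untested at realistic scale.

## Known limitations

Stance detection assumes straight-line walking along the fitted walkway
frame; sharply curved paths mix AP and ML displacement. The bout templates
assume a standing start and stop. Scores for Conditions 2–6 inherit the
thresholds' provenance — they demonstrate automation, and clinicians are
expected to tune them (`analysis_config()`) for their population. The
agreement machinery assumes both systems observe the same walk with at most
a constant time offset; drifting clocks are not modeled.
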