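---
title: "Methods: escape kinematics, motion-corrected calcium imaging, and cohort statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: escape kinematics, motion-corrected calcium imaging, and cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(escapekin)
```

## Scope

`escapekin` quantifies the acoustic startle (escape) response of larval
zebrafish from high-speed body-point tracks, extracts motion-corrected
calcium signals from two-channel fluorescence movies of moving spinal
neurons, and compares cohorts with nested linear mixed models. Because
escape kinematics and imaging signals are derived through a long chain of
filtering, segmentation and fitting steps, every stage ships with a
synthetic-data generator whose ground truth is known exactly; the test
suite and the acceptance script validate the chain end to end on those
synthetic recordings.

## Escape kinematics

### Tail angle

The input is an 11-point body track per frame: one point per eye, the swim
bladder, and eight points along the tail, as produced by commercial
larva-tracking software at 650 frames/s. The signed tail angle
$\alpha(t)$ is the angle between the tail vector (last tail point minus
swim bladder) and the caudally directed body axis (eye midpoint to swim
bladder, prolonged): $\alpha = \mathrm{atan2}(h \times v,\; h \cdot v)$,
so a straight body reads 0°, and the sign follows the 2-D cross product.
Frames missing a required point give NaN; rows are never dropped, so frame
indices stay aligned with the stimulus clock.

### Preprocessing

NaN gaps are filled by linear interpolation, single-frame tracker glitches
are removed with a 5-frame running median, and residual noise with a
penalized smoothing spline. Two penalties are used, both fixed and exposed
in the configuration:

* angle trace: $\lambda = 10^{-9}$ (all knots). Calibrated so a 40 Hz
  oscillation sampled at 650 frames/s — the top of the escape tail-beat
  band — is attenuated by well under 5%, while roughly halving 2°
  frame-to-frame tracker noise.
* angular velocity: $\lambda = 10^{-8}$. The velocity trace is the first
  difference of the raw (interpolated) angle, which amplifies
  high-frequency noise; since this trace only feeds a fixed 1°/frame
  motion threshold, suppressing its noise floor matters far more than
  preserving oscillation amplitude.

The median filter inevitably clips sharp extrema by a few percent. Peak
*positions* are therefore detected on the smoothed trace, but peak
*amplitudes* are re-read from the interpolated raw trace within ±3 frames
of each detected position, keeping the reported C-bend amplitude faithful.

### Bouts

A frame is "in motion" iff $|\dot\alpha| > 1$°/frame (strict). The binary
mask is closed morphologically with a flat 10-frame element — dilation
then erosion with the reflected element, the mask padded with background
on both sides, so interior gaps shorter than the element are filled, edge
gaps are not, and runs are never eroded. Maximal runs of the closed mask
are movement bouts.

The escape is the bout whose start is nearest to, and not before, the
stimulus. Three robustness refinements apply, all configurable:
bouts shorter than 10 frames are ignored (residual noise crossings, not
swimming); a candidate may start up to one closing block before the
stimulus, because closing can pull the bout boundary back when a noise
blip precedes the true motion onset (the latency criterion, computed from
the detected onset, still rejects genuinely pre-stimulus movements); and a
candidate containing no bend beyond the peak-detection delta is discarded
in favour of the next one.

### Peaks, hemicycles, tail-beat frequency

Within the escape bout the trace is oriented so the first bend — the
C-bend — is positive, then alternating extrema are found with the classic
`peakdet` scheme: a running maximum (minimum) is emitted once the trace
retreats from it by more than $\delta$ (default 10°, well below the 60°
C-bend scale and well above smoothed noise). A peak followed by a peak in
the opposite direction is *sequential*; each peak's *hemicycle* is the
frame count to the next peak in sequence. Mean tail-beat frequency is

$$\mathrm{TBF} = \frac{f_s}{2\,\overline{h}},$$

with $f_s$ the frame rate and $\overline{h}$ the mean hemicycle of
sequential peaks; it is reported as undefined with fewer than two
sequential peaks. The oscillation count is (positive + negative peaks)/2.

### Onset and latency

Escape onset is detected by an exponential-fit construction: a straight
line is fit to the ascending limb of the first bend (from the last
near-baseline frame to the peak); a composite target is built that is zero
from the stimulus to the line's baseline crossing and follows the line
afterwards; a single-term exponential $a e^{bt}$ is fit to the composite;
and the onset is the first frame where the fitted curve exceeds 2°.

Two numerical choices make this estimator accurate and amplitude-invariant:

* the whole construction operates on the trace normalized to a 75°
  reference bend, so rescaling the input changes nothing by construction
  (doubling a trace moves the detected onset by exactly 0 frames in the
  package's property tests);
* the exponential is fit with inverse-amplitude weights
  $w = (1 + y)^{-1.25}$. An unweighted fit is dominated by the steep limb
  and crosses threshold several frames early for fast C-bends; the chosen
  exponent balances the residual bias across shallow (5°/frame) and steep
  (30°/frame) rises to within ±1 frame of the true foot.

If the exponential cannot be evaluated (degenerate limb, non-positive
slope) the detector falls back to the first frame exceeding the threshold
and flags the result. Latency is onset minus stimulus time.

### Inclusion criteria and parameters

A bout is an escape iff latency ≤ 30 ms (inclusive) and the first bend
exceeds 60° in magnitude. Accepted escapes yield latency, bout duration,
swim distance (path length of the swim-bladder point × pixel scale),
speed, oscillation count, C-bend amplitude and TBF; rejected bouts yield a
record naming the failed criterion (`no_bout`, `no_peaks`, `no_onset`,
`latency`, `c_bend`).

## Synthetic escape tracks

`gen_escape_pointtrack()` emulates the study's recordings: 1-s clips at
650 frames/s, stimulus at 200 ms, latency ~20 ms, C-bend ~75°, damped
30–40 Hz oscillation, 2° angle noise, occasional point dropout (NaN). The
angle waveform is zero until onset, rises to the C-bend amplitude along a
quarter sine, then follows $A e^{-dt}\cos(2\pi f t)$ for `n_oscillations`
cycles, ending at a zero crossing. Two shape choices matter for
validation: the quarter-sine rise peaks smoothly, so the discrete-sampling
deficit of the C-bend stays below 1° at study frequencies (a linear rise
meeting the cosine forms a corner whose sampled maximum can fall 3–4°
short); and ending at a zero crossing rather than mid-swing avoids a
spurious trailing hemicycle that would bias TBF upward by ~1 Hz. The body
pose is reconstructed by bending the eight-point tail chain rigidly at the
swim bladder, which makes the derived angle equal the injected waveform
exactly; the swim bladder itself stays stationary, so ground-truth
distance is zero.

The generator reproduces the statistical structure the pipeline is
sensitive to — sampling grid, noise level, dropout, bout timing — but not
pixel-level larva appearance, tail flexion along the chain, swim
translation, or hydrodynamics. Passing round-trip tests therefore
establishes the correctness of the *analysis chain*, not the behaviour of
the upstream commercial tracker on real video.

## Calcium imaging in moving animals

### ROI tracking

Cells co-express GCaMP (activity-dependent) and tagRFP (activity-
independent). ROIs are tracked on the tagRFP channel — its correlation
drops reflect motion only — by normalized cross-correlation: the ROI patch
from frame 1 is a fixed template (no frame-to-frame update, so tracking
error cannot accumulate), compared by Pearson correlation at every integer
displacement within a 20 px radius. Frames whose best correlation falls
below a threshold (default 0.7, per-movie override) are invalid and
excluded downstream. Integer search recovers integer translations exactly
and sub-pixel motion to within 0.5 px without interpolation.

### Signals

With $F$ the ROI mean, $F_{bg}$ a static background ROI mean, and $F_0$
the mean of the first 10 valid frames,

$$\Delta F/F = \frac{F(t) - F_0}{F_0 - F_{bg,0}}, \qquad
\Delta R/R = \frac{F_G(t)\, F_{0,R}}{F_{0,G}\, F_R(t)} - 1,$$

all dR/R quantities background-corrected. Any gain applied to both
channels in a frame — focal drift, partial occlusion, lateral motion —
cancels in the ratio (verified to 10⁻⁹ in the property tests). Stimulus
responses are windowed differences: the mean of the $n_{post}$ scheduled
points starting `gap` frames after the stimulus minus the mean of the
$n_{pre}$ points before it (5/5 with a 4-frame gap for pressure
stimulation at 9 Hz; 3/3 with a 1-frame gap for tail-free escapes at
11 Hz), NaN points excluded from the means but not re-scheduled. Transient
decay constants come from a Levenberg–Marquardt fit of
$A e^{-t/\tau} + c$ to the post-peak segment, with log-linear starting
values; the offset $c$ absorbs a non-zero resting baseline.

### Synthetic movies

`gen_two_channel_movie()` renders cells as 2-D Gaussian spots (σ 2.5 px)
over a uniform background on a unit intensity scale, displaced per frame
by a caller-supplied trajectory, with additive Gaussian noise. The GCaMP
transient rises instantaneously at its onset frame and decays
exponentially (default τ 1.18 s) — in the emulated experiments the rise
happens during stimulation or motion, which cannot be imaged, so the first
usable frame sits at the peak. The ground truth includes the exact per-
frame cell positions and the noise-free ΔF/F and ΔR/R time courses.

One unit conversion is worth stating: published response amplitudes are
*windowed differences*, not transient peaks. Because the transient decays
across the post window, a peak injected at value $x$ yields a ground-truth
difference a few percent (3/3-point windows) to ~16% (5/5-point windows at
9 Hz) below $x$. When the package's validation targets a published
response value, the injected peak is scaled so the ground-truth windowed
difference equals that value; the scale factor is computed from the
noise-free truth trace.

## Cohort statistics

Repeated trials (and multiple cells) within a fish are not independent, so
group comparisons use linear mixed models: fixed genotype contrast and a
linear trial covariate (habituation across five trials at 2-min intervals
is an observed feature of the paradigm; categorical trial coding is
available), random intercept per fish, plus a nested per-cell intercept
for imaging responses. Estimation is REML via `lme4`, with Satterthwaite
degrees of freedom, p-values and confidence intervals via `lmerTest`.
Tests are two-sided at α = 0.05. Per-larva summaries are unweighted means
over that fish's accepted trials; fish with no accepted trials are
reported as missing rather than dropped.

`gen_behavior_cohort()` draws
$\mathrm{TBF}_{ij} = \mu_{g(i)} + s\,(j-1) + b_i + \varepsilon_{ij}$ with
$b_i \sim N(0, \sigma_f^2)$ and
$\varepsilon_{ij} \sim N(0, \sigma_r^2)$. The paper prints no inter-fish
dispersion, so the defaults — $\sigma_f = 2$ Hz, $\sigma_r = 2.5$ Hz,
habituation slope −0.5 Hz/trial — are plausible placeholders for this
assay, documented here and in the configuration, not claims about the
source data.

## Numerical choices and degenerate inputs

* Frames are 1-based in R objects and inclusive at both interval ends;
  the on-disk CSV `frame` column is 0-based and converted at the I/O
  boundary. Angles are degrees throughout.
* The motion threshold is strict (`>`), so exactly 1°/frame is not motion.
* The 30-ms latency criterion is inclusive (≤).
* Peak-detection delta must be positive; zero-length or monotone segments
  yield empty peak tables, not errors.
* Entirely-NaN angle traces, all-invalid ROIs, baselines not exceeding
  background, constant traces passed to the decay fitter, and background
  ROIs overlapping a tracked ROI all raise informative errors; inside
  `run_calcium_pipeline()` a failing ROI is reported per-ROI without
  aborting the rest.
* Singular mixed-model fits (a variance component at zero) warn and
  report the variance components rather than failing.
* Point-track CSVs are written with 17 significant digits so write/read
  round-trips are bit-identical; movies round-trip through 32-bit float
  multi-page TIFF.
* All generators are deterministic functions of their seed.

## Validation problem sizes

The shipped tests validate: peak detection against an independent
envelope-scan oracle on 1000 random traces (up to 500 frames) plus 200
more in the unit suite; morphological closing against a run-length
gap-fill reference on 1300 random masks; onset amplitude invariance on 100
seeded noisy escapes; TBF/latency recovery on 50-escape cohorts at each
published group mean (noise σ 2°); ratiometric recovery on 60-frame movies
with 10 px lateral motion and 5% shot noise; decay recovery at τ = 1.18 s
and 0.5 s; and mixed-model CI coverage on 100 cohorts of 140 fish. These
sizes were chosen to make sampling error small relative to the stated
tolerances while keeping the default test run fast.

## Known limitations

* The tail is modeled as a rigid chain pivoting at the swim bladder; real
  larvae flex along the tail, so body-shape-dependent effects (e.g. angle
  readout from intermediate tail points) are untested.
* Tracking handles translation only — no rotation, scaling, or
  out-of-plane warp; the ratiometric channel is the intended corrector for
  what translation cannot capture.
* The onset detector's 2° threshold is interpreted at a 75° reference
  amplitude (i.e. relative for large bends); with very small bends the
  absolute and reference readings diverge, but such bouts fail the 60°
  criterion regardless.
* Habituation enters the models linearly in trial index by default;
  strongly non-monotone trial effects would need the categorical coding.
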