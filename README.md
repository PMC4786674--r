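# escapekin

Quantitative analysis of larval zebrafish escape behavior and of calcium
imaging in moving animals, built around three pipelines:

1. **Escape kinematics** — from high-speed (650 frames/s) 11-point body
   tracks to per-escape parameters: the signed tail angle α(t) is computed
   from the eye/swim-bladder/tail geometry, denoised (median filter +
   smoothing spline), thresholded on angular velocity (>1°/frame),
   morphologically closed (10-frame element) into movement bouts, and the
   post-stimulus escape bout is decomposed into alternating tail-bend
   peaks. Escapes must start within 30 ms of the stimulus with a first
   bend >60° (a C-bend). Reported parameters: latency (exponential-fit
   onset detection with a 2° threshold, amplitude-invariant by
   construction), bout duration, swim distance and speed, oscillation
   count, C-bend amplitude, and mean tail-beat frequency
   TBF = frame rate / (2 × mean hemicycle of sequential peaks).
2. **Motion-corrected calcium imaging** — ROIs are tracked across
   two-channel (GCaMP + tagRFP) movies by normalized cross-correlation
   against a frame-1 template, with low-correlation frames omitted;
   signals are summarized as ΔF/F = (F − F₀)/(F₀ − F_bg) against a
   10-frame baseline and as the ratiometric
   ΔR/R = (F_G·F₀_R)/(F₀_G·F_R) − 1, which cancels motion artifacts
   shared by both channels; stimulus responses are pre/post windowed
   differences and transient decay constants come from a single-
   exponential fit.
3. **Cohort statistics** — nested linear mixed models (random intercept
   per fish, optionally per cell within fish; fixed genotype contrast and
   trial covariate; REML with Satterthwaite inference) for repeated-trial,
   multi-animal designs, plus per-larva averaging.

Every stage has a synthetic-data generator with exact ground truth
(escape point tracks, two-channel movies, behavioral cohorts), so the
whole chain is validated by parameter recovery.

## Worked example

Simulate one escape recording (650 frames/s, stimulus at 200 ms, 32.5 Hz
tail beat, 2° tracker noise) and run the full kinematics pipeline:

```r
library(escapekin)

g   <- gen_escape_pointtrack(escape_sim_params(
         oscillation_frequency = 32.5, seed = 42))
res <- run_kinematics_pipeline(g$track)
res
#> Accepted escape
#> Escape kinematics
#>   latency          18.5 ms
#>   duration        192.3 ms
#>   distance         0.00 mm
#>   speed             0.0 mm/s
#>   C-bend           76.4 deg
#>   oscillations      5.5
#>   TBF              32.8 Hz
```

The bout passed both inclusion criteria (18.5 ms ≤ 30 ms; 76.4° > 60°) and
its tail-beat frequency lands within 0.3 Hz of the injected 32.5 Hz ground
truth; distance is zero because the generator keeps the swim bladder
stationary. Now a two-genotype cohort (70 fish per arm, 5 trials each,
injected group means 35.2 vs 32.8 Hz, −0.5 Hz/trial habituation) and its
mixed-model comparison:

```r
co  <- gen_behavior_cohort(cohort_sim_params(n_fish_per_genotype = 70,
                                             seed = 1))
fit <- fit_mixed_model(co$table)
fit
#> Linear mixed model for 'tbf' (700 obs, 140 fish)
#>         term estimate    se  df  ci_lo  ci_hi        p
#>  (Intercept)    35.80 0.336 367 35.100 36.500 5.9e-278
#>  genotypemut    -2.94 0.361 138 -3.650 -2.220  2.1e-13
#>       .trial    -0.43 0.073 559 -0.574 -0.287  6.3e-09
#> Random-effect SDs: fish_id=1.75, Residual=2.73
```

The injected genotype effect (−2.4 Hz) and trial slope (−0.5 Hz/trial)
fall inside their 95% confidence intervals, and the fitted random-effect
SDs track the injected between-fish (2 Hz) and residual (2.5 Hz)
dispersions.

## Command-line use

```sh
Rscript inst/cli/escapekin.R simulate pointtrack --seed 1 --n 5 --out tracks/
Rscript inst/cli/escapekin.R kinematics --in tracks/ --out kin/
Rscript inst/cli/escapekin.R simulate movie --seed 1 --out mov/
Rscript inst/cli/escapekin.R calcium --gcamp mov/gcamp.tif --rfp mov/rfp.tif \
    --rois rois.csv --out ca/
Rscript inst/cli/escapekin.R stats --in kin/kinematics.csv --response tbf_hz \
    --out effects/
```

Every run writes a `provenance.yaml` (package version, seed, MD5 of the
configuration) sufficient to reproduce deterministic stages bit-
identically. Analysis tunables live in a single YAML configuration
(`default_config()` / `load_config()`); unknown keys are rejected by name.

See `vignettes/escapekin-methods.Rmd` for the model definitions, parameter
choices and their calibration, what the synthetic generators do and do not
emulate, and known limitations.
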