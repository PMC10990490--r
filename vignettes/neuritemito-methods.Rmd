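---
title: "Models and methods behind neuritemito"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind neuritemito}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuritemito)
```

This vignette documents the models, numerical choices and open design
decisions behind each analysis stage, and — equally important — what the
synthetic-data generator does and does not emulate, hence what a passing
recovery test does and does not establish about real microscopy data.

## The measurement problem

Neuronal activity drives Ca²⁺ into the cytoplasm and, through the
mitochondrial calcium uniporter, into the mitochondrial matrix; matrix
Ca²⁺ stimulates metabolism and reactive-oxygen-species (ROS) production;
mitochondrial ROS in turn modulate trafficking and synaptic recruitment of
AMPA-type glutamate receptors. Quantifying this chain in a living neurite
requires five distinct image-analysis pipelines — calcium event metrics,
ratiometric redox imaging, FRAP, transport kymographs, and spatial
proximity — each of which this package implements against calibrated
multi-page TIFF stacks with explicit pixel size (µm/px), frame interval or
z-step, and excitation metadata.

## Calcium events (ΔF/F_min)

A background-corrected trace `F(t)` is normalized as
`ΔF/F_min = (F − F_min)/F_min` where `F_min` is the **mean of the lowest
5% of samples**. This baseline definition (the original study's analysis
code is not published; the 5%-quantile mean is our documented stand-in,
robust to single-frame dropouts) has one quantitative consequence worth
knowing: on a trace with relative noise σ the estimator is biased low by
≈ 2.06σ (the mean of the lower 5% tail of a Gaussian). At the ~1% noise
of a bright indicator this keeps `F_min` within ~2% of truth and peak
amplitudes within the 5% bias budget; at 10% trace noise it would not.
The generator's default noise (1% of baseline) is chosen to be this
realistic bright-indicator regime.

Event detection: the trace is smoothed with a 0.3 s moving average
(default; `smooth_s = 0` disables), a robust noise SD is taken as the MAD,
and events are maximal runs at or above `median + 3×SD` lasting at least
3 frames, extended outward to the half-threshold crossing. Thresholding is
relative to the trace **median**, not zero, precisely because of the
`F_min` offset noted above. All three constants are exposed as arguments.
"Total activity" is the summed trapezoidal area of ΔF/F_min over detected
events (a combined amplitude × duration measure); a whole-trace integral
is available behind `mode = "whole_trace"`. The per-trace maximum
amplitude is reported one-value-per-mitochondrion. Both metrics are
invariant under a common gain on signal and background, which the tests
assert.

The synthetic transient is a difference of exponentials (0.2 s rise, 3 s
decay, normalized to unit analytic peak). These constants are free
simulator parameters chosen to resemble stimulus-locked mitochondrial
GCaMP transients at a 30 s inter-stimulus interval; nothing downstream
depends on their exact values. Responder heterogeneity is modeled as
amplitude profiles over the stimulus train: "first-dominant" (first
response strictly largest) versus "late-dominant".

## Ratiometric roGFP (405/488)

Per mitochondrion: `F_ratio = (F405 − B405)/(F488 − B488)`, all four
means taken at the single z-plane where the 488-excited signal is highest,
with background from an automatic annulus (2 px gap, 3 px wide, clipped
away from every segmented object). Segmentation is Gaussian smoothing +
Otsu threshold + 4-connected components on the maximum-intensity
projection — the study drew regions manually; an automatic method is
required for unattended testing, and manually supplied ROIs remain
supported. Touching objects merge (documented behavior). A measurement is
invalid when the 488 signal above background does not exceed 3× the
background SD; invalid ratios are suppressed rather than returned.

The ratio is mean-based (matching the "average fluorescence" reading of
the protocol; integrated intensity would cancel identically in the ratio
anyway for fixed pixel sets). The estimator is exactly `r` in the
noiseless expectation because both channels share one spatial profile per
object — any blur leakage cancels in the ratio. With photon noise the
ratio of ROI means is consistent; the 488 denominator is kept bright
enough (default photon budget) that its relative SD stays below 1%, making
the ratio-of-means bias (≈ CV² of the denominator) negligible.

Population structure is assessed by fitting 1- and 2-component Gaussian
mixtures by EM (one quantile start plus 5 seeded random restarts) and
selecting by BIC (penalties 2·log n vs 5·log n). The study reported
unimodality/bimodality descriptively from histograms; BIC selection is the
reproducible surrogate. Hartigan's dip test would be an alternative; it is
noted, not implemented. Variances are floored at 1e-6 of the sample SD to
avoid the classic mixture-likelihood singularity.

## FRAP

Timepoints follow the pre-bleach / 0 min / every-2-min-out-to-16-min
schedule. Region fluorescence is the mean inside the ROI of the
**maximum-intensity z-projection** minus a background-ROI mean (the
study's z-reduction is unstated; max projection matches the
brightest-plane convention used for the ratio measurements). Two
normalizations:

- **percent**: `100·(F(t) − F(0))/(F_pre − F(0))` — pre maps to 100 and
  0 min to 0 by construction, per animal;
- **subtract**: `F(t) − F(0)` in raw units, used when pre-bleach levels
  differ systematically between groups; the pre point is excluded from the
  recovery curve in both modes.

The recovery model is fixed as a one-phase exponential association through
the post-bleach origin, `Y(t) = plateau·(1 − e^(−kt))`. Fitting exploits
the model's structure: for fixed `k` the plateau is linear least squares
in closed form, so the fit is a 1-D profile scan over 120 log-spaced `k`
values refined by bounded optimization — deterministic, no starting-value
sensitivity, exact on noiseless data. A plateau indistinguishable from 0
(immobile pool) flags the fit as k-unidentifiable rather than failing.

Group curves are compared by the extra sum-of-squares F-test: one shared
curve fitted to the pooled points versus separate curves,
`F = ((SS_sh − SS_sep)/2)/(SS_sep/(n_a + n_b − 4))`, p from the F
distribution, Bonferroni-corrected over the comparison family
(group-vs-control by default, all pairs otherwise), significant at
adjusted p < 0.01. Monte-Carlo tests confirm the type-I rate at the 0.01
threshold sits in the stated [0.4%, 2%] band under Gaussian noise.

Pre-bleach puncta: a 20-px-wide linescan profile along the neurite, a
rolling-median local baseline (4 µm window — wider than any single
punctum, so the median inside a punctum still reads baseline), a
2×robust-SD threshold, and per-peak trapezoidal area between threshold
crossings.

## Kymographs and transport

A kymograph is time (rows) × arc-length (columns), the path resampled at
pixel spacing and each cell averaged across the path width via bilinear
interpolation. Detection per frame finds intensity maxima above
`row median + 4×MAD`, refines them to sub-pixel precision by a
log-parabolic fit (exact for Gaussian spots — the log of a Gaussian is a
parabola — with a plain parabolic fallback when a neighbor is
non-positive), and links them greedily across frames under a velocity cap
(default 5 µm/s) with a 2-frame gap allowance. Tracks of ≥ 5 detections
are kept; a track is a transport event when its net displacement reaches
2 µm (the motility threshold is not stated in the source protocol; 2 µm
cleanly separates directed transport from stationary/oscillating puncta
at these imaging scales). Direction is the sign of net displacement along
the path's orientation — anterograde means increasing arc length under
the user's proximal→distal path convention.

Instantaneous velocities follow the segment taxonomy of kymograph
velocimetry tools: a track splits at pauses (step speed < 0.1 µm/s
sustained ≥ 3 frames) and at reversals; each motile segment contributes
Δx/Δt, and pause time is excluded from mean speeds. The original study
counted events manually on blinded kymographs; the automated
detector-with-thresholds replaces the human for reproducibility, and every
threshold is a config parameter.

## Proximity

Detected objects in each channel are projected to the interval of
arc-length positions of their pixels' nearest path samples. The distance
between a mitochondrion and a punctum is the boundary-to-boundary axial
gap (0 if the intervals overlap); a mitochondrion is proximal when its
nearest gap is strictly below 1 µm. Whether the original "<1 µm" metric
was edge- or centroid-based, 1-D or 2-D, is unstated; the edge-gap reading
matches the "localized at or adjacent to" visual criterion, and a
centroid mode is available. The generator places non-proximal objects at
least 1.5 µm away (guard band) so that the ≤0.2 µm projection error of
thresholded segmentation can never flip a classification — this is what
makes exact fraction recovery a fair test rather than a fluke.

## Statistics

- **ROUT** (Q = 1%): robust location by IRLS with Lorentzian weights on a
  constant model (the datasets here are measurement lists, so the
  "regression" is a mean — a documented specialization), scale = 68.27th
  percentile of |residuals| × n/(n−1), per-point two-sided t tails with
  n−1 df, and a Benjamini–Hochberg step-up at rate Q over the most extreme
  residuals. If the robust scale collapses to zero, any point off the
  constant is flagged (infinitely extreme) and ties at the constant never
  are. Applied per group, not pooled (the source protocol does not say;
  per-group avoids masking between-group effects).
- **Dunnett**: adjusted p = P(max_j |T_j| ≥ |t_obs|) under the joint null.
  For two groups this reduces *analytically* to the two-sided pooled
  t-test, and the implementation special-cases it exactly; for k > 2 the
  reference distribution is a fixed-seed 10⁵-draw Monte Carlo sample
  (tolerance ≈ 3/√draws, reported in the output), precomputable via
  `dunnett_reference()` for repeated designs.
- **FRAP exclusion**: an animal is dropped when ≥ 50% of its timepoints
  are outliers (the boundary case excludes, per "50% or more").
- **Effect-size screen**: Pearson r of the values against acquisition
  order (which covariate the original screen used is unstated; acquisition
  order is the natural drift check), pass iff |r| < 0.3 strictly;
  zero-variance input yields an undefined-r flag, not a pass or fail.

## The camera model, and what the generator does not emulate

Rendering is `offset + gain·Poisson(photons_per_unit·blur(field)) +
N(0, read_noise·gain)`, clipped at zero — the standard EMCCD
Poisson–Gaussian chain with a Gaussian PSF. Flat-field variance is
verified against `gain²·photons + (read_noise·gain)²` to 5% in the tests.
A single experiment seed fans out to counter-based per-object and
per-frame substreams, so adding an object never reshuffles the noise of
the others and all outputs are bit-reproducible.

Deliberately not emulated: vectorial/defocus PSF structure, EM-register
excess noise factor, photobleaching chemistry, sample drift and worm
movement, out-of-focus haze from neighboring tissue, and segmentation
ambiguity from genuinely overlapping organelles. A green recovery test
therefore establishes the *algorithmic* correctness and calibration of
each stage under realistic shot noise — not robustness to motion artifacts
or crowded scenes, which real data would add.

Stated-world defaults used by the recovery tests: 1% trace noise for
calcium (see above), a 488-channel photon budget keeping denominator CV
< 1% for ratios, FRAP group simulations with n = 8 animals and Gaussian
noise SD 5 (percent units), transport velocities 0.5–2.5 µm/s with ≥
2.5 µm inter-particle separation (the "well separated" precondition), and
proximity scenes at 100 mitochondria with the 1.5 µm guard band.

## Numerical conventions

Coordinates are pixel-centered, 0-based, x = column, y = row; all micron
quantities derive from `px_um`. Z-stack span is (n−1)·dz (plane count and
spacing are treated as authoritative where a source protocol's prose
disagrees with them). TIFF I/O is restricted by design to baseline
multi-page 16-bit little-endian grayscale with a JSON sidecar for
calibration — maximal interoperability with zero imaging dependencies;
out-of-range intensities error rather than clip. Event areas integrate
the positive part of ΔF/F over the event window (trapezoid rule). The
CLI takes JSON configs; every stage writes a `run_manifest.json` with
inputs, parameters, seed and package version.

## File formats and CLI config schemas

On-disk objects (all JSON):

- `rois.json`: `{"rois":[{"id","kind","vertices":[[x,y],...],"background_id"}]}`
  with `kind` one of `rectangle` (2 corners) / `polygon` (≥3 vertices);
- `path.json`: `{"points":[[x,y],...],"width_px":20}`;
- `protocol.json`: `{"period_s","pulse_duration_s","total_duration_s"}` or
  `{"onset_times_s":[...],"pulse_duration_s"}`;
- every TIFF written by the package carries a `<file>.tif.json` sidecar
  with `axis_kind`, `dt_s`/`dz_um`, `px_um`, `exposure_ms`, `excitation_nm`.

`neuritemito <stage> --config CONFIG.json --out DIR [--seed N]` config keys
per stage:

- `simulate`: `scenario` (`calcium|rogfp|frap|transport|proximity`) plus
  scenario parameters (`n_mito`, `period_s`, `k_per_min`, `plateau_pct`,
  `n_particles`, `target_fraction`, ...). Outputs TIFF stacks, ROI/path/
  protocol JSON and `truth.csv`.
- `calcium`: `traces_csv` (columns `source_id,t_s,f_raw,f_bg`), optional
  `protocol_json`, `baseline_fraction`, `threshold_sd`, `smooth_s`.
  Outputs `events.csv`, `metrics.csv`, `evoked.csv`.
- `ratio`: `stack405`, `stack488` (TIFF paths). Outputs `ratios.csv`,
  `modality.json` (when ≥20 valid ratios).
- `frap`: `series_csv` (columns `animal_id,group,t_min,f`; `t_min` may be
  `"pre"`), `mode` (`percent|subtract`), optional `control`. Outputs
  `frap_norm.csv`, `fits.json`, `comparisons.csv`.
- `kymo`: `stream_tiff`, `path_json`. Outputs `events.csv`,
  `velocities.csv`, `summary.json`.
- `proximity`: `objects_csv` (columns `id,channel,s_start_um,s_end_um`) or
  `mito_tiff` + `puncta_tiff` + `path_json`; `threshold_um`. Outputs
  `proximity.csv`, `summary.json`.
- `stats`: `data_csv` (columns `group,value`), `control`, `test`
  (`anova_dunnett|paired_t`), `Q_percent`, `remove_outliers`. Outputs
  `stats.json`.

Each run additionally writes `run_manifest.json` (stage, config, seed,
package version, timestamp).

## Known limitations

- The event detector's thresholds are stand-ins for an unpublished
  analysis; with very different indicators or noise regimes they need
  retuning (they are all exposed).
- Greedy nearest-neighbor linking does not resolve crossing trajectories;
  crossing particles can fragment or swap tracks. The acceptance tests
  state non-crossing separation as a precondition, mirroring the manual
  counting they replace.
- The FRAP model family is fixed to one-phase association; reaction- or
  diffusion-dominated recoveries are out of scope (the experimental
  protocol suppresses lateral diffusion by flanking bleaches).
- Proximity is 1-D along the neurite axis by construction.
- ROUT on a constant model matches scalar datasets only; regression-model
  ROUT is not implemented.
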