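---
title: "Methods: behavioural quantification of cone-assay videos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavioural quantification of cone-assay videos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(victa)
```

## The measurement problem

A WHO cone test confines five mosquitoes against a netting sample for
three minutes. Filmed from a fixed rig, the assay becomes a quantitative
behavioural experiment: the footage contains when and where each mosquito
was active, whether activity concentrated at the net surface (the lower
cone half, LHC) or dispersed upward (UHC), and how much of the test was
spent motionless. `victa` extracts these quantities automatically from
standardized video (540 × 960 px, 30 fps), logging detections every
0.1 s — 1800 samples per 180-s test.

The package deliberately stops at the analysis-ready table. Fitting
LMMs/GLMMs to activity, or Cox models to post-exposure longevity, is
standard statistical practice on the merged output and is left to the
analyst.

## Detection model

Moving mosquitoes are segmented by a per-pixel Gaussian-mixture background
model of the classic adaptive-mixture family. Each pixel keeps `K = 3`
modes with weight `w`, mean `mu` and variance `sigma^2`. An observation
`x` matches the mode minimising its normalised squared deviation among
those with `(x - mu)^2 < c * sigma^2`, where `c` is the
`variance_threshold` (default 16, i.e. 4 sigma). Matched modes update by
exponential smoothing with learning rate `alpha`; an unmatched observation
replaces the weakest mode with a fresh one (`var_init = 225`, clamped to
`[4, 1125]`). Weights renormalise each step. Modes are background in
descending weight order until their cumulative weight first exceeds
`background_ratio`; a pixel is foreground when its matched mode is outside
that set, or no mode matches.

Assumptions this encodes:

* the scene is dominated by a quasi-static, brighter background;
* mosquitoes appear as compact darker regions whose *motion* between
  0.1-s samples is what makes them foreground — a mosquito that remains
  still is absorbed into the background and is, by design, not counted as
  moving;
* illumination changes are slow relative to the background memory.

`background_ratio` defaults to 0.8. With continuously flying mosquitoes a
path pixel is revisited periodically, so a weak "dark" mode persists at
equilibrium weight roughly `1 / T` for a revisit period of `T` samples;
a ratio of 0.8 keeps such modes out of the background set while still
absorbing genuinely static scene changes within seconds.

The model consumes the 0.1-s sample stream (every 3rd decoded frame).
`history` is expressed in decoded frames (default 150, about 5 s of wall
time); the automatic learning rate is `alpha = stride / history = 1/50`
per sample, preceded by a `1 / n_seen` warm-up so the model converges
within the acclimatisation window from a single initial frame.

### Preprocessing and contour regularisation

Each sampled frame is denoised by a 3 × 3 median blur and a grayscale
morphological opening (disc of `open_kernel = 3` px) before the mixture
update; the binary foreground mask is then opened (3 px) and closed
(`close_kernel = 5` px), connected components are labelled, and components
are kept when their area lies in `[min_area, max_area]` (defaults 20 and
2000 px², the plausible span of a mosquito at this resolution) and their
centroid falls inside the calibrated cone polygon. If more than
`max_movers = 5` remain, the largest are kept (five mosquitoes occupy the
cone; extras are necessarily artefacts). Two mosquitoes merged into one
contour count once — an acknowledged undercount with no split heuristic.
The compiled morphology was verified against `EBImage`'s
erosion/dilation on random masks.

## Region geometry

The cone's projection is a per-rig calibration: a polygon plus a
horizontal `split_line_y` dividing UHC from LHC. There is no automatic
cone detection — rigs are fixed, and a one-off calibration avoids an
error source. Tie-break: a centroid exactly on the split line is *lower*,
the net-facing region of interest; the rule is arbitrary but must be fixed
for determinism.

## Metrics

* **Epochs.** Samples with `t < 5` s are excluded (model acclimatisation);
  the remaining 175 s form 35 half-open windows `[5 + 5k, 5 + 5(k + 1))`.
  Half-open windows prevent double counting at boundaries; the sample at
  exactly `t = 5` s belongs to epoch 1. Epoch membership is computed on
  the integer sample grid (`round(t / 0.1)`), immune to floating-point
  jitter in timestamps.
* **Counting unit.** Activity is the *mosquito-sample*: one moving
  mosquito in one 0.1-s sample. Per-test totals then live on the observed
  scale of thousands, bounded by 5 × 1750 = 8750.
* **Resting.** The strict statistic counts samples where *no* mosquito
  moved relative to the previous sample; the first sample has no
  predecessor and is excluded, so a fully static 180-s test scores 1799.
  It is computed over all 1800 samples, acclimatisation included — during
  a genuinely static opening the converged model correctly reports no
  motion there — and `resting_seconds = 0.1 × resting_frames` exactly.
  The weaker reciprocal statistic `5 − n` is exposed as
  `inferred_inactivity()`.
* **Proportions.** `prop_lower = lower / total` is emitted as missing when
  total activity is zero — never 0, which would bias downstream models
  toward net-avoidance.
* **Validity.** Samples that cannot be decoded carry no detections and are
  excluded from epoch numerators and denominators;
  `valid_frames_proportion` (valid / 1800) is reported for use as a model
  covariate. Because total activity is defined over the 35 epochs yet the
  test nominally spans 180 s, the full-window sum including the first 5 s
  is also emitted (`total_activity_full`) rather than guessing intent.

## Video handling

No codec library is bundled: footage lives in a documented gzip
"frame-stack" container (single-channel 8-bit frames plus an ASCII
header), which the simulator writes and all readers stream
sequentially. `standardize_video()` letterboxes any input into
540 × 960 (scale to fit, centre, zero padding) — letterboxing rather than
cropping or distorting preserves the pixel geometry that region
calibrations depend on — and resamples to 30 fps by nearest-frame
selection. Timestamps always derive from frame index / fps, not container
metadata, for determinism across decoders. Multi-channel input collapses
to Rec. 601 luma. The 0.1-s sampler takes the frame nearest each multiple
of the interval — every 3rd frame at 30 fps — and yields
`floor(D / i) + 1` samples capped at the available frames.

## The simulator and what passing tests mean

`synthetic_scene()` renders dark anti-aliased discs (2-px soft edge, to
avoid aliasing a real camera would not produce) moving piecewise-linearly
through scripted waypoints over a uniform background with optional linear
drift and i.i.d. Gaussian pixel noise clipped to [0, 255]
(`noise_sd = 5` by default, a plausible sensor level). Resting intervals
freeze progress along the path, preserving continuity at take-off. Ground
truth marks a mosquito as moving when its centroid displaced more than
1 px since the previous sample — aligning "truth" with what a
background-subtraction detector can physically see.

Presets mirror the phenotypes seen in real assays: `crawler` (all five
circuit the net surface; truth `prop_lower > 0.8`), `dispersed` (three
upper, two lower, continuous flight; `prop_lower = 0.4`), `high_rest`
(all still for 100 s, then flight; resting 100 s) and `mixed` (two still
throughout, three flying). Flying paths are non-retracing rosettes or
stadium circuits with per-sample displacement above the blob diameter and
pairwise separation of at least three diameters — the regime where exact
ground-truth recovery is a fair demand. Under it, detection matches truth
sample-for-sample and epoch-for-epoch, noise-free and at the default
noise level alike.

Two caveats bound what this shows about real footage. First, any
background-subtraction detector exhibits short transients at motion-state
changes: a landing mosquito stays foreground for a fraction of a second
until absorbed, and a take-off leaves a brief "ghost" at the vacated
position. Scenes with rest/flight transitions are therefore held to
tolerance bands (activity within 5%, resting within two epochs' worth of
samples at default noise; transition overcounts bounded by ~1 s per
mosquito) rather than exactness. Second, the simulator does not emulate
real nuisance structure — flicker, shadows, specular net reflections,
occlusion of one mosquito by another, or optically merging individuals —
so field deployments still require rig-specific validation; the cap at
five movers and the merged-contour undercount are the designed-in
responses to the latter.

## Life-history merge

Mosquitoes are anonymous within the cone, so assay-level metrics attach to
each of the five cohabiting individuals — matching the use of a shared
per-assay activity proportion as a covariate downstream. The join is
strict: orphan records (unknown assay) abort with the ids listed,
duplicate keys are integrity errors, off-cohort assays warn. Haematin is
carried as measured (µg/ml); converting it to blood-meal weight via a
spectrophotometric standard curve is wet-lab calibration outside the
tool's scope. Missing values are empty fields, never sentinels.

## Problem sizes and performance

Unit tests run on compact scenes (240 × 320 px, 6–15 s) where every
detection property is checked against scripted truth; the full-scale
checks render the complete 540 × 960, 180-s dispersed preset once and
verify the 1800-sample / 35-epoch structure, exact regional recovery and
byte-identical determinism on it. A full 180-s render takes ~40 s and a
full detection pass ~2 min on one CPU core; the per-frame work (median
filter, mixture update, morphology) is compiled.

## Known limitations

* No identity tracking: metrics are counts, not trajectories, and
  individual-level behaviour within an assay is out of reach by design.
* Knockdown is not classified; a knocked-down mosquito simply stops
  contributing movement.
* A mosquito resting from the very first frame is part of the learned
  background — correct for resting statistics, but it means "present but
  never moving" and "absent" are indistinguishable.
* The H.264/MPEG-4 delivery format of field recordings is not decoded
  directly; footage must be transcoded to the frame-stack container
  upstream.
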