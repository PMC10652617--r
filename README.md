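# victa — video cone test analysis

`victa` quantifies mosquito behaviour in video-recorded WHO cone bioassays.
The standard cone test exposes five mosquitoes to a netting sample under a
plastic cone for three minutes and traditionally scores only knockdown and
mortality. Filming the cone and analysing the footage recovers what the
mosquitoes actually *did* during exposure — how much they flew, where in the
cone they were active, and how long they rested — behavioural endpoints that
differ sharply between untreated and insecticide-treated nets (ITNs) and
between susceptible and pyrethroid-resistant strains. The package is aimed
at vector-biology labs running cone assays who want automated, reproducible
behavioural metrics that can be joined to post-exposure life-history
follow-up (blood-feeding, blood meal weight, longevity) for downstream
mixed-model or survival analysis.

## What it computes

Videos are standardized to 540 × 960 px at 30 fps and sampled at 0.1-s
intervals (1800 samples over 180 s). Each sampled frame passes through:

1. **Moving-mosquito detection.** A per-pixel Gaussian-mixture background
   model (K modes per pixel; match by squared-Mahalanobis distance
   `d² < c·σ²`, weakest-mode replacement, background = highest-weight modes
   up to a cumulative ratio) classifies foreground pixels. The mask is
   regularised by morphological opening and closing and labelled into
   contours; components within the area bounds whose centroid lies inside
   the calibrated cone polygon are the movers `n(t)`, capped at the 5
   mosquitoes present.
2. **Spatio-temporal metrics.** Counts aggregate into 35 five-second
   epochs (the first 5 s excluded while the background model acclimatises),
   stratified into the upper (UHC) and lower (LHC) halves of the cone by a
   calibrated split line. Per assay: total activity
   `A = Σ_t n(t)` in mosquito-samples, regional activity, the proportion of
   activity in the LHC (`PLHC`, the region bordering the net), inferred
   inactivity `5 − n(t)` per sample, and the strict resting count — samples
   in which *no* mosquito moved relative to the previous sample.
3. **Composite imagery.** A minimum-intensity projection across all 0.1-s
   samples (mosquitoes are darker than the background) paints every visited
   position into one summary image.
4. **Life-history merge.** Assay metrics join per-mosquito post-exposure
   records (feeding at 1/24 h, haematin µg/ml, wing length, survival) into
   an analysis-ready CSV.

A scripted simulator renders synthetic cone scenes (dark discs on a
brighter, optionally drifting and noisy background) with exact per-sample
ground truth, so every stage is testable without real footage. Since no
video codec is bundled, footage is handled in a documented gzip frame-stack
container (`.fsv`); the simulator writes it and `standardize_video()`
normalises any frame-stack input to the canonical geometry.

## Worked example

```r
library(victa)

## render the "dispersed flyer" preset: 5 mosquitoes in continuous flight,
## three in the upper and two in the lower cone half, noise-free
scene <- preset_scenes(noise_sd = 0)$dispersed
sim <- generate_scene(scene, "dispersed.fsv")

assay <- analyze_assay("dispersed.fsv", scene$geometry,
                       assay_id = "dispersed_1")
assay$metrics
#> <victa_metrics> assay 'dispersed_1'
#>   total activity: 8750 (upper 5250, lower 3500)
#>   prop. lower-region: 0.4
#>   resting: 0 frames (0 s); inactive samples: 0
#>   valid-frame proportion: 1
```

All five mosquitoes move in every one of the 1750 post-acclimatisation
samples, so total activity is its ceiling 5 × 1750 = 8750 mosquito-samples;
two of five flyers occupy the lower cone, giving `PLHC = 0.4`; nothing
rests. The detection log, epoch table, metrics and composite PNG are
written by `write_assay_outputs(assay, "out/")`, and

```r
lh <- simulate_life_history("dispersed_1", seed = 12)
merged <- merge_life_history(assay$metrics, lh)   # 5 rows, one per mosquito
```

attaches the assay's covariates to each cohabiting mosquito. A thin CLI
wraps the same functions: `exec/victa convert|analyze|composite|simulate|merge`.

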