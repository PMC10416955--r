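# broilertrack

Estimation of **how long each broiler chicken feeds** — head-in-feeder time
per visit — from per-frame head-detection bounding boxes, for researchers
and precision-livestock engineers monitoring feeder pans with ceiling
cameras. The package is detector-agnostic: any object detector that emits
boxes per frame (MOT-Challenge CSV or per-frame YOLO text) plugs in; no
video decoding or learned model is included.

## Method

Three stages, run per camera scene:

1. **Centroid tracking.** A detection keeps the identity of the nearest
   stored head center when their Euclidean distance is below 20 px
   (strictly); otherwise it founds a new identity. Each identity keeps its
   last 10 observations and survives up to 10 consecutive missed frames
   before being retired. Conflicts are resolved greedily, smallest distance
   first, one-to-one.
2. **Feeding index.** With head box *B* and circular feeder region *F*,

   *I*<sub>feed</sub> = area(*B* ∩ *F*) / area(*F*),

   computed in closed form (circular-sector decomposition, no sampling).
   *I*<sub>feed</sub> > 0 ⇔ the head is in the feeder. A stricter
   center-in-circle criterion is available via configuration.
3. **Visit accounting.** Maximal runs of feeding frames per identity form
   visits; `n_frames / fps` (default 15 fps) converts counts to seconds.
   Evaluation against labeled ground truth reports head-count, overall and
   per-visit feeding-time accuracy as 100·(1 − relative absolute error),
   clamped at 0, with visits matched greedily by frame overlap.

A synthetic flock simulator (4-state behavior model: wander, approach,
feed, leave; Gaussian centroid jitter, missed detections, false positives)
generates ground-truthed scenarios so the whole chain is testable without
farm video. See `vignettes/feeding-time-methods.Rmd` for the model,
parameter rationale and limitations.

## Worked example

```r
library(broilertrack)

# one minute of synthetic video: 5 birds, default noisy detector
scenario <- simulate_flock(sim_params(n_birds = 5, n_frames = 900, seed = 7))
fit <- estimate_feeding(scenario$detections[, 1:6], scenario$scene,
                        n_frames = 900)
head(fit$visits, 5)
#>   track_id start_frame end_frame n_frames  duration_s
#> 1        1          71       246      167 11.13333333
#> 2        2         281       556      264 17.60000000
#> 3        2         704       899      183 12.20000000
#> 4        3         139       139        1  0.06666667
#> 5        3         141       190       48  3.20000000

evaluate_run(fit$visits, fit$head_count, scenario$true_visits,
             scenario$head_count, fps = 15)
#> Feeding-time evaluation
#>   head-count accuracy:         0.0 % (37 est / 5 true)
#>   overall time accuracy:      94.8 % (140.20 s est / 147.87 s true)
#>   per-visit time accuracy:    95.2 % (12 est / 11 true visits)
#>   mean duration per visit:   11.68 s
```

Reading the numbers: track 2 made two feeder visits (17.6 s and 12.2 s of
counted feeding). Total estimated feeding time is within ~5 % of ground
truth and matched visits recover their durations to ~95 % — the misses of
the simulated detector shave counted frames. The head count is inflated
(37 identities for 5 birds) because false positives above the 0.5
confidence cutoff found short-lived identities; that is a property of the
simulated detector, not of the bookkeeping, and is exactly the failure mode
head-count accuracy is meant to expose.

## Command line

```sh
inst/cli/broilertrack simulate --out scen --seed 4 --n-birds 3 --n-frames 450
inst/cli/broilertrack run \
  --detections scen/detections.csv --config scen/scene.yaml \
  --truth-visits scen/truth_visits.csv \
  --truth-head-count scen/truth_head_count.txt \
  --out results
```

`run` writes `visits.csv` and `report.json`; `track`, `feed` and `evaluate`
expose the stages individually. The scene configuration file format is
documented by example in `inst/extdata/example_scene.yaml`.

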