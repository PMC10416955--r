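---
title: "Methods: individual broiler feeding-time estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: individual broiler feeding-time estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(broilertrack)
```

## The problem

On commercial broiler farms, how long each bird keeps its head in the feeder
pan is a welfare and management signal: departures from the usual feeding
pattern are an early disease symptom. Ceiling cameras over the feeder pans
provide the raw signal; an object detector (typically a YOLO-family model)
marks each broiler head with a bounding box per frame. `broilertrack` takes
over from there. It is detector-agnostic by design: any detector that can
emit per-frame boxes (MOT-Challenge CSV or per-frame YOLO text) can feed the
pipeline, and the package itself contains no learned components.

The pipeline has three stages:

1. **Tracking.** Per-frame detections are linked into identities by
   nearest-centroid association.
2. **Feeding decision.** Each tracked head is flagged feeding or not,
   per frame, from its geometric relation to the circular feeder region.
3. **Visit accounting.** Feeding frames are grouped into visits; frame
   counts divided by the frame rate give seconds of feeding per visit and
   per bird.

## Tracking model

Association uses only the center point of the head box. A detection within
`match_radius` (default 20 px) of a live identity's last stored center keeps
that identity; a detection farther than the radius from every live identity
founds a new one. A distance of exactly 20 px does *not* match: the rule is
strictly "less than", and the boundary case is resolved toward a new
identity. Each identity stores its most recent `history_length` (default 10)
observations and survives up to `max_missed` (default 10) consecutive frames
without a detection, holding its last center static — there is no motion
model, so a coasting head is looked for where it was last seen. At 15 fps
these defaults suit birds that move a few pixels per frame; the radius
should stay below half the typical inter-bird head distance, or identities
will swap.

The association order needed a decision the nearest-centroid description
leaves open: when two detections fall within the radius of one identity (or
vice versa), we commit globally smallest distance first, one-to-one, ties
broken by lower detection input index and then by older identity. This is
the simplest deterministic refinement of sequential nearest matching;
a Hungarian-style global optimum was deliberately not used because the
per-frame geometry here rarely differs from greedy and the greedy rule is
what the sequential description actually induces.

Detections are filtered before association: confidence below
`min_confidence` (default 0.5 — a plumbing default, not a calibrated one)
and centers outside the polygonal tracking area are dropped.

## Feeding decision

The feeder pan is modeled as a circle in the image. For a head box $B$ and
feeder circle $F$ the feeding index is

$$ I_{\mathrm{feed}} = \frac{\operatorname{area}(B \cap F)}
                            {\operatorname{area}(F)} , $$

and the head is "in the feeder" whenever $I_{\mathrm{feed}} > 0$, i.e. the
box overlaps the circle with positive area. Note the denominator is the
*circle* area, so the index is not the fraction of the head inside the
feeder; only positivity matters for the decision, and the value is retained
mostly for inspection. An alternative `criterion = "center"` flags feeding
when the box center lies in the circle (boundary inclusive); it is stricter
near the rim. The area rule is the default.

The intersection area is computed in closed form by walking the box edges
and summing signed circular-sector and triangle contributions (Green's
theorem); a Monte-Carlo estimator exists in the test suite purely as an
oracle. One numerical subtlety matters: for a box far from the circle the
four sector terms cancel only to floating-point residue (~1e-16), which
would make the strict `> 0` feeding test fire spuriously, so disjointness is
decided exactly first (closest box point at distance ≥ r ⇒ area 0).
Remaining equality comparisons use an absolute tolerance of 1e-9 px.

## Visit segmentation

A visit is a maximal run of feeding-flagged observations of one identity.
Two boundary rules needed decisions:

* **Observed exits.** `gap_tolerance` (default 0) observed non-feeding
  frames may be bridged inside a visit without splitting it; bridged frames
  are never counted in `n_frames`. The default is 0 because frame counting
  is defined literally — a single observed frame with the head out of the
  feeder ends the visit.
* **Unobserved frames.** A frame in which the identity produced no
  detection does *not* split the visit: the occupancy is unobserved, not
  observed to have ended. The tracker's `max_missed` expiry bounds how long
  a visit can stay open without evidence, and identity loss terminates the
  visit. The alternative (treating a missed frame as an exit) makes
  estimated visit durations collapse under even mild detector miss rates —
  a 5 % miss rate fragments an 18-second visit into ~15 pieces — which is
  not what frame-counting over a tracked identity is meant to measure.

Durations are `n_frames / fps` with `fps` a constant from the scene
configuration (default 15); variable frame rates are out of scope.

## Evaluation protocol

Ground truth is a labeled head count plus per-bird feeding intervals.
Three figures are reported, all as `100 · max(0, 1 − |est − truth|/truth)`:

* **Head-count accuracy** — distinct identities vs the labeled head count.
* **Overall feeding-time accuracy** — total estimated seconds vs labeled
  seconds.
* **Per-visit accuracy** — estimated visits are matched to labeled visits
  greedily by maximal frame overlap (one-to-one; ties to the earlier true
  visit, then the earlier estimate); matched pairs score the relative
  duration error, unmatched true visits score 0, and the mean over true
  visits is reported.

The relative-error form and the overlap-greedy matching are this package's
conventions — field reports of such accuracies rarely print their formulas —
and every report object states them. Labeled identities are never required
to match tracker ids; matching is purely by intervals.

## The synthetic world

`simulate_flock()` emulates one ceiling camera over one feeder pan, with
defaults fixed once:

| parameter | default | why |
|---|---|---|
| scene | 800×600 px, 15 fps | common surveillance geometry; 15 fps matches farm camera practice |
| feeder circle | r = 60 px at image center | pan of ~0.3 m seen from ~3 m |
| head size | 24 ± 2 px | broiler head from ceiling height |
| step scale | 3 px/frame (capped at 12) | ~45 px/s walking pace; cap keeps steps surely below the 20-px match radius |
| feed dwell | mean 18.46 s (`p_leave = 1/(18.46·15)`) | field-scale mean visit length at a commercial pan |
| wander→approach | 0.008 / frame | a bird heads for the feeder every ~1–2 min |
| detector noise | σ = 2 px, p_miss = 0.05, λ_fp = 0.1 | a good but imperfect head detector |
| confidences | true 0.7–1.0, false 0.1–0.65 | false positives sit below the true mode so the 0.5 cutoff is exercised |

Each bird cycles wander → approach → feed → leave under per-frame transition
probabilities; approach walks toward a bird-specific spot at 0.7 r on the
pan, feeding holds that spot with sub-pixel jitter, leaving walks radially
out. The pan is treated as a physical obstacle for birds that are not
feeding: a wandering bird's head never crosses the rim (circle radius plus
half the head diagonal), because real birds walk around the feeder rather
than through it — without this, random walks graze the rim and create
hundreds of spurious one-frame "visits" that no observer would call feeding.
Ground-truth intervals are derived from the generated geometry itself
(frames where the true box satisfies the configured criterion), not from the
behavior state, so approach and leave edges are included exactly as the
estimator sees them.

All randomness flows from one seed; the caller's RNG state is preserved.
With `enforce_separation = TRUE`, pairwise distances are kept above
`min_separation` (default 45 px, just over twice the match radius) by
resampling or holding steps — the regime in which the tracker is provably
switch-free.

What the generator does **not** emulate: occlusion between birds, box-size
noise, correlated detector failures, perspective distortion, and feeding
pecks vs mere head-in-pan idling. A green synthetic test therefore
establishes algorithmic correctness of tracking, indexing and accounting —
not detector quality, and not that head-in-feeder equals true feed intake.

## Numerical and degenerate-input choices

* Boundary membership is inclusive for both circle and polygon, making
  region decisions deterministic on measure-zero sets.
* Polygons must be simple with positive area; this is validated at
  construction (O(n²) edge crossing check).
* Equal association distances are broken by detection input index, then
  track age; identities are never reused after expiry.
* Accuracy denominators must be positive; empty visit sets make
  mean-duration undefined rather than zero.
* Writers emit fixed 6-decimal formatting, so repeated runs are
  byte-identical and round-trips are lossless at that precision.

## Known limitations

* A bird that leaves and re-enters after the identity expires is counted as
  a new head, inflating head counts exactly as identity fragmentation does
  in the field.
* False positives above the confidence cutoff found (usually short-lived)
  identities; with the default noise this typically triples the raw
  identity count over a minute of video, so head-count accuracy is only
  meaningful with a well-calibrated cutoff or post-hoc track filtering,
  which this package intentionally does not apply.
* The feeding circle models whatever the user draws — pan rim or pan
  interior is a configuration decision, not a package one.
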