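---
title: "Occlusion-robust multi-mouse tracking: models and design"
author: "MRTrack authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Occlusion-robust multi-mouse tracking: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Open-field assays record several freely behaving mice with a single
overhead camera. Whole-body trackers lose identities whenever animals
touch, cross, or climb over one another, because the merged silhouette can
no longer be attributed to individuals. MRTrack implements an
occlusion-robust pipeline built around a simple observation: a mouse's
ears are small, nearly always visible from above, and carry enough
appearance and position information to follow an individual through a
crossing.

The pipeline has five stages:

1. **Preprocessing.** Each frame is normalized to a fixed mean intensity,
   a background model is built from subsampled frames, and foreground
   *blobs* (8-connected components of pixels that differ from the
   background by more than a threshold) are segmented. A frame whose blob
   count equals the declared number of subjects is a *non-occlusion*
   frame; any mismatch marks an *occlusion* frame. Maximal runs of equal
   kind partition the video into alternating fragments, and every
   occlusion fragment records its two flanking non-occlusion frames.
2. **Non-occlusion tracking.** At ordinary frame rates an animal moves
   little between frames, so the blob sharing the most pixels with an
   identified blob of the previous frame inherits its identity. MRTrack
   enforces the one-blob-one-individual model as a globally optimal
   bijective matching on shared-pixel counts (ties resolve by IoU, then
   by incumbent identity order).
3. **Ear detection.** An anchor-based convolutional detector locates the
   ears in occlusion frames. Its feature pyramid carries an extra
   low-level (stride-4) lateral connection and prediction head — the
   architectural modification under study — because an ear only a few
   pixels wide is badly served by a pyramid whose finest grid is 8 px.
4. **Identity assignment.** A dual-Siamese similarity model scores pairs
   of ear observations in adjacent frames: one weight-shared
   convolutional branch embeds the fixed-size image crop, one
   weight-shared fully connected branch embeds the centroid
   (normalized to [0, 1] by the frame size), both trained with a
   contrastive loss on their embedding distances; a two-layer fully
   connected head fuses the two distance signals into a similarity score
   trained with binary cross-entropy. Identities propagate through an
   occlusion fragment by globally optimal assignment on `1 - score`,
   with matches below a score floor rejected.
5. **Linking.** On each flank frame the ear-based individuals are matched
   to blob identities by spatial containment (nearest centroid as
   fallback), occlusion-fragment tracks are relabelled to global
   identities, and the next blob fragment is seeded accordingly. When the
   two flanks disagree the earlier flank wins (logged); an individual
   unmatched on both flanks leaves an explicit gap — gaps are never
   interpolated.

Evaluation uses IoU-based average precision (mAP at 0.5 and averaged over
IoU 0.5–0.9 in steps of 0.1) for detection, and two tracking metrics:
MOTA, `1 - (FN + FP + IDSW) / GT`, and the identity correct rate
ICR, `1 - (Miss + Switch + Drift) / GT`, where GT is frames times declared
identities. Behavioral analytics comprise per-frame velocity with 5-minute
block means, the two-dimensional population standard deviation
`sigma = sqrt(sum((x_i - mean(x))^2 + (y_i - mean(y))^2) / n)`, a
12-region occupancy histogram over the open field's main region, the
Wilcoxon rank-sum test, and the "N-1" chi-squared test for proportions
(the Pearson statistic scaled by `(N - 1) / N`).

## The synthetic arena

Real multi-animal videos with per-frame identity ground truth are scarce,
so the package ships a deterministic generator: a featureless bright
arena (intensity 220), dark ellipse bodies (60), and two ear disks (140)
placed at ±35° off the heading axis near the head focus of the body
ellipse, plus Gaussian sensor noise. (The centre distance is capped so
each disk overlaps the body silhouette by at least about 1.5 px — the
raw focus sits marginally outside the ellipse boundary at that bearing,
and a sub-pixel overlap can rasterize into a disconnected disk.)
Subjects follow a smooth random walk (heading persistence with Gaussian
turn noise, reflective walls) with two pieces of contact physics: bodies
are solid (centres cannot approach closer than one body width, so
animals cross and partially overlap but never pass through each other)
and mice disengage after bumping (a mild avoidance drift within about
2.5 body widths), so contacts are brief crossing events rather than
sustained wrestling bouts. With two or more subjects and enough travel,
the generator retries seed offsets until at least one frame shows body
contact, and records the final seed. A `minSeparation` option enforces a
hard separation floor for non-crossing control videos.

The default walking speed is 1 px/frame: at the 64 px two-mouse-cage
scale (about 3.5 px/cm, 25 fps) that is roughly 7 cm/s, a realistic
spontaneous locomotion speed. The single-subject clip used to train the
detector and similarity model walks at 2 px/frame instead
(`train_speed_scale`): a brisker walk yields more pose and location
diversity per frame and a cleaner background model.

A subject's ground-truth *occluded* flag is on exactly when its pixel
mask shares an 8-connected component of the union foreground with another
subject — i.e. contact at the same connectivity the segmenter uses. A
strict mask-intersection definition would disagree with blob counting on
the knife-edge frames where two masks are diagonal neighbours without
sharing a pixel.

Two arena layouts are used. The classification and overlap-tracking
studies use a 256 px arena with 24 × 12 px bodies (animal about a tenth
of the arena width, as in a large open field). The detector and
end-to-end studies use a 64 px arena with 18 × 9 px bodies and 5.6 px
ear disks — the proportions of a small two-mouse home cage, a size at
which a detector trains on one CPU in minutes, and an ear size in the
5–8 px band typical of overhead recordings; this is the small-object
regime the stride-4 pyramid connection targets.

What the generator does **not** emulate: fur texture, shadows, bedding
clutter, perspective distortion, grooming postures that hide both ears,
or appearance differences between individuals (all synthetic mice are
identical, so the image branch of the similarity model carries little
discriminative signal and the coordinate branch dominates — on real
videos the balance would differ). Passing the synthetic suite therefore
demonstrates the pipeline's mechanics and metric arithmetic, not
field-ready accuracy on laboratory recordings.

## Numerical and design choices

* **Background model.** The classical model is the pixel-wise mean of
  evenly subsampled normalized frames; it is exact on long recordings
  where each pixel is background most of the time. On clips of a few
  hundred frames a dwelling subject biases the mean enough to erode the
  slim ear/background contrast, so the pipeline defaults to the
  pixel-wise **median** (`background_stat = "median"`) over 40 samples,
  which tolerates up to half the samples being contaminated. Both are
  available in `buildBackground`.
* **Segmentation.** Absolute difference against the background (handles
  dark-on-light and light-on-dark), default threshold 35 on the
  normalized intensity scale, 8-connected components, minimum blob area
  50 px. The difference threshold is a config knob; its default was
  chosen on synthetic arenas so that both body and ear pixels clear it
  with a wide noise margin (the ear/background contrast is the slimmest,
  about 48 intensity units after normalization) while residual
  background bias does not.
* **Auto-labelling quality control.** Besides the two-components rule,
  a frame's labels are kept only when both ear components look like
  whole ears (at least 6 px each, areas within a factor 2.5); partial
  components from unlucky poses are skipped and logged rather than
  emitted as corrupt boxes.
* **Frames with more blobs than subjects** count as occlusion frames;
  noise specks are removed by the minimum-area filter first.
* **Normalization layers.** Convolution blocks are conv + per-channel
  normalization + leaky ReLU. During training the per-image channel
  statistics are used and accumulated into running averages; at
  inference the frozen running statistics are applied. Frozen statistics
  matter here: a detector trained on single-subject clips is applied to
  multi-subject frames whose global intensity distribution differs, and
  activation statistics must not shift with it.
* **Anchors.** Anchors are k-means-fit to the training label sizes, but
  never smaller than their level's stride — with same-size training
  objects the fit is otherwise degenerate and the level assignment
  arbitrary. A label matches all anchors with shape-IoU at least 0.3 at
  the level where that IoU is highest, at the nearest grid cell.
* **Detector loss.** Binary cross-entropy objectness over every cell
  (positive cells up-weighted, default 30), plus `1 - IoU` box
  regression on matched anchors decoded YOLO-style
  (`(2*sigmoid - 0.5 + cell) * stride`, `(2*sigmoid)^2 * anchor`).
  Training is SGD with momentum 0.937 under a one-cycle learning-rate
  schedule with final factor 0.2 and batch size 8 by default; the
  desk-scale studies use a learning rate of 0.02, about 150 training
  frames and tens of epochs, chosen so one training fits in roughly a
  minute of CPU.
* **Occlusion-phase detection.** Inside occlusion fragments the
  detector runs at a lower confidence threshold (`track_confidence`,
  default 0.1) than the general-purpose default: a missed ear breaks the
  frame-to-frame assignment chain, while an extra detection is simply
  left unassigned by the one-to-one matching.
* **Similarity model.** Contrastive margin 1, embedding dimension 16,
  32 px crops. Positive pairs are the same ear identity in adjacent kept
  frames; negatives are pairs separated by more than a configurable gap
  (default 60 s, shrunk proportionally on clips shorter than the gap).
  The assignment floor `min_score` defaults to 0.2.
* **Track scoring.** Predictions match ground truth per frame by nearest
  centroid (globally optimal, gate 20 px at the 64 px scale via config).
  Each predicted identity's mapping to a true identity is fixed by
  majority vote over its first 30 matched frames and then frozen, so a
  persistent identity swap keeps counting as switches — the behaviour
  that makes ICR sensitive to long-held wrong identities, which MOTA is
  not. MOTA's FN/FP/IDSW are tallied independently per standard CLEAR
  semantics; the identity-level tallies and the CLEAR tallies are not
  interchangeable.
* **Region occupancy.** The reference grid divides the main region
  (horizontal 320–960, vertical 240–720 at the 1280 × 960 reference
  resolution) into twelve 160 px cells numbered row-major; a permutation
  override exists because other numbering conventions are in use.
* **Rank-sum test.** Exact distribution when the combined sample size is
  at most 20 without ties; otherwise the normal approximation with tie
  correction. Fully tied data returns p = 1 with a log note.
* **Seeding.** One global seed fans out to per-stage seeds by fixed
  offsets (simulation, training video, detector, Siamese), so stages are
  individually reproducible without coupling.

## Problem sizes in the test-suite studies

The suite's study conditions are: frame-classification exactness on
256 px arenas with 2–4 subjects over 150 frames; overlap tracking on a
non-crossing 1,000-frame two-subject video; detector properties on 64 px
arenas with about 150 single-subject training frames; the paired
improved-versus-baseline comparison on five seeded 64 px runs with a
shared smaller budget per run; and the end-to-end occlusion study on a
seeded two-subject 64 px video with at least three crossings. These sizes
were chosen as the smallest at which each property is stable.

## Known limitations

* The networks are orders of magnitude smaller than production detectors;
  their absolute accuracy on real videos is out of scope by design.
* The ear-to-individual grouping assumes the flanking non-occlusion frame
  separates individuals cleanly; a video that opens and closes
  mid-occlusion yields gaps rather than guesses.
* Identity gaps inside unresolvable occlusion stretches are left
  explicit; no interpolation or smoothing is applied anywhere.
* Video containers are not read directly; frames must be extracted to
  numbered images first.
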