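# MRTrack

Occlusion-robust tracking of multiple mice in open-field video, in R.

Whole-body trackers lose animal identities whenever mice touch or cross:
the merged silhouette cannot be attributed to individuals. MRTrack keeps
identities through such occlusions by tracking **ears** instead of
bodies. Frames are classified by blob counting into occlusion and
non-occlusion fragments; identities propagate across non-occlusion frames
by maximal blob overlap (a bijective matching on shared-pixel counts);
inside occlusion fragments a small anchor-based convolutional detector
locates the ears — its feature pyramid carries an extra low-level
(stride-4) lateral connection for objects only a few pixels wide — and a
dual-Siamese similarity model (a weight-shared image branch and a
weight-shared coordinate branch, each under a contrastive loss, fused by
a small decision network) assigns ear identities frame to frame via
globally optimal matching. Fragment tracks are linked on the flanking
non-occlusion frames into per-individual trajectories.

The package also provides the evaluation metrics of this problem domain —
IoU, average precision and mAP over IoU 0.5–0.9, MOTA
(`1 − (FN+FP+IDSW)/GT`) and the identity correct rate ICR
(`1 − (Miss+Switch+Drift)/GT`) — behavioral analytics (velocity with
5-minute block means, the 2-D population spatial standard deviation
`σ = sqrt(Σ[(xᵢ−x̄)² + (yᵢ−ȳ)²]/n)`, 12-region occupancy, Wilcoxon
rank-sum), the "N-1" chi-squared proportion test, and a deterministic
synthetic open-field generator with full ground truth used throughout the
test suite.

## Worked example

A quick run on a simulated non-crossing control video (no model training
needed — every frame resolves by blob overlap), scored against the
generator's ground truth:

```r
library(MRTrack)

cfg <- loadConfig(NULL)          # documented defaults
cfg$seed <- 7L
cfg$arena_frames <- 150L
spec <- ArenaSpec(width = cfg$img_size, height = cfg$img_size,
                  nSubjects = 2, bodyAxes = c(cfg$body_major, cfg$body_minor),
                  earRadius = cfg$ear_radius, speedScale = cfg$speed_scale,
                  nFrames = cfg$arena_frames, frameRate = cfg$frame_rate,
                  noiseSd = cfg$noise_sd, minSeparation = 26, seed = cfg$seed)
video <- simulateArena(spec)
run <- runPipeline(cfg, video = video,
                   models = list(detector = NULL, siamese = NULL))
run$metrics$icr
#> [1] 1
head(run$tracks, 4)
#>   frame id        x        y source
#> 1     0  1 21.00000 26.58523   blob
#> 2     0  2 42.68098 52.22699   blob
#> 3     1  1 22.28659 26.12805   blob
#> 4     1  2 41.60606 51.77576   blob
round(run$behavior[[1]]$meanSpeed, 3)   # cm/s
#> [1] 2.841
round(run$behavior[[1]]$sigma2d, 3)     # cm
#> [1] 1.328
```

`run$metrics$icr` is the fraction of (frame, identity) pairs tracked
under the correct identity (1.0 = perfect); `run$tracks` holds the
per-frame positions with a `source` tag saying whether a position came
from blob overlap (`blob`) or from ear tracking through an occlusion
(`ear`). `run$behavior` carries per-individual mean speed, 5-minute
velocity blocks, the 2-D spatial SD and the region-occupancy histogram.
Calling `runPipeline(cfg)` without a video simulates one with crossings
and trains the detector and similarity model on an auto-labelled
single-subject clip first (several minutes of CPU); the acceptance suite
does exactly that and requires ICR of at least 0.95 through repeated
crossings.

The metric layer works standalone; for example the identity correct rate
from published error tallies of a 16,000-frame two-mouse benchmark video:

```r
icr(errorCounts(miss = 0, switch = 0, drift = 135, gt = 16000 * 2))
#> [1] 0.9957812     # printed as 99.58%
```

A command-line front end mirroring the pipeline stages
(`simulate`, `preprocess`, `train-detector`, `train-siamese`, `track`,
`eval`, `behavior`, `run`) is installed at `inst/cli/mrtrack.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/mrtrack.R", package="MRTrack"))')" \
    simulate --seed 1 --out sim_out/
```

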