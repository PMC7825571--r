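# mothtrap

Detection, tracking, classification and counting of moths in light-trap
image sequences.

Automated light traps photograph live nocturnal insects resting on a
uniformly lit white sheet. `mothtrap` turns a night's frame sequence into
per-species counts:

1. **Segment** — each frame is subtracted from a fixed background image of
   the empty sheet, binarized with Otsu's threshold, cleaned with a
   morphological open/close, and connected components become detections
   (bounding box, centroid, area).
2. **Track** — detections in consecutive frames are linked by minimum-cost
   assignment (Hungarian algorithm) under the cost
   `cost = (dist / √(Ih² + Iw²))·Wdist + (1 − min(A₁,A₂)/max(A₁,A₂))·Warea`,
   with dummy rows/columns absorbing entries and exits.
3. **Classify** — each detection crop (resized to 128×128×3) is classified
   by a compact CNN: four conv+pool layers, one hidden dense layer with
   dropout 0.3, 10-way softmax. The chosen architecture
   {kernel 5/3, depth 32/64, dense 512} has exactly 2,197,578 learnable
   parameters; `count_parameters()` accounts for any architecture in the
   grid.
4. **Count** — a track is labeled by majority vote over its per-frame
   predictions (background or low-confidence tracks become *unknown*) and
   counted only if it persists ≥ 3 consecutive frames, which filters
   insects flying close to the lens.

Tracking quality is scored by the tracking detection rate
`TDR = TP/GT` and false alarm rate `FAR = FP/(TP+FP)`; classification by
per-class precision, recall and F1. A synthetic scene and crop generator
with exact ground truth makes the whole pipeline testable end to end
without any field imagery.

## Worked example

Generate a synthetic survey, run the pipeline, and score it against the
generator's ground truth:

```r
library(mothtrap)

dir <- tempfile()
scene <- generate_scene(
  scene_config(n_insects = 5, n_frames = 50, seed = 205),
  dir = file.path(dir, "frames")
)
bg <- file.path(dir, "background.png")
EBImage::writeImage(
  EBImage::Image(scene_background(scene), colormode = "Color"), bg
)

detections <- segment_frames(file.path(dir, "frames"), bg)
tracked    <- track_detections(detections)
glance(evaluate_tracking(tracked, scene_truth(scene)))
#> # A tibble: 1 × 5
#>      GT    TP    FP   TDR   FAR
#>   <int> <int> <int> <dbl> <dbl>
#> 1     5     5     0     1     0
```

All five planted insects keep exactly one track each (TDR 1, FAR 0).
Evaluation from manually established counts works directly on the rates:

```r
round_half_up(tdr(65, 82))   # 0.79  — 65 of 82 individuals kept their track
round_half_up(far(65, 18))   # 0.22  — 18 of 83 tracks were false alarms
class_metrics(24, 6, 8)      # precision 0.80, recall 0.75, F1 0.77
```

Training the classifier on the separable synthetic crop dataset:

```r
crops <- generate_crop_dataset(n_classes = 10, n_per_class = 100, seed = 42)
fit <- train_cnn(
  build_model(arch_spec(5, 3, 32, 64, 512), seed = 42),
  augment(crops, factor = 8, seed = 42),
  train_config(epochs = 2, seed = 42)
)
glance(fit)   # macro-F1 on the 20% validation split
tidy(fit)     # per-class precision/recall/F1
```

A command-line interface wraps the same functions
(`inst/scripts/mcc.R simulate | segment | track | train | evaluate | run |
config`); `mcc_cli(c("evaluate", "--counts", "65", "18", "82"))` prints
`TDR 0.79, FAR 0.22`.

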