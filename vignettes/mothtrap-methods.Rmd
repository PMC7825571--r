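---
title: "Counting moths in light-trap image sequences: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting moths in light-trap image sequences: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mothtrap)
```

## The problem

Camera-based light traps photograph live nocturnal insects resting on a
uniformly lit white sheet. A night's survey is a time-ordered sequence of
high-resolution frames (nominally 3840×2160, captured at 0.5–2 s intervals
whenever the capture software detects motion). Turning such a sequence into
ecological data requires four steps, each of which this package implements
and tests:

1. **Segmentation** — find the insects in each frame;
2. **Tracking** — link the same individual across frames so it is counted
   once per visit;
3. **Classification** — assign each tracked individual to a species with a
   compact convolutional network;
4. **Counting** — reduce tracks to per-species counts with noise filtering.

A synthetic scene generator with exact ground truth makes the whole chain
verifiable without any field imagery.

## Segmentation

Each frame is converted to grayscale (Rec. 601 luma weights) and subtracted
from a fixed background image of the empty sheet; the absolute difference is
used so that insects both darker and lighter than the sheet are found. The
foreground image is binarized with Otsu's threshold — the 8-bit level
maximizing the between-class variance of the gray histogram — followed by a
morphological open (square element, default 5 px) that removes small noise
blobs and a close (default 7 px) that fills holes. Connected components with
at least `min_blob_area` pixels (default 2500) become detections; the
reported position is the bounding-box center, because the tracker reasons
about boxes.

Numerical conventions, chosen once and tested: coordinates are 0-based with
the origin at the top-left pixel and half-open boxes `[x_min, x_min+width)`;
Otsu ties break toward the lowest threshold; a constant foreground image
yields no detections rather than an error (an empty sheet is a legitimate
frame). The Otsu implementation is checked against an exhaustive
threshold-sweep oracle on random 8-bit histograms. An optional motion gate
reproduces the capture software's trigger — a frame counts as active when
strictly more than 1500 pixels change — with the per-pixel delta (which the
capture software does not document) exposed as configuration.

Known failure mode, shared with the deployed systems this emulates: two
insects that touch merge into a single component and are detected as one.

## Tracking

Between two consecutive accepted frames the tracker solves an assignment
problem. The cost of matching detection *i* (previous frame) to *j*
(current) is

$$\mathrm{cost}_{ij} \;=\; \frac{\mathrm{dist}_{ij}}{\sqrt{I_h^2+I_w^2}}\,W_{dist}
\;+\; \bigl(1-\tfrac{\min(A_i,A_j)}{\max(A_i,A_j)}\bigr)\,W_{area},$$

the Euclidean centroid distance normalized by the image diagonal plus a
bounding-box area dissimilarity. The matrix is padded to square with dummy
rows/columns whose cost strictly exceeds any real pairing; the Hungarian
algorithm (an $O(n^3)$ potentials / shortest-augmenting-path implementation,
verified against a brute-force permutation oracle up to 7×7) finds the
minimum-cost perfect matching. Current detections matched to a dummy have
entered the scene and open new tracks; previous detections matched to a
dummy have left and their tracks close immediately.

Defaults: $W_{dist}=0.8$, $W_{area}=0.2$ — insects on the sheet are mostly
stationary between captures, so position should dominate while the area term
breaks ties between equally near candidates; both weights are configurable.
The dummy cost is $2(W_{dist}+W_{area})$, scale-free and strictly above the
$W_{dist}+W_{area}$ bound of any real cost. There is no coasting, motion
model, or track revival: an individual that disappears and returns is a new
individual, which matches how such traps are scored in practice. Where
several assignments tie in cost, any optimum is accepted; tests assert the
total cost, not the particular matching.

## Classification

The classifier is a compact CNN family designed for small training sets:
four convolutional layers (ReLU, zero-padded to preserve size, each followed
by 2×2 stride-2 max pooling), a hidden dense layer with dropout 0.3, and a
10-way softmax (nine insect classes plus a background class for false blob
detections). The two middle layers are fixed at 64 kernels of 3×3; the
first/last kernel size (1/3/5), first/last depth (32/64/128) and dense width
(256/512) form the architecture grid. With a 128×128×3 input the four
poolings leave an 8×8 map, so the flatten stage has $8\cdot8\cdot d_{last}$
units — 4096 for the chosen architecture {5, 3, 32, 64, 512}, whose exact
learnable-parameter count is 2,197,578.

Two readings of the printed layer table were possible; only the one above
(pooling after *every* convolution, flatten = $8\cdot 8\cdot d_{last}$, a
single hidden dense layer, 10 outputs) reproduces every printed parameter
count exactly, so the package fixes it and verifies `count_parameters()`
against the actually allocated weight tensors across the whole grid. One
printed count ({5, 3, 32, 32, 512}) is inconsistent with every layout we
examined and is treated as a typo; it is not asserted anywhere.

Training minimizes softmax cross-entropy with Adam (default; SGD with
momentum 0.9 is available), learning rate $10^{-3}$, batch 32 — the source
material states the optimizer choice but no learning rate, batch size or
epoch count, so framework-conventional values are used and exposed in
`train_config()`. Inputs are scaled to $[0,1]$. The implementation is a
native single-precision im2col/BLAS engine (conv, max-pool, dense, inverted
dropout, Adam/SGD) behind `build_model()`/`train_cnn()`/`predict()`; it is
deterministic given a seed, and the gradient path is exercised by the
separable-data training tests.

Detections are prepared for the classifier by expanding the bounding box by
`pad_fraction` (default 0.1) per side, growing the shorter side to a square,
clipping to the frame and resizing to 128×128. Augmentation produces exactly
`factor` crops per source crop — the first an identity copy, the rest random
horizontal/vertical flips, rotation by an arbitrary angle, zoom (0.8–1.25)
and illumination gain (0.7–1.3), drawn from a seeded RNG. Rotation and zoom
are applied in a single bilinear resampling pass so that large augmented
sets (the 9×250 dataset scaled ×32 to 72,000) materialize quickly; crops are
stored as uint8 rasters to keep such sets small in memory. Counting checks
of the augmentation run on reduced-resolution crops, since the accounting is
independent of raster size; the classifier itself always trains at 128×128.

## Counting

Per-frame class predictions are aggregated per track by majority vote, with
ties broken toward the label seen earliest; a track whose winner is the
background class, or whose mean confidence falls below `unknown_threshold`
(default 0.5 — the source material describes an unknown category but no
rule), is counted as *unknown*. A track contributes to the survey totals
only if it persists for at least `min_consecutive` consecutive frames
(default 3), which suppresses insects flying close to the lens. The source
material states this rule once as "more than three" and once as "at least
three"; the package resolves the discrepancy as ≥3 and makes the value
configurable. The summary conserves counts: total individuals equals
counted tracks.

## Evaluation

Tracking quality uses the tracking detection rate and false alarm rate,

$$\mathrm{TDR} = \mathrm{TP}/\mathrm{GT}, \qquad
  \mathrm{FAR} = \mathrm{FP}/(\mathrm{TP}+\mathrm{FP}),$$

where a true positive is a ground-truth individual that kept one unique
track over its whole presence and a false positive is an individual that was
split, duplicated or reassigned — plus predicted tracks matching no
individual at all. Ground truth is matched frame-by-frame: a track owns an
individual when the individual's true centroid falls inside the track's box
(nearest centroid on ties), and a true positive requires a one-to-one
majority-ownership match. The original systems were scored by manual video
review; this automated rule is the package's own operationalization and is
exercised on constructed split/swap/phantom cases.

Classification quality uses per-class precision, recall and
$F_1 = 2\,\mathrm{TP}/(2\,\mathrm{TP}+\mathrm{FP}+\mathrm{FN})$, with a
micro-averaged total row; metrics with zero denominators are reported as
absent, not zero. Reported tables round half away from zero to two decimals.
Note that a micro-averaged total precision computed from summed counts can
differ in the last digit from an independently printed value; the package
always reports the computed value.

## The synthetic scene generator

The generator emulates the trap's imaging situation rather than its optics:
a near-white sheet (intensity 0.92) with a static Gaussian texture field
(σ = 0.01) standing in for sheet texture and fixed-pattern sensor noise;
dark elliptical insects with species-specific procedural stripe textures and
tints, everywhere darker than the sheet as real moths are under the trap's
illumination; bounding-box sizes drawn from the annotated-box distribution
(mean 368×353 px, SD 110, truncated below); mostly stationary motion
(stationary probability 0.9, 2 px jitter) with occasional ~150 px
repositioning moves that land on free sheet; optional near-lens transients —
large, soft-edged, dark, lasting two frames — and optional touching pairs.
Scenes are pure functions of their configuration and seed, down to the bytes
of written frames, and emit ground truth in the evaluation schema.

What it deliberately does not model: per-frame varying sensor noise,
shadows, specular reflections, wing motion blur, partial visibility at the
frame edge, and photo-realistic moth appearance. Passing the synthetic
end-to-end tests therefore shows that the algorithms are implemented
correctly and interact correctly — not that field accuracy on real imagery
is reproduced, which requires the original photographs. The synthetic crop
classes are separable by construction (even their mean colors separate
linearly, which a test confirms with a nearest-centroid baseline), so the
classifier smoke test validates the training machinery, not fine-grained
species discrimination.

Default problem sizes were fixed once with an eye to routine test runs:
frames default to 1920×1080 (the native 3840×2160 is supported), image-level
tests use 480×360 scenes with proportionally smaller insects, the end-to-end
tracking check uses 5 insects over 50 full-default frames, and the
classifier smoke test trains the chosen architecture for two epochs on the
ten-class 100-per-class set augmented ×8 (6400 training crops).

## Limitations

- Touching insects merge at segmentation; the tracker cannot split them.
- No occlusion memory: any missed detection terminates a track.
- The majority-vote label assumes per-frame classifications are mostly
  independent; systematic per-pose misclassification defeats it.
- The native CNN engine is single-threaded and CPU-bound; it is sized for
  the compact architecture family, not for general deep learning.
- The real-data validation scores of the original deployment cannot be
  reproduced here because the photographs are not distributed; the package's
  claims are therefore exact arithmetic reproductions plus synthetic
  end-to-end behavior.
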