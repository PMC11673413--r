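---
title: "Methods: a two-stage breast-lesion detector with a precise diagnosis stage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a two-stage breast-lesion detector with a precise diagnosis stage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bcrcnn)
```

## The problem and the model

Benign breast lesions on DCE-MRI are mostly round or lobulated with clear
boundaries; malignant ones show irregular, star-shaped margins. A two-stage
detector that classifies candidates from their *pre-regression* boxes feeds
the classifier a region that is systematically misaligned with the lesion,
diluting exactly the boundary evidence that separates the two classes.

`bcrcnn` implements a two-stage detector whose second stage — the precise
deep network (PDN) — re-extracts features from the *refined* box of each
candidate before classifying it:

1. **Stage one.** Backbone (VGG16-style 13-convolution stack, or the
   4-block `tiny` preset), optional feature pyramid P2–P6, RPN with ratios
   1:2 / 1:1 / 2:1, quantization-free ROI alignment to 7 × 7, and two
   parallel fully connected heads: `[n, 4K]` class-conditional deltas and
   `[n, K]` softmax scores, with K = 3 (background, benign, malignant) and
   n = 300 candidates.
2. **PDN.** Per candidate: argmax class; decode that class's four deltas
   against the proposal; clip to the image; re-pool the refined box at
   7 × 7 from P2, P3 or P4 by its size (`sqrt(w·h)` < 64, 64–128, > 128
   pixels); three extra 3 × 3 convolutions (ReLU, channel-preserving,
   no weight sharing with stage one); one fully connected softmax layer.
   A candidate is retained when its argmax class is a lesion class and the
   score strictly exceeds `malignant_threshold` (0.5).
3. **Dual-plane fusion.** A lesion is malignant when either plane says so;
   a lesion detected in neither plane is reported `undetected`, not benign.
4. **3D localization.** Up/down from the sagittal center against `Y_mid`,
   outside/inside from the axial center against `x_Rmid`/`x_Lmid`,
   laterality from `x_mid`.

The composite training loss is
`total = rpn_cls + rpn_loc + roi_cls + roi_loc + pdn_cls`, with binary
cross-entropy for RPN objectness, 3-way cross-entropy for the two
classification heads, and smooth L1 on encoded deltas for the two
localization terms. The PDN term is computed on the refined candidates,
whose labels are re-assigned against ground truth at IoU 0.5 (a refined box
that moved onto, or off, a lesion is relabeled accordingly). One published
description calls the second localization term a cross-entropy; a
cross-entropy on continuous offsets is ill-defined, so both localization
terms are smooth L1.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `iou_threshold` | 0.5 | target assignment and evaluation matching |
| `batch_size` | 1 | one slice per SGD step |
| `learning_rate` | 1e-5 | suited to fine-tuning a pretrained backbone |
| `epochs`, `momentum`, `weight_decay` | 30, 0.9, 5e-4 | SGD schedule |
| `num_candidates` | 300 | proposals kept after NMS |
| `pooled_size` | 7 | ROI-align output grid |
| `canonical_roi_size` | 160 | pyramid-level assignment pivot (reduced from the conventional 224) |
| `malignant_threshold` | 0.5 | strict retention threshold (`score > 0.5`) |
| `short_side` | 512 | rescale target |
| `use_fpn` | TRUE | pyramid on; single stride-16 map otherwise |

Knobs the recipe leaves unstated are set to the values customary for
two-stage detectors and logged with every run: RPN NMS threshold 0.7,
positive/negative anchor IoU 0.5/0.3, 128 sampled anchors and 128 sampled
ROIs per image with a 1:1 positive cap, class-wise test NMS 0.3, pyramid
base scales {32, 64, 128, 256, 512} with the "two neighbor scales" realized
as $\{s/\sqrt2,\ s\sqrt2\}$, and level assignment
$k = \lfloor 4 + \log_2(\sqrt{wh}/160)\rfloor$ clamped to [2, 5].

Two conventions make the arithmetic exact. Boxes are continuous, 0-based
and half-open, so width is `x_max − x_min` and IoU needs no "+1" fudge; VOC
XML (1-based inclusive integers) converts by subtracting 1 from min corners
on read. Class indices are fixed as 0 = background, 1 = benign,
2 = malignant, and every argmax breaks ties toward the lower index.

## The phantom generator

Real training data for this problem are private clinical MRI. The package's
study conditions are therefore defined by a deterministic dual-plane
phantom, whose defaults are the reference conditions used throughout the
tests: 128 × 128 slices; a constant additive background offset of 40
intensity units with Gaussian noise of SD 8 (nominal 0–255 scale); breast
tissue at 110 rendered as half-ellipses joined by a thin chest-wall band
(one connected foreground, as in real torso anatomy); lesions at 230 with
base radii 6–11 px; benign lesions as rotated ellipses (axis ratio
0.85–1.15); malignant lesions as radial stars
$r(\theta) = r_0(1 + 0.5\sin(7\theta + \phi))$. One lesion per case by
default; the same lesion is rendered in both planes (radius resampled
±20 %) at a 3D position whose anterior–posterior depth ties its axial row
to its sagittal column, so both planes agree on one ground-truth quadrant.
Lesion centers keep a 6 px margin from every quadrant boundary, which makes
the quadrant of the rendered bounding-box center unambiguous. Per-case RNG
streams are seeded `xor(seed, case_index)` so generation is stable under
any iteration order.

The phantom emulates: the additive offset the preprocessing must remove,
the bright breast-on-dark-background layout, the smooth-versus-spiculated
shape contrast (verified by the isoperimetric roughness statistic
$P^2/4\pi A$, ~1.0 for benign masks versus > 2 for malignant), dual-plane
consistency, and VOC2007 packaging. It deliberately does not emulate MR
physics, background parenchymal enhancement, fibroglandular texture,
multi-focal disease across breasts, partial-volume blur, or annotation
noise. Passing the end-to-end tests therefore demonstrates that the
pipeline is implemented correctly and can be trained, not that it reaches
clinical performance; the published clinical numbers require the private
datasets and GPU-scale training and are out of scope here.

## Numerical choices

- **Background subtraction** clamps at zero: intensities are magnitudes.
  The 4 × 4 block is taken literally from the top-left corner, with no
  fallback if anatomy intrudes.
- **Preprocessing order** is subtraction → masking → rescaling (the order
  is not stated in the source description; fixing it keeps the background
  estimate on the native grid), with bilinear resampling for images,
  round-half-away-from-zero for output dimensions.
- **ROI align** maps image point $x$ to lattice coordinate
  $x/\text{stride} − 0.5$ (pixel centers at $(j+0.5)\cdot\text{stride}$),
  uses 2 × 2 regularly spaced bilinear samples per bin, and never rounds a
  coordinate.
- **Delta decoding** clamps $|\log$ scale offsets$|$ at 20 so untrained
  regression outputs cannot overflow `exp()`; any encoding a real box pair
  produces is orders of magnitude below the clamp, so the
  encode/decode round trip is unaffected.
- **Initialization**: He-normal convolutions in the backbone/FPN/PDN
  stack; the RPN heads and the fully connected heads use small Gaussian
  weights (SD 0.01; 0.001 for box regression), the standard recipe that
  keeps early deltas near zero.
- **Loss normalization**: localization terms are summed over positive
  samples and divided by the *total* sampled count, and gradients are
  clipped to a global L2 norm of 10. Both choices bound the per-step
  update when an image yields very few positives.
- **Training-time candidates**: ground-truth boxes are appended to the
  proposal set (so the second stage sees positives from epoch one), and
  the PDN branch trains on a 64-candidate subsample per step to bound the
  cost of the extra convolutions; inference always uses all 300.
- **Proposal generation** takes the top 1000 anchors by objectness across
  all levels before NMS, stops NMS after 300 boxes are kept (the kept
  prefix is identical to full NMS), and pads by repeating the lowest-scored
  survivor to preserve the fixed `[300, ·]` head shapes. Degenerate refined
  boxes are given a minimum 2 px side before re-pooling.
- **Roughness statistic**: the mask is blurred (Gaussian, σ = 0.9 px)
  before the half-level marching-squares contour is measured, suppressing
  staircase inflation (a rasterized disk otherwise reads ~11 % long).
- **Quadrant boundaries**: `y = Y_mid` goes down, `x` on a breast midline
  goes inside, so the four indicators partition the plane; laterality ties
  go right.

## Design decisions on genuinely open points

- The anchor-count description for the single-level baseline is internally
  inconsistent in the source description (15 anchors/level versus one scale
  × three ratios). We implement the unambiguous endpoints: 9 shapes per
  location single-level (3 scales × 3 ratios, the classic configuration)
  and 6 per pyramid location (2 neighbor scales × 3 ratios).
- The printed laterality rule ("left when `x_ax < x_mid`") conflicts with
  the radiological display convention in which patient right appears on
  image left. We implement the printed rule and expose `flip = TRUE`; the
  phantom's ground truth follows the printed rule so that the pipeline is
  self-consistent.
- Whether rescaling happened before or after noise subtraction is unstated;
  we fix subtraction first and expose the target size in configuration.
- Benign detections are retained under the same strict `score > 0.5` rule
  as malignant ones; the source only states the malignant rule, and
  symmetry is needed for per-class precision/recall.
- The baseline breast mask (Otsu → largest connected component →
  morphological closing) is a deterministic stand-in for a learned
  segmenter; any mask provider can be plugged in.
- VOC annotations are stored per slice with a `lesion_id` attribute
  grouping the slices of one lesion across planes.
- Checkpoints are flat named-array containers with the configuration
  echoed alongside, written with `saveRDS()`.

## Problem sizes

The reference end-to-end run — also what `scripts/acceptance.R` executes —
generates 143 phantom cases (286 slices; 200 training, 42 validation, 44
test), trains the `tiny` backbone with the pyramid on for 15 epochs at
learning rate 0.01 (a from-scratch rate; the 1e-5 default presumes a
pretrained backbone), batch size 1, and evaluates the held-out split. This
sits comfortably in a single-CPU R session (~10 minutes) while leaving every
architectural constant — 300 candidates, `[300, 12]`/`[300, 3]` heads,
7 × 7 pooling, canonical size 160, PDN bins at 64/128, three extra
convolutions — at its published value. Oracle-equivalence suites
(rasterized IoU, rescan NMS, direct bilinear ROI align, threshold-enumerated
AP, pairwise AUC) each run on ≥ 1000 randomized instances.

## Known limitations

- The `vgg16` preset is architecturally faithful (13 convolutions, 512
  channels, ~14.7 M backbone parameters) but is exercised only at the shape
  level in tests; training it from scratch on a CPU is impractical, and
  loading external pretrained weights is a user-side hook, not a package
  requirement.
- Batch size is fixed at 1 (as in the training recipe); there is no
  batching or GPU path.
- The phantom's simplicity means detection metrics saturate; the
  benign/malignant false-positive rate is the only quantity that remains
  visibly imperfect at desk scale.
- Lesion-level matching (one slice-level IoU ≥ 0.5 hit suffices; stray
  malignant detections count one false positive per overlapping cluster per
  image) is a documented choice; the clinical description leaves the rule
  unstated.
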