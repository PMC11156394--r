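---
title: "pestdet: model, training procedure and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pestdet: model, training procedure and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`pestdet` implements a two-stage object detector aimed at farmland pest
monitoring, where targets span a wide range of scales, species counts are
heavily imbalanced, and labelled data is scarce. The pipeline is:

1. a hierarchical shifted-window multi-head self-attention backbone
   producing three feature maps at strides 8/16/32;
2. a feature-enhancement neck that computes, per pyramid level, a sliding
   window neighborhood autocorrelation tensor and fuses it back into the
   features (the "SCF" block), followed by top-down pyramid construction
   (P3–P6);
3. a region proposal network, three cascade refinement stages with rising
   IoU thresholds (0.5/0.6/0.7), classifier ensembling across stages, and
   linear soft non-maximum suppression.

Everything runs on a small reverse-mode autodiff engine over base-R arrays
(`R/autograd.R`); there is no external deep-learning runtime. That engine is
deliberately minimal: matrix multiplication, gathers/scatters, layer norm,
fused softmax losses and a fused batched window-attention op cover the whole
architecture.

# Backbone

The input image is split into non-overlapping 4x4 patches, each flattened
(row-major within the patch, channels fastest) into a 48-vector, then
linearly embedded to `embed_dim` channels (default 128). Four stages follow;
stages 2–4 begin with patch merging (2x2 concatenation + linear projection
halving resolution and doubling channels). Each block applies

    zhat = Attn(LN(z)) + z
    z'   = MLP(LN(zhat)) + zhat

where `Attn` is multi-head self-attention inside MxM token windows, with a
learned relative-position bias. Odd blocks use plain windows; even blocks
shift the grid cyclically by `M/2` and mask attention between tokens whose
content is non-adjacent in the unshifted image (the zone map lives in
post-shift coordinates; only windows overlapping the wrap margin carry a
mask; a 2Mx2M grid partitions into nine distinct zones). The detector
consumes the outputs of stages 2, 3 and 4: at a 1280x1280 input and
`embed_dim = 128` these are (160,160,256), (80,80,512) and (40,40,1024).

Design notes:

* The embedding width is pinned by the stage-shape contract: the neck
  consumes 256/512/1024-channel maps, which forces `embed_dim = 128`
  (canonical Swin variants use 96 or 96-derived widths and would emit
  192/384/768). The separate "256" appearing in this design is therefore
  the neck width, not the embedding dimension.
* The attention window defaults to M = 8 rather than the conventional 7:
  the stage grids at 1280 px input (320/160/80/40) are divisible by 8 but
  not by 7, and exact divisibility avoids padding ambiguity.
* Depths default to (2,2,6,2) with heads (4,8,16,32). A `tiny` profile
  (embed 32, depths 2/2/2/2, heads 2/4/8/16, window 4, 256 px input) exists
  for CPU-scale work; all tests use it.
* Weights are truncated-normal (sd 0.02) for transformer layers; no
  pretraining. Conv and head-MLP layers use He (`sqrt(2/fan_in)`) scaling —
  with fixed sd 0.02 the activations through the neck/head stack shrink by
  an order of magnitude per layer and short training runs stall.

# Neighborhood-autocorrelation neck

Each backbone map is first reduced to `neck_channels` (default 256) by a 1x1
projection, giving X. For a per-level window (U,V) — defaults (7,7), (5,5),
(3,3) for the stride-8/16/32 maps — the regional tensor

    R[i,j,u,v,] = X[i + u - ctr_u, j + v - ctr_v, ]

is gathered with zero padding, and the autocorrelation tensor D is the
elementwise product of R with X broadcast over the window axes, flattened to
U*V*C channels (u outermost, then v, channels fastest — any consistent order
works; this one is fixed so checkpoints are portable). The embedding block
concatenates G = [X; D], applies two 1x1 projections (C+UVC -> C -> C,
no intermediate nonlinearity or normalization — the block is specified as
two plain convolutions), and adds the result back: A = X + I'. The second
projection is zero-initialized, so at initialization A == X exactly and the
attention branch cannot perturb early training. A 3x3 convolution follows
per level; the pyramid is then built top-down (P5 = enhanced feat3,
P4 = enhanced feat2 + up2(P5), P3 likewise; one 3x3 smoothing conv per
level; P6 = stride-2 max pool of P5).

Open choices resolved here:

* Border handling of the neighborhood window is unspecified in the source
  description; zero padding with same-size output keeps A aligned with X
  for the residual.
* The channel "downsampling" ahead of the SCF block is implemented as a 1x1
  stride-1 reduction, not spatial downsampling: the architecture figure
  shows feat3 -> P5 at unchanged resolution.
* X' ("dimensionality augmentation") is interpreted as broadcast over the
  window axes; no equation supports a learned lift.
* The SCF branch runs per level before top-down fusion, and one 3x3 conv
  follows each merged P level.
* The per-level windows are overridable (e.g. uniform (3,3)/(5,5)/(7,7)
  across levels) to reproduce window-size ablations.

# Detection head

Anchors: 3 aspect ratios (0.5, 1, 2) x 3 sub-octave scales per location,
with base size 4x the level stride. The RPN is a shared 3x3 conv + ReLU with
1x1 objectness and box-delta heads; proposals are decoded, clipped,
filtered per level by top-k and hard NMS (0.7), then merged. Box deltas use
the standard (dx, dy, log dw, log dh) parameterization with per-stage
scalings (10,10,5,5)/(20,20,10,10)/(30,30,15,15) so regression outputs stay
near unit scale as the boxes tighten.

Each cascade stage pools a 7x7 bilinear grid from the pyramid level matched
to the box scale, runs a 2-layer MLP head, and refines the previous stage's
boxes (B0 = proposals, stage s trained at IoU threshold 0.5/0.6/0.7). At
inference the final boxes are B3, and classification ensembles all three
stage classifiers re-evaluated on the B3 boxes, averaging their softmax
outputs; a flag selects the alternative of averaging each stage's scores on
its own boxes. Detection lists are then pruned per class by linear soft-NMS:

    s_i <- s_i                    if iou(M, b_i) < Nt
    s_i <- s_i * (1 - iou(M, b_i)) otherwise

iterated against each successive highest-scoring box M, with `Nt = 0.5` and
a 0.05 score floor (the mechanism is prescribed; these two values are
conventional defaults exposed in the configuration).

# Training

The reference optimization schedule is momentum SGD (momentum 0.9, base lr
0.01, weight decay 0.05), 100 epochs, effective batch 64 (realized by
gradient accumulation of single-image micro-batches), lr stepped x0.1 at
epochs 80 and 90, 1280 px inputs. `lr_at_epoch()` reproduces that schedule
exactly and training logs it per iteration.

Losses: balanced binary cross-entropy over all labelled anchors plus
smooth-L1 (beta 1/9) on positive anchors for the RPN; per stage,
cross-entropy over proposals (RPN top-k + ground-truth boxes + jittered
copies, so every stage sees positives from the start) and smooth-L1 on the
encoded deltas of positives, with stage weights (1, 0.5, 0.25). Stage inputs
are detached: gradients do not flow through box coordinates.

For short CPU runs the package additionally provides:

* **AdamW** (`optimizer = "adamw"`): with a few hundred updates spanning
  layers whose gradient scales differ by orders of magnitude, momentum SGD
  either crawls (lr <= 0.02) or diverges (lr >= 0.1), while per-parameter
  step normalization converges reliably. Per-module learning-rate
  multipliers (`rpn_lr_mult`, `head_lr_mult`) let the anchor heads — which
  sit on a stationary feature distribution when the trunk is frozen — take
  larger steps than the neck.
* **Frozen-trunk modes**: `train_backbone = FALSE` freezes the randomly
  initialized backbone and caches per-image features; `train_neck = FALSE`
  additionally freezes the neck and caches the full P3–P6 pyramid.
* **ROI replay** (`roi_replay = TRUE`, frozen pyramid only): pooled ROI
  features of every visited image are kept in a buffer, and each update
  trains the cascade heads on the whole buffer instead of one image's
  handful of proposals — with frozen features the cached activations are
  exact, so this turns head optimization into near-full-batch learning.
  All three stage heads share the buffered proposal set with their own
  assignment thresholds (box-refinement chaining still happens at
  inference); `rpn_images_per_step` similarly batches the cheap anchor
  losses over several cached pyramids per update.

The in-package overfit check (20 scenes of 256 px, 3 classes, 4 instances
of 24–80 px each, 200 updates) uses exactly this frozen-trunk replay recipe
(AdamW, base lr 3e-3, RPN multiplier 3, head multiplier 2, 15 anchors per
location with sub-octave scales centred on each level's base size, soft-NMS
`Nt = 0.3` with stage-wise score averaging — the tighter suppression suits
many small near-duplicate boxes). Under it the detector reaches
mAP\_0.5 ≈ 0.72 on its training scenes in about eight CPU-minutes, with
recall ≈ 0.89. Two limits keep it from going much higher without
pretraining: box regression on features that were never trained saturates
at a small correction, and the coarsest pooling stride available (P3,
stride 8 — there is no P2 level in this architecture) bounds localization
precision for targets a few tens of pixels wide. Tripling the update budget
does not change the plateau, so the ceiling is representational, not an
optimization budget. Problem sizes throughout the test suite were chosen so
the whole suite runs in minutes on one CPU core.

# Synthetic scenes

The generator emulates the data regime the detector targets: multi-scale
targets (configurable size range), many classes, long-tailed instance
counts (`make_imbalanced_counts()` interpolates a head count of 242 down to
a tail count of 3 across 28 classes, matching the kind of skew seen in real
pest surveys), and dense packing (placement rejection-samples positions
with an IoU cap of 0.2, relaxed to 0.7 in `density_mode`; 100 retries per
instance before the spec is declared infeasible). Instances are textured
ellipses with class-coded hue, aspect ratio and appendage count, so classes
are genuinely learnable from pixels; ground-truth boxes are the exact drawn
extent. Scenes are bitwise reproducible from (spec, seed), and datasets
round-trip through COCO JSON.

What the generator does *not* emulate: real insect morphology and pose,
lighting physics, occlusion by foliage, camera noise statistics, label
noise. A model passing the in-package checks has demonstrated that the
architecture, losses and data plumbing work end to end — not field accuracy.

# Copy-paste balancing and online augmentation

`balance_classes()` cuts annotated instances (rectangular, unblended — so a
cut/paste round trip is pixel-exact and testable), optionally scale-jitters
(±20%) and flips them, and pastes them onto background images until each
class reaches the target count exactly; classes already at or above the
target are untouched, and original images are never modified. Expanded
per-class counts in the motivating study hover near a common target with
small unexplained jitter; we expose a single deterministic `target_count`
instead of reproducing that jitter. Pasted boxes respect a pairwise IoU cap
(0.2) against both pasted and pre-existing boxes. Online augmentation
applies color jitter, mean-filled rectangular erasing (never covering more
than half of any ground-truth box), gaussian noise and horizontal flip; the
flip is the only geometric op and remaps x-coordinates exactly.

# Numerical notes

* Box convention: 0-based continuous corners (x1,y1,x2,y2) everywhere;
  COCO's (x,y,w,h) exists only in the I/O layer.
* Evaluation: greedy matching at IoU 0.5, 101-point interpolated AP per
  class, mean over classes; detection order at equal scores is made
  deterministic by sorting on box coordinates.
* Soft-NMS selection order is non-increasing in the rescored values, so
  the first-selected (global max) box is never demoted.
* `exp` arguments in box decoding are clamped to ±4 to keep degenerate
  early-training deltas finite.
* All randomness (scene synthesis, augmentation, sampling, init) flows
  through a seed parameter and restores the caller's RNG state.

# Known limitations

* Single-image micro-batching only; no parallelism, no GPU, no mixed
  precision.
* CPU cost bounds realistic experiments to the tiny profile at a few
  hundred pixels; full-scale (1280 px, embed 128) forward passes work but
  are minutes-per-image, so quantitative claims at that scale are limited
  to shape/bookkeeping checks.
* The mask head, Gaussian soft-NMS variant and backbone pretraining are
  out of scope.
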