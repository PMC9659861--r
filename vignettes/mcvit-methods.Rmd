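---
title: "Two-stage multi-scale transformers for thymoma slide typing: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage multi-scale transformers for thymoma slide typing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcvit)
```

## The problem

Whole-slide images (WSIs) of H&E-stained thymic tumours are gigapixel
pyramids scanned at several magnifications (here 10x, 20x, 40x).  Histological
typing into the WHO categories (A, AB, B1, B1+B2, B2, B2+B3, B3, and thymic
carcinoma, TC) depends on patch-level findings — which epithelial cell types
dominate, whether fibrous septa, perivascular spaces or medullary
differentiated areas are present, how dense the lymphocytic infiltrate is —
and different findings are legible at different magnifications: broad
architectural features survive at 10x while nuclear texture needs 40x.

`mcvit` implements a two-stage pipeline that mirrors this reading process:

1. **CAST** (cross attentive scale-aware transformer) classifies
   co-registered patch triplets — the same tissue field at 64x64 (10x),
   128x128 (20x), and 256x256 (40x) pixels — into ten pathological-information
   classes, using three parallel transformer branches fused at every block.
2. **WT** (WSI transformer) types the slide: a fixed number `m` of patches is
   sampled, each contributing its CAST multi-scale embedding (768 values)
   concatenated with its predicted class label rescaled to `[0,1]`
   (`class/9`), giving an `m x 769` feature matrix that a three-stage
   transformer encoder maps to one of eight types.

## The CAST architecture

Each branch starts with a patch-splitting stem (non-overlapping `P x P`
patches, linearly embedded): `P = 2/4/8` for the 10x/20x/40x inputs, so all
three branches share one 32x32 token grid at stage 1.  Three stages follow
with widths 128/256/512, heads 2/4/8, MLP expansion ratios 8/4/4, and a 2x2
patch-merge (concatenate each 2x2 token neighbourhood, project linearly)
between stages.  The branches differ only in their attention family:

* **GGB** (global branch, 10x): classical pre-norm blocks,
  `x + MSA(LN(x))` then `x + MLP(LN(x))`, with GELU activations.
* **LGB** (local branch, 40x): two successive windowed blocks,
  W-MSA → MLP → SW-MSA → MLP, with learned relative position bias inside
  each window, cyclic shift by half a window in the second attention, and
  additive `-1e9` masking of wrapped token pairs.
* **FAB** (aggregation branch, 20x): the CAS block
  `C' = SRA(LN(CAM(A, B, C))) + C`, `C = MLP(LN(C')) + C'`, where CAM fuses
  the three branches (previous block's outputs) and SRA computes keys and
  values from a spatially reduced copy of the grid.

Attention scores are scaled by `1/sqrt(head_dim)` (the convention of the
windowed-attention family this design builds on); the literal `1/head_dim`
variant is available via `attn_scale = "inv_d"` for comparison.

**CAM.** The cross-correlation attention module stacks the three same-shape
scale features, passes each slice through a shared 1x1 convolution, and
takes, at every spatial position, the channel inner product between each
convolved slice and the raw aggregation feature.  A sigmoid turns the three
inner-product maps into per-scale spatial attention in `(0,1)`; each raw
slice is re-weighted by its map, the three are concatenated (3c channels)
and fused back to c channels by a 3x3 convolution.  "Batch-wise
multiplication" is implemented as this per-position `(3 x c) . (c x 1)`
product — the only reading that produces a `3 x h x w` attention tensor.
There is no pre-scaling of the inner product, so the sigmoid can saturate at
large channel widths; tests therefore standardise CAM inputs to unit
variance.  A per-scale-weights 1x1 convolution is available behind
`share_conv1 = FALSE`.  `cam_oracle()` recomputes the module with explicit
loops over scales, channels and positions and serves as the equivalence
oracle for the vectorised path.

**Head and embedding.**  The classifier head global-average-pools the FAB
stage-3 grid and applies a linear layer with softmax over the ten classes
(no class token).  The slide-level embedding concatenates per-branch
`GAP(512) -> linear(256)` projections in the order GGB/FAB/LGB; disabled
branches contribute zeros, so the 768-width interface survives ablations.
These projection layers feed only WT, not the classification loss, so they
remain at their seeded initialisation and act as fixed random projections of
the learned pooled features.

**Ablation toggles.**  `use_ggb`/`use_fab`/`use_lgb` and `use_cam` reproduce
the single-branch (SSwT/SPVT/SViT) and fusion-ablation variants: with
`use_cam = FALSE` the CAS block fuses the available branches by channel
concatenation and a linear projection (identity when FAB is alone); CAM with
a missing branch is rejected, since the module is defined on all three
inputs.

## The WT architecture

The feature-matrix width 769 is not divisible by the 12 heads of the
full-scale encoder, so a linear input projection (769 → 768) precedes the
blocks — the only reading consistent with both the printed interface width
and the head count.  Learned absolute position encodings are added (the
rows are an arbitrary patch sample, so `use_abs_pos = FALSE` disables them
and makes the network provably permutation invariant — a property the tests
verify numerically).  Three stages of two classical blocks (12 heads, MLP
ratio 4) are followed by token-wise global average pooling and an 8-way
linear head.  The label prior is injected as a single normalised scalar
(`class/9`); a one-hot injection would widen the interface to 778 and break
the printed contract.  During slide inference the labels are CAST's
predictions; `--use-true-labels` (teacher forcing) substitutes ground truth
for controlled experiments.

Two input-conditioning choices in `fit_wt()`/`wt_forward()` deserve
explanation, because both were forced by a diagnosed optimisation
pathology of the literal interface rather than by taste:

* **Column standardisation** (default `standardize = TRUE`; statistics
  estimated on the training set, stored on the model, re-applied at
  prediction).  CAST embeddings and the label scalar live on very
  different scales, so the unstandardised rows are nearly rank-one; after
  a linear input projection every token lies close to one affine line,
  the pre-norm layer normalisation initially cancels the along-line
  magnitude, and optimisation stalls.  Diagnostically, a label-only
  matrix trains *worse* than one with nuisance embedding columns —
  exactly what the rank-one collapse predicts.
* **Fourier encoding of the label prior** (default `label_fourier = 8`).
  The slide-level signal is the *composition* of the ten classes among
  the sampled patches: a plain multinomial logistic regression on the
  10-bin label histogram of the very same sampled rows classifies the
  synthetic types at ~0.95.  But the interface carries the label as one
  scalar (`class/9`), so to pool a histogram the per-token layers must
  first synthesise ten indicator functions of a single input direction —
  and a desk-scale optimisation budget (≤30 epochs) demonstrably cannot
  learn this (validation accuracy plateaued at 0.76–0.87 across a wide
  learning-rate/batch/dropout/data-size grid).  Appending fixed
  `cos(πks), sin(πks)` features (k = 1..8) of the scalar before the —
  still linear — input projection makes the ten discrete label values
  linearly separable token features; with it the same network reaches
  0.97–0.99 in 5–8 epochs at every data scale tried.  The `m × 769`
  feature-matrix interface is unchanged; `label_fourier = 0` restores
  the literal scalar projection.

## Training

Both networks minimise the multi-class cross-entropy
`-sum_k y_k log p_k` (K = 10 for CAST, T = 8 for WT) with Adam
(`beta1 = 0.9`, `beta2 = 0.999`).  The full-scale recipe — 160 epochs,
CAST at learning rate 2e-3 with batch 64, WT at 1e-3 with batch 8 — is the
`train_config()` default ("paper profile").  No weight decay, augmentation,
warm-up or dropout is applied, and the learning-rate schedule is constant
unless `lr_schedule = "cosine"` is requested; where the recipe is silent the
package implements nothing and exposes a knob instead.  Class imbalance is
not reweighted.  Initialisation is truncated normal (sd 0.02, clipped at 2
sd).  Training is deterministic given the seed: shuffling, initialisation
and the synthetic data all derive from explicit seeds, and the best
validation checkpoint is retained.

The gradients are computed by a small reverse-mode autodiff engine on
matrices (linear, layer-norm, GELU, sigmoid, gather/scatter, concatenation,
pooled means, and a batched attention kernel written with RcppArmadillo).
Analytic gradients are verified against central finite differences at
`1e-4` relative tolerance in the test suite.

## The synthetic dataset

Real thymoma WSIs are not available to this package, so a generator
(`simulate_thw()`, `render_scene()`, `generate_wsi_bag()`) produces data
with exactly the statistical structure the architecture assumes, and the
end-to-end claims in this package are claims about that structure:

* **Co-registered triplets.**  One 40x scene is rendered per patch; the 20x
  and 10x views are exact 2x2 and 4x4 area averages — one field of view at
  three resolutions, so mean intensity is conserved across scales to
  rounding error.  Scenes are snapped to the 8-bit intensity grid so the
  PNG on-disk form is bit-exact.
* **Two signal families.**  Coarse layout classes (fibrous septa =
  horizontal bands, perivascular space = rings, medullary areas = large
  blobs) are overlaid with a high-frequency "clutter" field (amplitude 0.3)
  whose 2x2 cells average to zero exactly: these classes are clean at
  10x/20x but noisy at 40x.  Fine-texture classes (four epithelial nucleus
  gradations, erythrocyte/lymphocyte specks, a dense irregular tumour
  field) differ in nucleus size and density and are attenuated by
  downsampling.  The B2/B3 epithelial pair shares its stain area fraction
  (radius 3 vs 4 at compensating densities) so it is separable only through
  fine texture, while the bands/rings pair is separable only through coarse
  layout — making multi-branch fusion genuinely informative.  A
  fixed-budget reference classifier (a classification tree on 64 sampled
  pixel locations) verifies the split: it separates the coarse pair at 10x
  but stays below ceiling at 40x (≥15 percentage-point gap).
* **Slide bags.**  Each thymoma type fixes a mixture over the ten patch
  classes (`default_type_composition()`); mixed types (AB, B1+B2, B2+B3)
  are exact averages of their components, type A concentrates on
  spindle-cell + tumour, B1 on B1 cells + lymphocytes + medullary areas,
  TC on tumour.  A per-slide composition is drawn from a Dirichlet centred
  on the type's row with concentration 200 — enough slide-to-slide
  variability to be non-trivial while keeping the type mixtures separable
  from a realistic patch sample (a multinomial-logistic oracle on the
  label histogram of 64 sampled patches classifies types at ~0.95+,
  bounding what WT can achieve).  The default 3,000 patches per slide
  matches the full-scale slide division; desk-scale runs use 16–64.
  Patches are all-foreground: whether the full-scale division was
  tissue-filtered is not stated anywhere we could rely on, so no background
  class is emulated.

What the generator does **not** model: real H&E appearance, stain
variation/deconvolution, scanner artefacts, tissue boundaries, pyramidal
file formats, or spatial correlation between neighbouring patches.  Passing
the synthetic end-to-end tests therefore demonstrates that the
implementation can learn the designed multi-scale and compositional
structure — not performance on real slides.

## Problem sizes and numerical choices

Shape conformance is asserted at the full-scale geometry (256/128/64 pixel
triplets through 32/16/8 grids at widths 128/256/512; WT at 512x769).
Optimisation runs use the desk profile: 8/16/32 pixel triplets, widths
16/32/64 (`cast_config_tiny()`), WT at width 49, model dim 64, 4 heads
(`wt_config_tiny()`).  The patch-level end-to-end check trains on 600
triplets of three classes (bands, lymphocyte, tumour) for up to 30 epochs;
the slide-level check uses 24 slides per type with 64 patches each.  These
sizes were chosen so the whole suite runs on a single laptop-class CPU
core in minutes while leaving the architecture untouched.

Other numerical conventions: window size defaults to 8 (dividing the
32/16/8 grids) with shift `window/2`, clipped per stage so a window never
exceeds the grid — at stage 3 the window equals the grid and the shifted
pass degenerates to the unshifted one, which is documented rather than
padded around; SRA reduction ratios default to 8/4/2 (keeping at least a
4x4 key grid) and the reduction projection is skipped entirely at ratio 1,
which is what makes the `SRA(ratio 1) = MSA` identity exact; cyclic-shift
boundary handling uses masking (additive -1e9) rather than padding;
softmax rows are computed max-shifted; cross-entropy probabilities are
clamped at 1e-12; argmax ties break to the lowest index; layer-norm uses
eps 1e-5.  Where a printed configuration conflicted with prose (2x2 vs 4x4
patch merging between stages; stage-1 MLP ratio 8 vs 4), the printed
configuration table was followed, since the alternative contradicts the
printed intermediate shapes.

## Known limitations

* The autodiff engine is desk-scale: no fused kernels, no mixed precision,
  no multi-threaded batching; full-scale (160-epoch, 3,000-patch-per-slide)
  training is out of reach in R and is not attempted.
* CAST's embedding projections are untrained (see above); a fully
  end-to-end variant would need a joint loss, which the two-stage recipe
  does not define.
* The Wilson interval is used for sensitivity/specificity CIs; published
  per-class CI bounds of this kind are not reproducible without the
  per-class denominators, so no CI values are asserted against external
  tables.
* McNemar tests use the clamped continuity correction
  `max(|b-c|-1, 0)^2/(b+c)` — the form consistent with a printed statistic
  of 0 and significance 1 for tied discordant counts — and the asymptotic
  chi-square(1) tail; no exact binomial variant is provided.
* Ablation accuracy orderings (full CAST vs two-branch vs single-branch)
  are reported by the ablation toggles when run, not hard-asserted: at desk
  scale their differences are within seed noise.
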