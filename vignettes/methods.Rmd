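---
title: "Attention U-Nets, cosine loss and SAM for total kidney volume segmentation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pkdseg)
```

## The problem

Autosomal dominant polycystic kidney disease (ADPKD) progressively replaces
kidney parenchyma with fluid-filled cysts. Total kidney volume (TKV), measured
from MRI, is the established imaging biomarker of disease progression, and
computing it requires delineating both kidneys — including their cysts — on
every coronal slice of an abdominal scan. Manual delineation takes an expert
hours per case; `pkdseg` implements an automated deep-learning pipeline for
this segmentation task, built for the small-data regime that is typical of
rare-disease imaging: on the order of a hundred annotated volumes rather than
thousands.

The package is a complete, self-contained CPU implementation: the networks,
their backward passes and the optimizers are authored here on top of base R
array operations, BLAS matrix multiplication and two small C++ kernels, so the
whole method can be studied, tested and rerun without any external
deep-learning framework.

## The method stack

Four fully-convolutional 2D networks share a residual U-Net trunk
(`build_network()`): convolution blocks are two 3×3 convolutions with batch
normalization and elu activations plus an identity-add shortcut; each encoder
stage halves resolution with 2×2 max pooling and doubles the channel count;
the decoder mirrors this with nearest-neighbour upsampling, a 3×3 convolution
and concatenation with the skip connection; a 1×1 convolution and softmax
produce per-voxel probabilities for background, left kidney and right kidney.

* **Attention U-Net** adds attention gates on the skip connections: the
  coarser decoder feature (the gating signal $g$) and the skip feature $x_l$
  are each mapped by 1×1 convolutions to an intermediate channel count at
  $g$'s resolution, summed, passed through ReLU, a 1×1 convolution to one
  channel and a sigmoid, and the resulting coefficients $\alpha \in (0,1)$ are
  upsampled and multiplied into $x_l$. Irrelevant skip activations (cysts
  outside the kidneys, neighbouring organs) are thereby suppressed before the
  decoder sees them.
* **SE U-Net** additionally applies a squeeze-and-excitation block after each
  encoder stage: global average pooling to a $1 \times 1 \times C$ descriptor
  $z$, then $E_x = \sigma(W_2\,\mathrm{ReLU}(W_1 z))$ with a reduction
  bottleneck (ratio $r = 8$ by default), rescaling each channel by its
  excitation.
* **CBAM U-Net** instead applies a convolutional block attention module after
  each encoder stage: channel attention from spatially average- and max-pooled
  descriptors passed through a shared two-layer MLP, summed and squashed;
  then spatial attention from the channel-wise mean and max maps, concatenated
  and convolved (7×7) to a single sigmoid map. Both SE and CBAM variants
  extend the Attention U-Net, i.e. they retain the gates.

### Losses

All losses (`dsc_loss()`, `ce_loss()`, `combined_loss()`, `cosine_loss()`)
operate on per-voxel class probabilities $\hat Y$ and one-hot labels $Y$ and
sum over all three classes including background:

* soft Dice loss $L_{DSC} = 1 - 2\sum_c\sum_i \hat y_{i,c} y_{i,c} /
  (\sum_c\sum_i \hat y_{i,c} + \sum_c\sum_i y_{i,c})$;
* cross-entropy $L_{CE} = -\sum_c\sum_i y_{i,c}\log \hat y_{i,c} / (c\,N)$
  with probabilities clipped at $10^{-7}$ (a numerical floor the formula
  itself leaves implicit);
* the combination $L_{CE+DSC} = L_{DSC} + \lambda L_{CE}$ with
  $\lambda = 10$;
* the cosine loss $L_{COS} = 1 - \langle \hat Y, Y\rangle /
  (\|\hat Y\|_2 \|Y\|_2)$, which drives the (flattened, ℓ2-normalized)
  prediction toward the direction of the one-hot ground truth and is
  invariant to positive rescaling of the prediction.

The cosine loss is computed on one global flattening of the whole batch
tensor, because its defining formula is written on whole tensors; a per-class
variant (one cosine term per channel, averaged) is available via
`per_class = TRUE` for comparison. Background inclusion in the Dice and
cross-entropy sums follows the literal three-class summation of the formulas.

### Sharpness-aware minimization

`sam_update()` wraps any base optimizer (Adam here, the protocol's choice).
Each update evaluates the gradient twice: once at the current weights $w$
(giving $g_1$), then at the adversarially perturbed point
$\tilde w = w + \rho\, g_1/\|g_1\|_2$, and the base optimizer applies the
second gradient at the original $w$. Flat minima — parameter neighbourhoods
of uniformly low loss — are favoured over sharp ones, which improves
generalization from small training sets. The radius $\rho = 0.05$ with a
single global ℓ2 norm over all parameters is the originally published
default; the source this method builds on does not state a value, so both
the radius and the normalization granularity are exposed in `sam_config()`.
Batch-norm statistics are updated only on the second forward pass, so one
SAM update consumes exactly one batch-statistics update, as a plain step
would.

### Training protocol

`train_model()` implements the patch-based protocol: volumes are z-score
normalized as a whole (`zscore_normalize()`; population standard deviation,
computed per volume rather than per slice so that all slices of a case share
one intensity scale); patch centres are
drawn 50:50 from the label (either kidney) and background strata, resampled
every epoch, with 160 patches per volume per epoch at full scale; patches of
96 or 128 pixels are paired with batch sizes 16 and 8 respectively; Adam runs
at learning rate $10^{-3}$ with L2 regularization $10^{-7}$ and dropout 0.01.
Networks train for at least 20 epochs and stop once the per-kidney validation
Dice has a range below $10^{-4}$ over the last ten epochs, each kidney
checked separately (`early_stop_check()`); the checkpoint with the highest
mean per-kidney validation Dice within those last ten epochs is kept,
earliest epoch on ties (`select_checkpoint()`). Validation Dice is computed
volume-wise on full-size slices, mirroring the train-on-patches /
test-on-full-images protocol. Cross-validation uses 5 folds with a 70:10:20
train:validation:test split (`make_folds()`), every case appearing in exactly
one test set.

### Inference, post-processing, ensembles

`predict_volume()` forwards each coronal slice independently (the networks
are 2D) and stacks the probabilities; labels are the per-voxel argmax with
ties broken toward the lower class index. `largest_component_filter()` keeps,
per kidney class, only the largest 3D face-connected component — components
are computed in 3D because kidneys span slices, and 6-connectivity avoids
diagonal leakage through chains of cysts; 2D-vs-3D analysis was a genuinely
open choice and 3D is the package's default and recommendation.

Two fusion schemes combine multiple trained models (`fuse_ensemble()`):
majority voting (`majority_vote()`; any tie for the per-voxel maximum
resolves conservatively to background) and binary STAPLE per foreground class
(`staple_consensus()`): an EM algorithm that alternates a posterior estimate
of the true segmentation with per-rater sensitivity/specificity updates. The
spatial prior is the mean foreground rate across members, initialization is
$p_j = q_j = 0.99999$, convergence is a mean posterior change below
$10^{-7}$ or 100 iterations — the published conventions of the original
STAPLE formulation, to which the method description defers entirely. Fusion
operates on post-processed hard labels by default (ensembles are reported
after post-processing); fusing raw labels is available by flag.

### Evaluation

`evaluate_report()` assembles, per case: Dice per kidney and averaged; mean
symmetric surface distance (MSSD, mm) — nearest-neighbour distances between
*boundary* voxel sets, symmetric, normalized by the sum of the two set sizes,
with the anisotropic voxel spacing applied (slice thickness is more than
twice the in-plane resolution, so ignoring anisotropy would distort
through-slice distances); TKV in mL as voxel count × voxel volume / 1000;
TKV percent difference; cohort mean ± sd; the OLS $R^2$ of predicted versus
reference TKV; and one-sided paired t-tests (`paired_t_test()`) whose null
hypothesis is that the baseline configuration is at least as good, rejected
at $p < 0.05$. The evaluation formula for MSSD is printed in the literature
over full voxel sets while being *named* a surface distance; boundary sets
match the name and standard practice and are the default, with the literal
full-set variant behind `surface = FALSE`. A Dice of two empty sets is
defined as 1 (agreement on absence); an MSSD with one empty set is reported
as undefined and flagged rather than forced to a sentinel value.

## The synthetic phantom cohort

The restricted patient data this method was developed for cannot be shipped,
so `generate_phantom()` builds synthetic abdominal volumes with the
statistical structure the method assumes: a 256 × 256 in-plane matrix at
1.41 × 1.41 mm with ~3.06 mm coronal slices (the emulated acquisition
geometry); two non-overlapping ellipsoidal kidneys (randomly jittered
semi-axes and small in-plane rotations) that are brighter than background;
hyper- and hypo-intense intrarenal cysts (T1-like heterogeneity); optional
bright extra-renal cyst blobs labelled background — the hard-case structure
where cystic tissue outside the kidneys punishes purely intensity-based
segmentation; a smooth second-order polynomial multiplicative bias field; and
additive Gaussian noise. Class 1 is the patient-left kidney placed in the
image-right half (radiological convention; configurable), a convention the
method description itself never fixes. The generator returns the analytic
ellipsoid volume $\tfrac43\pi abc$ per kidney, so TKV recovery can be checked
against a closed form; rasterization error at the default geometry is within
5% and shrinks with the spacing.

What the phantoms deliberately do **not** model: realistic MR physics (coil
profiles beyond a smooth bias field, motion, partial-volume mixtures),
anatomical shape variability beyond ellipsoids, and neighbouring organs.
Passing the end-to-end tests therefore demonstrates that the implementation
is correct and that the method behaves as described under its own
assumptions — not that these accuracy numbers transfer to patient data.

`rater_perturb()` turns a ground-truth mask into a simulated imperfect rater
with known sensitivity and specificity (false positives confined to a dilated
band around each kidney), giving label-fusion tests a known truth to recover.

## Numerical and scale choices

* Convolutions are im2col + BLAS GEMM with two small C++ kernels for the
  im2col assembly and zero-padding; the backward pass reuses the same
  primitive with a spatially flipped, channel-transposed kernel. All
  gradients are verified against central finite differences in the test
  suite, for every network variant.
* Default architecture: depth 4, 32 base filters. Encoder filter counts and
  the upsampling operator are not fixed by the method description; 32
  doubling per level and nearest-neighbour upsampling followed by a 3×3
  convolution were chosen once and are configurable. Attention-gate
  internals use ReLU/sigmoid even though the trunk uses elu, following the
  gates' original formulation.
* The package's own test and demonstration scale is reduced so the full
  pipeline runs in minutes on one CPU: 64 × 64 × 16-voxel phantoms (same
  spacing, proportionally smaller kidneys with semi-axes (11, 22, 14) mm), a
  20-case cohort, depth-3 networks with 16 base filters, 64-pixel patches
  and 16 patch samples per volume per epoch. Reduced-scale runs use batch
  size 4 — the protocol's batch pairing (16 for 96-pixel patches, 8 for
  128) does not cover 64-pixel patches, and separating the two kidney
  classes empirically depends on the optimizer step count, so smaller
  batches converge in less wall time — with learning rate 2 × 10⁻³ for the
  CE+DSC loss and 5 × 10⁻⁴ for the cosine loss, over roughly ten epochs.
  The full-scale defaults remain batch 16/8 and learning rate 10⁻³. These
  sizes are the package's reduced-scale study conditions; the README's
  worked example reports numbers from exactly these settings.
* The cosine loss is bounded and, unlike cross-entropy, does not penalize
  confident errors unboundedly: once the softmax saturates, its gradients
  vanish. At reduced scale this makes it sensitive to the learning rate —
  at 2 × 10⁻³ and above it can lock into a one-kidney solution — hence the
  gentler 5 × 10⁻⁴ default for cosine runs.
* Batch-norm inference statistics use momentum 0.1 running averages;
  `eps = 1e-5`. Dropout masks are held fixed across the two SAM forward
  passes of one update so both gradients see the same stochastic network.
* Ties: max-pool and argmax ties resolve to the first (lowest-index)
  element; majority-vote ties resolve to background; component-size ties
  keep the component with the lowest voxel index; checkpoint ties keep the
  earliest epoch.

## Known limitations

* 2D slice-wise networks cannot use through-slice context; the 3D
  largest-component filter recovers some of it post hoc.
* The cosine loss at global flattening is dominated by the background
  channel on very empty batches; the per-class variant mitigates this but is
  not the default, to stay with the formula as written.
* STAPLE here is the binary per-class formulation run twice, not a
  multi-label generalization; overlapping claims are resolved by the higher
  posterior.
* Training at the full 256 × 256 × 40 scale with 100-case cohorts is
  possible with this implementation but slow on a single CPU; the package's
  purpose at that scale is method study and correctness, not throughput.
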