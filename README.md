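# pkdseg

Automated total kidney volume (TKV) segmentation for polycystic kidney
disease, in R.

Autosomal dominant polycystic kidney disease (ADPKD) is a hereditary
disorder in which kidneys progressively fill with cysts and enlarge; TKV
measured from coronal abdominal MRI is the accepted imaging biomarker of
progression. Computing TKV requires delineating both kidneys — cysts
included — on every slice, which is slow to do by hand. `pkdseg` implements
a deep-learning segmentation pipeline designed for the small-data regime of
rare-disease imaging (~100 annotated volumes), entirely in R: the networks,
their backward passes, and the optimizers are authored in the package on
top of base-R array operations, BLAS matrix multiplies and two small C++
kernels, so there is no external deep-learning framework to install.

The method stack:

* **Networks** (`build_network()`): four fully-convolutional residual 2D
  U-Nets — a baseline, an Attention U-Net with gated skip connections
  (coefficients α ∈ (0,1) computed from the coarser decoder feature), and
  SE / CBAM variants that add squeeze-and-excitation or convolutional block
  attention modules to the Attention U-Net encoder. Batch normalization,
  elu activations, dropout.
* **Losses**: soft Dice `L_DSC`, cross-entropy `L_CE` (combined as
  `L_DSC + 10·L_CE`), and a cosine segmentation loss
  `L_COS = 1 − ⟨Ŷ,Y⟩/(‖Ŷ‖₂‖Y‖₂)` suited to small datasets.
* **Optimizer** (`sam_update()`): Adam, optionally wrapped in
  sharpness-aware minimization (SAM) — two gradient evaluations per update,
  the second at the adversarial point `w + ρ·g/‖g‖₂`, ρ = 0.05.
* **Protocol** (`train_model()`): whole-volume z-score normalization,
  50:50 label:background patch mining resampled every epoch, patch sizes
  96/128 with batch sizes 16/8, 5-fold 70:10:20 cross-validation, at least
  20 epochs with a 10-epoch / 1e-4 early-stopping window on per-kidney
  validation Dice, best-of-last-10 checkpoint selection.
* **Inference** (`predict_volume()`, `largest_component_filter()`):
  slice-wise full-resolution prediction; per-class largest 3D
  face-connected component post-processing.
* **Ensembles** (`majority_vote()`, `staple_consensus()`): majority voting
  and per-class binary STAPLE (EM estimation of a consensus plus per-rater
  sensitivity/specificity).
* **Evaluation** (`evaluate_report()`): Dice, mean symmetric surface
  distance (MSSD, mm, anisotropic spacing), TKV (mL), TKV % difference,
  R² of predicted vs reference TKV, one-sided paired t-tests.
* **Phantoms** (`generate_phantom()`, `generate_cohort()`,
  `rater_perturb()`): a synthetic abdominal cohort generator emulating the
  256×256, 1.41×1.41 mm, ~3.06 mm coronal acquisition geometry, with
  ellipsoidal cystic kidneys, extra-renal cyst blobs, bias field and noise —
  the restricted patient data cannot be shipped, so all tests and examples
  run on phantoms with known analytic kidney volumes.

## Worked example

Generate a small phantom cohort, train a reduced-scale baseline U-Net, and
evaluate it on the held-out fold (a few minutes on one CPU):

```r
library(pkdseg)

cfg <- phantom_config(shape = c(64, 64, 16), kidney_semiaxes = c(11, 22, 14),
                      n_intrarenal_cysts = 3, n_abdominal_cysts = 1)
man <- generate_cohort(20, master_seed = 123, "phantoms/", cfg)
fold <- make_folds(man$case_id, k = 5, seed = 1)[[1]]

tc <- train_config(variant = "baseline_unet", loss = "ce_dsc",
                   patch_size = 64, batch_size = 8, depth = 3,
                   base_filters = 16, samples_per_volume = 16, lr = 2e-3,
                   min_epochs = 12, stop_window = 5, max_epochs = 12,
                   seed = 11)
model <- train_model(tc, fold, man, verbose = TRUE)

refs <- results <- list()
for (id in fold$test) {
  row <- man[man$case_id == id, ]
  vol <- zscore_normalize(read_volume(row$volume_path))
  results[[id]] <- predict_volume(model, vol, case_id = id)
  refs[[id]] <- read_mask(row$mask_path)
}
evaluate_report(results, refs)
#> <pkdseg_report> 4 cases
#>   DSC  0.982 +/- 0.012   MSSD 0.236 +/- 0.179 mm
#>   TKV diff -2.33%   R^2 0.986
```

Read: the four held-out phantoms are segmented with a mean Dice overlap of
0.982, mean boundary error of 0.24 mm, and the automated TKV underestimates
the reference TKV by 2.3% on average. `tidy(report)` returns the per-case
tibble, `glance(report)` the one-row summary, and
`ggplot2::autoplot(report)` the predicted-vs-reference TKV scatter.

A command-line interface wrapping the same functions is installed at
`system.file("scripts", "pkdseg", package = "pkdseg")`, with subcommands
`make-phantoms`, `train`, `predict`, `ensemble`, `evaluate`.

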