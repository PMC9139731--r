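# Evaluation suite: Dice, mean symmetric surface distance, total kidney
# volume, TKV percent difference, R-squared of the TKV fit and one-sided
# paired t-tests, plus the per-cohort report assembly.

#' Dice similarity coefficient
#'
#' \eqn{2 |A \cap B| / (|A| + |B|)} for one class's voxel sets. Defined as 1
#' when both sets are empty (agreement on absence). `class_id = "mean"`
#' returns the average of the class-1 and class-2 scores (the
#' averaged-over-both-kidneys convention used in cohort summaries).
#'
#' @param pred,ref `label_mask` objects (or plain integer arrays) of equal
#'   shape.
#' @param class_id 1, 2, or `"mean"`.
#' @return Scalar in `[0, 1]`.
#' @export
dice_score <- function(pred, ref, class_id = "mean") {
  p <- if (inherits(pred, "label_mask")) pred$data else pred
  r <- if (inherits(ref, "label_mask")) ref$data else ref
  if (!identical(dim(p), dim(r))) abort("mask shapes differ")
  if (identical(class_id, "mean")) {
    return(mean(c(dice_score(p, r, 1L), dice_score(p, r, 2L))))
  }
  a <- p == class_id
  b <- r == class_id
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

# Boundary voxels of a class: class voxels with at least one face neighbour
# outside the class (voxels at the array border count as boundary).
boundary_voxels <- function(mask, class_id) {
  b <- mask == class_id
  d <- dim(b)
  interior <- array(TRUE, d)
  interior[c(1L, d[1]), , ] <- FALSE
  interior[, c(1L, d[2]), ] <- FALSE
  interior[, , c(1L, d[3])] <- FALSE
  core <- b & interior
  if (any(core)) {
    idx <- which(core)
    steps <- c(1L, d[1], d[1] * d[2])
    all_nb <- b[idx + steps[1]] & b[idx - steps[1]] &
      b[idx + steps[2]] & b[idx - steps[2]] &
      b[idx + steps[3]] & b[idx - steps[3]]
    core[idx] <- all_nb
  }
  which(b & !core)
}

# Exact nearest-neighbour distances from each point of A to the set B
# (coordinates in mm), computed in blocks to bound memory.
nn_distances <- function(A, B, block = 512L) {
  out <- numeric(nrow(A))
  i <- 1L
  while (i <= nrow(A)) {
    j <- min(i + block - 1L, nrow(A))
    blk <- i:j
    # exact squared distances from per-axis differences (the expanded
    # |a|^2 + |b|^2 - 2ab form loses precision for identical points)
    d2 <- outer(A[blk, 1], B[, 1], `-`)^2 +
      outer(A[blk, 2], B[, 2], `-`)^2 +
      outer(A[blk, 3], B[, 3], `-`)^2
    out[blk] <- sqrt(apply(d2, 1L, min))
    i <- j + 1L
  }
  out
}

#' Mean symmetric surface distance (mm)
#'
#' The symmetric mean of nearest-neighbour Euclidean distances between the
#' boundary-voxel sets of prediction and reference for one class,
#' \eqn{(\sum_{\hat y} \min d(\hat y, Y) + \sum_{y} \min d(y, \hat Y)) /
#' (|\hat Y| + |Y|)}, with the anisotropic voxel spacing applied to all
#' distances. With `surface = FALSE` the literal full-voxel-set variant is
#' computed instead of the boundary-set one.
#'
#' @inheritParams dice_score
#' @param class_id 1 or 2 (use [evaluate_report()] for the per-case mean).
#' @param spacing voxel spacing in mm (taken from `pred` if a `label_mask`).
#' @param surface use boundary voxels (default) or full voxel sets.
#' @return Distance in mm, or `NA` (with attribute `undefined = TRUE`) when
#'   either voxel set is empty.
#' @export
mssd <- function(pred, ref, class_id, spacing = NULL, surface = TRUE) {
  p <- if (inherits(pred, "label_mask")) pred$data else pred
  r <- if (inherits(ref, "label_mask")) ref$data else ref
  if (is.null(spacing) && inherits(pred, "label_mask")) {
    spacing <- pred$spacing
  }
  if (is.null(spacing)) abort("`spacing` required for plain-array input")
  if (!identical(dim(p), dim(r))) abort("mask shapes differ")
  idx_p <- if (surface) boundary_voxels(p, class_id) else which(p == class_id)
  idx_r <- if (surface) boundary_voxels(r, class_id) else which(r == class_id)
  if (length(idx_p) == 0 || length(idx_r) == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  d <- dim(p)
  A <- sweep(arrayInd(idx_p, d), 2L, spacing, `*`)
  B <- sweep(arrayInd(idx_r, d), 2L, spacing, `*`)
  (sum(nn_distances(A, B)) + sum(nn_distances(B, A))) /
    (nrow(A) + nrow(B))
}

#' Total kidney volume (mL)
#'
#' The number of voxels in the two kidney classes multiplied by the voxel
#' volume (product of the spacings, mm^3) divided by 1000.
#'
#' @param mask a `label_mask` (or integer array with `spacing` given).
#' @param spacing voxel spacing in mm.
#' @return TKV in mL.
#' @export
compute_tkv <- function(mask, spacing = NULL) {
  m <- if (inherits(mask, "label_mask")) mask$data else mask
  if (is.null(spacing) && inherits(mask, "label_mask")) {
    spacing <- mask$spacing
  }
  sum(m == 1L | m == 2L) * prod(spacing) / 1000
}

#' TKV percent difference
#'
#' `(pred - ref) / ref * 100`; negative values indicate under-segmentation.
#'
#' @param pred_mL,ref_mL volumes in mL; `ref_mL` must be positive.
#' @export
tkv_percent_diff <- function(pred_mL, ref_mL) {
  if (any(ref_mL <= 0)) abort("reference TKV must be > 0")
  (pred_mL - ref_mL) / ref_mL * 100
}

#' Coefficient of determination of the TKV fit
#'
#' R-squared of the ordinary-least-squares regression of predicted on
#' reference TKV.
#'
#' @param pred_mL,ref_mL paired volumes (>= 3 pairs; reference not constant).
#' @export
r2_fit <- function(pred_mL, ref_mL) {
  if (length(pred_mL) != length(ref_mL) || length(pred_mL) < 3) {
    abort("need >= 3 paired TKV values")
  }
  if (stats::var(ref_mL) == 0) abort("reference TKV is constant")
  if (stats::var(pred_mL) == 0) return(0)  # no explained variance
  fit <- lm(pred_mL ~ ref_mL)
  summary(fit)$r.squared
}

#' One-sided paired t-test (method B better than baseline A)
#'
#' Tests the null hypothesis that baseline `a` is at least as good as method
#' `b` on per-case paired metric values; the alternative is that `b` is
#' better. For metrics where larger is better (Dice) the test is on
#' `b - a > 0`; for smaller-is-better metrics (MSSD) set
#' `higher_is_better = FALSE`. If every per-case difference is zero the test
#' is degenerate and `p = 0.5` is returned with `t = 0`.
#'
#' @param metric_a,metric_b equal-length (>= 2) per-case metric vectors,
#'   paired by case.
#' @param higher_is_better direction of improvement.
#' @param alpha rejection level reported in the result.
#' @return A list with `t`, `p`, `reject`.
#' @export
paired_t_test <- function(metric_a, metric_b, higher_is_better = TRUE,
                          alpha = 0.05) {
  if (length(metric_a) != length(metric_b)) abort("length mismatch")
  if (length(metric_a) < 2) abort("need at least 2 pairs")
  d <- if (higher_is_better) metric_b - metric_a else metric_a - metric_b
  if (all(d == 0)) {
    return(list(t = 0, p = 0.5, reject = FALSE))
  }
  tt <- t.test(d, alternative = "greater")
  list(t = unname(tt$statistic), p = unname(tt$p.value),
       reject = unname(tt$p.value) < alpha)
}

#' Assemble a cohort metrics report
#'
#' Computes per-case, per-kidney Dice, MSSD, predicted and reference TKV and
#' the TKV percent difference, plus cohort aggregates (mean and sd of each
#' column) and the R-squared of predicted versus reference TKV.
#'
#' @param results list of `segmentation_result` objects (or `label_mask`
#'   predictions) with case ids.
#' @param refs named list of reference `label_mask` objects keyed by case id.
#' @param spacing voxel spacing in mm (defaults to each reference's).
#' @param use_postprocessed evaluate `post_labels` (default) or raw `labels`
#'   when `results` holds `segmentation_result` objects.
#' @return A list of class `pkdseg_report`: `cases` (per-case tibble),
#'   `summary` (aggregate tibble), `r2` (TKV R-squared, `NA` for < 3 cases).
#' @export
evaluate_report <- function(results, refs, spacing = NULL,
                            use_postprocessed = TRUE) {
  rows <- vector("list", length(results))
  for (i in seq_along(results)) {
    res <- results[[i]]
    if (inherits(res, "segmentation_result")) {
      pred <- if (use_postprocessed) res$post_labels else res$labels
      cid <- res$case_id
    } else {
      pred <- res
      cid <- names(results)[i] %||% sprintf("case_%03d", i)
    }
    ref <- refs[[cid]]
    if (is.null(ref)) abort(sprintf("missing reference for case '%s'", cid))
    sp <- spacing %||% ref$spacing
    m1 <- mssd(pred, ref, 1L, sp)
    m2 <- mssd(pred, ref, 2L, sp)
    rows[[i]] <- tibble(
      case_id = cid,
      dsc_left = dice_score(pred, ref, 1L),
      dsc_right = dice_score(pred, ref, 2L),
      dsc_mean = dice_score(pred, ref, "mean"),
      mssd_left = as.numeric(m1),
      mssd_right = as.numeric(m2),
      mssd_mean = mean(c(m1, m2)),
      mssd_undefined = isTRUE(attr(m1, "undefined")) ||
        isTRUE(attr(m2, "undefined")),
      tkv_pred = compute_tkv(pred, sp),
      tkv_ref = compute_tkv(ref, sp),
      tkv_diff_pct = tkv_percent_diff(compute_tkv(pred, sp),
                                      compute_tkv(ref, sp))
    )
  }
  cases <- dplyr::bind_rows(rows)
  num_cols <- c("dsc_left", "dsc_right", "dsc_mean", "mssd_left",
                "mssd_right", "mssd_mean", "tkv_pred", "tkv_ref",
                "tkv_diff_pct")
  summary_tbl <- dplyr::bind_rows(lapply(num_cols, function(col) {
    v <- cases[[col]]
    tibble(metric = col, mean = mean(v, na.rm = TRUE),
           sd = if (sum(!is.na(v)) > 1) sd(v, na.rm = TRUE) else NA_real_)
  }))
  r2 <- if (nrow(cases) >= 3 && stats::var(cases$tkv_ref) > 0) {
    r2_fit(cases$tkv_pred, cases$tkv_ref)
  } else {
    NA_real_
  }
  structure(list(cases = cases, summary = summary_tbl, r2 = r2),
            class = "pkdseg_report")
}

#' @export
print.pkdseg_report <- function(x, ...) {
  cat(sprintf("<pkdseg_report> %d cases\n", nrow(x$cases)))
  cat(sprintf("  DSC  %.3f +/- %.3f   MSSD %.3f +/- %.3f mm\n",
              x$summary$mean[x$summary$metric == "dsc_mean"],
              x$summary$sd[x$summary$metric == "dsc_mean"],
              x$summary$mean[x$summary$metric == "mssd_mean"],
              x$summary$sd[x$summary$metric == "mssd_mean"]))
  cat(sprintf("  TKV diff %+.2f%%   R^2 %.3f\n",
              x$summary$mean[x$summary$metric == "tkv_diff_pct"], x$r2))
  invisible(x)
}

#' Write a metrics report to CSV
#'
#' Writes the per-case table to `path` and the aggregate summary to
#' `<path base>_summary.csv`.
#'
#' @param report a `pkdseg_report`.
#' @param path output CSV path for the per-case table.
#' @export
write_report <- function(report, path) {
  utils::write.csv(report$cases, path, row.names = FALSE)
  base <- tools::file_path_sans_ext(path)
  utils::write.csv(report$summary, paste0(base, "_summary.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' Tidy methods for metrics reports
#'
#' `tidy()` returns the per-case metric tibble; `glance()` returns a
#' one-row cohort summary.
#'
#' @param x a `pkdseg_report`.
#' @param ... unused.
#' @importFrom generics tidy glance
#' @export
tidy.pkdseg_report <- function(x, ...) x$cases

#' @rdname tidy.pkdseg_report
#' @export
glance.pkdseg_report <- function(x, ...) {
  s <- x$summary
  tibble(
    n_cases = nrow(x$cases),
    dsc_mean = s$mean[s$metric == "dsc_mean"],
    dsc_sd = s$sd[s$metric == "dsc_mean"],
    mssd_mean = s$mean[s$metric == "mssd_mean"],
    mssd_sd = s$sd[s$metric == "mssd_mean"],
    tkv_diff_pct_mean = s$mean[s$metric == "tkv_diff_pct"],
    r2 = x$r2
  )
}

#' @rdname tidy.pkdseg_report
#' @export
tidy.pkdseg_model <- function(x, ...) x$history

#' @rdname tidy.pkdseg_report
#' @export
glance.pkdseg_model <- function(x, ...) {
  n <- nrow(x$history)
  tibble(variant = x$config$variant, loss = x$config$loss,
         sam = x$config$sam, epochs = n,
         selected_epoch = x$selected_epoch,
         val_dsc_left = x$history$dsc_left[n],
         val_dsc_right = x$history$dsc_right[n])
}

#' @export
generics::tidy

#' @export
generics::glance
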