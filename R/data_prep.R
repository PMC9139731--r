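#' Z-score intensity normalization
#'
#' Normalizes a whole volume to zero mean and unit standard deviation,
#' \eqn{\hat I = (I - \mu(I)) / \sigma(I)}, where \eqn{\mu} and \eqn{\sigma}
#' are the mean and the population (divide-by-N) standard deviation of the
#' volume. A constant volume (\eqn{\sigma = 0}) maps to all zeros. The
#' statistics are computed per volume, not per slice.
#'
#' @param volume a `volume_grid`.
#' @return A `volume_grid` with normalized intensities (unitless).
#' @export
zscore_normalize <- function(volume) {
  stopifnot(inherits(volume, "volume_grid"))
  v <- volume$data
  if (length(v) == 0) abort("empty volume")
  mu <- mean(v)
  sg <- sqrt(mean((v - mu)^2))
  out <- if (sg == 0) array(0, dim(v)) else (v - mu) / sg
  volume_grid(out, volume$spacing)
}

#' Balanced patch-centre mining
#'
#' Draws patch centres from a label mask with a 50:50 stratification between
#' label (any kidney class) and background voxels: each draw first picks the
#' stratum with probability 1/2, then a voxel uniformly within that stratum.
#' If a stratum is empty all draws come from the other one. Row/column
#' coordinates are clamped so that a `size` x `size` in-plane window fits
#' inside the slice.
#'
#' @param mask a `label_mask` (slices stacked along axis 3).
#' @param n number of centres to draw.
#' @param seed integer RNG seed.
#' @param size patch edge length in voxels (used only for clamping).
#' @param label_prob probability of the label stratum (0.5 by default).
#' @return A tibble with columns `slice`, `row`, `col`, `stratum`.
#' @export
sample_patch_centers <- function(mask, n, seed, size = 96L,
                                 label_prob = 0.5) {
  stopifnot(inherits(mask, "label_mask"))
  if (n == 0) {
    return(tibble(slice = integer(), row = integer(), col = integer(),
                  stratum = character()))
  }
  m <- mask$data
  d <- dim(m)
  if (size > d[1] || size > d[2]) abort("patch size exceeds slice size")
  fg_idx <- which(m != 0L)
  bg_idx <- which(m == 0L)
  if (length(bg_idx) == 0 && length(fg_idx) == 0) abort("empty mask array")
  with_seed(seed, {
    pick_fg <- runif(n) < label_prob
    if (length(fg_idx) == 0) pick_fg[] <- FALSE
    if (length(bg_idx) == 0) pick_fg[] <- TRUE
    idx <- integer(n)
    nf <- sum(pick_fg)
    if (nf > 0) idx[pick_fg] <- fg_idx[sample.int(length(fg_idx), nf,
                                                  replace = TRUE)]
    if (nf < n) idx[!pick_fg] <- bg_idx[sample.int(length(bg_idx), n - nf,
                                                   replace = TRUE)]
    coord <- arrayInd(idx, d)
    half <- size %/% 2
    tibble(
      slice = as.integer(coord[, 3]),
      row = as.integer(clamp(coord[, 1], half + 1L, d[1] - (size - half) + 1L)),
      col = as.integer(clamp(coord[, 2], half + 1L, d[2] - (size - half) + 1L)),
      stratum = ifelse(pick_fg, "label", "background")
    )
  })
}

#' Extract one square patch from a slice
#'
#' Cuts a `size` x `size` window centred at `center` from an intensity slice
#' and its label slice. Centres nearer than `size / 2` to a border are
#' clamped inward, so the window always lies fully inside the slice and no
#' padding is ever introduced.
#'
#' @param slice 2D numeric matrix of intensities.
#' @param mask_slice 2D integer matrix of labels, same shape.
#' @param center length-2 (row, col) centre.
#' @param size window edge length (must not exceed either slice dimension).
#' @return A list with `patch`, `label_patch` (both `size` x `size`) and
#'   `origin`, the 1-based (row, col) of the window's top-left corner.
#' @export
extract_patch <- function(slice, mask_slice, center, size) {
  d <- dim(slice)
  if (size > d[1] || size > d[2]) abort("patch size exceeds slice dimensions")
  half <- size %/% 2
  r0 <- clamp(center[1] - half, 1L, d[1] - size + 1L)
  c0 <- clamp(center[2] - half, 1L, d[2] - size + 1L)
  rows <- r0:(r0 + size - 1L)
  cols <- c0:(c0 + size - 1L)
  list(patch = slice[rows, cols, drop = FALSE],
       label_patch = mask_slice[rows, cols, drop = FALSE],
       origin = c(as.integer(r0), as.integer(c0)))
}

#' Cross-validation fold construction
#'
#' Builds `k` folds with a train:validation:test split in the given
#' proportions of the cohort (70:10:20 by default). The cohort is shuffled
#' deterministically by `seed` and partitioned into `k` equal test blocks,
#' so every case appears in exactly one fold's test set; the remaining cases
#' of each fold are split into train and validation.
#'
#' @param case_ids character vector of unique case identifiers.
#' @param k number of folds.
#' @param ratios train/validation/test proportions (must sum to 1).
#' @param seed integer RNG seed for the shuffle.
#' @return A list of `k` fold splits, each a list with `fold_id`, `train`,
#'   `val`, `test`.
#' @export
make_folds <- function(case_ids, k = 5L, ratios = c(0.7, 0.1, 0.2), seed = 1L) {
  n <- length(case_ids)
  if (anyDuplicated(case_ids)) abort("case_ids must be unique")
  if (n < k) abort("fewer cases than folds")
  if (abs(sum(ratios) - 1) > 1e-8) abort("ratios must sum to 1")
  with_seed(seed, {
    shuffled <- sample(case_ids)
    blocks <- split(shuffled, rep(seq_len(k), length.out = n))
    n_val <- max(1L, round(ratios[2] * n))
    lapply(seq_len(k), function(i) {
      test <- blocks[[i]]
      rest <- setdiff(shuffled, test)
      # deterministic per-fold rotation of the remainder for the val split
      rot <- ((i - 1L) * n_val) %% length(rest)
      rest_rot <- if (rot == 0L) rest else c(rest[-seq_len(rot)],
                                             rest[seq_len(rot)])
      val <- rest_rot[seq_len(n_val)]
      train <- setdiff(rest_rot, val)
      list(fold_id = i, train = train, val = val, test = test)
    })
  })
}

#' Serialize fold splits to JSON
#'
#' @param folds result of [make_folds()].
#' @param path output JSON file.
#' @export
write_folds <- function(folds, path) {
  jsonlite::write_json(folds, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_folds
#' @export
read_folds <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(f) {
    list(fold_id = as.integer(f$fold_id),
         train = as.character(unlist(f$train)),
         val = as.character(unlist(f$val)),
         test = as.character(unlist(f$test)))
  })
}
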