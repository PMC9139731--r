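#' Full-resolution volume prediction
#'
#' Forwards each coronal slice of a normalized volume independently through a
#' 2D network, stacks the per-slice class probabilities into a 3-channel
#' probability volume, and derives hard labels by per-voxel argmax (ties
#' broken toward the lower class index). The networks are fully
#' convolutional, so a model trained on patches applies directly to
#' full-size slices.
#'
#' @param model a `pkdseg_model` (or a bare `pkdseg_net`).
#' @param volume a normalized `volume_grid` (see [zscore_normalize()]).
#' @param postprocess apply [largest_component_filter()] to the labels.
#' @param case_id optional identifier carried into the result.
#' @return A list of class `segmentation_result`: `prob` (4D array
#'   H x W x slices x 3), `labels` (`label_mask`), `post_labels`
#'   (`label_mask`, equal to `labels` when `postprocess = FALSE`), `case_id`.
#' @export
predict_volume <- function(model, volume, postprocess = TRUE,
                           case_id = NA_character_) {
  net <- if (inherits(model, "pkdseg_model")) model$net else model
  stopifnot(inherits(net, "pkdseg_net"), inherits(volume, "volume_grid"))
  d <- dim(volume$data)
  div <- 2L^(net$spec$depth - 1L)
  if (d[1] %% div != 0L || d[2] %% div != 0L) {
    abort(sprintf("slice size %dx%d incompatible with network depth %d",
                  d[1], d[2], net$spec$depth))
  }
  prob <- array(0, c(d[1], d[2], d[3], 3L))
  lab <- array(0L, d)
  for (sl in seq_len(d[3])) {
    x <- array(volume$data[, , sl], c(d[1], d[2], 1L, 1L))
    fw <- net_forward(net, x, train = FALSE)
    p <- matrix(fw$probs, ncol = 3L)
    prob[, , sl, ] <- array(p, c(d[1], d[2], 1L, 3L))
    lab[, , sl] <- matrix(max.col(p, ties.method = "first") - 1L, d[1], d[2])
  }
  labels <- label_mask(lab, volume$spacing)
  post <- if (postprocess) largest_component_filter(labels) else labels
  structure(list(prob = prob, labels = labels, post_labels = post,
                 case_id = case_id),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  d <- dim(x$labels$data)
  cat(sprintf("<segmentation_result> %s: %d x %d x %d, %d kidney voxels\n",
              x$case_id, d[1], d[2], d[3], sum(x$post_labels$data != 0L)))
  invisible(x)
}

# Connected components of a logical 3D array under face (6-neighbour)
# connectivity, via the adjacency graph of foreground voxels. Returns an
# integer array of component labels (0 = background).
connected_components_3d <- function(b) {
  d <- dim(b)
  idx <- which(b)
  out <- array(0L, d)
  if (length(idx) == 0) return(out)
  pos <- array(0L, d)
  pos[idx] <- seq_along(idx)
  co <- arrayInd(idx, d)
  edges <- integer(0)
  # neighbour in +direction along each axis
  for (ax in 1:3) {
    step <- c(1L, d[1], d[1] * d[2])[ax]
    ok <- co[, ax] < d[ax]
    nb <- idx[ok] + step
    nb_ok <- b[nb]
    from <- pos[idx[ok][nb_ok]]
    to <- pos[nb[nb_ok]]
    edges <- c(edges, rbind(from, to))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  comp <- as.integer(igraph::components(g)$membership)
  out[idx] <- comp
  out
}

#' Largest-connected-component post-processing
#'
#' For each foreground class independently, keeps only the largest
#' face-connected (6-neighbourhood) 3D component and relabels all other
#' voxels of that class as background. Component-size ties are broken in
#' favour of the component containing the lowest linear voxel index. The
#' filter never adds foreground voxels and is idempotent.
#'
#' @param labels a `label_mask`.
#' @param connectivity `6` (faces) is the only supported option.
#' @return A filtered `label_mask`.
#' @export
largest_component_filter <- function(labels, connectivity = 6L) {
  stopifnot(inherits(labels, "label_mask"))
  if (connectivity != 6L) abort("only 6-connectivity is implemented")
  m <- labels$data
  out <- m
  for (cls in 1:2) {
    b <- m == cls
    if (!any(b)) next
    comp <- connected_components_3d(b)
    sizes <- tabulate(comp[comp > 0L])
    best <- which(sizes == max(sizes))
    if (length(best) > 1L) {
      # tie: keep the component whose first (lowest-index) voxel comes first
      firsts <- vapply(best, function(k) which(comp == k)[1L], integer(1))
      best <- best[which.min(firsts)]
    }
    out[b & comp != best] <- 0L
  }
  label_mask(out, labels$spacing)
}
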