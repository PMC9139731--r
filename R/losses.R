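# Training objectives. All losses take a prediction array of per-voxel class
# probabilities and a one-hot target of the same shape, with the class axis
# last. Sums run over all classes including background. Each loss has a
# companion *_grad returning both the value and the analytic gradient with
# respect to the probabilities (used by the training loop, which chains it
# through the softmax).

as_class_matrix <- function(x) {
  d <- dim(x)
  if (is.null(d)) abort("loss inputs must be arrays with a trailing class axis")
  matrix(x, ncol = d[length(d)])
}

check_loss_inputs <- function(pred, target) {
  if (!identical(dim(pred), dim(target))) {
    abort("prediction and target must have identical shape")
  }
}

#' One-hot encode an integer label array
#'
#' @param labels integer array with values in `0:(n_classes-1)`.
#' @param n_classes number of classes.
#' @return A numeric array with one extra trailing class axis.
#' @export
one_hot <- function(labels, n_classes = 3L) {
  d <- dim(labels) %||% length(labels)
  v <- as.integer(labels)
  out <- numeric(length(v) * n_classes)
  out[seq_along(v) + as.numeric(v) * length(v)] <- 1
  array(out, c(d, n_classes))
}

#' Soft Dice segmentation loss
#'
#' \eqn{1 - 2 \sum_c \sum_i \hat y_{i,c} y_{i,c} /
#' (\sum_c \sum_i \hat y_{i,c} + \sum_c \sum_i y_{i,c})}, summing over all
#' classes (background included) and all voxels of the batch. Zero exactly
#' when the prediction equals the one-hot target.
#'
#' @param pred array of class probabilities, class axis last.
#' @param target one-hot array of identical shape.
#' @return Scalar loss in `[0, 1]`.
#' @export
dsc_loss <- function(pred, target) dsc_loss_grad(pred, target)$loss

dsc_loss_grad <- function(pred, target) {
  check_loss_inputs(pred, target)
  inter <- sum(pred * target)
  denom <- sum(pred) + sum(target)
  if (denom == 0) abort("Dice loss undefined: prediction and target sum to 0")
  loss <- 1 - 2 * inter / denom
  dpred <- array(-2 * target / denom + 2 * inter / denom^2, dim(pred))
  list(loss = loss, dpred = dpred)
}

#' Cross-entropy segmentation loss
#'
#' \eqn{-\sum_c \sum_i y_{i,c} \log \hat y_{i,c} / (c \cdot N)} with `c` the
#' number of classes and `N` the number of voxels in the batch. Probabilities
#' are clipped to `[eps, 1]` before the log.
#'
#' @inheritParams dsc_loss
#' @param eps numerical floor for the log argument.
#' @return Scalar loss, `>= 0`.
#' @export
ce_loss <- function(pred, target, eps = 1e-7) {
  ce_loss_grad(pred, target, eps)$loss
}

ce_loss_grad <- function(pred, target, eps = 1e-7) {
  check_loss_inputs(pred, target)
  d <- dim(pred)
  C <- d[length(d)]
  N <- prod(d[-length(d)])
  p <- pmax(pred, eps)
  loss <- -sum(target * log(p)) / (C * N)
  dpred <- array(-target / (p * C * N), d)
  list(loss = loss, dpred = dpred)
}

#' Combined cross-entropy + Dice loss
#'
#' \eqn{L_{DSC} + \lambda L_{CE}} with \eqn{\lambda = 10} by default.
#'
#' @inheritParams ce_loss
#' @param lambda weight of the cross-entropy term.
#' @export
combined_loss <- function(pred, target, lambda = 10, eps = 1e-7) {
  dsc_loss(pred, target) + lambda * ce_loss(pred, target, eps)
}

combined_loss_grad <- function(pred, target, lambda = 10, eps = 1e-7) {
  a <- dsc_loss_grad(pred, target)
  b <- ce_loss_grad(pred, target, eps)
  list(loss = a$loss + lambda * b$loss,
       dpred = a$dpred + lambda * b$dpred)
}

#' Cosine segmentation loss
#'
#' One minus the cosine similarity between the flattened prediction and
#' one-hot target tensors,
#' \eqn{1 - \langle \hat Y, Y\rangle / (\|\hat Y\|_2 \|Y\|_2)}. By default a
#' single global flattening over all voxels and classes of the batch is used;
#' `per_class = TRUE` instead averages one cosine loss per class channel.
#' The loss is invariant to positive rescaling of the prediction and lies in
#' `[0, 1]` for non-negative inputs.
#'
#' @inheritParams dsc_loss
#' @param per_class compute one cosine term per class and average.
#' @export
cosine_loss <- function(pred, target, per_class = FALSE) {
  cosine_loss_grad(pred, target, per_class)$loss
}

cosine_loss_grad <- function(pred, target, per_class = FALSE) {
  check_loss_inputs(pred, target)
  if (per_class) {
    P <- as_class_matrix(pred)
    Y <- as_class_matrix(target)
    C <- ncol(P)
    dP <- matrix(0, nrow(P), C)
    losses <- numeric(C)
    for (c in seq_len(C)) {
      g <- cosine_flat_grad(P[, c], Y[, c])
      losses[c] <- g$loss
      dP[, c] <- g$dp
    }
    list(loss = mean(losses), dpred = array(dP / C, dim(pred)))
  } else {
    g <- cosine_flat_grad(as.vector(pred), as.vector(target))
    list(loss = g$loss, dpred = array(g$dp, dim(pred)))
  }
}

cosine_flat_grad <- function(p, y) {
  np <- sqrt(sum(p^2)); ny <- sqrt(sum(y^2))
  if (np == 0 || ny == 0) abort("cosine loss undefined for a zero-norm operand")
  ip <- sum(p * y)
  S <- ip / (np * ny)
  dp <- -(y / (np * ny) - S * p / np^2)
  list(loss = 1 - S, dp = dp)
}

# Loss registry keyed by the configuration names used throughout the package.
get_loss <- function(key, lambda = 10) {
  switch(key,
    dsc = function(pred, target) dsc_loss_grad(pred, target),
    ce_dsc = function(pred, target) combined_loss_grad(pred, target, lambda),
    cosine = function(pred, target) cosine_loss_grad(pred, target),
    abort(sprintf("unknown loss key '%s' (use dsc, ce_dsc or cosine)", key)))
}
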