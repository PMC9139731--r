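#' Ensemble configuration
#'
#' @param method `"staple"` or `"voting"`.
#' @param max_iter maximum STAPLE EM iterations.
#' @param tol convergence threshold on the mean absolute change of the
#'   posterior between iterations.
#' @param init_p,init_q initial per-rater sensitivity / specificity.
#' @return A list of class `ensemble_config`.
#' @export
ensemble_config <- function(method = c("staple", "voting"), max_iter = 100L,
                            tol = 1e-7, init_p = 0.99999, init_q = 0.99999) {
  structure(list(method = match.arg(method), max_iter = as.integer(max_iter),
                 tol = tol, init_p = init_p, init_q = init_q),
            class = "ensemble_config")
}

check_mask_list <- function(masks) {
  if (length(masks) < 1L) abort("need at least one mask")
  d <- dim(masks[[1]]$data)
  for (m in masks) {
    stopifnot(inherits(m, "label_mask"))
    if (!identical(dim(m$data), d)) abort("masks must share a common shape")
  }
  d
}

#' Majority-vote label fusion
#'
#' Per voxel, the class with the most votes among the member masks wins. Any
#' tie for the maximum — whether it involves background or only the two
#' kidney classes — resolves to background (conservative rule).
#'
#' @param masks list of `label_mask` objects of a common shape.
#' @return The fused `label_mask`.
#' @export
majority_vote <- function(masks) {
  d <- check_mask_list(masks)
  if (length(masks) < 2L) abort("majority voting needs at least two members")
  n0 <- array(0L, d); n1 <- array(0L, d); n2 <- array(0L, d)
  for (m in masks) {
    v <- m$data
    n0 <- n0 + (v == 0L)
    n1 <- n1 + (v == 1L)
    n2 <- n2 + (v == 2L)
  }
  out <- array(0L, d)
  out[n1 > n0 & n1 > n2] <- 1L
  out[n2 > n0 & n2 > n1] <- 2L
  label_mask(out, masks[[1]]$spacing)
}

# Binary STAPLE EM for one foreground class. dmat: voxels x raters 0/1
# matrix restricted to voxels where any rater voted foreground; n_bg: count
# of all-background voxels (treated in closed form); prior: spatially
# constant foreground prior.
staple_binary <- function(dmat, n_bg, prior, config) {
  J <- ncol(dmat)
  p <- rep(config$init_p, J)
  q <- rep(config$init_q, J)
  w <- rowMeans(dmat)
  w_bg <- 0
  loglik <- numeric(0)
  converged <- FALSE
  for (it in seq_len(config$max_iter)) {
    # E-step in log space
    la <- log(prior) + dmat %*% log(p) + (1 - dmat) %*% log(1 - p)
    lb <- log1p(-prior) + (1 - dmat) %*% log(q) + dmat %*% log(1 - q)
    mx <- pmax(la, lb)
    a <- exp(la - mx); bb <- exp(lb - mx)
    w_new <- as.vector(a / (a + bb))
    ll <- sum(mx + log(a + bb))
    # all-background voxels contribute a closed-form block
    la_bg <- log(prior) + sum(log(1 - p))
    lb_bg <- log1p(-prior) + sum(log(q))
    mb <- max(la_bg, lb_bg)
    w_bg_new <- exp(la_bg - mb) / (exp(la_bg - mb) + exp(lb_bg - mb))
    ll <- ll + n_bg * (mb + log(exp(la_bg - mb) + exp(lb_bg - mb)))
    loglik <- c(loglik, ll)
    delta <- (sum(abs(w_new - w)) + n_bg * abs(w_bg_new - w_bg)) /
      (nrow(dmat) + n_bg)
    w <- w_new; w_bg <- w_bg_new
    # M-step
    sw <- sum(w) + w_bg * n_bg
    s1w <- sum(1 - w) + (1 - w_bg) * n_bg
    p <- pmin(pmax(colSums(dmat * w) / sw, 1e-8), 1 - 1e-8)
    q <- pmin(pmax((colSums((1 - dmat) * (1 - w)) + (1 - w_bg) * n_bg) / s1w,
                   1e-8), 1 - 1e-8)
    if (it > 1 && delta < config$tol) {
      converged <- TRUE
      break
    }
  }
  list(w = w, w_bg = w_bg, p = as.vector(p), q = as.vector(q),
       loglik = loglik, converged = converged)
}

#' STAPLE consensus
#'
#' Runs binary simultaneous-truth-and-performance-level-estimation EM once
#' per foreground class: the E-step computes the per-voxel posterior that
#' the voxel truly belongs to the class given current rater sensitivities
#' `p_j` and specificities `q_j`; the M-step re-estimates `p_j`, `q_j` from
#' the posterior. The spatial prior is the mean foreground rate across
#' members (spatially constant). A voxel is assigned to a class when its
#' posterior exceeds 0.5; a voxel claimed by both classes goes to the class
#' with the higher posterior.
#'
#' @param masks list of `label_mask` objects of a common shape.
#' @param config an [ensemble_config()].
#' @return A list of class `staple_result` with `mask` (fused `label_mask`)
#'   and `estimate`, which carries per-class tibbles of rater sensitivities /
#'   specificities, the EM log-likelihood traces, and convergence flags.
#' @export
staple_consensus <- function(masks, config = ensemble_config("staple")) {
  d <- check_mask_list(masks)
  J <- length(masks)
  post <- array(0, c(prod(d), 2L))
  perf <- list()
  trace <- list()
  warn_flag <- FALSE
  for (cls in 1:2) {
    bin <- vapply(masks, function(m) as.numeric(m$data == cls),
                  numeric(prod(d)))
    any_fg <- rowSums(bin) > 0
    prior <- mean(bin)
    if (prior == 0) {
      perf[[cls]] <- tibble(rater = seq_len(J), sensitivity = NA_real_,
                            specificity = NA_real_)
      trace[[cls]] <- numeric(0)
      next
    }
    fit <- staple_binary(bin[any_fg, , drop = FALSE], sum(!any_fg), prior,
                         config)
    if (!fit$converged) {
      warn_flag <- TRUE
      warn(sprintf("STAPLE for class %d did not converge in %d iterations",
                   cls, config$max_iter))
    }
    pc <- numeric(prod(d))
    pc[any_fg] <- fit$w
    pc[!any_fg] <- fit$w_bg
    post[, cls] <- pc
    perf[[cls]] <- tibble(rater = seq_len(J), sensitivity = fit$p,
                          specificity = fit$q)
    trace[[cls]] <- fit$loglik
  }
  lab <- integer(prod(d))
  take1 <- post[, 1] > 0.5 & post[, 1] >= post[, 2]
  take2 <- post[, 2] > 0.5 & post[, 2] > post[, 1]
  lab[take1] <- 1L
  lab[take2] <- 2L
  structure(list(
    mask = label_mask(array(lab, d), masks[[1]]$spacing),
    estimate = list(performance = perf, loglik = trace,
                    posterior = array(post, c(d, 2L)),
                    converged = !warn_flag)),
    class = "staple_result")
}

#' Fuse an ensemble of segmentation results
#'
#' Applies majority voting or STAPLE to the (by default post-processed) hard
#' labels of several [predict_volume()] results.
#'
#' @param results list of `segmentation_result` objects for the same case.
#' @param method `"voting"` or `"staple"`.
#' @param use_postprocessed fuse `post_labels` (default) or raw `labels`.
#' @param config an [ensemble_config()] (STAPLE only).
#' @return The fused `label_mask`.
#' @export
fuse_ensemble <- function(results, method = c("voting", "staple"),
                          use_postprocessed = TRUE,
                          config = ensemble_config("staple")) {
  method <- match.arg(method)
  masks <- lapply(results, function(r) {
    if (use_postprocessed) r$post_labels else r$labels
  })
  if (method == "voting") majority_vote(masks) else
    staple_consensus(masks, config)$mask
}
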