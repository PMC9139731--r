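# Parameter trees are nested named lists with numeric leaves. These helpers
# apply elementwise operations across whole trees (used by the optimizers and
# for parameter counting).

tree_map <- function(f, t) {
  if (is.null(t)) return(NULL)
  if (is.numeric(t)) return(f(t))
  lapply(t, function(x) tree_map(f, x))
}

# Trees are paired by element name where names exist (sub-lists may be
# assembled in a different order by the backward pass), by position otherwise.
tree_map2 <- function(f, a, b) {
  if (is.null(a)) return(NULL)
  if (is.numeric(a)) return(f(a, b))
  out <- vector("list", length(a))
  names(out) <- names(a)
  nms <- names(a)
  for (i in seq_along(a)) {
    bi <- if (!is.null(nms) && nzchar(nms[i])) b[[nms[i]]] else b[[i]]
    out[i] <- list(tree_map2(f, a[[i]], bi))  # [i]<-list() keeps NULL slots
  }
  out
}

# like tree_map2 but the function also receives the leaf's name
tree_map2_named <- function(f, a, b, name = "") {
  if (is.null(a)) return(NULL)
  if (is.numeric(a)) return(f(a, b, name))
  out <- vector("list", length(a))
  names(out) <- names(a)
  nms <- names(a)
  for (i in seq_along(a)) {
    bi <- if (!is.null(nms) && nzchar(nms[i])) b[[nms[i]]] else b[[i]]
    out[i] <- list(tree_map2_named(f, a[[i]], bi, nms[i] %||% ""))
  }
  out
}

tree_reduce <- function(f, t, init = 0) {
  acc <- init
  rec <- function(x) {
    if (is.null(x)) return(invisible(NULL))
    if (is.numeric(x)) {
      acc <<- f(acc, x)
      return(invisible(NULL))
    }
    for (e in x) rec(e)
  }
  rec(t)
  acc
}

tree_global_norm <- function(t) {
  sqrt(tree_reduce(function(acc, x) acc + sum(x^2), t))
}

tree_count <- function(t) tree_reduce(function(acc, x) acc + length(x), t)

tree_finite <- function(t) {
  tree_reduce(function(acc, x) acc && all(is.finite(x)), t, init = TRUE)
}

#' Build a 2D segmentation network
#'
#' Constructs one of four fully-convolutional residual U-Net variants for
#' 3-class kidney segmentation:
#' \describe{
#'   \item{`baseline_unet`}{residual 2D U-Net.}
#'   \item{`attention_unet`}{adds attention gates on the skip connections,
#'     driven by the coarser decoder feature as gating signal.}
#'   \item{`se_unet`}{the Attention U-Net with a squeeze-and-excitation block
#'     after each encoder stage.}
#'   \item{`cbam_unet`}{the Attention U-Net with a convolutional block
#'     attention module after each encoder stage.}
#' }
#' Convolution blocks use batch normalization and elu activations with an
#' identity-add residual connection; attention-gate internals use ReLU and
#' sigmoid. The network is fully convolutional: it can be trained on patches
#' and applied to any input whose side lengths are divisible by
#' `2^(depth - 1)`.
#'
#' @param variant one of `"baseline_unet"`, `"attention_unet"`, `"se_unet"`,
#'   `"cbam_unet"`.
#' @param depth number of resolution levels (including the bottleneck).
#' @param base_filters channels at the finest level; doubled per level.
#' @param dropout dropout probability inside conv blocks (training only).
#' @param l2 L2 weight-decay coefficient applied to convolution and dense
#'   weights by the optimizer.
#' @param seed RNG seed for weight initialization (deterministic).
#' @param se_reduction,cbam_reduction bottleneck reduction ratio of the SE /
#'   CBAM channel MLPs.
#' @param spatial_kernel CBAM spatial-attention convolution kernel size.
#' @param n_classes number of output classes (3: background, left, right).
#' @return An object of class `pkdseg_net` with elements `spec`, `params`,
#'   `state`.
#' @export
build_network <- function(variant = c("baseline_unet", "attention_unet",
                                      "se_unet", "cbam_unet"),
                          depth = 4L, base_filters = 32L, dropout = 0.01,
                          l2 = 1e-7, seed = 1L, se_reduction = 8L,
                          cbam_reduction = 8L, spatial_kernel = 7L,
                          n_classes = 3L) {
  variant <- match.arg(variant)
  depth <- as.integer(depth)
  stopifnot(depth >= 2L, base_filters >= 1L)
  filters <- base_filters * 2L^(seq_len(depth) - 1L)
  has_gates <- variant != "baseline_unet"
  with_seed(seed, {
    params <- list(enc = vector("list", depth - 1L),
                   dec = vector("list", depth - 1L))
    state <- list(enc = vector("list", depth - 1L),
                  dec = vector("list", depth - 1L))
    cin <- 1L
    for (l in seq_len(depth - 1L)) {
      rb <- res_block_init(cin, filters[l])
      attn <- switch(variant,
        se_unet = se_block_init(filters[l], se_reduction)$params,
        cbam_unet = cbam_block_init(filters[l], cbam_reduction,
                                    spatial_kernel)$params,
        NULL)
      params$enc[[l]] <- list(block = rb$params, attn = attn)
      state$enc[[l]] <- list(block = rb$state)
      cin <- filters[l]
    }
    bott <- res_block_init(filters[depth - 1L], filters[depth])
    params$bott <- bott$params
    state$bott <- bott$state
    for (l in rev(seq_len(depth - 1L))) {
      cg <- filters[l + 1L]
      upconv <- conv_init(3L, cg, filters[l])
      gate <- if (has_gates) {
        attention_gate_init(cg, filters[l], max(1L, filters[l] %/% 2L))$params
      }
      rb <- res_block_init(2L * filters[l], filters[l])
      params$dec[[l]] <- list(upconv = upconv, gate = gate,
                              block = rb$params)
      state$dec[[l]] <- list(block = rb$state)
    }
    params$head <- conv_init(1L, filters[1L], n_classes)
    structure(list(
      spec = list(variant = variant, depth = depth,
                  base_filters = as.integer(base_filters),
                  dropout = dropout, l2 = l2, seed = as.integer(seed),
                  se_reduction = se_reduction,
                  cbam_reduction = cbam_reduction,
                  spatial_kernel = spatial_kernel,
                  n_classes = as.integer(n_classes)),
      params = params, state = state), class = "pkdseg_net")
  })
}

#' @export
print.pkdseg_net <- function(x, ...) {
  cat(sprintf("<pkdseg_net> %s, depth %d, base filters %d, %d parameters\n",
              x$spec$variant, x$spec$depth, x$spec$base_filters,
              n_parameters(x)))
  invisible(x)
}

#' Number of trainable parameters of a network
#' @param net a `pkdseg_net`.
#' @return integer count.
#' @export
n_parameters <- function(net) tree_count(net$params)

# Forward pass. x: (H, W, N, 1) array with H, W divisible by 2^(depth-1).
# Returns probs, logits, the cache tree for the backward pass and the
# (possibly updated) batch-norm state.
net_forward <- function(net, x, train = FALSE, update_state = TRUE) {
  spec <- net$spec
  p <- net$params; s <- net$state
  d <- dim(x)
  div <- 2L^(spec$depth - 1L)
  if (d[1] %% div != 0L || d[2] %% div != 0L) {
    abort(sprintf("input size %dx%d not divisible by 2^(depth-1) = %d",
                  d[1], d[2], div))
  }
  drop <- spec$dropout
  cache <- list(enc = vector("list", spec$depth - 1L),
                dec = vector("list", spec$depth - 1L))
  skips <- vector("list", spec$depth - 1L)
  h <- x
  for (l in seq_len(spec$depth - 1L)) {
    rb <- res_block_fwd(p$enc[[l]]$block, s$enc[[l]]$block, h, train, drop,
                        update_state)
    s$enc[[l]]$block <- rb$state
    a <- rb$out
    attn_cache <- NULL
    if (spec$variant == "se_unet") {
      ab <- se_block_fwd(p$enc[[l]]$attn, a)
      a <- ab$out; attn_cache <- ab$cache
    } else if (spec$variant == "cbam_unet") {
      ab <- cbam_block_fwd(p$enc[[l]]$attn, a, spec$spatial_kernel)
      a <- ab$out; attn_cache <- ab$cache
    }
    skips[[l]] <- a
    mp <- maxpool2_fwd(a)
    cache$enc[[l]] <- list(block = rb$cache, attn = attn_cache,
                           pool = mp$cache)
    h <- mp$out
  }
  rb <- res_block_fwd(p$bott, s$bott, h, train, drop, update_state)
  s$bott <- rb$state
  cache$bott <- rb$cache
  h <- rb$out
  for (l in rev(seq_len(spec$depth - 1L))) {
    g <- h
    up <- upsample2_fwd(h)
    uc <- conv2d_fwd(up, p$dec[[l]]$upconv$W, p$dec[[l]]$upconv$b, 3L)
    ua <- elu_fwd(uc$out)
    if (!is.null(p$dec[[l]]$gate)) {
      gt <- attention_gate_fwd(p$dec[[l]]$gate, g, skips[[l]])
      sk <- gt$out; gate_cache <- gt$cache
    } else {
      sk <- skips[[l]]; gate_cache <- NULL
    }
    du <- dim(ua$out)
    cat_out <- array(c(ua$out, sk), c(du[1], du[2], du[3], du[4] + dim(sk)[4]))
    rb <- res_block_fwd(p$dec[[l]]$block, s$dec[[l]]$block, cat_out, train,
                        drop, update_state)
    s$dec[[l]]$block <- rb$state
    cache$dec[[l]] <- list(uc = uc, ua = ua$cache, gate = gate_cache,
                           block = rb$cache, n_up = du[4])
    h <- rb$out
  }
  hd <- conv2d_fwd(h, p$head$W, p$head$b, 1L)
  cache$head <- hd
  probs <- softmax_channels(hd$out)
  list(probs = probs, logits = hd$out, cache = cache, state = s)
}

# Backward pass from dL/dlogits; returns the gradient tree (same shape as
# net$params).
net_backward <- function(net, cache, dlogits) {
  spec <- net$spec
  p <- net$params
  g <- list(enc = vector("list", spec$depth - 1L),
            dec = vector("list", spec$depth - 1L))
  hb <- conv2d_bwd(dlogits, cache$head, p$head$W)
  g$head <- list(W = hb$dW, b = hb$db)
  dh <- hb$dx
  dskips <- vector("list", spec$depth - 1L)
  for (l in seq_len(spec$depth - 1L)) {
    cc <- cache$dec[[l]]
    rbb <- res_block_bwd(p$dec[[l]]$block, cc$block, dh)
    dcat <- rbb$dx
    n_up <- cc$n_up
    dc <- dim(dcat)
    dua <- dcat[, , , seq_len(n_up), drop = FALSE]
    dsk <- dcat[, , , n_up + seq_len(dc[4] - n_up), drop = FALSE]
    duc <- elu_bwd(dua, cc$ua)
    ucb <- conv2d_bwd(duc, cc$uc, p$dec[[l]]$upconv$W)
    dprev <- upsample2_bwd(ucb$dx)
    gate_grads <- NULL
    if (!is.null(cc$gate)) {
      gb <- attention_gate_bwd(p$dec[[l]]$gate, cc$gate, dsk)
      dprev <- dprev + gb$dg
      dskips[[l]] <- gb$dxl
      gate_grads <- gb$grads
    } else {
      dskips[[l]] <- dsk
    }
    g$dec[[l]] <- list(upconv = list(W = ucb$dW, b = ucb$db),
                       gate = gate_grads, block = rbb$grads)
    dh <- dprev
  }
  rbb <- res_block_bwd(p$bott, cache$bott, dh)
  g$bott <- rbb$grads
  dh <- rbb$dx
  for (l in rev(seq_len(spec$depth - 1L))) {
    cc <- cache$enc[[l]]
    da <- maxpool2_bwd(dh, cc$pool) + dskips[[l]]
    attn_grads <- NULL
    if (spec$variant == "se_unet") {
      ab <- se_block_bwd(p$enc[[l]]$attn, cc$attn, da)
      da <- ab$dx; attn_grads <- ab$grads
    } else if (spec$variant == "cbam_unet") {
      ab <- cbam_block_bwd(p$enc[[l]]$attn, cc$attn, da)
      da <- ab$dx; attn_grads <- ab$grads
    }
    rbe <- res_block_bwd(p$enc[[l]]$block, cc$block, da)
    g$enc[[l]] <- list(block = rbe$grads, attn = attn_grads)
    dh <- rbe$dx
  }
  g
}

# Note: net_backward walks the decoder from fine to coarse, but the forward
# pass ran coarse to fine, so the loops above must mirror each other exactly;
# the decoder backward loop therefore iterates l = 1 .. depth-1 (fine first).
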