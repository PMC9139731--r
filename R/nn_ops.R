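# Low-level differentiable array operations.
#
# Feature maps are 4D double arrays with layout (H, W, N, C): spatial rows,
# spatial columns, batch, channels. All convolutions are stride-1 with
# "same" zero padding; the gradient of such a convolution with respect to its
# input is again a same-padded convolution with the spatially flipped,
# channel-transposed kernel, so a single conv primitive serves both passes.
# Convolution itself is im2col + BLAS matrix multiply.

# im2col by k^2 contiguous block copies: for each kernel offset (di, dj)
# the corresponding columns of the im2col matrix are a shifted sub-array of
# the padded input, so the whole matrix is assembled from k*k slice copies
# instead of per-element gathers. Kernel matrices store rows in the order
# (cin fastest, then di, then dj) to keep each block's columns contiguous.
im2col <- function(xp, H, W, N, C, k) {
  dp <- dim(xp)
  im2col_cpp(xp, dp[1], dp[2], N, C, H, W, k)
}

add_bias <- function(y, b) add_bias_cpp(y, b)

pad_hw <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  pad_hw_cpp(x, d[1], d[2], d[3], d[4], p)
}

# Same-padded stride-1 2D convolution. `W` is a (k*k*Cin) x Cout matrix with
# rows ordered (di, dj, cin); `b` length Cout. Returns out and the im2col
# matrix (needed for the weight gradient).
conv2d_fwd <- function(x, W, b, k) {
  d <- dim(x)
  p <- (k - 1L) %/% 2L
  xp <- pad_hw(x, p)
  cols <- im2col(xp, d[1], d[2], d[3], d[4], k)
  y <- cols %*% W
  y <- add_bias(y, b)
  Cout <- ncol(W)
  dim(y) <- c(d[1], d[2], d[3], Cout)
  list(out = y, cols = cols, in_dim = d, k = k)
}

# Rearrange W for the input-gradient pass: spatial flip + channel transpose.
# The permutation depends only on (k, Cin, Cout) and is cached.
.flip_cache <- new.env(parent = emptyenv())

flip_perm <- function(k, Cin, Cout) {
  key <- paste(k, Cin, Cout, sep = "_")
  hit <- .flip_cache[[key]]
  if (!is.null(hit)) return(hit)
  # rows of W are ordered (cin, di, dj); the flipped kernel has rows
  # (cout, di, dj) with both spatial offsets mirrored
  src <- array(seq_len(Cin * k * k * Cout), c(Cin, k, k, Cout))
  perm <- as.vector(aperm(src[, k:1, k:1, , drop = FALSE], c(4, 2, 3, 1)))
  .flip_cache[[key]] <- perm
  perm
}

flip_kernel <- function(W, k, Cin, Cout) {
  Wf <- W[flip_perm(k, Cin, Cout)]
  dim(Wf) <- c(k * k * Cout, Cin)
  Wf
}

conv2d_bwd <- function(dout, cache, W) {
  d <- cache$in_dim
  k <- cache$k
  Cout <- ncol(W)
  Cin <- d[4]
  dy <- matrix(dout, nrow = d[1] * d[2] * d[3], ncol = Cout)
  dW <- crossprod(cache$cols, dy)
  db <- colSums(dy)
  Wf <- flip_kernel(W, k, Cin, Cout)
  p <- (k - 1L) %/% 2L
  dyp <- pad_hw(array(dout, c(d[1], d[2], d[3], Cout)), p)
  colsb <- im2col(dyp, d[1], d[2], d[3], Cout, k)
  dx <- colsb %*% Wf
  dim(dx) <- d
  list(dx = dx, dW = dW, db = db)
}

conv_init <- function(k, Cin, Cout) {
  list(W = matrix(rnorm(k * k * Cin * Cout, 0, sqrt(2 / (k * k * Cin))),
                  nrow = k * k * Cin, ncol = Cout),
       b = numeric(Cout))
}

# --- batch normalization (per channel over space and batch) ----------------

bn_init <- function(C) {
  list(params = list(gamma = rep(1, C), beta = numeric(C)),
       state = list(mean = numeric(C), var = rep(1, C)))
}

bn_fwd <- function(x, gamma, beta, state, train, momentum = 0.1,
                   eps = 1e-5, update_state = TRUE) {
  d <- dim(x)
  M <- d[1] * d[2] * d[3]
  if (train) {
    r <- bn_fwd_cpp(x, M, d[4], gamma, beta, eps)
    if (update_state) {
      state$mean <- (1 - momentum) * state$mean + momentum * r$mean
      state$var <- (1 - momentum) * state$var + momentum * r$var
    }
    out <- r$out
    dim(out) <- d
    return(list(out = out,
                cache = list(xhat = r$xhat, invstd = r$invstd, dims = d,
                             gamma = gamma, train = TRUE),
         state = state))
  }
  invstd <- 1 / sqrt(state$var + eps)
  X <- matrix(x, M, d[4])
  xhat <- (X - rep(state$mean, each = M)) * rep(invstd, each = M)
  Y <- xhat * rep(gamma, each = M) + rep(beta, each = M)
  list(out = array(Y, d),
       cache = list(xhat = xhat, invstd = invstd, dims = d, gamma = gamma,
                    train = FALSE),
       state = state)
}

bn_bwd <- function(dout, cache) {
  d <- cache$dims
  M <- d[1] * d[2] * d[3]
  if (cache$train) {
    r <- bn_bwd_cpp(dout, cache$xhat, M, d[4], cache$gamma, cache$invstd)
    dx <- r$dx
    dim(dx) <- d
    return(list(dx = dx, dgamma = r$dgamma, dbeta = r$dbeta))
  }
  dY <- matrix(dout, M, d[4])
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dX <- dY * rep(cache$gamma * cache$invstd, each = M)
  list(dx = array(dX, d), dgamma = dgamma, dbeta = dbeta)
}

# --- activations -----------------------------------------------------------

elu_fwd <- function(x) {
  r <- elu_fwd_cpp(x)
  list(out = r$out, cache = r$deriv)
}

elu_bwd <- function(dout, cache) dout * cache

relu_fwd <- function(x) {
  y <- x
  y[y < 0] <- 0
  list(out = y, cache = x > 0)
}

relu_bwd <- function(dout, cache) dout * cache

sigmoid <- function(x) 1 / (1 + exp(-x))

# --- dropout (inverted) ----------------------------------------------------

dropout_fwd <- function(x, rate, train) {
  if (!train || rate <= 0) return(list(out = x, cache = NULL))
  keep <- (runif(length(x)) >= rate) / (1 - rate)
  dim(keep) <- dim(x)
  list(out = x * keep, cache = keep)
}

dropout_bwd <- function(dout, cache) {
  if (is.null(cache)) dout else dout * cache
}

# --- 2x2 pooling and nearest upsampling ------------------------------------

maxpool2_fwd <- function(x) {
  d <- dim(x)
  r <- maxpool2_cpp(x, d[1], d[2], d[3] * d[4])
  out <- r$out
  dim(out) <- c(d[1] %/% 2L, d[2] %/% 2L, d[3], d[4])
  list(out = out, cache = list(argmax = r$argmax, in_dim = d))
}

maxpool2_bwd <- function(dout, cache) {
  d <- cache$in_dim
  dx <- maxpool2_bwd_cpp(dout, cache$argmax, d[1], d[2], d[3] * d[4])
  dim(dx) <- d
  dx
}

avgpool2_fwd <- function(x) {
  d <- dim(x)
  io <- seq(1L, d[1], 2L); ie <- io + 1L
  jo <- seq(1L, d[2], 2L); je <- jo + 1L
  y <- (x[io, jo, , , drop = FALSE] + x[ie, jo, , , drop = FALSE] +
        x[io, je, , , drop = FALSE] + x[ie, je, , , drop = FALSE]) / 4
  list(out = y, cache = d)
}

avgpool2_bwd <- function(dout, in_dim) {
  d <- in_dim
  dx <- array(0, d)
  q <- dout / 4
  io <- seq(1L, d[1], 2L); ie <- io + 1L
  jo <- seq(1L, d[2], 2L); je <- jo + 1L
  dx[io, jo, , ] <- q; dx[ie, jo, , ] <- q
  dx[io, je, , ] <- q; dx[ie, je, , ] <- q
  dx
}

upsample2_fwd <- function(x) {
  d <- dim(x)
  y <- upsample2_cpp(x, d[1], d[2], d[3] * d[4])
  dim(y) <- c(2L * d[1], 2L * d[2], d[3], d[4])
  y
}

upsample2_bwd <- function(dout) {
  d <- dim(dout)
  dx <- upsample2_bwd_cpp(dout, d[1], d[2], d[3] * d[4])
  dim(dx) <- c(d[1] %/% 2L, d[2] %/% 2L, d[3], d[4])
  dx
}

# --- softmax over the channel axis ----------------------------------------

softmax_channels <- function(z) {
  d <- dim(z)
  p <- softmax_cpp(z, prod(d[-length(d)]), d[length(d)])
  dim(p) <- d
  p
}

# Chain rule through softmax: given p = softmax(z) and dL/dp, return dL/dz.
softmax_bwd <- function(p, dp) {
  d <- dim(p)
  dz <- softmax_bwd_cpp(p, dp, prod(d[-length(d)]), d[length(d)])
  dim(dz) <- d
  dz
}
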