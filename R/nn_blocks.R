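# Composite network blocks: residual conv block, attention gate,
# squeeze-and-excitation, CBAM. Each block has an _init (parameters/state),
# _fwd (returns out + cache) and _bwd (returns input gradients + parameter
# gradients, mirroring the parameter structure).

# broadcast helpers ---------------------------------------------------------

expand_channel_scale <- function(s, d) {
  array(rep(as.vector(s), each = d[1] * d[2]), d)
}

channel_scale_grad <- function(dy, x, d) {
  matrix(colSums(matrix(dy * x, d[1] * d[2])), nrow = d[3], ncol = d[4])
}

expand_spatial_map <- function(m, d) {
  array(rep(as.vector(m), times = d[4]), d)
}

spatial_map_grad <- function(dy, x, d) {
  array(rowSums(matrix(dy * x, d[1] * d[2] * d[3], d[4])),
        c(d[1], d[2], d[3], 1L))
}

global_avg_pool <- function(x) {
  d <- dim(x)
  matrix(colMeans(matrix(x, d[1] * d[2])), nrow = d[3], ncol = d[4])
}

global_max_pool <- function(x) {
  d <- dim(x)
  X <- matrix(x, d[1] * d[2])
  am <- max.col(t(X), ties.method = "first")
  mx <- X[cbind(am, seq_len(ncol(X)))]
  list(z = matrix(mx, d[3], d[4]), argmax = am)
}

dense_fwd <- function(z, W, b) sweep(z %*% W, 2L, b, `+`)

dense_bwd <- function(dout, z, W) {
  list(dz = dout %*% t(W), dW = crossprod(z, dout), db = colSums(dout))
}

# residual conv block --------------------------------------------------------
# conv3x3 -> BN -> elu -> dropout -> conv3x3 -> BN, plus identity (or 1x1
# conv) shortcut, elu on the sum.

res_block_init <- function(Cin, Cout) {
  p <- list(conv1 = conv_init(3L, Cin, Cout),
            conv2 = conv_init(3L, Cout, Cout))
  b1 <- bn_init(Cout); b2 <- bn_init(Cout)
  p$bn1 <- b1$params; p$bn2 <- b2$params
  if (Cin != Cout) p$short <- conv_init(1L, Cin, Cout)
  list(params = p, state = list(bn1 = b1$state, bn2 = b2$state))
}

res_block_fwd <- function(p, s, x, train, drop_rate, update_state = TRUE) {
  c1 <- conv2d_fwd(x, p$conv1$W, p$conv1$b, 3L)
  b1 <- bn_fwd(c1$out, p$bn1$gamma, p$bn1$beta, s$bn1, train,
               update_state = update_state)
  a1 <- elu_fwd(b1$out)
  dp <- dropout_fwd(a1$out, drop_rate, train)
  c2 <- conv2d_fwd(dp$out, p$conv2$W, p$conv2$b, 3L)
  b2 <- bn_fwd(c2$out, p$bn2$gamma, p$bn2$beta, s$bn2, train,
               update_state = update_state)
  if (!is.null(p$short)) {
    sc <- conv2d_fwd(x, p$short$W, p$short$b, 1L)
    sum_in <- b2$out + sc$out
    sc_cache <- list(cols = sc$cols, in_dim = sc$in_dim, k = 1L)
  } else {
    sc <- NULL
    sum_in <- b2$out + x
    sc_cache <- NULL
  }
  a2 <- elu_fwd(sum_in)
  list(out = a2$out,
       cache = list(c1 = c1, b1 = b1$cache, a1 = a1$cache, dp = dp$cache,
                    c2 = c2, b2 = b2$cache, sc = sc_cache, a2 = a2$cache),
       state = list(bn1 = b1$state, bn2 = b2$state))
}

res_block_bwd <- function(p, cache, dout) {
  dsum <- elu_bwd(dout, cache$a2)
  g <- list()
  if (!is.null(p$short)) {
    scb <- conv2d_bwd(dsum, cache$sc, p$short$W)
    dx_short <- scb$dx
    g$short <- list(W = scb$dW, b = scb$db)
  } else {
    dx_short <- dsum
  }
  b2b <- bn_bwd(dsum, cache$b2)
  g$bn2 <- list(gamma = b2b$dgamma, beta = b2b$dbeta)
  c2b <- conv2d_bwd(b2b$dx, cache$c2, p$conv2$W)
  g$conv2 <- list(W = c2b$dW, b = c2b$db)
  ddp <- dropout_bwd(c2b$dx, cache$dp)
  da1 <- elu_bwd(ddp, cache$a1)
  b1b <- bn_bwd(da1, cache$b1)
  g$bn1 <- list(gamma = b1b$dgamma, beta = b1b$dbeta)
  c1b <- conv2d_bwd(b1b$dx, cache$c1, p$conv1$W)
  g$conv1 <- list(W = c1b$dW, b = c1b$db)
  list(dx = c1b$dx + dx_short, grads = g)
}

# attention gate -------------------------------------------------------------
# Gating signal g (coarse) and skip connection xl: 1x1 convs bring both to an
# intermediate channel count at g's resolution (xl average-pooled when it is
# 2x larger), additive fusion, ReLU, 1x1 conv to one channel, sigmoid, and
# upsampling yield the attention coefficients alpha in (0,1), which multiply
# the skip connection.

attention_gate_init <- function(Cg, Cx, Ci) {
  stopifnot(Ci >= 1)
  list(params = list(theta_g = conv_init(1L, Cg, Ci),
                     theta_x = conv_init(1L, Cx, Ci),
                     psi = conv_init(1L, Ci, 1L)))
}

attention_gate_fwd <- function(p, g, xl) {
  dg <- dim(g); dx <- dim(xl)
  if (!(dx[1] == dg[1] || dx[1] == 2L * dg[1])) {
    abort("attention gate: skip must match gate resolution or be 2x larger")
  }
  factor <- dx[1] %/% dg[1]
  if (factor == 2L) {
    apool <- avgpool2_fwd(xl)
    xd <- apool$out
  } else {
    xd <- xl
  }
  tg <- conv2d_fwd(g, p$theta_g$W, p$theta_g$b, 1L)
  tx <- conv2d_fwd(xd, p$theta_x$W, p$theta_x$b, 1L)
  r <- relu_fwd(tg$out + tx$out)
  ps <- conv2d_fwd(r$out, p$psi$W, p$psi$b, 1L)
  a <- sigmoid(ps$out)
  alpha <- if (factor == 2L) upsample2_fwd(a) else a
  out <- xl * expand_spatial_map(alpha, dx)
  list(out = out, alpha = alpha,
       cache = list(tg = tg, tx = tx, r = r$cache, ps = ps, a = a,
                    alpha = alpha, factor = factor, xl = xl, dx = dx))
}

attention_gate_bwd <- function(p, cache, dout) {
  dx <- cache$dx
  dxl1 <- dout * expand_spatial_map(cache$alpha, dx)
  dalpha <- spatial_map_grad(dout, cache$xl, dx)
  da <- if (cache$factor == 2L) upsample2_bwd(dalpha) else dalpha
  dps <- da * cache$a * (1 - cache$a)
  psb <- conv2d_bwd(dps, cache$ps, p$psi$W)
  dr <- relu_bwd(psb$dx, cache$r)
  tgb <- conv2d_bwd(dr, cache$tg, p$theta_g$W)
  txb <- conv2d_bwd(dr, cache$tx, p$theta_x$W)
  dxd <- txb$dx
  dxl2 <- if (cache$factor == 2L) avgpool2_bwd(dxd, dx) else dxd
  list(dg = tgb$dx, dxl = dxl1 + dxl2,
       grads = list(theta_g = list(W = tgb$dW, b = tgb$db),
                    theta_x = list(W = txb$dW, b = txb$db),
                    psi = list(W = psb$dW, b = psb$db)))
}

# squeeze-and-excitation -----------------------------------------------------
# Global average pool to a 1x1xC descriptor, two fully connected layers with
# a reduction bottleneck (ReLU then sigmoid), channel-wise rescaling.

se_block_init <- function(C, r = 8L) {
  Cr <- C %/% r
  if (Cr < 1L) abort("SE block: channels / reduction ratio must be >= 1")
  list(params = list(
    W1 = matrix(rnorm(C * Cr, 0, sqrt(2 / C)), C, Cr), b1 = numeric(Cr),
    W2 = matrix(rnorm(Cr * C, 0, sqrt(2 / Cr)), Cr, C), b2 = numeric(C)))
}

se_block_fwd <- function(p, x) {
  d <- dim(x)
  z <- global_avg_pool(x)
  h_pre <- dense_fwd(z, p$W1, p$b1)
  h <- relu_fwd(h_pre)
  e <- sigmoid(dense_fwd(h$out, p$W2, p$b2))
  out <- x * expand_channel_scale(e, d)
  list(out = out, excitation = e,
       cache = list(z = z, h = h$out, hmask = h$cache, e = e, x = x, d = d))
}

se_block_bwd <- function(p, cache, dout) {
  d <- cache$d
  dx1 <- dout * expand_channel_scale(cache$e, d)
  de <- channel_scale_grad(dout, cache$x, d)
  dl2 <- de * cache$e * (1 - cache$e)
  b2 <- dense_bwd(dl2, cache$h, p$W2)
  dh <- relu_bwd(b2$dz, cache$hmask)
  b1 <- dense_bwd(dh, cache$z, p$W1)
  dz <- b1$dz
  dx2 <- expand_channel_scale(dz / (d[1] * d[2]), d)
  list(dx = dx1 + dx2,
       grads = list(W1 = b1$dW, b1 = b1$db, W2 = b2$dW, b2 = b2$db))
}

# CBAM -----------------------------------------------------------------------
# Channel attention (shared two-layer MLP over the spatially average- and
# max-pooled descriptors, summed, sigmoid) applied first; spatial attention
# (channel-wise mean and max maps, concatenated, 7x7 conv, sigmoid) applied
# to the result.

cbam_block_init <- function(C, r = 8L, spatial_kernel = 7L) {
  Cr <- max(1L, C %/% r)
  list(params = list(
    W1 = matrix(rnorm(C * Cr, 0, sqrt(2 / C)), C, Cr), b1 = numeric(Cr),
    W2 = matrix(rnorm(Cr * C, 0, sqrt(2 / Cr)), Cr, C), b2 = numeric(C),
    spatial = conv_init(spatial_kernel, 2L, 1L)),
    spatial_kernel = spatial_kernel)
}

cbam_block_fwd <- function(p, x, spatial_kernel = 7L) {
  d <- dim(x)
  za <- global_avg_pool(x)
  gm <- global_max_pool(x)
  ha_pre <- dense_fwd(za, p$W1, p$b1); ha <- relu_fwd(ha_pre)
  hm_pre <- dense_fwd(gm$z, p$W1, p$b1); hm <- relu_fwd(hm_pre)
  logit_c <- dense_fwd(ha$out, p$W2, p$b2) + dense_fwd(hm$out, p$W2, p$b2)
  s <- sigmoid(logit_c)
  y1 <- x * expand_channel_scale(s, d)

  Y <- matrix(y1, d[1] * d[2] * d[3], d[4])
  pa <- rowMeans(Y)
  mx <- Y[, 1]; amc <- rep(1L, nrow(Y))
  for (c in seq_len(d[4])[-1]) {
    upd <- Y[, c] > mx
    mx[upd] <- Y[upd, c]
    amc[upd] <- c
  }
  desc <- array(c(pa, mx), c(d[1], d[2], d[3], 2L))
  cv <- conv2d_fwd(desc, p$spatial$W, p$spatial$b, spatial_kernel)
  m <- sigmoid(cv$out)
  out <- y1 * expand_spatial_map(m, d)
  list(out = out, channel_attention = s, spatial_attention = m,
       cache = list(d = d, x = x, za = za, gm = gm, ha = ha, hm = hm,
                    s = s, y1 = y1, amc = amc, cv = cv, m = m))
}

cbam_block_bwd <- function(p, cache, dout) {
  d <- cache$d
  HWN <- d[1] * d[2] * d[3]
  dy1 <- dout * expand_spatial_map(cache$m, d)
  dm <- spatial_map_grad(dout, cache$y1, d)
  dcv <- dm * cache$m * (1 - cache$m)
  cvb <- conv2d_bwd(dcv, cache$cv, p$spatial$W)
  ddesc <- matrix(cvb$dx, HWN, 2L)
  # mean map spreads evenly over channels, max map routes to the argmax
  dy1m <- matrix(0, HWN, d[4])
  dy1m <- dy1m + ddesc[, 1] / d[4]
  dy1m[cbind(seq_len(HWN), cache$amc)] <-
    dy1m[cbind(seq_len(HWN), cache$amc)] + ddesc[, 2]
  dy1 <- dy1 + array(dy1m, d)

  dx1 <- dy1 * expand_channel_scale(cache$s, d)
  ds <- channel_scale_grad(dy1, cache$x, d)
  dlog <- ds * cache$s * (1 - cache$s)
  ba <- dense_bwd(dlog, cache$ha$out, p$W2)
  bm <- dense_bwd(dlog, cache$hm$out, p$W2)
  dha <- relu_bwd(ba$dz, cache$ha$cache)
  dhm <- relu_bwd(bm$dz, cache$hm$cache)
  b1a <- dense_bwd(dha, cache$za, p$W1)
  b1m <- dense_bwd(dhm, cache$gm$z, p$W1)
  dza <- b1a$dz
  dzm <- b1m$dz
  dx2 <- expand_channel_scale(dza / (d[1] * d[2]), d)
  # scatter max-pool gradient to spatial argmax positions per (batch, channel)
  dx3 <- numeric(prod(d))
  colidx <- seq_len(d[3] * d[4])
  lin <- cache$gm$argmax + (colidx - 1L) * (d[1] * d[2])
  dx3[lin] <- as.vector(dzm)
  dx3 <- array(dx3, d)
  list(dx = dx1 + dx2 + dx3,
       grads = list(W1 = b1a$dW + b1m$dW, b1 = b1a$db + b1m$db,
                    W2 = ba$dW + bm$dW, b2 = ba$db + bm$db,
                    spatial = list(W = cvb$dW, b = cvb$db)))
}
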