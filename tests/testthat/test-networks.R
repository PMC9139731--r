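ns <- asNamespace("pkdseg")

test_that("attention gate: coefficients in (0,1), identity limit, hand chain", {
  gi <- ns$attention_gate_init(2L, 2L, 2L)
  withr::with_seed(1, {
    g <- array(rnorm(2 * 2 * 1 * 2), c(2, 2, 1, 2))
    xl <- array(rnorm(4 * 4 * 1 * 2), c(4, 4, 1, 2))
  })
  fw <- ns$attention_gate_fwd(gi$params, g, xl)
  expect_true(all(fw$alpha > 0 & fw$alpha < 1))
  expect_identical(dim(fw$out), dim(xl))
  # contrived weights: huge psi bias drives all pre-sigmoid logits >> 0,
  # so alpha ~ 1 and the gate passes the skip through unchanged
  pid <- gi$params
  pid$psi$b <- 50
  fid <- ns$attention_gate_fwd(pid, g, xl)
  expect_equal(fid$out, xl, tolerance = 1e-6)
  # tiny fixed weights on a 1-batch 2x2 toy input, equal resolution:
  # hand-computed 1x1 conv -> add -> ReLU -> 1x1 conv -> sigmoid -> multiply
  p1 <- list(theta_g = list(W = matrix(0.5, 1, 1), b = 0.1),
             theta_x = list(W = matrix(-0.25, 1, 1), b = 0),
             psi = list(W = matrix(2, 1, 1), b = -0.3))
  gg <- array(c(1, -1, 0.5, 2), c(2, 2, 1, 1))
  xx <- array(c(2, 1, -1, 0.5), c(2, 2, 1, 1))
  hand_s <- pmax(0.5 * gg + 0.1 - 0.25 * xx, 0)
  hand_alpha <- 1 / (1 + exp(-(2 * hand_s - 0.3)))
  hf <- ns$attention_gate_fwd(p1, gg, xx)
  expect_equal(as.vector(hf$out), as.vector(hand_alpha * xx),
               tolerance = 1e-12)
  # incompatible spatial ratio rejected
  bad_g <- array(0, c(3, 3, 1, 2))
  expect_error(ns$attention_gate_fwd(gi$params, bad_g, xl), "resolution")
})

test_that("SE block: squeeze of constants, contraction, hand evaluation", {
  se <- ns$se_block_init(4L, r = 2L)
  # constant channels: squeeze descriptor equals the constant value
  x <- array(0, c(3, 3, 2, 4))
  for (c in 1:4) x[, , , c] <- c * 1.5
  z <- ns$global_avg_pool(x)
  expect_equal(as.vector(z[1, ]), (1:4) * 1.5)
  # sigmoid scale < 1: output never exceeds input in magnitude
  withr::with_seed(2, xr <- array(rnorm(3 * 3 * 2 * 4), c(3, 3, 2, 4)))
  fw <- ns$se_block_fwd(se$params, xr)
  expect_true(all(abs(fw$out) <= abs(xr) + 1e-12))
  expect_true(all(fw$excitation > 0 & fw$excitation < 1))
  # C = 2 toy case with fixed weights: hand evaluation of the excitation
  p <- list(W1 = matrix(c(1, -1), 2, 1), b1 = 0,
            W2 = matrix(c(0.5, 2), 1, 2), b2 = c(0, -1))
  xt <- array(0, c(2, 2, 1, 2))
  xt[, , , 1] <- 4; xt[, , , 2] <- 1
  # z = (4, 1); h = relu(4 - 1) = 3; Ex = sigmoid(c(1.5, 6 - 1))
  ex_hand <- 1 / (1 + exp(-c(1.5, 5)))
  ft <- ns$se_block_fwd(p, xt)
  expect_equal(as.vector(ft$excitation), ex_hand, tolerance = 1e-12)
  expect_equal(ft$out[1, 1, 1, ], c(4, 1) * ex_hand, tolerance = 1e-12)
  expect_error(ns$se_block_init(4L, r = 8L), ">= 1")
})

test_that("CBAM: pooled descriptors, spatial attention contract, hand case", {
  cb <- ns$cbam_block_init(4L, r = 2L, spatial_kernel = 3L)
  # spatially constant input: max-pool and avg-pool descriptors coincide
  x <- array(0, c(4, 4, 2, 4))
  for (c in 1:4) x[, , , c] <- c
  za <- ns$global_avg_pool(x)
  gm <- ns$global_max_pool(x)
  expect_equal(za, gm$z)
  # spatial attention map: one channel, values in (0,1), shape preserved
  withr::with_seed(3, xr <- array(rnorm(4 * 4 * 2 * 4), c(4, 4, 2, 4)))
  fw <- ns$cbam_block_fwd(cb$params, xr, 3L)
  expect_identical(dim(fw$spatial_attention), c(4L, 4L, 2L, 1L))
  expect_true(all(fw$spatial_attention > 0 & fw$spatial_attention < 1))
  expect_identical(dim(fw$out), dim(xr))
  # identity-weight MLP, C = 2: channel attention reduces to
  # sigmoid(avg + max) per channel
  p <- cb$params
  p$W1 <- diag(2); p$b1 <- c(0, 0)
  p$W2 <- diag(2); p$b2 <- c(0, 0)
  xt <- array(0, c(2, 2, 1, 2))
  xt[, , 1, 1] <- c(1, 2, 3, 4)   # avg 2.5, max 4
  xt[, , 1, 2] <- c(-1, 0, 1, 0)  # avg 0, max 1
  ft <- ns$cbam_block_fwd(p, xt, 3L)
  s_hand <- 1 / (1 + exp(-(c(2.5, 0) + c(4, 1))))
  expect_equal(as.vector(ft$channel_attention), s_hand, tolerance = 1e-12)
})

test_that("networks emit per-voxel probability simplices at any valid size", {
  for (variant in c("baseline_unet", "attention_unet")) {
    net <- build_network(variant, depth = 3L, base_filters = 4L, seed = 2L)
    withr::with_seed(4, x <- array(rnorm(16 * 16 * 2), c(16, 16, 2, 1)))
    fw <- ns$net_forward(net, x)
    sums <- apply(fw$probs, c(1, 2, 3), sum)
    expect_true(all(abs(sums - 1) < 1e-6))
    # fully convolutional: train-size 16, predict at 32 and 64
    for (sz in c(32L, 64L)) {
      xb <- array(rnorm(sz * sz), c(sz, sz, 1L, 1L))
      fb <- ns$net_forward(net, xb)
      expect_identical(dim(fb$probs), c(sz, sz, 1L, 3L))
      expect_true(all(abs(apply(fb$probs, c(1, 2, 3), sum) - 1) < 1e-6))
    }
    expect_error(ns$net_forward(net, array(0, c(10, 10, 1, 1))),
                 "divisible")
  }
})

test_that("parameter counts are ordered baseline < attention < {se, cbam}", {
  n <- vapply(c("baseline_unet", "attention_unet", "se_unet", "cbam_unet"),
              function(v) {
                n_parameters(build_network(v, depth = 3L, base_filters = 8L,
                                           se_reduction = 2L,
                                           cbam_reduction = 2L, seed = 1L))
              }, numeric(1))
  expect_lt(n[["baseline_unet"]], n[["attention_unet"]])
  expect_lt(n[["attention_unet"]], n[["se_unet"]])
  expect_lt(n[["attention_unet"]], n[["cbam_unet"]])
  # deterministic construction
  n2 <- n_parameters(build_network("cbam_unet", depth = 3L, base_filters = 8L,
                                   se_reduction = 2L, cbam_reduction = 2L,
                                   seed = 1L))
  expect_identical(n2, n[["cbam_unet"]])
})

test_that("backward pass matches finite differences on every variant", {
  withr::with_seed(5, {
    x <- array(rnorm(8 * 8 * 2), c(8, 8, 2, 1))
    y <- one_hot(array(sample(0:2, 8 * 8 * 2, TRUE), c(8, 8, 2)), 3)
  })
  flatten <- function(t, pre = "") {
    if (is.null(t)) return(list())
    if (is.numeric(t)) return(stats::setNames(list(t), pre))
    out <- list()
    nms <- names(t)
    for (i in seq_along(t)) {
      tag <- if (!is.null(nms) && nzchar(nms[i])) paste0(pre, "$", nms[i])
             else paste0(pre, "[[", i, "]]")
      out <- c(out, flatten(t[[i]], tag))
    }
    out
  }
  for (variant in c("baseline_unet", "attention_unet", "se_unet",
                    "cbam_unet")) {
    net <- build_network(variant, depth = 2L, base_filters = 2L, dropout = 0,
                         seed = 7L, se_reduction = 2L, cbam_reduction = 2L,
                         spatial_kernel = 3L)
    loss_of <- function(params) {
      n2 <- net; n2$params <- params
      fw <- ns$net_forward(n2, x, train = TRUE, update_state = FALSE)
      combined_loss(fw$probs, y)
    }
    fw <- ns$net_forward(net, x, train = TRUE, update_state = FALSE)
    lg <- ns$combined_loss_grad(fw$probs, y)
    grads <- ns$net_backward(net, fw$cache,
                             ns$softmax_bwd(fw$probs, lg$dpred))
    pf <- flatten(net$params)
    withr::with_seed(8, probes <- sample(length(pf), 6))
    for (k in probes) {
      j <- withr::with_seed(k, sample(length(pf[[k]]), 1))
      eps <- 1e-5
      bump <- function(delta) {
        params <- net$params
        eval(parse(text = paste0("params", names(pf)[k], "[", j,
                                 "] <- params", names(pf)[k], "[", j,
                                 "] + ", delta))[[1]])
        params
      }
      fd <- (loss_of(bump(eps)) - loss_of(bump(-eps))) / (2 * eps)
      an <- eval(parse(text = paste0("grads", names(pf)[k], "[", j, "]"))[[1]])
      expect_equal(an, fd, tolerance = 1e-3,
                   label = paste(variant, names(pf)[k]))
    }
  }
})

test_that("gating identity limit: attention net equals gate-free forward", {
  # freeze the gates open (psi bias >> 0) and compare against the same
  # parameters run through the baseline topology
  net <- build_network("attention_unet", depth = 2L, base_filters = 2L,
                       dropout = 0, seed = 9L)
  for (l in seq_along(net$params$dec)) {
    net$params$dec[[l]]$gate$psi$b <- 100
  }
  base <- build_network("baseline_unet", depth = 2L, base_filters = 2L,
                        dropout = 0, seed = 9L)
  # graft the attention net's shared weights onto the baseline
  base$params$enc <- lapply(net$params$enc,
                            function(e) list(block = e$block, attn = NULL))
  base$params$bott <- net$params$bott
  base$params$dec <- lapply(net$params$dec,
    function(d) list(upconv = d$upconv, gate = NULL, block = d$block))
  base$params$head <- net$params$head
  base$state <- net$state
  withr::with_seed(10, x <- array(rnorm(8 * 8 * 1), c(8, 8, 1, 1)))
  fa <- ns$net_forward(net, x)
  fb <- ns$net_forward(base, x)
  expect_equal(fa$probs, fb$probs, tolerance = 1e-6)
})
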