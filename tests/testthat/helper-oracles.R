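# Independent oracles used across tests. These deliberately avoid the
# package's own implementation paths: plain loops, queues and closed forms.

# queue-based flood fill, 6-connectivity; returns component label array
oracle_flood_fill <- function(b) {
  d <- dim(b)
  lab <- array(0L, d)
  nextlab <- 0L
  for (start in which(b & lab == 0L)) {
    if (lab[start] != 0L) next
    nextlab <- nextlab + 1L
    queue <- start
    lab[start] <- nextlab
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      co <- arrayInd(v, d)
      for (ax in 1:3) {
        for (dir in c(-1L, 1L)) {
          nb <- co
          nb[ax] <- nb[ax] + dir
          if (nb[ax] < 1 || nb[ax] > d[ax]) next
          lin <- nb[1] + (nb[2] - 1) * d[1] + (nb[3] - 1) * d[1] * d[2]
          if (b[lin] && lab[lin] == 0L) {
            lab[lin] <- nextlab
            queue <- c(queue, lin)
          }
        }
      }
    }
  }
  lab
}

# all-pairs nearest-distance MSSD on boundary sets extracted by brute force
oracle_mssd <- function(pred, ref, class_id, spacing) {
  bnd <- function(m) {
    d <- dim(m)
    out <- integer(0)
    for (v in which(m == class_id)) {
      co <- arrayInd(v, d)
      onb <- FALSE
      for (ax in 1:3) for (dir in c(-1L, 1L)) {
        nb <- co; nb[ax] <- nb[ax] + dir
        if (nb[ax] < 1 || nb[ax] > d[ax]) { onb <- TRUE; break }
        if (m[nb[1], nb[2], nb[3]] != class_id) { onb <- TRUE; break }
      }
      if (onb) out <- c(out, v)
    }
    out
  }
  ip <- bnd(pred); ir <- bnd(ref)
  if (length(ip) == 0 || length(ir) == 0) return(NA_real_)
  A <- sweep(arrayInd(ip, dim(pred)), 2, spacing, `*`)
  B <- sweep(arrayInd(ir, dim(ref)), 2, spacing, `*`)
  dmin_ab <- vapply(seq_len(nrow(A)), function(i) {
    min(sqrt(colSums((t(B) - A[i, ])^2)))
  }, numeric(1))
  dmin_ba <- vapply(seq_len(nrow(B)), function(i) {
    min(sqrt(colSums((t(A) - B[i, ])^2)))
  }, numeric(1))
  (sum(dmin_ab) + sum(dmin_ba)) / (nrow(A) + nrow(B))
}

# rasterize an ellipsoid pair on an n-times finer grid and return its volume
# in mL (used to bound the discretization error of the generator)
oracle_ellipsoid_volume <- function(semi, spacing, refine = 4L) {
  sp <- spacing / refine
  n <- ceiling(2.4 * semi / sp)
  cx <- (seq_len(n[1]) - 0.5) * sp[1] - 1.2 * semi[1]
  cy <- (seq_len(n[2]) - 0.5) * sp[2] - 1.2 * semi[2]
  cz <- (seq_len(n[3]) - 0.5) * sp[3] - 1.2 * semi[3]
  inside <- outer(outer((cx / semi[1])^2, (cy / semi[2])^2, `+`),
                  (cz / semi[3])^2, `+`) <= 1
  sum(inside) * prod(sp) / 1000
}

# tiny synthetic mask pair generator for metric property tests
random_mask_pair <- function(d, seed) {
  withr::with_seed(seed, {
    a <- array(sample(0:2, prod(d), replace = TRUE, prob = c(0.7, 0.15, 0.15)),
               d)
    b <- a
    flip <- runif(length(b)) < 0.2
    b[flip] <- sample(0:2, sum(flip), replace = TRUE)
    list(pred = label_mask(a, c(1.41, 1.41, 3.06)),
         ref = label_mask(b, c(1.41, 1.41, 3.06)))
  })
}

# small phantom configuration shared by several tests (coarse grid keeps
# runtimes low while preserving the generator's structure)
small_phantom_config <- function(seed = 1L, ...) {
  phantom_config(shape = c(64L, 64L, 16L), spacing = c(1.41, 1.41, 3.06),
                 kidney_semiaxes = c(11, 22, 14), n_intrarenal_cysts = 3L,
                 n_abdominal_cysts = 1L, noise_sigma = 8, seed = seed, ...)
}
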