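test_that("Dice score: overlap arithmetic and empty-set convention", {
  d <- c(8L, 8L, 4L)
  a <- array(0L, d); a[1:4, 1:4, 1] <- 1L
  expect_equal(dice_score(label_mask(a), label_mask(a), 1L), 1)
  b <- array(0L, d); b[5:8, 5:8, 2] <- 1L
  expect_equal(dice_score(label_mask(a), label_mask(b), 1L), 0)
  # |pred| = |ref| = 4, intersection 2
  p <- array(0L, d); p[1:4, 1, 1] <- 1L
  r <- array(0L, d); r[3:6, 1, 1] <- 1L
  expect_equal(dice_score(label_mask(p), label_mask(r), 1L), 0.5)
  # both empty: defined as 1; symmetric
  e <- label_mask(array(0L, d))
  expect_equal(dice_score(e, e, 2L), 1)
  expect_equal(dice_score(label_mask(p), label_mask(r), 1L),
               dice_score(label_mask(r), label_mask(p), 1L))
  # "mean" averages the two kidney classes
  m2 <- a; m2[5:8, 5:8, 3] <- 2L
  expect_equal(dice_score(label_mask(m2), label_mask(m2), "mean"), 1)
})

test_that("MSSD closed forms: identity, single-pair offset, anisotropy", {
  d <- c(8L, 8L, 4L)
  sp <- c(1.41, 1.41, 3.06)
  a <- array(0L, d); a[3:5, 3:5, 2:3] <- 1L
  expect_equal(mssd(label_mask(a, sp), label_mask(a, sp), 1L), 0)
  # two single-voxel masks offset by one in-plane voxel: 1.41 mm
  p <- array(0L, d); p[4, 4, 2] <- 1L
  r <- array(0L, d); r[5, 4, 2] <- 1L
  expect_equal(mssd(label_mask(p, sp), label_mask(r, sp), 1L), 1.41,
               tolerance = 1e-12)
  # one-slice offset uses the slice spacing
  r2 <- array(0L, d); r2[4, 4, 3] <- 1L
  expect_equal(mssd(label_mask(p, sp), label_mask(r2, sp), 1L), 3.06,
               tolerance = 1e-12)
  # empty class is undefined and flagged
  e <- label_mask(array(0L, d), sp)
  out <- mssd(label_mask(p, sp), e, 1L)
  expect_true(is.na(out))
  expect_true(attr(out, "undefined"))
})

test_that("Dice and MSSD agree with brute-force oracles on random masks", {
  n_checked <- 0
  for (seed in 1:25) {
    mp <- random_mask_pair(c(9L, 8L, 5L), seed)
    for (cls in 1:2) {
      # Dice oracle by direct set counting
      A <- which(mp$pred$data == cls)
      B <- which(mp$ref$data == cls)
      dso <- if (length(A) + length(B) == 0) 1 else
        2 * length(intersect(A, B)) / (length(A) + length(B))
      expect_equal(dice_score(mp$pred, mp$ref, cls), dso, tolerance = 1e-12)
      # MSSD oracle by all-pairs boundary distances
      mo <- oracle_mssd(mp$pred$data, mp$ref$data, cls, mp$pred$spacing)
      ours <- mssd(mp$pred, mp$ref, cls)
      if (is.na(mo)) {
        expect_true(is.na(ours))
      } else {
        expect_equal(as.numeric(ours), mo, tolerance = 1e-9)
        # symmetry
        expect_equal(as.numeric(mssd(mp$ref, mp$pred, cls)), mo,
                     tolerance = 1e-9)
        n_checked <- n_checked + 1
      }
    }
  }
  expect_gte(n_checked, 25)
})

test_that("TKV arithmetic in mL", {
  d <- c(20L, 20L, 10L)
  m <- array(0L, d)
  m[seq_len(1000)] <- 1L
  expect_equal(compute_tkv(label_mask(m, c(1, 1, 1))), 1.0)
  m2 <- array(0L, c(30L, 30L, 12L))
  m2[seq_len(6000)] <- 1L
  m2[6000 + seq_len(4000)] <- 2L
  expect_equal(compute_tkv(label_mask(m2, c(1.41, 1.41, 3.06))),
               10000 * 1.41 * 1.41 * 3.06 / 1000, tolerance = 1e-12)
  expect_equal(compute_tkv(label_mask(array(0L, d), c(1, 1, 1))), 0)
})

test_that("TKV percent difference and R-squared", {
  expect_equal(tkv_percent_diff(100, 100), 0)
  expect_equal(tkv_percent_diff(95, 100), -5)
  withr::with_seed(12, {
    ref <- runif(20, 100, 900)
    pred <- ref * runif(20, 0.9, 1.1)
  })
  expect_equal(tkv_percent_diff(pred, ref), (pred - ref) / ref * 100)
  expect_error(tkv_percent_diff(50, 0), "> 0")
  # R2: perfect fit 1, constant prediction 0, random case vs normal equations
  expect_equal(suppressWarnings(r2_fit(ref, ref)), 1)
  expect_equal(r2_fit(rep(5, 20), ref), 0, tolerance = 1e-12)
  b <- cov(pred, ref) / var(ref)
  a <- mean(pred) - b * mean(ref)
  ss_res <- sum((pred - a - b * ref)^2)
  ss_tot <- sum((pred - mean(pred))^2)
  expect_equal(r2_fit(pred, ref), 1 - ss_res / ss_tot, tolerance = 1e-10)
  expect_error(r2_fit(1:2, 1:2), "3")
})

test_that("one-sided paired t-test directionality and textbook case", {
  # self-comparison: degenerate, p = 0.5, no rejection
  x <- c(0.8, 0.85, 0.9, 0.7, 0.75)
  self <- paired_t_test(x, x)
  expect_equal(self$p, 0.5)
  expect_false(self$reject)
  # textbook 5-pair example, hand-computed t and p
  a <- c(0.80, 0.82, 0.78, 0.85, 0.81)
  b <- c(0.84, 0.85, 0.80, 0.86, 0.84)
  d <- b - a
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  p_hand <- 1 - pt(t_hand, df = 4)
  res <- paired_t_test(a, b)
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$p, p_hand, tolerance = 1e-12)
  expect_true(res$reject == (p_hand < 0.05))
  # swapping the roles maps p to 1 - p
  swapped <- paired_t_test(b, a)
  expect_equal(swapped$p, 1 - res$p, tolerance = 1e-12)
  # direction flips for smaller-is-better metrics
  res_l <- paired_t_test(b, a, higher_is_better = FALSE)
  expect_equal(res_l$p, res$p, tolerance = 1e-12)
  expect_error(paired_t_test(a, b[1:3]), "length")
})

test_that("report assembly: perfect pipeline, cardinality, aggregates", {
  ph1 <- generate_phantom(small_phantom_config(seed = 41L))
  ph2 <- generate_phantom(small_phantom_config(seed = 42L))
  refs <- list(c1 = ph1$mask, c2 = ph2$mask)
  preds <- list(c1 = ph1$mask, c2 = ph2$mask)
  rep <- evaluate_report(preds, refs)
  expect_identical(nrow(rep$cases), 2L)
  expect_true(all(rep$cases$dsc_mean == 1))
  expect_true(all(rep$cases$mssd_mean == 0))
  expect_true(all(rep$cases$tkv_diff_pct == 0))
  # aggregate mean equals the mean of the per-case column
  expect_equal(rep$summary$mean[rep$summary$metric == "tkv_pred"],
               mean(rep$cases$tkv_pred), tolerance = 1e-12)
  # imperfect prediction: degrade one case and check bookkeeping
  noisy <- rater_perturb(ph2$mask, 0.85, 0.97, seed = 9L)
  rep2 <- evaluate_report(list(c1 = ph1$mask, c2 = noisy), refs)
  expect_lt(rep2$cases$dsc_mean[2], 1)
  expect_gt(rep2$cases$mssd_mean[2], 0)
  expect_error(evaluate_report(list(zz = ph1$mask), refs), "missing")
  # tidy/glance interface
  expect_identical(tidy(rep2), rep2$cases)
  g <- glance(rep2)
  expect_identical(g$n_cases, 2L)
  expect_equal(g$dsc_mean, mean(rep2$cases$dsc_mean), tolerance = 1e-12)
})
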