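test_that("majority vote counts votes exactly and ties go to background", {
  d <- c(6L, 6L, 3L)
  base <- array(0L, d)
  m1 <- base; m1[1:3, 1:3, ] <- 1L
  m2 <- base; m2[1:3, 1:3, ] <- 1L; m2[4:6, 4:6, ] <- 2L
  m3 <- base; m3[4:6, 4:6, ] <- 2L
  masks <- lapply(list(m1, m2, m3), label_mask)
  mv <- majority_vote(masks)
  expect_identical(mv$data[1, 1, 1], 1L)   # 2/3 votes for class 1
  expect_identical(mv$data[5, 5, 1], 2L)   # 2/3 votes for class 2
  expect_identical(mv$data[1, 6, 1], 0L)   # unanimous background
  # unanimity: identical members reproduce the mask
  mu <- majority_vote(list(masks[[2]], masks[[2]], masks[[2]]))
  expect_identical(mu$data, masks[[2]]$data)
  # 2/2 foreground-foreground tie resolves to background
  t1 <- base; t1[1, 1, 1] <- 1L
  t2 <- base; t2[1, 1, 1] <- 1L
  t3 <- base; t3[1, 1, 1] <- 2L
  t4 <- base; t4[1, 1, 1] <- 2L
  tv <- majority_vote(lapply(list(t1, t2, t3, t4), label_mask))
  expect_identical(tv$data[1, 1, 1], 0L)
  # 2-vs-2 tie against background also resolves to background
  tb <- majority_vote(lapply(list(t1, t2, base, base), label_mask))
  expect_identical(tb$data[1, 1, 1], 0L)
  expect_error(majority_vote(masks[1]), "two members")
})

test_that("majority vote equals an exhaustive counting oracle", {
  withr::with_seed(11, {
    masks <- lapply(1:7, function(i) {
      label_mask(array(sample(0:2, 5 * 5 * 4, TRUE), c(5, 5, 4)))
    })
  })
  mv <- majority_vote(masks)$data
  arr <- sapply(masks, function(m) as.vector(m$data))
  oracle <- apply(arr, 1, function(v) {
    n <- tabulate(v + 1L, 3L)
    w <- which(n == max(n))
    if (length(w) > 1 || w[1] == 1L) 0L else w[1] - 1L
  })
  expect_identical(as.vector(mv), oracle)
  # permutation invariance
  mv2 <- majority_vote(masks[c(4, 1, 7, 3, 2, 6, 5)])$data
  expect_identical(mv2, majority_vote(masks)$data)
})

test_that("STAPLE degenerate fixed points: identical raters, single rater", {
  ph <- generate_phantom(small_phantom_config(seed = 31L))
  same <- list(ph$mask, ph$mask, ph$mask)
  st <- staple_consensus(same)
  expect_identical(st$mask$data, ph$mask$data)
  for (cls in 1:2) {
    expect_true(all(st$estimate$performance[[cls]]$sensitivity >= 0.999))
    expect_true(all(st$estimate$performance[[cls]]$specificity >= 0.999))
  }
  # single rater: consensus equals that rater
  st1 <- staple_consensus(list(ph$mask))
  expect_identical(st1$mask$data, ph$mask$data)
})

test_that("STAPLE recovers simulated rater performance and beats the mean", {
  ph <- generate_phantom(small_phantom_config(seed = 33L))
  raters <- lapply(1:5, function(j) {
    rater_perturb(ph$mask, sensitivity = 0.9, specificity = 0.95,
                  seed = 100L + j)
  })
  st <- staple_consensus(raters)
  member_dsc <- vapply(raters, function(r) dice_score(r, ph$mask), numeric(1))
  consensus_dsc <- dice_score(st$mask, ph$mask)
  expect_gte(consensus_dsc, mean(member_dsc))
  for (cls in 1:2) {
    est <- st$estimate$performance[[cls]]$sensitivity
    expect_true(all(abs(est - 0.9) < 0.05))
  }
  # EM objective is non-decreasing for both classes
  for (cls in 1:2) {
    ll <- st$estimate$loglik[[cls]]
    expect_true(all(diff(ll) > -1e-6 * abs(ll[-length(ll)])))
  }
  # permutation invariance of the consensus
  st2 <- staple_consensus(raters[c(3, 5, 1, 4, 2)])
  expect_identical(st2$mask$data, st$mask$data)
})

test_that("vote fusion of noisy raters beats the median member", {
  ph <- generate_phantom(small_phantom_config(seed = 35L))
  raters <- lapply(1:5, function(j) {
    rater_perturb(ph$mask, sensitivity = 0.85, specificity = 0.92,
                  seed = 200L + j)
  })
  mv <- majority_vote(raters)
  member_dsc <- vapply(raters, function(r) dice_score(r, ph$mask), numeric(1))
  expect_gte(dice_score(mv, ph$mask), stats::median(member_dsc))
})

test_that("fuse_ensemble dispatches to voting and STAPLE on result objects", {
  ph <- generate_phantom(small_phantom_config(seed = 37L))
  as_result <- function(mask, id) {
    structure(list(prob = NULL, labels = mask, post_labels = mask,
                   case_id = id), class = "segmentation_result")
  }
  raters <- lapply(1:3, function(j) {
    rater_perturb(ph$mask, 0.95, 0.98, seed = 300L + j)
  })
  results <- Map(as_result, raters, c("a", "b", "c"))
  v <- fuse_ensemble(results, method = "voting")
  s <- fuse_ensemble(results, method = "staple")
  expect_s3_class(v, "label_mask")
  expect_s3_class(s, "label_mask")
  expect_gte(dice_score(v, ph$mask), 0.9)
  expect_gte(dice_score(s, ph$mask), 0.9)
})
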