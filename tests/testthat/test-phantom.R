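test_that("phantom generation is deterministic and respects the geometry", {
  cfg <- small_phantom_config(seed = 42L)
  a <- generate_phantom(cfg)
  b <- generate_phantom(cfg)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$mask$data, b$mask$data)
  expect_identical(dim(a$volume$data), c(64L, 64L, 16L))
  expect_equal(a$volume$spacing, c(1.41, 1.41, 3.06))
  # different seed changes the data
  c2 <- generate_phantom(small_phantom_config(seed = 43L))
  expect_false(identical(a$volume$data, c2$volume$data))
})

test_that("default-geometry phantom matches the emulated acquisition", {
  cfg <- phantom_config(seed = 5L)
  expect_identical(cfg$shape, c(256L, 256L, 40L))
  expect_equal(cfg$spacing, c(1.41, 1.41, 3.06))
  ph <- generate_phantom(cfg)
  expect_identical(dim(ph$mask$data), c(256L, 256L, 40L))
  # mask TKV within 5% of the analytic ellipsoid-pair volume
  tkv <- compute_tkv(ph$mask)
  expect_lt(abs(tkv - sum(ph$analytic_volume_mL)) / sum(ph$analytic_volume_mL),
            0.05)
})

test_that("each kidney class is one face-connected component, classes disjoint", {
  ph <- generate_phantom(small_phantom_config(seed = 7L))
  m <- ph$mask$data
  for (cls in 1:2) {
    lab <- oracle_flood_fill(m == cls)
    expect_identical(max(lab), 1L)
  }
  expect_identical(sum(m == 1L & m == 2L), 0L)
  # left/right placement: class 2 in the low-row half, class 1 in the high
  rows1 <- which(m == 1L, arr.ind = TRUE)[, 1]
  rows2 <- which(m == 2L, arr.ind = TRUE)[, 1]
  expect_gt(min(rows1), max(rows2))
})

test_that("rasterized kidney volume converges to the ellipsoid formula", {
  semi <- c(11, 22, 14)
  analytic <- 4 / 3 * pi * prod(semi) / 1000
  coarse <- oracle_ellipsoid_volume(semi, c(2.82, 2.82, 6.12), refine = 1L)
  fine <- oracle_ellipsoid_volume(semi, c(1.41, 1.41, 3.06), refine = 1L)
  expect_lt(abs(fine - analytic), abs(coarse - analytic))
  expect_lt(abs(fine - analytic) / analytic, 0.05)
})

test_that("invalid phantom configurations are rejected", {
  expect_error(phantom_config(shape = c(8, 64, 16)), "shape")
  expect_error(phantom_config(spacing = c(0, 1, 1)), "spacing")
  expect_error(phantom_config(n_intrarenal_cysts = -1), "cyst")
  # kidneys too large for the grid
  big <- small_phantom_config(seed = 1L)
  big$kidney_semiaxes <- c(40, 22, 14)
  expect_error(generate_phantom(big), "overlap|outside")
})

test_that("generate_cohort writes a reproducible cohort to disk", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  cfg <- small_phantom_config()
  m1 <- generate_cohort(4, master_seed = 99L, dir1, cfg)
  m2 <- generate_cohort(4, master_seed = 99L, dir2, cfg)
  expect_identical(nrow(m1), 4L)
  expect_identical(anyDuplicated(m1$case_id), 0L)
  expect_true(all(file.exists(m1$volume_path)))
  expect_true(all(file.exists(m1$mask_path)))
  expect_identical(length(list.files(dir1, pattern = "nii.gz$")), 8L)
  # same master seed: identical content; distinct derived seeds: distinct data
  expect_identical(m1$seed, m2$seed)
  v1 <- read_volume(m1$volume_path[1])
  v1b <- read_volume(m2$volume_path[1])
  expect_equal(v1$data, v1b$data)
  v2 <- read_volume(m1$volume_path[2])
  expect_false(identical(v1$data, v2$data))
  # analytic volumes are recovered by the voxel masks to within 5%
  msk <- read_mask(m1$mask_path[1])
  expect_lt(abs(compute_tkv(msk) - m1$analytic_class1_mL[1] -
                  m1$analytic_class2_mL[1]) /
              (m1$analytic_class1_mL[1] + m1$analytic_class2_mL[1]), 0.05)
})

test_that("NIfTI round-trip preserves data and spacing", {
  ph <- generate_phantom(small_phantom_config(seed = 3L))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(ph$volume, f)
  back <- read_volume(f)
  expect_equal(back$data, ph$volume$data, tolerance = 1e-12)
  expect_equal(back$spacing, ph$volume$spacing, tolerance = 1e-6)
  fm <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(ph$mask, fm)
  expect_identical(read_mask(fm)$data, ph$mask$data)
})

test_that("rater_perturb degrades a mask with the requested error rates", {
  ph <- generate_phantom(small_phantom_config(seed = 11L))
  # identity at perfect sensitivity/specificity
  r1 <- rater_perturb(ph$mask, 1, 1, seed = 5L)
  expect_identical(r1$data, ph$mask$data)
  # deterministic given the seed
  r2 <- rater_perturb(ph$mask, 0.9, 0.95, seed = 5L)
  r3 <- rater_perturb(ph$mask, 0.9, 0.95, seed = 5L)
  expect_identical(r2$data, r3$data)
  # empirical kept fraction within 3 binomial sd of the sensitivity
  for (cls in 1:2) {
    n_true <- sum(ph$mask$data == cls)
    kept <- sum(ph$mask$data == cls & r2$data == cls)
    sens_hat <- kept / n_true
    expect_lt(abs(sens_hat - 0.9), 3 * sqrt(0.9 * 0.1 / n_true))
  }
  # empty mask stays empty when specificity is 1
  empty <- label_mask(array(0L, c(8, 8, 4)))
  expect_identical(rater_perturb(empty, 0.9, 1, seed = 1L)$data,
                   empty$data)
  expect_error(rater_perturb(ph$mask, 0, 1, seed = 1L), "sensitivity")
})
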