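#' Configuration for the synthetic kidney phantom
#'
#' The phantom emulates the acquisition geometry of coronal T1-weighted
#' abdominal MRI in polycystic kidney disease studies: a 256 x 256 in-plane
#' matrix at 1.41 x 1.41 mm resolution with ~3.06 mm thick coronal slices.
#' Each phantom contains two non-overlapping ellipsoidal kidneys (brighter
#' than the background tissue), hyper- and hypo-intense intrarenal cysts,
#' optional bright extra-renal cyst blobs (hard cases: cystic tissue outside
#' the kidneys that a naive intensity rule would over-segment), a smooth
#' multiplicative bias field and additive Gaussian noise.
#'
#' @param shape integer length-3: voxels per axis (rows, cols, slices).
#' @param spacing numeric length-3: mm per voxel along each axis.
#' @param kidney_semiaxes numeric length-3: ellipsoid semi-axes in mm
#'   (in-plane left-right, in-plane superior-inferior, through-slice).
#' @param n_intrarenal_cysts cysts rasterised inside each kidney.
#' @param n_abdominal_cysts bright cyst blobs outside the kidneys
#'   (labelled background).
#' @param noise_sigma standard deviation of additive Gaussian noise
#'   (intensity units; tissue contrast is ~80 units).
#' @param bias_field_amplitude peak fractional deviation of the smooth
#'   multiplicative bias field.
#' @param semiaxis_jitter fractional per-case jitter of the semi-axes (gives
#'   the cohort a spread of kidney volumes).
#' @param left_is_class1 if `TRUE` (radiological convention) class 1 is the
#'   patient-left kidney, placed in the image-right half (higher row index).
#' @param seed integer RNG seed; the phantom is a pure function of
#'   configuration and seed.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(256L, 256L, 40L),
                           spacing = c(1.41, 1.41, 3.06),
                           kidney_semiaxes = c(28, 55, 32),
                           n_intrarenal_cysts = 6L,
                           n_abdominal_cysts = 2L,
                           noise_sigma = 8,
                           bias_field_amplitude = 0.15,
                           semiaxis_jitter = 0.1,
                           left_is_class1 = TRUE,
                           seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 16L)) {
    abort("`shape` must be 3 integers, each >= 16.")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0)) {
    abort("`spacing` components must be > 0.")
  }
  if (n_intrarenal_cysts < 0 || n_abdominal_cysts < 0) {
    abort("cyst counts must be >= 0.")
  }
  structure(list(shape = shape, spacing = spacing,
                 kidney_semiaxes = as.numeric(kidney_semiaxes),
                 n_intrarenal_cysts = as.integer(n_intrarenal_cysts),
                 n_abdominal_cysts = as.integer(n_abdominal_cysts),
                 noise_sigma = noise_sigma,
                 bias_field_amplitude = bias_field_amplitude,
                 semiaxis_jitter = semiaxis_jitter,
                 left_is_class1 = isTRUE(left_is_class1),
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Voxel-centre physical coordinates along one axis (mm, 0-based voxel index).
axis_coords <- function(n, sp) (seq_len(n) - 0.5) * sp

# Rasterise an ellipsoid (centre and semi-axes in mm, small in-plane
# rotation `theta`) onto the voxel grid; returns a logical array.
rasterize_ellipsoid <- function(shape, spacing, center, semi, theta = 0) {
  cx <- axis_coords(shape[1], spacing[1]) - center[1]
  cy <- axis_coords(shape[2], spacing[2]) - center[2]
  cz <- axis_coords(shape[3], spacing[3]) - center[3]
  ct <- cos(theta); st <- sin(theta)
  # in-plane rotation of (x, y); z unrotated
  X <- outer(cx, cy, function(x, y) (ct * x + st * y)^2 / semi[1]^2 +
               (-st * x + ct * y)^2 / semi[2]^2)
  Z <- (cz / semi[3])^2
  arr <- outer(X, Z, `+`)
  arr <- array(arr, dim = shape)
  arr <= 1
}

#' Generate one synthetic abdominal phantom
#'
#' @param config a [phantom_config()].
#' @return A list with elements `volume` (`volume_grid`), `mask`
#'   (`label_mask`) and `analytic_volume_mL`, a named numeric vector with the
#'   exact ellipsoid volume (4/3 pi abc, converted to mL) of the class-1 and
#'   class-2 kidneys.
#' @export
generate_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(config$seed, {
    shape <- config$shape; spacing <- config$spacing
    ext <- shape * spacing                # physical extent (mm)
    semi0 <- config$kidney_semiaxes

    # Per-side jittered semi-axes and centres; side A sits in the low-row
    # half, side B in the high-row half.
    jit <- function() semi0 * (1 + runif(3, -config$semiaxis_jitter,
                                         config$semiaxis_jitter))
    semiA <- jit(); semiB <- jit()
    thA <- rnorm(1, 0, 0.06); thB <- rnorm(1, 0, 0.06)
    centerA <- c(0.27 * ext[1], 0.5 * ext[2], 0.5 * ext[3]) +
      c(rnorm(2, 0, 0.01 * ext[1:2]), rnorm(1, 0, 0.01 * ext[3]))
    centerB <- c(0.73 * ext[1], 0.5 * ext[2], 0.5 * ext[3]) +
      c(rnorm(2, 0, 0.01 * ext[1:2]), rnorm(1, 0, 0.01 * ext[3]))

    # support extent of the rotated ellipse along the row / column axes
    extents <- function(semi, th) {
      c(sqrt((semi[1] * cos(th))^2 + (semi[2] * sin(th))^2),
        sqrt((semi[1] * sin(th))^2 + (semi[2] * cos(th))^2),
        semi[3])
    }
    exA <- extents(semiA, thA); exB <- extents(semiB, thB)
    # reject configurations whose kidneys could overlap or leave the grid
    margin <- 0.02 * ext[1]
    if (centerA[1] + exA[1] + margin > centerB[1] - exB[1]) {
      abort("kidneys would overlap: reduce `kidney_semiaxes` or enlarge `shape`.")
    }
    for (s in list(list(centerA, exA), list(centerB, exB))) {
      if (any(s[[1]] - s[[2]] < 0) || any(s[[1]] + s[[2]] > ext)) {
        abort("kidney extends outside the volume: shrink `kidney_semiaxes`.")
      }
    }

    inA <- rasterize_ellipsoid(shape, spacing, centerA, semiA, thA)
    inB <- rasterize_ellipsoid(shape, spacing, centerB, semiB, thB)

    # class 1 = patient-left kidney = image-right (high-row) half under the
    # radiological convention; configurable.
    if (config$left_is_class1) {
      in1 <- inB; in2 <- inA
      semi1 <- semiB; semi2 <- semiA
      c1 <- centerB; c2 <- centerA; s1 <- semiB; s2 <- semiA
    } else {
      in1 <- inA; in2 <- inB
      c1 <- centerA; c2 <- centerB; s1 <- semiA; s2 <- semiB
    }
    mask <- array(0L, shape)
    mask[in1] <- 1L
    mask[in2] <- 2L

    vol <- array(100, shape)              # background soft tissue
    vol[in1 | in2] <- 180                 # kidney parenchyma

    place_cysts <- function(vol, center, semi, n) {
      for (i in seq_len(n)) {
        # cyst centre inside the ellipsoid (rejection sampling)
        repeat {
          u <- runif(3, -0.7, 0.7)
          if (sum(u^2) <= 0.49) break
        }
        cc <- center + u * semi
        r <- runif(1, 3, min(10, 0.4 * min(semi)))
        cyst <- rasterize_ellipsoid(shape, spacing, cc, rep(r, 3))
        vol[cyst] <- if (runif(1) < 0.5) 250 else 60
      }
      vol
    }
    vol <- place_cysts(vol, centerA, semiA, config$n_intrarenal_cysts)
    vol <- place_cysts(vol, centerB, semiB, config$n_intrarenal_cysts)

    # extra-renal bright cysts (hard cases); labelled background
    for (i in seq_len(config$n_abdominal_cysts)) {
      repeat {
        cc <- runif(3, 0.1, 0.9) * ext
        r <- runif(1, 4, 12)
        blob <- rasterize_ellipsoid(shape, spacing, cc, rep(r, 3))
        if (!any(blob & (in1 | in2))) break
      }
      vol[blob] <- 230
    }

    # smooth multiplicative bias field: second-order polynomial in
    # normalised coordinates, scaled to peak amplitude
    if (config$bias_field_amplitude > 0) {
      nx <- axis_coords(shape[1], spacing[1]) / ext[1] - 0.5
      ny <- axis_coords(shape[2], spacing[2]) / ext[2] - 0.5
      nz <- axis_coords(shape[3], spacing[3]) / ext[3] - 0.5
      cf <- rnorm(9)
      fx <- cf[1] * nx + cf[4] * nx^2
      fy <- cf[2] * ny + cf[5] * ny^2
      fz <- cf[3] * nz + cf[6] * nz^2
      field <- outer(outer(fx, fy, `+`), fz, `+`)
      field <- field / max(abs(field), 1e-12)
      vol <- vol * (1 + config$bias_field_amplitude * array(field, shape))
    }

    if (config$noise_sigma > 0) {
      vol <- vol + array(rnorm(prod(shape), 0, config$noise_sigma), shape)
    }

    analytic <- c(class1 = 4 / 3 * pi * prod(s1) / 1000,
                  class2 = 4 / 3 * pi * prod(s2) / 1000)

    list(volume = volume_grid(vol, spacing),
         mask = label_mask(mask, spacing),
         analytic_volume_mL = analytic)
  })
}

#' Generate a cohort of phantoms on disk
#'
#' Writes `n` NIfTI volume/mask pairs under `out_dir` and returns a manifest
#' tibble. Per-case seeds are derived deterministically from `master_seed`,
#' so the same call reproduces the same cohort bit for bit.
#'
#' @param n number of cases (>= 1).
#' @param master_seed integer seed from which per-case seeds are derived.
#' @param out_dir output directory (created if missing).
#' @param config a [phantom_config()]; its `seed` field is overridden per case.
#' @return A tibble of class `cohort_manifest` with columns `case_id`,
#'   `volume_path`, `mask_path`, `seed`, `analytic_class1_mL`,
#'   `analytic_class2_mL`. Also written as `manifest.csv` in `out_dir`.
#' @export
generate_cohort <- function(n, master_seed, out_dir, config = phantom_config()) {
  stopifnot(n >= 1)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create output directory '%s'", out_dir))
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    seed_i <- derive_seed(master_seed, i)
    cfg <- config
    cfg$seed <- seed_i
    ph <- generate_phantom(cfg)
    case_id <- sprintf("case_%03d", i)
    vp <- file.path(out_dir, paste0(case_id, "_vol.nii.gz"))
    mp <- file.path(out_dir, paste0(case_id, "_mask.nii.gz"))
    write_volume(ph$volume, vp)
    write_volume(ph$mask, mp)
    rows[[i]] <- tibble(case_id = case_id, volume_path = vp, mask_path = mp,
                        seed = seed_i,
                        analytic_class1_mL = ph$analytic_volume_mL[["class1"]],
                        analytic_class2_mL = ph$analytic_volume_mL[["class2"]])
  }
  manifest <- dplyr::bind_rows(rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  class(manifest) <- c("cohort_manifest", class(manifest))
  manifest
}

#' Simulate an imperfect rater from a ground-truth mask
#'
#' Produces a degraded copy of a label mask, used as a synthetic "rater" for
#' testing label-fusion algorithms with known per-rater sensitivity and
#' specificity. Per foreground class, each true voxel is kept with
#' probability `sensitivity`; background voxels inside a dilated band around
#' the class are flipped to foreground with probability `1 - specificity`.
#'
#' @param mask a `label_mask`.
#' @param sensitivity,specificity probabilities in (0, 1].
#' @param seed integer RNG seed (output is deterministic given the seed).
#' @param band_voxels width of the dilation band (face-connected dilations).
#' @return A `label_mask` of the same geometry.
#' @export
rater_perturb <- function(mask, sensitivity, specificity, seed,
                          band_voxels = 2L) {
  stopifnot(inherits(mask, "label_mask"))
  if (sensitivity <= 0 || sensitivity > 1 || specificity <= 0 ||
      specificity > 1) {
    abort("sensitivity and specificity must lie in (0, 1].")
  }
  with_seed(seed, {
    m <- mask$data
    out <- array(0L, dim(m))
    for (cls in 1:2) {
      fg <- m == cls
      nfg <- sum(fg)
      if (nfg > 0) {
        keep <- runif(nfg) < sensitivity
        idx <- which(fg)[keep]
        out[idx] <- cls
      }
      if (specificity < 1 && nfg > 0) {
        band <- dilate6(fg, band_voxels) & m == 0L & out == 0L
        nb <- sum(band)
        if (nb > 0) {
          flip <- runif(nb) < (1 - specificity)
          out[which(band)[flip]] <- cls
        }
      }
    }
    label_mask(out, mask$spacing)
  })
}

# Binary dilation with the 6-connected (face) structuring element,
# iterated `k` times.
dilate6 <- function(b, k = 1L) {
  d <- dim(b)
  for (i in seq_len(k)) {
    nb <- b
    nb[-1, , ]    <- nb[-1, , ]    | b[-d[1], , ]
    nb[-d[1], , ] <- nb[-d[1], , ] | b[-1, , ]
    nb[, -1, ]    <- nb[, -1, ]    | b[, -d[2], ]
    nb[, -d[2], ] <- nb[, -d[2], ] | b[, -1, ]
    nb[, , -1]    <- nb[, , -1]    | b[, , -d[3]]
    nb[, , -d[3]] <- nb[, , -d[3]] | b[, , -1]
    b <- nb
  }
  b
}
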