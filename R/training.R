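#' Training configuration
#'
#' Defaults follow the training protocol the networks are designed for:
#' Adam with learning rate 1e-3, batch size 16 for 96-voxel patches (8 for
#' 128), L2 regularization 1e-7, dropout 0.01, 160 patch samples per volume
#' per epoch, at least 20 epochs with a 10-epoch / 1e-4 early-stopping
#' window on the per-kidney validation Dice score.
#'
#' @param variant network variant key (see [build_network()]).
#' @param loss loss key: `"dsc"`, `"ce_dsc"` or `"cosine"`.
#' @param sam logical, enable sharpness-aware minimization.
#' @param rho SAM neighborhood radius.
#' @param patch_size training patch edge length.
#' @param batch_size defaults to 16 for patch 96, 8 for patch 128,
#'   max(4, 1024/patch) otherwise.
#' @param lr,l2,dropout optimizer and regularization settings.
#' @param depth,base_filters network size.
#' @param samples_per_volume patches drawn per training volume per epoch.
#' @param min_epochs,stop_window,stop_tol early-stopping protocol.
#' @param max_epochs hard cap on epochs.
#' @param lambda weight of the cross-entropy term in the combined loss.
#' @param val_max_slices at most this many coronal slices per validation
#'   volume are scored during training (centred on the stack); full volumes
#'   are used when `Inf`.
#' @param seed master RNG seed for initialization and patch sampling.
#' @return A list of class `train_config`.
#' @export
train_config <- function(variant = "baseline_unet", loss = "ce_dsc",
                         sam = FALSE, rho = 0.05, patch_size = 96L,
                         batch_size = NULL, lr = 1e-3, l2 = 1e-7,
                         dropout = 0.01, depth = 4L, base_filters = 32L,
                         samples_per_volume = 160L, min_epochs = 20L,
                         stop_window = 10L, stop_tol = 1e-4,
                         max_epochs = 60L, lambda = 10,
                         val_max_slices = Inf, seed = 1L) {
  if (is.null(batch_size)) {
    batch_size <- if (patch_size == 96L) 16L
                  else if (patch_size == 128L) 8L
                  else max(4L, as.integer(1024 / patch_size))
  }
  structure(list(variant = variant, loss = loss, sam = isTRUE(sam),
                 rho = rho, patch_size = as.integer(patch_size),
                 batch_size = as.integer(batch_size), lr = lr, l2 = l2,
                 dropout = dropout, depth = as.integer(depth),
                 base_filters = as.integer(base_filters),
                 samples_per_volume = as.integer(samples_per_volume),
                 min_epochs = as.integer(min_epochs),
                 stop_window = as.integer(stop_window),
                 stop_tol = stop_tol, max_epochs = as.integer(max_epochs),
                 lambda = lambda, val_max_slices = val_max_slices,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Early-stopping rule
#'
#' Training stops once at least `min_epochs` epochs have run and, for each
#' kidney class, the range (max minus min) of the per-kidney validation
#' metric over the last `window` epochs is strictly below `tol`.
#'
#' @param history tibble with one row per completed epoch and columns
#'   `dsc_left`, `dsc_right` (validation Dice per kidney).
#' @param min_epochs minimum number of epochs before stopping is allowed.
#' @param window number of trailing epochs over which stability is required.
#' @param tol strict upper bound on the metric range within the window.
#' @return `TRUE` if training should stop.
#' @export
early_stop_check <- function(history, min_epochs = 20L, window = 10L,
                             tol = 1e-4) {
  n <- nrow(history)
  if (n == 0) abort("history is empty")
  if (n < min_epochs || n < window) return(FALSE)
  tail_idx <- (n - window + 1L):n
  for (col in c("dsc_left", "dsc_right")) {
    v <- history[[col]][tail_idx]
    if (diff(range(v)) >= tol) return(FALSE)
  }
  TRUE
}

#' Checkpoint selection
#'
#' Picks, among the last `window` epochs, the epoch with the highest mean of
#' the two per-kidney validation metrics. Ties go to the earliest epoch in
#' the window.
#'
#' @inheritParams early_stop_check
#' @return The selected epoch index (1-based over the full history).
#' @export
select_checkpoint <- function(history, window = 10L) {
  n <- nrow(history)
  if (n < window) abort("history shorter than the selection window")
  tail_idx <- (n - window + 1L):n
  avg <- (history$dsc_left[tail_idx] + history$dsc_right[tail_idx]) / 2
  tail_idx[which.max(avg)]
}

# Load, normalize and cache a cohort's volumes and masks keyed by case id.
load_cases <- function(manifest, ids) {
  out <- list()
  rows <- manifest[manifest$case_id %in% ids, ]
  for (i in seq_len(nrow(rows))) {
    vol <- zscore_normalize(read_volume(rows$volume_path[i]))
    msk <- read_mask(rows$mask_path[i])
    out[[rows$case_id[i]]] <- list(volume = vol, mask = msk)
  }
  out
}

# Assemble one training batch: arrays x (S,S,B,1) and one-hot y (S,S,B,3).
make_batch <- function(cases, picks, size) {
  B <- nrow(picks)
  x <- array(0, c(size, size, B, 1L))
  yl <- array(0L, c(size, size, B))
  for (b in seq_len(B)) {
    cs <- cases[[picks$case_id[b]]]
    sl <- cs$volume$data[, , picks$slice[b]]
    ml <- cs$mask$data[, , picks$slice[b]]
    pt <- extract_patch(sl, ml, c(picks$row[b], picks$col[b]), size)
    x[, , b, 1L] <- pt$patch
    yl[, , b] <- pt$label_patch
  }
  list(x = x, y = one_hot(yl, 3L))
}

# Volume-wise validation Dice per kidney class on full-size slices.
validation_dice <- function(net, cases, ids, max_slices = Inf) {
  inter <- c(0, 0); psum <- c(0, 0); rsum <- c(0, 0)
  for (id in ids) {
    cs <- cases[[id]]
    d <- dim(cs$volume$data)
    slices <- seq_len(d[3])
    if (is.finite(max_slices) && length(slices) > max_slices) {
      mid <- (d[3] + 1) / 2
      slices <- slices[order(abs(slices - mid))][seq_len(max_slices)]
    }
    for (sl in slices) {
      x <- array(cs$volume$data[, , sl], c(d[1], d[2], 1L, 1L))
      fw <- net_forward(net, x, train = FALSE)
      pc <- max.col(matrix(fw$probs, ncol = 3L), ties.method = "first") - 1L
      ref <- as.vector(cs$mask$data[, , sl])
      for (k in 1:2) {
        inter[k] <- inter[k] + sum(pc == k & ref == k)
        psum[k] <- psum[k] + sum(pc == k)
        rsum[k] <- rsum[k] + sum(ref == k)
      }
    }
  }
  sapply(1:2, function(k) {
    if (psum[k] + rsum[k] == 0) 1 else 2 * inter[k] / (psum[k] + rsum[k])
  })
}

#' Train a segmentation network on a phantom cohort
#'
#' Implements the patch-based training protocol: per epoch, draws
#' `samples_per_volume` patch centres per training volume with 50:50
#' label:background stratification (resampled every epoch), optimizes the
#' configured loss with Adam — through the SAM two-step update when enabled —
#' and records the per-kidney volume-wise validation Dice on full-size
#' slices. Training stops by [early_stop_check()] (or at `max_epochs`) and
#' the returned model carries the weights chosen by [select_checkpoint()]
#' over the trailing window. Test-fold cases are never touched.
#'
#' @param config a [train_config()].
#' @param fold one fold from [make_folds()] (`train`, `val`, `test` ids).
#' @param cohort a cohort manifest from [generate_cohort()].
#' @param verbose print one line per epoch.
#' @return A list of class `pkdseg_model`: `net` (with selected weights),
#'   `history` (tibble), `selected_epoch`, `config`, `fold`.
#' @export
train_model <- function(config, fold, cohort, verbose = FALSE) {
  stopifnot(inherits(config, "train_config"))
  cases <- load_cases(cohort, c(fold$train, fold$val))
  missing <- setdiff(c(fold$train, fold$val), names(cases))
  if (length(missing) > 0) {
    abort(sprintf("cohort is missing cases: %s",
                  paste(missing, collapse = ", ")))
  }
  net <- build_network(config$variant, depth = config$depth,
                       base_filters = config$base_filters,
                       dropout = config$dropout, l2 = config$l2,
                       seed = config$seed)
  loss_grad <- get_loss(config$loss, config$lambda)
  opt_cfg <- sam_config(enabled = config$sam, rho = config$rho,
                        base = "adam", lr = config$lr,
                        weight_decay = config$l2)
  opt_state <- NULL
  history <- tibble(epoch = integer(), train_loss = numeric(),
                    dsc_left = numeric(), dsc_right = numeric())
  snapshots <- list()   # ring buffer of the last `stop_window` param sets
  size <- config$patch_size

  for (epoch in seq_len(config$max_epochs)) {
    epoch_seed <- derive_seed(config$seed, epoch)
    picks_list <- lapply(seq_along(fold$train), function(i) {
      id <- fold$train[i]
      ctr <- sample_patch_centers(cases[[id]]$mask,
                                  config$samples_per_volume,
                                  seed = derive_seed(epoch_seed, i),
                                  size = size)
      ctr$case_id <- id
      ctr
    })
    picks <- dplyr::bind_rows(picks_list)
    picks <- with_seed(derive_seed(epoch_seed, 0L),
                       picks[sample.int(nrow(picks)), ])
    n_steps <- nrow(picks) %/% config$batch_size
    losses <- numeric(n_steps)
    for (step in seq_len(n_steps)) {
      rows <- picks[((step - 1L) * config$batch_size + 1L):
                      (step * config$batch_size), ]
      batch <- make_batch(cases, rows, size)
      step_seed <- derive_seed(epoch_seed, 10000L + step)
      grad_fn <- function(params, final = TRUE) {
        net$params <- params
        # dropout mask fixed per step so both SAM passes see the same
        # stochastic network; BN stats update only on the final pass
        fw <- with_seed(step_seed,
                        net_forward(net, batch$x, train = TRUE,
                                    update_state = final))
        if (final) net$state <<- fw$state
        lg <- loss_grad(fw$probs, batch$y)
        dlogits <- softmax_bwd(fw$probs, lg$dpred)
        list(loss = lg$loss, grads = net_backward(net, fw$cache, dlogits))
      }
      up <- sam_update(grad_fn, net$params, opt_cfg, opt_state)
      net$params <- up$params
      opt_state <- up$opt_state
      losses[step] <- up$loss
      if (!is.finite(up$loss)) {
        abort(sprintf("training diverged (non-finite loss) at epoch %d step %d",
                      epoch, step))
      }
    }
    vd <- validation_dice(net, cases, fold$val, config$val_max_slices)
    history <- dplyr::bind_rows(history,
      tibble(epoch = epoch, train_loss = mean(losses),
             dsc_left = vd[1], dsc_right = vd[2]))
    snapshots[[1L + (epoch - 1L) %% config$stop_window]] <-
      list(epoch = epoch, params = net$params, state = net$state)
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  val DSC L %.4f R %.4f",
                      epoch, mean(losses), vd[1], vd[2]))
    }
    if (early_stop_check(history, config$min_epochs, config$stop_window,
                         config$stop_tol)) break
  }

  window <- min(config$stop_window, nrow(history))
  sel <- select_checkpoint(history, window)
  snap <- Filter(function(s) s$epoch == sel, snapshots)
  if (length(snap) == 1) {
    net$params <- snap[[1]]$params
    net$state <- snap[[1]]$state
  }
  structure(list(net = net, history = history, selected_epoch = sel,
                 config = config, fold = fold),
            class = "pkdseg_model")
}

#' @export
print.pkdseg_model <- function(x, ...) {
  n <- nrow(x$history)
  cat(sprintf(paste0("<pkdseg_model> %s (%s%s), %d epochs, ",
                     "selected epoch %d, final val DSC %.3f/%.3f\n"),
              x$config$variant, x$config$loss,
              if (x$config$sam) "+SAM" else "", n, x$selected_epoch,
              x$history$dsc_left[n], x$history$dsc_right[n]))
  invisible(x)
}

#' Save / load a trained model
#'
#' Weights are stored as an RDS file with a JSON sidecar
#' (`<path>.json`) describing the network spec, the training configuration
#' and the selected epoch.
#'
#' @param model a `pkdseg_model`.
#' @param path output path (conventionally `.rds`).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  sidecar <- list(variant = model$net$spec$variant,
                  spec = model$net$spec,
                  config = unclass(model$config),
                  selected_epoch = model$selected_epoch,
                  n_parameters = n_parameters(model$net))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
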