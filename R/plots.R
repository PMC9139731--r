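# Plotting helpers (ggplot2 is in Suggests; every function checks for it).

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("ggplot2 is required for plotting")
  }
}

#' Plot one coronal slice with an optional mask overlay
#'
#' @param volume a `volume_grid`.
#' @param slice coronal slice index (middle slice by default).
#' @param mask optional `label_mask` whose kidney classes are overlaid.
#' @return A ggplot object.
#' @export
plot_slice <- function(volume, slice = NULL, mask = NULL) {
  need_ggplot()
  d <- dim(volume$data)
  slice <- slice %||% ((d[3] + 1L) %/% 2L)
  df <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  df$intensity <- as.vector(volume$data[, , slice])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(ratio = volume$spacing[1] / volume$spacing[2]) +
    ggplot2::theme_void()
  if (!is.null(mask)) {
    mdf <- df
    mdf$class <- factor(as.vector(mask$data[, , slice]))
    mdf <- mdf[mdf$class != "0", ]
    if (nrow(mdf) > 0) {
      p <- p + ggplot2::geom_raster(data = mdf,
        ggplot2::aes(x = .data$col, y = .data$row, alpha = .data$class),
        fill = "red", inherit.aes = FALSE) +
        ggplot2::scale_alpha_manual(values = c("1" = 0.35, "2" = 0.55))
    }
  }
  p
}

#' Autoplot methods
#'
#' For a `pkdseg_model`, plots the validation Dice learning curves per
#' kidney; for a `pkdseg_report`, a scatter of predicted versus reference
#' TKV with the identity line.
#'
#' @param object a `pkdseg_model` or `pkdseg_report`.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pkdseg_model <- function(object, ...) {
  need_ggplot()
  h <- object$history
  df <- rbind(
    data.frame(epoch = h$epoch, dsc = h$dsc_left, kidney = "left"),
    data.frame(epoch = h$epoch, dsc = h$dsc_right, kidney = "right"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$dsc,
                                   colour = .data$kidney)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$selected_epoch,
                        linetype = "dashed") +
    ggplot2::labs(y = "validation DSC") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.pkdseg_model
#' @exportS3Method ggplot2::autoplot
autoplot.pkdseg_report <- function(object, ...) {
  need_ggplot()
  ggplot2::ggplot(object$cases,
                  ggplot2::aes(x = .data$tkv_ref, y = .data$tkv_pred)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "reference TKV (mL)", y = "predicted TKV (mL)") +
    ggplot2::theme_minimal()
}
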