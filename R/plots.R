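# ggplot2 displays for the main result types.

raster_df <- function(m, value = "value") {
  df <- expand.grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df[[value]] <- as.vector(m)
  df
}

#' Plot a synthetic scene
#'
#' Shows the rendered micrograph with the ground-truth membrane polyline
#' and granule centres overlaid.
#'
#' @param object A `scene_truth`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scene_truth <- function(object, ...) {
  df <- raster_df(object$image$pixels, "gray")
  mem <- as.data.frame(object$membrane_polyline)
  names(mem) <- c("row", "col")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$gray)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 255)) +
    ggplot2::geom_path(data = mem, colour = "red", linewidth = 0.4) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "col (px)", y = "row (px)", fill = "gray")
  if (nrow(object$granule_params) > 0) {
    p <- p + ggplot2::geom_point(
      data = object$granule_params,
      ggplot2::aes(x = .data$center_col, y = .data$center_row),
      colour = "cyan", shape = 3, size = 1)
  }
  p
}

#' Plot the training loss trace
#'
#' @param object An `mfcn_train_state`.
#' @param ... Unused.
#' @return A ggplot object of loss against optimisation step.
#' @export
autoplot.mfcn_train_state <- function(object, ...) {
  ggplot2::ggplot(object$loss_history,
                  ggplot2::aes(x = .data$step, y = .data$loss)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "step", y = "weighted cross-entropy")
}

#' Plot a membrane-distance profile
#'
#' Relative frequency of granules per membrane-distance bin, the standard
#' display for docking enrichment near the plasma membrane.
#'
#' @param profile Tibble from [distance_profile()].
#' @return A ggplot object.
#' @export
plot_distance_profile <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = (.data$bin_lo_nm + .data$bin_hi_nm) / 2,
                               y = .data$rel_freq)) +
    ggplot2::geom_col(width = NULL, fill = "grey35") +
    ggplot2::labs(x = "distance to plasma membrane (nm)",
                  y = "relative frequency")
}

#' Plot an instance map
#'
#' @param imap An `instance_map`.
#' @return A ggplot object with background transparent and instances
#'   coloured by label.
#' @export
plot_instances <- function(imap) {
  df <- raster_df(unclass(imap), "label")
  df$label <- ifelse(df$label == 0, NA, df$label)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = factor(.data$label))) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = "col (px)", y = "row (px)")
}
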