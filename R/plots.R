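# ggplot2 views of the main result types.

#' Plot a sub-region partition
#'
#' Raster of the R1..R4 label map with the longest chord, its quarter
#' points and the region centroids overlaid. The y axis is reversed so the
#' plot matches image coordinates (R1 at the bottom of the fruit).
#'
#' @param object A `subregion_partition`.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot subregion_partition
#' @export
autoplot.subregion_partition <- function(object, ...) {
  lab <- object$labels
  df <- tibble(
    x = rep(0:(ncol(lab) - 1), each = nrow(lab)),
    y = rep(0:(nrow(lab) - 1), ncol(lab)),
    region = as.vector(lab)
  ) |> filter(.data$region > 0) |>
    mutate(region = paste0("R", .data$region))
  chord_df <- tibble(
    x = c(object$chord$p_start[["x"]], object$chord$p_end[["x"]]),
    y = c(object$chord$p_start[["y"]], object$chord$p_end[["y"]])
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$region)) +
    ggplot2::geom_path(data = chord_df, linewidth = 0.8) +
    ggplot2::geom_point(data = object$quarter_points, shape = 4, size = 2) +
    ggplot2::geom_point(data = object$region_centroids, shape = 21,
                        fill = "white", size = 2) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_brewer(palette = "RdYlGn", direction = -1) +
    ggplot2::labs(x = "x (px)", y = "y (px)", fill = "sub-region")
}

#' Plot an evaluation report as a confusion heatmap
#'
#' @param object A `ripeness_eval`.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot ripeness_eval
#' @export
autoplot.ripeness_eval <- function(object, ...) {
  cm <- object$confusion
  df <- as_tibble(as.table(cm)) |>
    mutate(truth = factor(.data$truth, levels = rownames(cm)),
           pred = factor(.data$pred, levels = colnames(cm)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_fill_gradient(low = "white", high = "#b2182b") +
    ggplot2::labs(x = "predicted", y = "true",
                  title = sprintf("accuracy %.3f (n = %d)", object$accuracy,
                                  object$n))
}

#' Channel-mean ripeness trends
#'
#' Computes per-stage means of whole-fruit channel values over a dataset and
#' plots them against the stage code — the view used to pick the informative
#' channels (a and S rise with ripeness; B, G and L fall).
#'
#' @param data Dataset tibble with `mask`, `rgb` and `label` columns.
#' @param channels Channels to plot (any of the nine).
#' @return A ggplot.
#' @export
plot_channel_trends <- function(data, channels = c("B", "G", "L", "a", "S")) {
  means <- purrr::map(seq_len(nrow(data)), function(i) {
    bind_cols(tibble(label = data$label[[i]]),
              whole_fruit_means(to_channel_stack(data$rgb[[i]]), data$mask[[i]]))
  }) |> bind_rows()
  long <- means |>
    tidyr::pivot_longer(-"label", names_to = "channel", values_to = "value") |>
    filter(.data$channel %in% channels) |>
    group_by(.data$label, .data$channel) |>
    summarise(value = mean(.data$value), .groups = "drop") |>
    mutate(code = as.integer(.data$label) - 1)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$code, y = .data$value,
                                     colour = .data$channel)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "ripeness stage (0 = White .. 5 = Full ripe)",
                  y = "mean channel value (8-bit scale)", colour = "channel")
}
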