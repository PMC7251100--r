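#' Plot a connectivity or synchronizability series
#'
#' Line plot of the algebraic-connectivity feature over time, with optional
#' threshold line and shaded annotated seizure intervals.
#'
#' @param object a `connectivity_series` or `sync_series`.
#' @param threshold optional horizontal detection threshold.
#' @param annotations optional [annotations_tbl()] to shade.
#' @param value_col feature column to draw (defaults to `ema` if present,
#'   else `lambda2`).
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.connectivity_series <- function(object, threshold = NULL,
                                         annotations = NULL,
                                         value_col = NULL, ...) {
  sv <- series_values(object, value_col)
  df <- tibble::tibble(time_s = sv$time, value = sv$value)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value))
  if (!is.null(annotations) && nrow(annotations) > 0) {
    p <- p + ggplot2::geom_rect(
      data = tibble::as_tibble(annotations),
      ggplot2::aes(xmin = .data$onset, xmax = .data$offset),
      ymin = -Inf, ymax = Inf, fill = "firebrick", alpha = 0.15,
      inherit.aes = FALSE
    )
  }
  p <- p + ggplot2::geom_line(linewidth = 0.3)
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                                 colour = "steelblue")
  }
  p + ggplot2::labs(x = "time (s)", y = sv$col) + ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.sync_series <- autoplot.connectivity_series

#' Heat map of a coupling or adjacency matrix
#'
#' @param m square weight matrix (e.g. one entry of a `coupling_series`, or
#'   a `network_frame`'s adjacency).
#' @param title optional plot title.
#' @return a ggplot object.
#' @export
plot_coupling_matrix <- function(m, title = NULL) {
  df <- tibble::tibble(
    src = factor(col(m), labels = colnames(m) %||% seq_len(ncol(m))),
    dst = factor(row(m), labels = rownames(m) %||% seq_len(nrow(m))),
    weight = as.numeric(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$src, y = .data$dst,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "source", y = "target", title = title) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6),
                   axis.text.y = ggplot2::element_text(size = 6))
}
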