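#' Plot benchmark metrics
#'
#' Sensitivity against precision, one point per method, faceted by dataset —
#' the usual way to read off the agreement-threshold trade-off (strict
#' consensus buys precision at the cost of missed fusions).
#'
#' @param object A `fusemble_benchmark`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fusemble_benchmark
#' @export
autoplot.fusemble_benchmark <- function(object, ...) {
  ggplot2::ggplot(object$results,
    ggplot2::aes(x = .data$sensitivity, y = .data$precision,
      label = .data$method)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::facet_wrap(~dataset) +
    ggplot2::coord_cartesian(xlim = c(0, 105), ylim = c(0, 105)) +
    ggplot2::labs(x = "Sensitivity (%)", y = "Precision (%)") +
    ggplot2::theme_bw()
}

#' Plot the detection matrix
#'
#' Truth fusions in rows, methods in columns; filled tiles mark correct
#' detection of the expected rearrangement.
#'
#' @param x A `fusemble_benchmark`.
#' @return A ggplot object.
#' @export
plot_detection_matrix <- function(x) {
  d <- x$detection |>
    mutate(fusion = paste0(.data$sample_id, " ", .data$gene5, "::", .data$gene3))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$method, y = .data$fusion,
    fill = .data$detected)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2e8b57", `FALSE` = "grey90"),
      labels = c(`TRUE` = "detected", `FALSE` = "not detected"),
      name = NULL) +
    ggplot2::facet_grid(dataset ~ ., scales = "free_y", space = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the integration funnel
#'
#' Event counts at each pipeline stage (raw calls, merged events, k-of-5
#' consensus, retained after filtering).
#'
#' @param object A `fusemble_integration`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fusemble_integration
#' @export
autoplot.fusemble_integration <- function(object, ...) {
  d <- object$funnel |>
    mutate(stage = factor(.data$stage, levels = .data$stage))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stage, y = .data$n)) +
    ggplot2::geom_col(fill = "#4878a8") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "events") +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
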