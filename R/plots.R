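#' @export
autoplot.kdemg_density <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$grid,
                                             y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "value", y = "density",
                  title = sprintf("KDE (%s, h = %.3g, n = %d)",
                                  object$method, object$bandwidth, object$n))
}

#' @export
autoplot.kdemg_derivative <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$grid,
                                             y = .data$derivative)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "value", y = sprintf("density derivative (r = %d)",
                                           object$order))
}

#' @export
autoplot.kdemg_metrics <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$class, y = .data$f1)) +
    ggplot2::geom_col() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "class", y = "F-score",
                  title = sprintf("Per-class F (accuracy %.3f)",
                                  object$accuracy))
}

#' Confusion-matrix heatmap
#'
#' @param cm A `kdemg_confusion` matrix.
#' @return A ggplot object.
#' @export
plot_confusion <- function(cm) {
  df <- as.data.frame(as.table(unclass(cm)))
  names(df) <- c("truth", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "predicted", y = "truth")
}

#' @export
autoplot.kdemg_online <- function(object, ...) {
  ggplot2::ggplot(object$results,
                  ggplot2::aes(x = .data$width_ms, y = .data$accuracy)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "epoch width (ms)", y = "accuracy (TMD + LDA)")
}
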