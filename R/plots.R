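#' Plot a class-distance ranking
#'
#' Bar chart of the between-class distance per feature, descending, with
#' the preliminary pool (top m) highlighted — the standard way to display
#' the stage-1 ranking.
#'
#' @param object An `"eus_ranking"` from [rank_features()].
#' @param top How many features to show (default: all).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot eus_ranking
#' @export
autoplot.eus_ranking <- function(object, top = nrow(object), ...) {
  d <- utils::head(as_tibble(object), top)
  d$feature <- factor(d$feature, levels = rev(d$feature))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$feature, y = .data$score,
                                  fill = .data$selected)) +
    ggplot2::geom_col(show.legend = TRUE) +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2c7fb8", `FALSE` = "grey70"),
                               name = "preliminary pool") +
    ggplot2::labs(x = NULL, y = "between-class distance",
                  title = "Class-distance feature ranking")
}

#' Plot a sequential-forward-selection trace
#'
#' Correct classification rate against the number of features added, with
#' the optimum subset size marked.
#'
#' @param object An `"eus_sfs_trace"` from [sfs_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot eus_sfs_trace
#' @export
autoplot.eus_sfs_trace <- function(object, ...) {
  opt <- attr(object, "optimum")
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$k, y = .data$ccr)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = opt$k, linetype = 2, color = "#d95f02") +
    ggplot2::annotate("text", x = opt$k, y = min(object$ccr),
                      label = sprintf("k* = %d (%.2f%%)", opt$k, opt$ccr),
                      hjust = -0.05, vjust = 0, color = "#d95f02") +
    ggplot2::labs(x = "features added (ranked order)",
                  y = "correct classification rate (%)",
                  title = "Sequential forward selection")
}

#' Plot a validation report
#'
#' Distribution of the per-trial diagnostic metrics (boxplots) for a
#' repeated-split report, or a dot plot for a single pooled metric set.
#'
#' @param object An `"eus_metrics"` report.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot eus_metrics
#' @export
autoplot.eus_metrics <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_trial, -"trial",
                              names_to = "metric", values_to = "value")
  long$metric <- factor(long$metric, levels = metric_names())
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value))
  p <- if (object$n_trials > 1) p + ggplot2::geom_boxplot(fill = "#a6bddb")
  else p + ggplot2::geom_point(size = 3, color = "#2c7fb8")
  p + ggplot2::labs(x = NULL, y = "percent",
                    title = sprintf("Diagnostic metrics (%s)", object$protocol))
}

#' Display a grey-level image or texture
#'
#' Raster plot of a grey-level matrix in its natural orientation (row 1 at
#' the top), intensity-true grayscale.
#'
#' @param image Grey-level matrix.
#' @return A ggplot.
#' @export
plot_gray_image <- function(image) {
  d <- tidyr::expand_grid(row = seq_len(nrow(image)), col = seq_len(ncol(image)))
  d$value <- image[cbind(d$row, d$col)]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255), name = "intensity") +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
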