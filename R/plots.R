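#' Plot helpers
#'
#' ggplot2 views of the main result types: per-model accuracy
#' distributions, confusion matrices, and kernel matrices.
#'
#' @name plots
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Accuracy distributions per model
#'
#' Box plots of fold-level cross-validation accuracies, Riemannian and
#' traditional models color-coded, ordered by mean accuracy.
#'
#' @param object a `riemnirs_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot riemnirs_report
#' @export
autoplot.riemnirs_report <- function(object, ...) {
  df <- tidy(object)
  types <- stats::setNames(object$type, object$model)
  df$type <- types[df$model]
  ord <- object$model[order(object$mean_accuracy)]
  df$model <- factor(df$model, levels = ord)
  n_classes <- length(unique(attr(object, "labels")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$accuracy,
                                   fill = .data$type)) +
    ggplot2::geom_boxplot(outlier.size = 0.7) +
    ggplot2::geom_hline(yintercept = 1 / n_classes, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "cross-validation accuracy", fill = NULL,
                  caption = "dashed line: theoretical chance") +
    ggplot2::theme_minimal()
}

#' Confusion matrix heatmap for one model
#'
#' @param report a `riemnirs_report`.
#' @param model model name; defaults to the most accurate one.
#' @return a ggplot object.
#' @export
plot_confusion <- function(report, model = NULL) {
  stopifnot(inherits(report, "riemnirs_report"))
  if (is.null(model)) model <- report$model[which.max(report$mean_accuracy)]
  conf <- attr(report, "confusions")[[model]]
  if (is.null(conf)) stop(sprintf("no confusion matrix for '%s'", model), call. = FALSE)
  df <- as.data.frame(as.table(conf))
  names(df) <- c("true", "predicted", "count")
  df$prop <- df$count / stats::ave(df$count, df$true, FUN = sum)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$prop)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$prop)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2166ac",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(title = model, x = "predicted", y = "true",
                  fill = "row prop.") +
    ggplot2::theme_minimal()
}

#' Heatmap of a kernel/covariance matrix
#'
#' @param K symmetric matrix (e.g. from [build_block_kernel()]).
#' @param zero_diag set the diagonal to zero before plotting, which makes
#'   the off-diagonal structure visible when channel variances dominate.
#' @return a ggplot object.
#' @export
plot_kernel_matrix <- function(K, zero_diag = TRUE) {
  stopifnot(is.matrix(K))
  if (zero_diag) diag(K) <- 0
  df <- expand.grid(row = seq_len(nrow(K)), col = seq_len(ncol(K)))
  df$value <- as.vector(K)
  lim <- max(abs(df$value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", limits = c(-lim, lim)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "channel", y = "channel", fill = "value") +
    ggplot2::theme_minimal()
}
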