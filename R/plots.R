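# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   facet_wrap labs theme_minimal coord_flip
#' @export
ggplot2::autoplot

#' Plot a 2-D embedding colored by class
#'
#' @param object An `eeg_embedding` (from [tsne_embed()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eeg_embedding <- function(object, ...) {
  df <- as_tibble(object)
  p <- ggplot(df, aes(x = .data$x, y = .data$y))
  if ("label" %in% names(df))
    p <- ggplot(df, aes(x = .data$x, y = .data$y,
                        colour = factor(.data$label)))
  p + geom_point(alpha = 0.8) +
    labs(colour = "class", x = "t-SNE 1", y = "t-SNE 2",
         title = sprintf("t-SNE embedding (perplexity %g, %d iterations)",
                         attr(object, "perplexity"),
                         attr(object, "iterations"))) +
    theme_minimal()
}

#' Plot CNN training curves
#'
#' Loss and accuracy per epoch for the training and monitoring-validation
#' sets.
#'
#' @param object A trained `eeg_cnn`.
#' @param ... Unused.
#' @return A ggplot (facets: loss, accuracy).
#' @export
autoplot.eeg_cnn <- function(object, ...) {
  h <- tidy(object)
  long <- tidyr::pivot_longer(h, c("loss", "val_loss", "accuracy",
                                   "val_accuracy"),
                              names_to = "series", values_to = "value")
  long$panel <- ifelse(grepl("loss", long$series), "loss", "accuracy")
  ggplot(long, aes(x = .data$epoch, y = .data$value,
                   colour = .data$series)) +
    geom_line() +
    facet_wrap(~panel, scales = "free_y") +
    labs(x = "epoch", y = NULL, title = "Training history") +
    theme_minimal()
}

#' Plot back-projected feature importances
#'
#' @param object A `feature_importance` tibble (optionally tiered by
#'   [rank_and_bucket()]).
#' @param top_n Show the top `top_n` features (default all).
#' @param ... Unused.
#' @return A ggplot bar chart.
#' @export
autoplot.feature_importance <- function(object, top_n = nrow(object), ...) {
  df <- utils::head(dplyr::arrange(object, .data$rank), top_n)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  p <- if ("tier" %in% names(df))
    ggplot(df, aes(x = .data$feature, y = .data$importance,
                   fill = .data$tier))
  else ggplot(df, aes(x = .data$feature, y = .data$importance))
  p + geom_col() + coord_flip() +
    labs(x = NULL, y = "mean |SHAP| x |loading|",
         title = "Back-projected EEG feature importance") +
    theme_minimal()
}

#' Scatter of the first two principal components
#'
#' @param scores Score matrix.
#' @param label Class labels.
#' @return A ggplot.
#' @export
plot_pca_scores <- function(scores, label) {
  df <- tibble(PC1 = scores[, 1], PC2 = scores[, 2], label = factor(label))
  ggplot(df, aes(x = .data$PC1, y = .data$PC2, colour = .data$label)) +
    geom_point(alpha = 0.8) +
    labs(title = "PCA scores") +
    theme_minimal()
}
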