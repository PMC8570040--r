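#' Learning-curve plot
#'
#' Train and test loss (left) and accuracy (right) over epochs — the standard
#' overfitting diagnostic: a test loss that turns upward while the train loss
#' keeps falling marks an overconfident model.
#'
#' @param history a `train_history` tibble (from an `mi_fit`), or an
#'   `mi_fit`.
#' @return A ggplot object.
#' @export
plot_history <- function(history) {
  if (inherits(history, "mi_fit")) history <- history$history
  h <- tibble::as_tibble(history)
  long <- rbind(
    data.frame(epoch = h$epoch, value = h$train_loss, series = "train",
               panel = "loss"),
    data.frame(epoch = h$epoch, value = h$test_loss, series = "test",
               panel = "loss"),
    data.frame(epoch = h$epoch, value = h$train_acc, series = "train",
               panel = "accuracy"),
    data.frame(epoch = h$epoch, value = h$test_acc, series = "test",
               panel = "accuracy"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mi_fit <- function(object, ...) plot_history(object)

#' 2-D feature map
#'
#' PCA projection of penultimate features, colored by class — the visual
#' check that joint supervision with the center loss tightens classes and
#' separates them.
#'
#' @param features `n x d` feature matrix (see [extract_features()]).
#' @param labels 0-based integer class labels.
#' @return A ggplot object.
#' @export
plot_features <- function(features, labels) {
  sco <- pca_project(features, 2L)
  ev <- attr(sco, "explained_variance")
  df <- data.frame(pc1 = sco[, 1], pc2 = sco[, 2],
                   class = factor(labels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pc1, y = .data$pc2,
                                   colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * ev[1]),
                  y = sprintf("PC2 (%.1f%%)", 100 * ev[2])) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mi_ablation <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$value, y = .data$test_accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = unique(object$parameter), y = "test accuracy") +
    ggplot2::theme_minimal()
}
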