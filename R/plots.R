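#' Plot cross-validation metrics
#'
#' Boxplots of the per-run metric values, one panel per metric, comparing
#' the graph-autoencoder pipeline with the absolute-Spearman baseline.
#'
#' @param object A `grn_metrics` from [run_grn_cv()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.grn_metrics <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_run,
                              c("auroc", "auprc", "epr", "aupr_ratio"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$method, y = .data$value,
                                     fill = .data$method)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Cross-validated inference metrics (%d runs)",
                                  object$n_runs)) +
    ggplot2::theme_minimal()
}

#' Plot the training history of a fitted graph autoencoder
#'
#' Train and validation loss per epoch, with the restored best epoch marked.
#'
#' @param object A [gae_fit()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gae_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                              names_to = "series", values_to = "loss")
  long <- long[!is.na(long$loss), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed") +
    ggplot2::labs(x = "epoch", y = "binary cross-entropy",
                  colour = NULL, title = "GAE training history") +
    ggplot2::theme_minimal()
}

#' Heatmap of a signed regulatory score matrix
#'
#' Diverging-colour tile map of the score matrix from [infer_grn()]:
#' positive scores (activating) in red, negative (inhibitory) in blue.
#'
#' @param scores A genes x genes signed score matrix.
#' @return A ggplot object.
#' @export
plot_score_matrix <- function(scores) {
  df <- as.data.frame(as.table(scores), stringsAsFactors = FALSE)
  names(df) <- c("regulator", "target", "score")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$target, y = .data$regulator,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b") +
    ggplot2::labs(title = "Inferred regulatory scores") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
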