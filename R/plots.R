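#' Training-history plot
#'
#' Train and validation joint loss per epoch, with the best-validation
#' epoch marked.
#'
#' @param object A `ktm_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ktm_fit <- function(object, ...) {
  df <- tidy.ktm_fit(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$dataset)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2,
                        colour = "grey40") +
    ggplot2::labs(x = "epoch", y = "joint loss", colour = NULL,
                  title = "Training history",
                  subtitle = paste0("best validation epoch ",
                                    object$best_epoch)) +
    ggplot2::theme_minimal()
}

#' Confusion-matrix heatmap of a cross-validation report
#'
#' @param object A `ktm_eval` with a confusion matrix.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ktm_eval <- function(object, ...) {
  if (is.null(object$confusion)) {
    stop("report has no confusion matrix (regression-only run)",
         call. = FALSE)
  }
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("truth", "prediction", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$prediction, y = .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev(ktm_classes())) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = "Pooled confusion matrix",
                  x = "predicted class", y = "true class") +
    ggplot2::theme_minimal()
}

#' One-vs-rest ROC curves
#'
#' @param truth Labels among the 4 classes.
#' @param probs Class-probability matrix in the fixed class order.
#' @return A ggplot of the four one-vs-rest ROC curves with AUCs in the
#'   legend.
#' @export
plot_roc <- function(truth, probs) {
  roc <- roc_auc_ovr(truth, probs)
  lab <- stats::setNames(
    sprintf("%s (AUC %.2f)", names(roc$auc), roc$auc), names(roc$auc))
  df <- roc$curves
  df$class <- factor(df$class, levels = ktm_classes())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                   colour = .data$class)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3,
                         colour = "grey60") +
    ggplot2::scale_colour_discrete(labels = lab) +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  colour = NULL, title = "One-vs-rest ROC") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
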