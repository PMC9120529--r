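#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a trained fit
#'
#' @param x A `ktm_fit`.
#' @param ... Unused.
#' @return The per-epoch training history as a long tibble
#'   (`epoch`, `dataset`, `loss`).
#' @export
tidy.ktm_fit <- function(x, ...) {
  tidyr::pivot_longer(x$history, -"epoch", names_to = "dataset",
                      values_to = "loss",
                      names_pattern = "(.*)_loss")
}

#' @rdname tidy.ktm_fit
#' @return `glance()`: a one-row tibble with `variant`, `n_params`,
#'   `epochs_run`, `best_epoch`, `best_val_loss`, `alpha`, `beta`.
#' @export
glance.ktm_fit <- function(x, ...) {
  tibble::tibble(variant = x$model$config$variant,
                 n_params = x$model$n_params,
                 epochs_run = x$epochs_run,
                 best_epoch = x$best_epoch,
                 best_val_loss = x$best_val_loss,
                 alpha = x$loss_config$alpha,
                 beta = x$loss_config$beta)
}

#' Tidy an evaluation report
#'
#' @param x A `ktm_eval`.
#' @param ... Unused.
#' @return A long tibble with one row per metric: `metric`, `group`
#'   (timepoint or class), `mean`, `sd`.
#' @export
tidy.ktm_eval <- function(x, ...) {
  rows <- list()
  if (!is.null(x$regression)) {
    rows$reg <- purrr::map_dfr(c("rmse", "corr"), function(m) {
      tibble::tibble(metric = m, group = x$regression$timepoint,
                     mean = x$regression[[paste0(m, "_mean")]],
                     sd = x$regression[[paste0(m, "_sd")]])
    })
  }
  if (!is.null(x$per_class)) {
    rows$cls <- purrr::map_dfr(c("precision", "sensitivity", "f1", "auc"),
                               function(m) {
      tibble::tibble(metric = m, group = x$per_class$class,
                     mean = x$per_class[[paste0(m, "_mean")]],
                     sd = x$per_class[[paste0(m, "_sd")]])
    })
    rows$acc <- tibble::tibble(metric = "accuracy", group = "overall",
                               mean = x$accuracy_mean, sd = x$accuracy_sd)
  }
  dplyr::bind_rows(rows)
}

#' @rdname tidy.ktm_eval
#' @export
glance.ktm_eval <- function(x, ...) {
  tibble::tibble(
    n_folds = x$n_folds,
    accuracy_mean = x$accuracy_mean,
    accuracy_sd = x$accuracy_sd,
    mean_rmse = if (!is.null(x$regression)) mean(x$regression$rmse_mean)
                else NA_real_,
    mean_corr = if (!is.null(x$regression)) mean(x$regression$corr_mean)
                else NA_real_,
    mean_auc = if (!is.null(x$per_class)) mean(x$per_class$auc_mean)
               else NA_real_,
    n_excluded = x$n_excluded
  )
}
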