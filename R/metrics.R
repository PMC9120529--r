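#' Root mean square error
#'
#' @param y,y_hat Equal-length numeric vectors.
#' @return `sqrt(mean((y - y_hat)^2))`.
#' @export
rmse <- function(y, y_hat) {
  if (length(y) == 0 || length(y) != length(y_hat)) {
    stop("rmse: need equal, non-zero lengths", call. = FALSE)
  }
  sqrt(mean((y - y_hat)^2))
}

#' Pearson correlation between truth and prediction
#'
#' The standard product-moment correlation, each vector centered by its own
#' mean. Constant inputs make the correlation undefined; it is reported as
#' `NA` with a warning rather than an arbitrary value.
#'
#' @param y,y_hat Equal-length numeric vectors (length >= 2).
#' @return A value in [-1, 1], or `NA` when undefined.
#' @export
pearson_r <- function(y, y_hat) {
  if (length(y) < 2 || length(y) != length(y_hat)) {
    stop("pearson_r: need equal lengths >= 2", call. = FALSE)
  }
  dy <- y - mean(y)
  dh <- y_hat - mean(y_hat)
  den <- sqrt(sum(dy^2) * sum(dh^2))
  if (den == 0) {
    warning("pearson_r undefined for constant input; returning NA")
    return(NA_real_)
  }
  sum(dy * dh) / den
}

#' Multiclass classification report
#'
#' Converts class probabilities to hard labels by argmax (lowest-index
#' tie-break in the fixed class order AD, MCI-C, MCI-NC, CN) and computes
#' the one-vs-rest precision, sensitivity and F1 per class, the overall
#' accuracy, and the 4 x 4 confusion matrix (rows = truth, columns =
#' prediction). Ratios with a zero denominator are reported as `NA`.
#'
#' @param truth Factor/character labels among the 4 classes.
#' @param probs Numeric matrix, one column per class in the fixed order.
#' @return A list: `per_class` tibble (`class`, `precision`, `sensitivity`,
#'   `f1`, each as a fraction), `accuracy` (percent), `confusion` (integer
#'   matrix).
#' @export
multiclass_report <- function(truth, probs) {
  cl <- ktm_classes()
  truth <- as.character(truth)
  if (any(!truth %in% cl)) {
    stop("truth labels outside the 4-class set", call. = FALSE)
  }
  probs <- as.matrix(probs)
  stopifnot(ncol(probs) == length(cl), nrow(probs) == length(truth))
  pred <- cl[max.col(probs, ties.method = "first")]
  confusion <- table(factor(truth, levels = cl), factor(pred, levels = cl))
  confusion <- matrix(as.integer(confusion), 4, 4, dimnames = dimnames(confusion))
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  safe_div <- function(num, den) ifelse(den == 0, NA_real_, num / den)
  precision <- safe_div(tp, tp + fp)
  sensitivity <- safe_div(tp, tp + fn)
  f1 <- ifelse(is.na(precision) | is.na(sensitivity) |
                 (precision + sensitivity) == 0, NA_real_,
               2 * precision * sensitivity / (precision + sensitivity))
  list(
    per_class = tibble::tibble(class = cl, precision = unname(precision),
                               sensitivity = unname(sensitivity),
                               f1 = unname(f1)),
    accuracy = 100 * sum(tp) / length(truth),
    confusion = confusion
  )
}

#' One-vs-rest ROC curves and AUC
#'
#' For each class, the class-probability column scores that class against
#' the rest. AUC uses the rank (Mann-Whitney) formulation with midpoint
#' handling of ties, equivalent to trapezoidal integration of the ROC
#' curve over all thresholds. Classes without both a positive and a
#' negative example get `NA`.
#'
#' @param truth Factor/character labels among the 4 classes.
#' @param probs Numeric matrix, one column per class in the fixed order.
#' @return A list: `auc` (named length-4 vector) and `curves` (tibble of
#'   `class`, `fpr`, `tpr`, `threshold` staircase coordinates).
#' @export
roc_auc_ovr <- function(truth, probs) {
  cl <- ktm_classes()
  truth <- as.character(truth)
  probs <- as.matrix(probs)
  auc <- stats::setNames(rep(NA_real_, 4), cl)
  curves <- vector("list", 4)
  for (k in seq_along(cl)) {
    pos <- truth == cl[k]
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) next
    s <- probs[, k]
    r <- rank(s)  # average ranks = midpoint tie convention
    auc[k] <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    thr <- sort(unique(s), decreasing = TRUE)
    tpr <- vapply(thr, function(t_) sum(pos & s >= t_) / n1, numeric(1))
    fpr <- vapply(thr, function(t_) sum(!pos & s >= t_) / n0, numeric(1))
    curves[[k]] <- tibble::tibble(class = cl[k],
                                  fpr = c(0, fpr), tpr = c(0, tpr),
                                  threshold = c(Inf, thr))
  }
  list(auc = auc, curves = dplyr::bind_rows(curves))
}

# Metrics of a single fold's prediction table.
fold_metrics <- function(fr) {
  stopifnot(inherits(fr, "ktm_fold_result"))
  p <- fr$predictions
  tp_cols <- ktm_mmse_cols()
  has_r <- all(paste0("PRED_", tp_cols) %in% names(p))
  has_c <- all(paste0("PROB_", ktm_classes()) %in% names(p))
  reg <- NULL
  if (has_r) {
    reg <- tibble::tibble(
      timepoint = tp_cols,
      rmse = vapply(tp_cols, function(cl)
        rmse(p[[cl]], p[[paste0("PRED_", cl)]]), numeric(1)),
      corr = vapply(tp_cols, function(cl) {
        yh <- p[[paste0("PRED_", cl)]]
        if (stats::sd(p[[cl]]) == 0 || stats::sd(yh) == 0) NA_real_
        else pearson_r(p[[cl]], yh)
      }, numeric(1))
    )
  }
  cls <- NULL; acc <- NA_real_; confusion <- NULL; auc <- NULL
  if (has_c) {
    probs <- as.matrix(p[, paste0("PROB_", ktm_classes())])
    rep_ <- multiclass_report(p$LABEL_24M, probs)
    cls <- rep_$per_class
    cls$auc <- unname(roc_auc_ovr(p$LABEL_24M, probs)$auc)
    acc <- rep_$accuracy
    confusion <- rep_$confusion
  }
  list(fold_id = fr$fold_id, regression = reg, per_class = cls,
       accuracy = acc, confusion = confusion, epochs_run = fr$epochs_run)
}

mean_sd <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(c(mean = NA_real_, sd = NA_real_))
  c(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else NA_real_)
}

#' Aggregate cross-validation folds into an evaluation report
#'
#' Every metric is computed within fold and reported as mean +/- sample
#' standard deviation across folds; the confusion matrix is the element-wise
#' sum over folds. Metrics undefined in a fold (e.g. a class absent from
#' that fold) are excluded from the aggregate rather than zero-filled, and
#' the number of such exclusions is reported.
#'
#' @param results A `ktm_cv` (or plain list of `ktm_fold_result`s) with at
#'   least 2 folds.
#' @return A `ktm_eval` report: `regression` (per-timepoint RMSE and
#'   correlation, mean and sd), `per_class` (precision, sensitivity, F1,
#'   AUC), `accuracy_mean`/`accuracy_sd` (percent), summed `confusion`,
#'   `per_fold` summaries, and `n_excluded` undefined-metric exclusions.
#' @export
aggregate_cv <- function(results) {
  if (length(results) < 2) stop("need >= 2 folds to aggregate", call. = FALSE)
  fms <- lapply(results, fold_metrics)
  has_r <- !is.null(fms[[1]]$regression)
  has_c <- !is.null(fms[[1]]$per_class)
  n_excluded <- 0L
  regression <- NULL
  if (has_r) {
    tp_cols <- ktm_mmse_cols()
    regression <- purrr::map_dfr(seq_along(tp_cols), function(i) {
      rv <- vapply(fms, function(f) f$regression$rmse[i], numeric(1))
      cv <- vapply(fms, function(f) f$regression$corr[i], numeric(1))
      n_excluded <<- n_excluded + sum(is.na(cv))
      tibble::tibble(timepoint = tp_cols[i],
                     rmse_mean = mean_sd(rv)[["mean"]],
                     rmse_sd = mean_sd(rv)[["sd"]],
                     corr_mean = mean_sd(cv)[["mean"]],
                     corr_sd = mean_sd(cv)[["sd"]])
    })
  }
  per_class <- NULL; confusion <- NULL
  acc <- c(mean = NA_real_, sd = NA_real_)
  per_fold <- tibble::tibble(
    fold = vapply(fms, function(f) f$fold_id, numeric(1)),
    accuracy = vapply(fms, function(f) f$accuracy, numeric(1)),
    mean_rmse = if (has_r) {
      vapply(fms, function(f) mean(f$regression$rmse), numeric(1))
    } else NA_real_,
    epochs_run = vapply(fms, function(f) f$epochs_run %||% NA_real_,
                        numeric(1))
  )
  if (has_c) {
    per_class <- purrr::map_dfr(seq_along(ktm_classes()), function(k) {
      row <- tibble::tibble(class = ktm_classes()[k])
      for (m in c("precision", "sensitivity", "f1", "auc")) {
        v <- vapply(fms, function(f) f$per_class[[m]][k], numeric(1))
        n_excluded <<- n_excluded + sum(is.na(v))
        ms <- mean_sd(v)
        row[[paste0(m, "_mean")]] <- ms[["mean"]]
        row[[paste0(m, "_sd")]] <- ms[["sd"]]
      }
      row
    })
    acc <- mean_sd(vapply(fms, function(f) f$accuracy, numeric(1)))
    confusion <- Reduce(`+`, lapply(fms, function(f) f$confusion))
  }
  structure(list(
    regression = regression,
    per_class = per_class,
    accuracy_mean = acc[["mean"]],
    accuracy_sd = acc[["sd"]],
    confusion = confusion,
    per_fold = per_fold,
    n_folds = length(fms),
    n_excluded = n_excluded
  ), class = "ktm_eval")
}

#' @export
print.ktm_eval <- function(x, ...) {
  cat("<ktm_eval> ", x$n_folds, "-fold aggregate\n", sep = "")
  if (!is.null(x$per_class)) {
    cat(sprintf("  accuracy: %.2f +/- %.2f %%\n", x$accuracy_mean,
                x$accuracy_sd))
  }
  if (!is.null(x$regression)) {
    cat(sprintf("  mean RMSE across timepoints: %.3f\n",
                mean(x$regression$rmse_mean)))
  }
  invisible(x)
}

#' Paired t test between per-fold metrics
#'
#' Two-sided paired t-test on fold-wise differences of a metric between two
#' models evaluated on the same folds. Zero-variance differences make the
#' statistic degenerate; the result is then flagged and the p-value is
#' reported as 1 (all differences zero) or 0 (a consistent non-zero
#' difference) instead of erroring.
#'
#' @param metric_a,metric_b Equal-length (>= 2) numeric vectors, paired by
#'   fold.
#' @return A tibble with `t`, `p_value`, `mean_diff`, `df`, `degenerate`.
#' @export
paired_ttest <- function(metric_a, metric_b) {
  if (length(metric_a) != length(metric_b) || length(metric_a) < 2) {
    stop("paired_ttest: need equal lengths >= 2", call. = FALSE)
  }
  d <- metric_a - metric_b
  if (stats::sd(d) == 0) {
    all_zero <- all(d == 0)
    return(tibble::tibble(
      t = if (all_zero) 0 else sign(d[1]) * Inf,
      p_value = if (all_zero) 1 else 0,
      mean_diff = mean(d),
      df = length(d) - 1,
      degenerate = TRUE
    ))
  }
  tt <- stats::t.test(metric_a, metric_b, paired = TRUE)
  tibble::tibble(t = unname(tt$statistic), p_value = tt$p.value,
                 mean_diff = unname(tt$estimate),
                 df = unname(tt$parameter), degenerate = FALSE)
}

#' Serialize an evaluation report
#'
#' Writes the full report as JSON and, alongside it, the confusion matrix
#' and per-class ROC-ready coordinates as CSV for plotting.
#'
#' @param x A `ktm_eval`.
#' @param path JSON output path; `<path>_confusion.csv` is written next to
#'   it when a confusion matrix is present.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(x, path) {
  stopifnot(inherits(x, "ktm_eval"))
  obj <- list(
    n_folds = x$n_folds,
    accuracy_mean = x$accuracy_mean,
    accuracy_sd = x$accuracy_sd,
    regression = x$regression,
    per_class = x$per_class,
    per_fold = x$per_fold,
    confusion = if (!is.null(x$confusion)) as.data.frame(x$confusion),
    n_excluded = x$n_excluded
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  if (!is.null(x$confusion)) {
    utils::write.csv(x$confusion,
                     sub("\\.json$", "_confusion.csv", path))
  }
  invisible(path)
}
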