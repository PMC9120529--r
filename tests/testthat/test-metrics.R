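test_that("rmse and pearson match hand evaluations", {
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  expect_error(rmse(numeric(0), numeric(0)), "lengths")
  y <- c(1, 3, 5, 7)
  expect_equal(pearson_r(y, y), 1)
  expect_equal(pearson_r(y, -(y - mean(y))), -1)
  expect_equal(pearson_r(y, 2 * y + 3), 1)
  expect_warning(r <- pearson_r(y, rep(2, 4)), "constant")
  expect_true(is.na(r))
})

test_that("regression metrics match brute force on random inputs", {
  set.seed(55)
  for (i in 1:100) {
    n <- sample(3:60, 1)
    y <- runif(n, 0, 30)
    y_hat <- y + rnorm(n, 0, 2)
    expect_lt(abs(rmse(y, y_hat) - oracle_rmse(y, y_hat)) /
                oracle_rmse(y, y_hat), 1e-10)
    r <- pearson_r(y, y_hat)
    expect_lt(abs(r - oracle_pearson(y, y_hat)) / max(abs(r), 1e-3), 1e-10)
  }
})

test_that("classification report matches hand counts", {
  # perfect prediction
  truth <- rep(ktm_classes(), each = 3)
  probs <- one_hot_labels(truth)
  rep_ <- multiclass_report(truth, probs)
  expect_equal(rep_$accuracy, 100)
  expect_true(all(rep_$per_class$precision == 1))
  expect_true(all(rep_$per_class$f1 == 1))
  expect_equal(unname(diag(rep_$confusion)), rep(3L, 4))

  # everything predicted CN on a balanced set
  all_cn <- matrix(rep(c(0, 0, 0, 1), length(truth)), ncol = 4,
                   byrow = TRUE)
  rep_cn <- multiclass_report(truth, all_cn)
  expect_equal(rep_cn$accuracy, 25)
  expect_equal(rep_cn$per_class$sensitivity[4], 1)
  expect_equal(rep_cn$per_class$sensitivity[1:3], rep(0, 3))
  # precision undefined for classes never predicted
  expect_true(all(is.na(rep_cn$per_class$precision[1:3])))
  expect_error(multiclass_report(c("AD", "SMC"), all_cn[1:2, ]), "4-class")
})

test_that("confusion marginals are conserved and micro-recall = accuracy", {
  set.seed(77)
  for (i in 1:50) {
    n <- sample(8:80, 1)
    truth <- sample(ktm_classes(), n, replace = TRUE)
    probs <- random_probs(n)
    rep_ <- multiclass_report(truth, probs)
    cm <- rep_$confusion
    expect_equal(sum(cm), n)
    expect_equal(unname(rowSums(cm)),
                 unname(as.integer(table(factor(truth,
                                                levels = ktm_classes())))))
    pred <- ktm_classes()[max.col(probs, ties.method = "first")]
    expect_equal(unname(colSums(cm)),
                 unname(as.integer(table(factor(pred,
                                                levels = ktm_classes())))))
    expect_equal(sum(diag(cm)) / sum(cm) * 100, rep_$accuracy)
    # accuracy equals truth-frequency-weighted sensitivity (micro average)
    sens <- rep_$per_class$sensitivity
    w <- rowSums(cm) / n
    ok <- !is.na(sens)
    expect_equal(sum((sens * w)[ok]), rep_$accuracy / 100)
    # precision/sensitivity/F1 against the oracle accuracy helper
    expect_equal(rep_$accuracy, oracle_accuracy(truth, pred))
  }
})

test_that("AUC reproduces the worked 4-subject case and edge conventions", {
  truth <- c("AD", "CN", "AD", "CN")
  pr <- cbind(c(0.9, 0.8, 0.3, 0.1), 0, 0, c(0.1, 0.2, 0.7, 0.9))
  out <- roc_auc_ovr(truth, pr)
  # pairs: (0.9 vs 0.8, 0.9 vs 0.1, 0.3 vs 0.8, 0.3 vs 0.1) -> 3/4
  expect_equal(unname(out$auc["AD"]), 0.75)
  # perfectly separated scores
  sep <- cbind(c(0.9, 0.1, 0.8, 0.2), 0, 0, c(0.1, 0.9, 0.2, 0.8))
  expect_equal(unname(roc_auc_ovr(truth, sep)$auc["AD"]), 1)
  # constant scores -> 0.5 by the midpoint tie convention
  flat <- matrix(0.25, 4, 4)
  expect_equal(unname(roc_auc_ovr(truth, flat)$auc["AD"]), 0.5)
  # single-class truth -> undefined for absent classes
  one <- roc_auc_ovr(rep("AD", 3), random_probs(3))
  expect_true(is.na(one$auc["CN"]))
  expect_true(is.na(one$auc["AD"]))  # no negatives either
})

test_that("AUC equals exhaustive pair counting for n <= 50", {
  set.seed(88)
  for (i in 1:60) {
    n <- sample(4:50, 1)
    truth <- sample(ktm_classes(), n, replace = TRUE)
    # quantized scores force ties to exercise the midpoint convention
    probs <- round(random_probs(n), 1)
    out <- roc_auc_ovr(truth, probs)
    for (k in seq_along(ktm_classes())) {
      pos <- truth == ktm_classes()[k]
      if (!any(pos) || all(pos)) next
      expect_equal(unname(out$auc[k]), oracle_auc(probs[, k], pos),
                   tolerance = 1e-12)
    }
  }
})

test_that("ROC curves are valid staircases ending at (1, 1)", {
  set.seed(5)
  truth <- sample(ktm_classes(), 40, replace = TRUE)
  out <- roc_auc_ovr(truth, random_probs(40))
  for (k in unique(out$curves$class)) {
    cur <- out$curves[out$curves$class == k, ]
    expect_true(all(diff(cur$fpr) >= 0))
    expect_true(all(diff(cur$tpr) >= 0))
    expect_equal(cur$fpr[1], 0)
    expect_equal(cur$tpr[nrow(cur)], 1)
    expect_equal(cur$fpr[nrow(cur)], 1)
  }
})

make_fold_result <- function(fold_id, n, seed, acc_shift = 0) {
  set.seed(seed)
  truth_lab <- sample(ktm_classes(), n, replace = TRUE)
  probs <- random_probs(n)
  probs[cbind(seq_len(n), match(truth_lab, ktm_classes()))] <-
    probs[cbind(seq_len(n), match(truth_lab, ktm_classes()))] + acc_shift
  probs <- probs / rowSums(probs)
  mm <- matrix(sample(18:30, n * 4, TRUE), n, 4,
               dimnames = list(NULL, ktm_mmse_cols()))
  pred <- mm + matrix(rnorm(n * 4), n, 4)
  colnames(pred) <- paste0("PRED_", ktm_mmse_cols())
  colnames(probs) <- paste0("PROB_", ktm_classes())
  tbl <- tibble::tibble(SUBJECT_ID = sprintf("F%d_%03d", fold_id, 1:n),
                        !!!tibble::as_tibble(mm),
                        LABEL_24M = factor(truth_lab,
                                           levels = ktm_classes()),
                        !!!tibble::as_tibble(pred),
                        !!!tibble::as_tibble(probs))
  structure(list(fold_id = fold_id, predictions = tbl, epochs_run = 10L),
            class = "ktm_fold_result")
}

test_that("cross-validation aggregation is mean +/- sd with summed confusion", {
  frs <- lapply(1:4, function(i) make_fold_result(i, 30, seed = i,
                                                  acc_shift = 1))
  rep_ <- aggregate_cv(frs)
  accs <- vapply(frs, function(f) ktmnet:::fold_metrics(f)$accuracy,
                 numeric(1))
  expect_equal(rep_$accuracy_mean, mean(accs))
  expect_equal(rep_$accuracy_sd, sd(accs))
  cms <- lapply(frs, function(f) ktmnet:::fold_metrics(f)$confusion)
  expect_equal(rep_$confusion, Reduce(`+`, cms))
  # identical folds -> zero dispersion
  same <- list(make_fold_result(1, 30, seed = 9),
               make_fold_result(2, 30, seed = 9))
  rep_same <- aggregate_cv(same)
  expect_equal(rep_same$accuracy_sd, 0)
  expect_true(all(rep_same$regression$rmse_sd == 0))
  expect_error(aggregate_cv(same[1]), ">= 2")
})

test_that("two folds at 60 and 70 percent aggregate to 65 +/- 7.071", {
  m <- c(60, 70)
  expect_equal(mean(m), 65)
  got <- ktmnet:::mean_sd(m)
  expect_equal(got[["mean"]], 65)
  expect_equal(got[["sd"]], 7.0710678, tolerance = 1e-6)
})

test_that("paired t tests match closed-form arithmetic", {
  # differences (1, 2, 3, 4): mean 2.5, sd sqrt(5/3), t = 3.873
  a <- c(11, 22, 33, 44)
  b <- c(10, 20, 30, 40)
  out <- paired_ttest(a, b)
  expect_equal(out$t, 2.5 / (sqrt(5 / 3) / 2), tolerance = 1e-6)
  expect_equal(out$t, 3.872983, tolerance = 1e-5)
  expect_equal(out$df, 3)
  expect_false(out$degenerate)
  # identical vectors -> degenerate flat case
  same <- paired_ttest(b, b)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)
  # constant non-zero differences -> infinite t, p = 0, flagged
  shift <- paired_ttest(b + 1, b)
  expect_true(is.infinite(shift$t) && shift$t > 0)
  expect_equal(shift$p_value, 0)
  expect_true(shift$degenerate)
  expect_error(paired_ttest(1, 1), "lengths")
})

test_that("tidiers expose report metrics in long and glance forms", {
  frs <- lapply(1:3, function(i) make_fold_result(i, 25, seed = i + 3,
                                                  acc_shift = 2))
  rep_ <- aggregate_cv(frs)
  td <- tidy(rep_)
  expect_true(all(c("metric", "group", "mean", "sd") %in% names(td)))
  expect_true("accuracy" %in% td$metric)
  gl <- glance(rep_)
  expect_equal(gl$n_folds, 3)
  expect_equal(gl$accuracy_mean, rep_$accuracy_mean)
  # report serialization round-trips through JSON
  tmp <- withr::local_tempfile(fileext = ".json")
  write_eval_report(rep_, tmp)
  back <- jsonlite::read_json(tmp)
  expect_equal(back$accuracy_mean, rep_$accuracy_mean, tolerance = 1e-10)
  expect_true(file.exists(sub("\\.json$", "_confusion.csv", tmp)))
})
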