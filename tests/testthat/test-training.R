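test_that("patience arithmetic stops after the stated epoch", {
  # monotone worsening from epoch 1: best epoch 1, stop at 1 + patience
  worsening <- seq(1, 2, length.out = 100)
  es <- ktmnet:::early_stop_epoch(worsening, patience = 30)
  expect_equal(es$stop_epoch, 31)
  expect_equal(es$best_epoch, 1)
  # improvement resets the wait counter
  vals <- c(5, 4, 4.5, 4.6, 3.9, 4.2, 4.3, 4.4)
  es2 <- ktmnet:::early_stop_epoch(vals, patience = 3)
  expect_equal(es2$stop_epoch, 8)
  expect_equal(es2$best_epoch, 5)
  # never triggers -> runs to the end
  es3 <- ktmnet:::early_stop_epoch(rev(seq_len(10)), patience = 3)
  expect_equal(es3$stop_epoch, 10)
  expect_equal(es3$best_epoch, 10)
})

test_that("training is deterministic and restores best-validation weights", {
  co <- tiny_cohort(40, seed = 2)
  zs <- zscore_fit(co)
  coz <- zscore_apply(co, zs)
  sp <- stratified_split(coz, 0.25, seed = 1)
  tc <- training_config(batch_size = 10, max_epochs = 8, patience = 4,
                        seed = 123)
  fit1 <- ktm_train(assemble_model(tiny_config(), seed = 5),
                    sp$rest, sp$part, loss_config(beta = 5), tc)
  fit2 <- ktm_train(assemble_model(tiny_config(), seed = 5),
                    sp$rest, sp$part, loss_config(beta = 5), tc)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$model$params, fit2$model$params)

  # restored weights reproduce the best observed validation loss
  expect_equal(fit1$best_val_loss, min(fit1$history$val_loss))
  va <- ktmnet:::cohort_matrices(sp$part)
  fwd <- ktmnet:::ktm_forward(fit1$model, va$features)
  reval <- mse_loss(va$mmse, fwd$yr) + 5 * ce_loss(va$onehot, fwd$probs)
  expect_equal(reval, fit1$best_val_loss, tolerance = 1e-10)
})

test_that("max_epochs = 1 runs exactly one epoch without early stop", {
  co <- tiny_cohort(30, seed = 3)
  sp <- stratified_split(zscore_apply(co, zscore_fit(co)), 0.2, seed = 2)
  fit <- ktm_train(assemble_model(tiny_config(), seed = 1),
                   sp$rest, sp$part, loss_config(beta = 5),
                   training_config(batch_size = 8, max_epochs = 1,
                                   patience = 0, seed = 1))
  expect_equal(fit$epochs_run, 1)
  expect_equal(nrow(fit$history), 1)
})

test_that("an empty validation set is rejected", {
  co <- tiny_cohort(20)
  empty <- co[0, ]
  expect_error(
    ktm_train(assemble_model(tiny_config()), co, empty,
              loss_config(), training_config(max_epochs = 2, patience = 1)),
    "validation")
})

test_that("training configuration invariants hold", {
  expect_error(training_config(patience = 200, max_epochs = 200), "patience")
  expect_error(training_config(batch_size = 0), "batch_size")
  expect_error(split_plan(hyperparam_fraction = 0), "fractions")
  expect_error(split_plan(main_folds = 1), "fold")
})

test_that("folds are disjoint, exhaustive, stratified and seed-stable", {
  co <- generate_cohort(synthetic_spec(n_subjects = 950, seed = 31))
  f <- make_folds(co, 10, seed = 4)
  expect_equal(sort(unique(f)), 1:10)
  expect_equal(unname(table(f)), rep(95L, 10), ignore_attr = TRUE)
  # stratification within one subject per class
  for (k in ktm_classes()) {
    counts <- table(f[co$LABEL_24M == k])
    expect_lte(max(counts) - min(counts), 1)
  }
  # pure function of ids + seed: row order must not matter
  perm <- sample(nrow(co))
  co_perm <- ktmnet:::restore_cohort(co[perm, ], cohort_schema(co))
  f_perm <- make_folds(co_perm, 10, seed = 4)
  expect_identical(f[perm], f_perm)
  expect_identical(f, make_folds(co, 10, seed = 4))
  expect_false(identical(f, make_folds(co, 10, seed = 5)))
})

test_that("four subjects split into two stratified folds of two", {
  co <- generate_cohort(synthetic_spec(n_subjects = 4,
                                       class_proportions = rep(0.25, 4),
                                       seed = 1))
  f <- make_folds(co, 2, seed = 1)
  expect_equal(unname(table(f)), c(2L, 2L), ignore_attr = TRUE)
})

test_that("the 15/85 split is stratified and seeded", {
  co <- generate_cohort(synthetic_spec(n_subjects = 400, seed = 6))
  sp <- stratified_split(co, 0.15, seed = 9)
  expect_equal(nrow(sp$part) + nrow(sp$rest), 400)
  expect_equal(nrow(sp$part), 60, tolerance = 0.05)
  for (k in ktm_classes()) {
    frac <- sum(sp$part$LABEL_24M == k) / sum(co$LABEL_24M == k)
    expect_lt(abs(frac - 0.15), 0.03)
  }
  sp2 <- stratified_split(co, 0.15, seed = 9)
  expect_identical(sp$part$SUBJECT_ID, sp2$part$SUBJECT_ID)
})

test_that("grid-cell selection follows mean, variance, width tie-breaks", {
  res <- tibble::tibble(
    beta = c(10, 20, 200, 10),
    head_hidden_width = c(256, 64, 8, NA),
    mean_val_loss = c(2, 1, 1, 1.5),
    sd_val_loss = c(0.1, 0.5, 0.2, 0.1))
  # equal means -> lower variance wins
  expect_equal(ktmnet:::select_grid_cell(res), 3)
  res$sd_val_loss[2] <- 0.2
  # equal mean and variance -> smaller width wins
  expect_equal(ktmnet:::select_grid_cell(res), 3)
  res$mean_val_loss <- c(2, 3, 3, 3)
  expect_equal(ktmnet:::select_grid_cell(res), 1)
})

test_that("a single-cell search returns that cell", {
  co <- generate_cohort(synthetic_spec(n_subjects = 60, seed = 12,
                                       feature_effect = 1.5))
  out <- hyperparameter_search(
    co, grid = list(beta = 20, head_hidden_width = NA),
    plan = split_plan(hyperparam_folds = 2, seed = 1),
    net_cfg = tiny_default_config(),
    train_cfg = training_config(batch_size = 16, max_epochs = 2,
                                patience = 1, seed = 1))
  expect_equal(out$best_loss_config$beta, 20)
  expect_null(out$best_net_config$head_hidden_width)
  expect_equal(nrow(out$results), 1)
  expect_error(hyperparameter_search(
    co, grid = list(beta = numeric(0), head_hidden_width = NA)),
    "empty")
})

test_that("cross-validation yields aligned, seed-stable fold predictions", {
  co <- generate_cohort(synthetic_spec(n_subjects = 80, seed = 14,
                                       feature_effect = 1.5))
  plan <- split_plan(main_folds = 2, seed = 3)
  tc <- training_config(batch_size = 32, max_epochs = 2, patience = 1,
                        seed = 1)
  cv1 <- cross_validate(co, tiny_default_config(), loss_config(beta = 20),
                        tc, plan)
  cv2 <- cross_validate(co, tiny_default_config(), loss_config(beta = 20),
                        tc, plan)
  expect_length(cv1, 2)
  ids <- sort(unlist(lapply(cv1, function(f) f$predictions$SUBJECT_ID)))
  expect_identical(ids, sort(co$SUBJECT_ID))  # disjoint + exhaustive
  expect_identical(lapply(cv1, function(f) f$predictions),
                   lapply(cv2, function(f) f$predictions))
  # predictions align truth and estimate per subject
  p <- cv1[[1]]$predictions
  expect_true(all(!is.na(p$PRED_MMSE_M0)))
  expect_true(all(abs(rowSums(as.matrix(
    p[, paste0("PROB_", ktm_classes())])) - 1) < 1e-6))
})
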