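#' Training configuration
#'
#' Adam optimizer and training-loop settings. Defaults follow the reference
#' protocol: learning rate 0.001, moment decay rates 0.9/0.999, mini-batches
#' of 150, at most 200 epochs, early stopping on the validation joint loss
#' with a patience of 30 epochs.
#'
#' @param learning_rate,adam_beta1,adam_beta2,adam_epsilon Adam parameters.
#' @param batch_size Mini-batch size (>= 1; the last batch may be smaller).
#' @param max_epochs Epoch cap.
#' @param patience Consecutive non-improving validation epochs tolerated
#'   before stopping (must be < `max_epochs`).
#' @param seed Seed controlling weight initialization, shuffling and
#'   dropout.
#' @param deterministic_mode If `TRUE` (default), all stochastic pieces run
#'   off the single seeded RNG stream so identical calls produce identical
#'   histories and weights.
#' @return A `ktm_train_config` list.
#' @export
training_config <- function(learning_rate = 0.001, adam_beta1 = 0.9,
                            adam_beta2 = 0.999, adam_epsilon = 1e-8,
                            batch_size = 150, max_epochs = 200,
                            patience = 30, seed = 1,
                            deterministic_mode = TRUE) {
  if (batch_size < 1) stop("batch_size must be >= 1", call. = FALSE)
  if (patience >= max_epochs) {
    stop("patience must be smaller than max_epochs", call. = FALSE)
  }
  structure(list(learning_rate = learning_rate, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, adam_epsilon = adam_epsilon,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 deterministic_mode = isTRUE(deterministic_mode)),
            class = "ktm_train_config")
}

#' Split plan for the nested evaluation protocol
#'
#' 15% of subjects go to a 3-fold hyperparameter-search pool; 10-fold cross
#' validation runs on the remaining 85%; within each training split, 10% is
#' held out as the early-stopping validation set. All splits are stratified
#' by the 4-class label and seeded.
#'
#' @param hyperparam_fraction Fraction reserved for hyperparameter search.
#' @param hyperparam_folds Folds of the search CV.
#' @param main_folds Folds of the main CV.
#' @param inner_validation_fraction Fraction of each training split held
#'   out for early stopping.
#' @param stratified Stratify all splits by label.
#' @param seed Integer seed; splits are a pure function of the subject ids
#'   and this seed.
#' @return A `ktm_split_plan` list.
#' @export
split_plan <- function(hyperparam_fraction = 0.15, hyperparam_folds = 3,
                       main_folds = 10, inner_validation_fraction = 0.10,
                       stratified = TRUE, seed = 1) {
  if (hyperparam_fraction <= 0 || hyperparam_fraction >= 1 ||
      inner_validation_fraction <= 0 || inner_validation_fraction >= 1) {
    stop("fractions must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (hyperparam_folds < 2 || main_folds < 2) {
    stop("fold counts must be >= 2", call. = FALSE)
  }
  structure(list(hyperparam_fraction = hyperparam_fraction,
                 hyperparam_folds = as.integer(hyperparam_folds),
                 main_folds = as.integer(main_folds),
                 inner_validation_fraction = inner_validation_fraction,
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "ktm_split_plan")
}

# Evaluate an expression under a temporarily seeded RNG, restoring the
# caller's stream afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Stratified fold assignment
#'
#' Assigns each subject to one of `k` folds. Within each class, subjects are
#' ordered by id, shuffled under the seed and dealt round-robin, so folds
#' are stratified within one subject per class, and the assignment is a pure
#' function of the subject ids and the seed (not of row order).
#'
#' @param x A `ktm_cohort`.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @param stratified Stratify by `LABEL_24M` (default) or split ignoring
#'   labels.
#' @return Integer vector of fold memberships (1..k), aligned with rows of
#'   `x`.
#' @export
make_folds <- function(x, k, seed = 1, stratified = TRUE) {
  stopifnot(inherits(x, "ktm_cohort"), k >= 2)
  n <- nrow(x)
  fold <- integer(n)
  groups <- if (stratified) split(seq_len(n), x$LABEL_24M, drop = TRUE)
            else list(all = seq_len(n))
  with_seed(seed, {
    offset <- 0L
    for (g in names(sort(vapply(groups, length, integer(1)),
                         decreasing = TRUE))) {
      idx <- groups[[g]]
      idx <- idx[order(x$SUBJECT_ID[idx])]
      idx <- idx[sample.int(length(idx))]
      # continue the deal across classes so overall fold sizes stay within 1
      fold[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
      offset <- offset + length(idx)
    }
  })
  fold
}

#' Stratified two-way split
#'
#' Splits a cohort into a `fraction` part and its complement (e.g. the 15%
#' hyperparameter pool vs. the 85% main pool, or the inner early-stopping
#' validation split), stratified by label and deterministic under the seed.
#'
#' @param x A `ktm_cohort`.
#' @param fraction Fraction of subjects in the first part.
#' @param seed Integer seed.
#' @param stratified Stratify by label.
#' @return A list with `ktm_cohort` elements `part` and `rest`.
#' @export
stratified_split <- function(x, fraction, seed = 1, stratified = TRUE) {
  stopifnot(inherits(x, "ktm_cohort"), fraction > 0, fraction < 1)
  n <- nrow(x)
  take <- logical(n)
  groups <- if (stratified) split(seq_len(n), x$LABEL_24M, drop = TRUE)
            else list(all = seq_len(n))
  with_seed(seed, {
    for (g in names(groups)) {
      idx <- groups[[g]]
      idx <- idx[order(x$SUBJECT_ID[idx])]
      n_take <- round(length(idx) * fraction)
      take[idx[sample.int(length(idx))][seq_len(n_take)]] <- TRUE
    }
  })
  sc <- cohort_schema(x)
  list(part = restore_cohort(x[take, , drop = FALSE], sc),
       rest = restore_cohort(x[!take, , drop = FALSE], sc))
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, cfg) {
  state$t <- state$t + 1L
  b1 <- cfg$adam_beta1; b2 <- cfg$adam_beta2
  lr_t <- cfg$learning_rate * sqrt(1 - b2^state$t) / (1 - b1^state$t)
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    params[[nm]] <- params[[nm]] -
      lr_t * state$m[[nm]] / (sqrt(state$v[[nm]]) + cfg$adam_epsilon)
  }
  list(params = params, state = state)
}

# Patience arithmetic, shared by the trainer and directly testable: given
# the full sequence of per-epoch validation losses, the epoch at which
# training halts (the epoch completing `patience` consecutive
# non-improvements), and the best epoch.
early_stop_epoch <- function(val_losses, patience) {
  best <- Inf
  best_epoch <- 0L
  wait <- 0L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best) {
      best <- val_losses[e]
      best_epoch <- e
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) {
        return(list(stop_epoch = e, best_epoch = best_epoch))
      }
    }
  }
  list(stop_epoch = length(val_losses), best_epoch = best_epoch)
}

#' Train a multitask network
#'
#' Adam mini-batch training of a `ktm_model` under the joint loss, with
#' per-epoch reshuffling, early stopping on the validation joint loss, and
#' restoration of the best-validation weights. Both cohorts must already be
#' preprocessed and z-scored with training statistics.
#'
#' @param model An untrained [assemble_model()] output.
#' @param train_tbl,val_tbl Training and validation `ktm_cohort`s.
#' @param loss_cfg A [loss_config()].
#' @param train_cfg A [training_config()].
#' @return A `ktm_fit`: the trained model (best-validation weights), a
#'   per-epoch `history` tibble, `best_epoch`, `best_val_loss` and
#'   `epochs_run`.
#' @export
ktm_train <- function(model, train_tbl, val_tbl,
                      loss_cfg = loss_config(),
                      train_cfg = training_config()) {
  stopifnot(inherits(model, "ktm_model"),
            inherits(loss_cfg, "ktm_loss_config"),
            inherits(train_cfg, "ktm_train_config"))
  if (!inherits(val_tbl, "ktm_cohort") || nrow(val_tbl) == 0) {
    stop("a non-empty validation cohort is required for early stopping",
         call. = FALSE)
  }
  tr <- cohort_matrices(train_tbl)
  va <- cohort_matrices(val_tbl)
  n <- nrow(tr$features)
  cfg <- model$config
  alpha <- loss_cfg$alpha; beta <- loss_cfg$beta
  if (!model$has_r) alpha <- 0
  if (!model$has_c) beta <- 0
  if (alpha + beta <= 0) {
    stop("loss weights incompatible with the model's heads", call. = FALSE)
  }

  set.seed(train_cfg$seed)
  params <- model$params
  # start the regression outputs at the training-set target means: with
  # Adam's bounded per-step updates a zero-initialized output bias needs
  # hundreds of steps just to climb to the MMSE scale, which wastes most
  # of the epoch budget on a known offset
  if (model$has_r && all(params[["head_r.b"]] == 0)) {
    params[["head_r.b"]] <- unname(colMeans(tr$mmse))
  }
  state <- adam_init(params)
  best_params <- params
  best_val <- Inf
  best_epoch <- 0L
  wait <- 0L
  hist_train <- hist_val <- numeric(0)

  eval_loss <- function(p, mats) {
    fwd <- ktm_forward(model, mats$features, training = FALSE, params = p)
    l <- 0
    if (alpha > 0) l <- l + alpha * mse_loss(mats$mmse, fwd$yr)
    if (beta > 0) l <- l + beta * ce_loss(mats$onehot, fwd$probs)
    l
  }

  for (epoch in seq_len(train_cfg$max_epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = train_cfg$batch_size)
    batch_losses <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      idx <- ord[starts[bi]:min(starts[bi] + train_cfg$batch_size - 1L, n)]
      nb <- length(idx)
      xb <- tr$features[idx, , drop = FALSE]
      fwd <- ktm_forward(model, xb, training = TRUE, params = params)
      d_yr <- d_zc <- NULL
      l <- 0
      if (alpha > 0) {
        yb <- tr$mmse[idx, , drop = FALSE]
        l <- l + alpha * mse_loss(yb, fwd$yr)
        d_yr <- alpha * 2 * (fwd$yr - yb) / length(yb)
      }
      if (beta > 0) {
        cb <- tr$onehot[idx, , drop = FALSE]
        l <- l + beta * ce_loss(cb, fwd$probs)
        d_zc <- beta * (fwd$probs - cb) / nb
      }
      batch_losses[bi] <- l
      grads <- ktm_backward(model, fwd, d_yr = d_yr, d_zc = d_zc,
                            params = params)
      if (cfg$l1_coeff > 0) {
        for (nm in intersect(c("head_r.W", "head_c.W"), names(grads))) {
          grads[[nm]] <- grads[[nm]] + cfg$l1_coeff * sign(params[[nm]])
        }
      }
      upd <- adam_step(params, grads, state, train_cfg)
      params <- upd$params
      state <- upd$state
    }
    hist_train[epoch] <- mean(batch_losses)
    vl <- eval_loss(params, va)
    hist_val[epoch] <- vl
    if (vl < best_val) {
      best_val <- vl
      best_epoch <- epoch
      best_params <- params
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= train_cfg$patience) break
    }
  }
  model$params <- best_params
  structure(list(
    model = model,
    history = tibble::tibble(epoch = seq_along(hist_train),
                             train_loss = hist_train, val_loss = hist_val),
    best_epoch = best_epoch,
    best_val_loss = best_val,
    epochs_run = length(hist_train),
    loss_config = loss_cfg,
    train_config = train_cfg
  ), class = "ktm_fit")
}

#' @export
print.ktm_fit <- function(x, ...) {
  cat("<ktm_fit> ", x$epochs_run, " epochs (best ", x$best_epoch,
      ", val loss ", signif(x$best_val_loss, 5), "), variant=",
      x$model$config$variant, "\n", sep = "")
  invisible(x)
}

#' @export
predict.ktm_fit <- function(object, newdata, ...) {
  predict(object$model, newdata, ...)
}

#' Grid search for the loss weight and head width
#'
#' Evaluates the cartesian grid of `beta` values and head hidden widths by
#' k-fold cross-validation on the hyperparameter pool; in each fold the
#' held-out part serves as the early-stopping validation set and its best
#' joint loss scores the cell. The cell with the smallest mean validation
#' loss wins; ties break to the lower variance, then to the smaller width
#' (minimum bias, then minimum variance, then parsimony).
#'
#' @param pool The hyperparameter `ktm_cohort` (typically the 15% split),
#'   already preprocessed but not z-scored; scoring z-scores per fold.
#' @param grid Named list with elements `beta` and `head_hidden_width`
#'   (`NA` entries mean "no hidden layer").
#' @param plan A [split_plan()].
#' @param net_cfg Base [network_config()]; the searched width overrides
#'   `head_hidden_width`.
#' @param train_cfg A [training_config()].
#' @return A list: `best_loss_config`, `best_net_config`, and a `results`
#'   tibble with one row per grid cell.
#' @export
hyperparameter_search <- function(pool,
                                  grid = list(
                                    beta = c(10, 20, 200),
                                    head_hidden_width = c(256, 128, 64,
                                                          32, 16, 8)),
                                  plan = split_plan(),
                                  net_cfg = network_config(),
                                  train_cfg = training_config()) {
  stopifnot(inherits(pool, "ktm_cohort"))
  cells <- expand.grid(beta = grid$beta,
                       head_hidden_width = grid$head_hidden_width,
                       KEEP.OUT.ATTRS = FALSE)
  if (nrow(cells) == 0) stop("empty hyperparameter grid", call. = FALSE)
  fold <- make_folds(pool, plan$hyperparam_folds, seed = plan$seed,
                     stratified = plan$stratified)
  sc <- cohort_schema(pool)
  scores <- matrix(NA_real_, nrow(cells), plan$hyperparam_folds)
  for (ci in seq_len(nrow(cells))) {
    hw <- cells$head_hidden_width[ci]
    cfg_ci <- utils::modifyList(
      net_cfg, list(head_hidden_width = if (is.na(hw)) NULL else hw))
    class(cfg_ci) <- "ktm_config"
    lcfg <- loss_config(alpha = 1, beta = cells$beta[ci])
    for (f in seq_len(plan$hyperparam_folds)) {
      tr <- restore_cohort(pool[fold != f, , drop = FALSE], sc)
      te <- restore_cohort(pool[fold == f, , drop = FALSE], sc)
      zs <- zscore_fit(tr)
      fit <- ktm_train(assemble_model(cfg_ci, seed = train_cfg$seed + f),
                       zscore_apply(tr, zs), zscore_apply(te, zs),
                       lcfg, train_cfg)
      scores[ci, f] <- fit$best_val_loss
    }
  }
  res <- tibble::tibble(
    beta = cells$beta,
    head_hidden_width = cells$head_hidden_width,
    mean_val_loss = rowMeans(scores),
    sd_val_loss = apply(scores, 1, stats::sd)
  )
  best <- select_grid_cell(res)
  hw <- res$head_hidden_width[best]
  best_cfg <- utils::modifyList(
    net_cfg, list(head_hidden_width = if (is.na(hw)) NULL else hw))
  class(best_cfg) <- "ktm_config"
  list(best_loss_config = loss_config(alpha = 1, beta = res$beta[best]),
       best_net_config = best_cfg,
       results = res)
}

# Winning row of a grid-search results table: minimum mean validation
# loss, ties broken by lower variance, then by smaller head width (absent
# hidden layer ranks last among width ties).
select_grid_cell <- function(res) {
  order(res$mean_val_loss, res$sd_val_loss,
        ifelse(is.na(res$head_hidden_width), Inf,
               res$head_hidden_width))[1]
}

#' Main k-fold cross-validation
#'
#' Stratified k-fold CV of the full train/evaluate pipeline on the main
#' pool: per fold, z-scoring statistics are fit on the training split only,
#' a fresh model is trained with an inner stratified validation holdout for
#' early stopping, and predictions are made on the held-out fold.
#'
#' @param pool The main `ktm_cohort` (typically the 85% split), already
#'   preprocessed but not z-scored.
#' @param net_cfg A [network_config()].
#' @param loss_cfg A [loss_config()].
#' @param train_cfg A [training_config()].
#' @param plan A [split_plan()].
#' @return A `ktm_cv` list of per-fold results; each element carries
#'   `fold_id`, a `predictions` tibble (truth and predictions for both
#'   tasks), `epochs_run` and `best_val_loss`.
#' @export
cross_validate <- function(pool, net_cfg = network_config(),
                           loss_cfg = loss_config(),
                           train_cfg = training_config(),
                           plan = split_plan()) {
  stopifnot(inherits(pool, "ktm_cohort"))
  fold <- make_folds(pool, plan$main_folds, seed = plan$seed,
                     stratified = plan$stratified)
  sc <- cohort_schema(pool)
  out <- vector("list", plan$main_folds)
  for (f in seq_len(plan$main_folds)) {
    tr_all <- restore_cohort(pool[fold != f, , drop = FALSE], sc)
    te <- restore_cohort(pool[fold == f, , drop = FALSE], sc)
    if (any(table(te$LABEL_24M) == 0)) {
      warning("fold ", f, " lacks at least one class; per-class metrics ",
              "will be undefined there")
    }
    zs <- zscore_fit(tr_all)
    inner <- stratified_split(tr_all, plan$inner_validation_fraction,
                              seed = plan$seed + f,
                              stratified = plan$stratified)
    fit <- ktm_train(assemble_model(net_cfg, seed = train_cfg$seed + f),
                     zscore_apply(inner$rest, zs),
                     zscore_apply(inner$part, zs),
                     loss_cfg, train_cfg)
    pred <- predict(fit, zscore_apply(te, zs))
    truth <- te[, c("SUBJECT_ID", ktm_mmse_cols(), "LABEL_24M")]
    out[[f]] <- structure(list(
      fold_id = f,
      predictions = dplyr::left_join(truth, pred, by = "SUBJECT_ID"),
      epochs_run = fit$epochs_run,
      best_epoch = fit$best_epoch,
      best_val_loss = fit$best_val_loss
    ), class = "ktm_fold_result")
  }
  structure(out, class = "ktm_cv")
}
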