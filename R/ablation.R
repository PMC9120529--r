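#' Modality-combination subsets
#'
#' Restricts a cohort (and its schema) to a named combination of modality
#' blocks, used in the modality-contribution experiments:
#' `C0` = MRI+PET, `C1` = MRI+PET+RF, `C2` = MRI+PET+RF+COG,
#' `C3` = MRI+PET+RF+CSF, `C4` = MRI+PET+RF+COG+CSF (all five blocks).
#'
#' @param x A `ktm_cohort`.
#' @param combo One of `"C0" .. "C4"`.
#' @return The restricted `ktm_cohort`; encoder widths downstream re-derive
#'   from the reduced schema.
#' @export
modality_subset <- function(x, combo) {
  stopifnot(inherits(x, "ktm_cohort"))
  combos <- modality_combos()
  if (!combo %in% names(combos)) {
    stop("unknown modality combination: ", combo, " (expected ",
         paste(names(combos), collapse = ", "), ")", call. = FALSE)
  }
  sc <- schema_subset(cohort_schema(x), combos[[combo]])
  keep <- c("SUBJECT_ID", schema_features(sc), ktm_mmse_cols(), "LABEL_24M")
  restore_cohort(x[, keep, drop = FALSE], sc)
}

#' @rdname modality_subset
#' @export
modality_combos <- function() {
  list(C0 = c("MRI", "PET"),
       C1 = c("MRI", "PET", "RF"),
       C2 = c("MRI", "PET", "RF", "COG"),
       C3 = c("MRI", "PET", "RF", "CSF"),
       C4 = c("MRI", "PET", "RF", "COG", "CSF"))
}

#' Build an architecture variant
#'
#' Design-exploration variants of the full network, all inheriting every
#' other hyperparameter unchanged:
#' * `de1` — the kernelization/tensorization/feature-extraction stack is
#'   removed; the fused modality vector feeds the heads directly.
#' * `de2` — the stack is replaced by a single plain 100-unit dense layer.
#' * `de3` — the Gaussian-kernel layer is kept but the tensorization and
#'   feature-extraction layers are removed.
#' * `single_regression` / `single_classification` — the full trunk with
#'   one head (and the corresponding loss term) removed.
#' * `full` — the unmodified network.
#'
#' @param name Variant name (above), or a modality-combination tag
#'   (`"C0".."C4"`) which keeps the full architecture on a reduced schema.
#' @param base A [network_config()] for the full model.
#' @return A `ktm_config` for the variant.
#' @export
variant_config <- function(name, base = network_config()) {
  stopifnot(inherits(base, "ktm_config"))
  if (name %in% names(modality_combos())) {
    cfg <- base
    cfg$schema <- schema_subset(base$schema, modality_combos()[[name]])
    cfg$variant <- "full"
    return(cfg)
  }
  if (!name %in% c("full", "de1", "de2", "de3", "single_regression",
                   "single_classification")) {
    stop("unknown variant: ", name, call. = FALSE)
  }
  cfg <- base
  cfg$variant <- name
  cfg
}

#' @rdname variant_config
#' @param seed Weight-initialization seed.
#' @return `make_variant()`: an assembled `ktm_model`.
#' @export
make_variant <- function(name, base = network_config(), seed = 1) {
  assemble_model(variant_config(name, base), seed = seed)
}

# Loss weights appropriate for a variant (single-task variants drop the
# other task's term).
variant_loss_config <- function(name, loss_cfg) {
  if (identical(name, "single_regression")) {
    loss_config(alpha = loss_cfg$alpha, beta = 0)
  } else if (identical(name, "single_classification")) {
    loss_config(alpha = 0, beta = loss_cfg$beta)
  } else loss_cfg
}

#' Run a paired ablation study
#'
#' Cross-validates each requested variant under the identical split plan,
#' training configuration and preprocessing (fold membership is a pure
#' function of subject ids and the plan seed, so comparisons are paired),
#' then contrasts every variant against the full model with paired t-tests
#' on per-fold accuracy and per-fold mean RMSE.
#'
#' @param data The preprocessed `ktm_cohort` pool to cross-validate on.
#' @param variants Character vector of variant names / combo tags
#'   ([variant_config()]); `"full"` is added if absent.
#' @param net_cfg,loss_cfg,train_cfg,plan Shared configuration for all
#'   variants.
#' @return A `ktm_ablation` list: `reports` (named `ktm_eval` per variant),
#'   `comparison` (one row per variant: per-timepoint RMSE/correlation,
#'   accuracy, epochs to stop, mean +/- sd), and `ttests` (per-variant
#'   paired tests against the full model).
#' @export
run_ablation_study <- function(data, variants = c("full", "de1", "de2", "de3"),
                               net_cfg = network_config(),
                               loss_cfg = loss_config(),
                               train_cfg = training_config(),
                               plan = split_plan()) {
  stopifnot(inherits(data, "ktm_cohort"))
  variants <- unique(c("full", variants))
  cvs <- list()
  for (v in variants) {
    dat_v <- if (v %in% names(modality_combos())) modality_subset(data, v)
             else data
    cfg_v <- variant_config(v, net_cfg)
    cfg_v$schema <- cohort_schema(dat_v)
    cvs[[v]] <- cross_validate(dat_v, cfg_v,
                               variant_loss_config(v, loss_cfg),
                               train_cfg, plan)
  }
  reports <- lapply(cvs, aggregate_cv)

  comparison <- purrr::map_dfr(variants, function(v) {
    r <- reports[[v]]
    row <- tibble::tibble(variant = v)
    if (!is.null(r$regression)) {
      for (i in seq_len(nrow(r$regression))) {
        tp <- sub("MMSE_", "", r$regression$timepoint[i])
        row[[paste0("rmse_", tp)]] <-
          sprintf("%.2f ± %.2f", r$regression$rmse_mean[i],
                  r$regression$rmse_sd[i])
        row[[paste0("corr_", tp)]] <-
          sprintf("%.2f ± %.2f", r$regression$corr_mean[i],
                  r$regression$corr_sd[i])
      }
    }
    if (!is.na(r$accuracy_mean)) {
      row$accuracy <- sprintf("%.2f ± %.2f", r$accuracy_mean,
                              r$accuracy_sd)
    }
    row$mean_epochs <- mean(r$per_fold$epochs_run)
    row
  })

  full_pf <- reports[["full"]]$per_fold
  ttests <- purrr::map_dfr(setdiff(variants, "full"), function(v) {
    pf <- reports[[v]]$per_fold
    out <- tibble::tibble(variant = v)
    if (!all(is.na(pf$accuracy)) && !all(is.na(full_pf$accuracy))) {
      ta <- paired_ttest(full_pf$accuracy, pf$accuracy)
      out$acc_t <- ta$t; out$acc_p <- ta$p_value
      out$acc_degenerate <- ta$degenerate
    }
    if (!all(is.na(pf$mean_rmse)) && !all(is.na(full_pf$mean_rmse))) {
      tr_ <- paired_ttest(full_pf$mean_rmse, pf$mean_rmse)
      out$rmse_t <- tr_$t; out$rmse_p <- tr_$p_value
      out$rmse_degenerate <- tr_$degenerate
    }
    out
  })

  structure(list(reports = reports, comparison = comparison,
                 ttests = ttests, variants = variants),
            class = "ktm_ablation")
}

#' @export
print.ktm_ablation <- function(x, ...) {
  cat("<ktm_ablation> variants: ", paste(x$variants, collapse = ", "),
      "\n", sep = "")
  print(x$comparison)
  invisible(x)
}
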