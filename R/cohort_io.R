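#' Cohort tables
#'
#' A cohort table is a tibble with one row per subject: a `SUBJECT_ID` key,
#' the modality feature columns named by its schema (kept in schema order),
#' the four MMSE regression targets `MMSE_M0`, `MMSE_M6`, `MMSE_M12`,
#' `MMSE_M24` and the 24-month diagnosis `LABEL_24M` (one of `AD`, `MCI-C`,
#' `MCI-NC`, `CN`). Extra columns (e.g. biomarkers slated for removal) are
#' carried along untouched. The schema travels with the table as an
#' attribute so downstream steps agree on block structure.
#'
#' @param data A data frame with the columns above.
#' @param schema A [modality_schema()]; defaults to [default_schema()].
#' @return A `ktm_cohort` tibble.
#' @export
as_cohort <- function(data, schema = default_schema()) {
  stopifnot(inherits(schema, "ktm_schema"))
  data <- tibble::as_tibble(data)
  required <- c("SUBJECT_ID", schema_features(schema), ktm_mmse_cols(),
                "LABEL_24M")
  missing <- setdiff(required, names(data))
  if (length(missing)) {
    stop("cohort is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(data$SUBJECT_ID)) {
    stop("duplicate SUBJECT_ID values: ",
         paste(unique(data$SUBJECT_ID[duplicated(data$SUBJECT_ID)]),
               collapse = ", "), call. = FALSE)
  }
  lab <- as.character(data$LABEL_24M)
  bad <- setdiff(unique(lab[!is.na(lab)]), ktm_classes())
  if (length(bad)) {
    stop("LABEL_24M outside {AD, MCI-C, MCI-NC, CN}: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  data$LABEL_24M <- factor(lab, levels = ktm_classes())
  # canonical column order: id, schema features, extras, targets, label
  extras <- setdiff(names(data), required)
  data <- data[, c("SUBJECT_ID", schema_features(schema), extras,
                   ktm_mmse_cols(), "LABEL_24M")]
  structure(data, schema = schema,
            class = c("ktm_cohort", class(tibble::tibble())))
}

#' @rdname as_cohort
#' @param x A `ktm_cohort`.
#' @export
cohort_schema <- function(x) {
  sc <- attr(x, "schema")
  if (is.null(sc)) stop("not a cohort table: no schema attribute", call. = FALSE)
  sc
}

# Re-attach class/schema after dplyr-style manipulation.
restore_cohort <- function(data, template_schema) {
  structure(tibble::as_tibble(data), schema = template_schema,
            class = c("ktm_cohort", class(tibble::tibble())))
}

#' Read a cohort CSV
#'
#' Reads a wide-format, comma-delimited, UTF-8 subject table. All numeric
#' fields are parsed leniently: cells that do not parse as numbers (e.g.
#' `"NA"`, `""`, stray text) become missing values and the row is retained —
#' dropping incomplete subjects is the job of [filter_complete_cases()].
#'
#' @param path Path to a CSV file with a header row containing
#'   `SUBJECT_ID`, every schema feature, `MMSE_M0..MMSE_M24` and
#'   `LABEL_24M`.
#' @param schema A [modality_schema()] describing the expected feature
#'   blocks.
#' @return A `ktm_cohort` tibble (see [as_cohort()]).
#' @export
read_cohort <- function(path, schema = default_schema()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("SUBJECT_ID", schema_features(schema), ktm_mmse_cols(),
                "LABEL_24M")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("cohort file lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  num_cols <- setdiff(names(raw), c("SUBJECT_ID", "LABEL_24M"))
  for (cl in num_cols) {
    raw[[cl]] <- suppressWarnings(as.numeric(raw[[cl]]))
  }
  lab <- raw$LABEL_24M
  lab[!is.na(lab) & !(lab %in% ktm_classes())] <- NA
  raw$LABEL_24M <- lab
  as_cohort(raw, schema)
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()]: writes the same comma-delimited dialect with
#' full numeric precision, so a read/write/read round trip preserves values
#' and column order exactly.
#'
#' @param x A `ktm_cohort`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "ktm_cohort"))
  out <- as.data.frame(x)
  out$LABEL_24M <- as.character(out$LABEL_24M)
  readr::write_csv(tibble::as_tibble(out), path, progress = FALSE)
  invisible(path)
}

#' Complete-case filter
#'
#' Retains only subjects with all four MMSE values, a 24-month diagnosis
#' label, and no missing feature values, mirroring the exclusion of
#' unreported cognitive scores or labels from the analysis cohort. No
#' imputation is performed anywhere in the package.
#'
#' @param x A `ktm_cohort`.
#' @return The filtered `ktm_cohort`; the number of dropped subjects is
#'   reported via `message()`. An empty result triggers a warning.
#' @export
filter_complete_cases <- function(x) {
  stopifnot(inherits(x, "ktm_cohort"))
  sc <- cohort_schema(x)
  needed <- c(schema_features(sc), ktm_mmse_cols(), "LABEL_24M")
  keep <- stats::complete.cases(x[, needed])
  dropped <- sum(!keep)
  message("filter_complete_cases: dropped ", dropped, " of ", nrow(x),
          " subjects")
  out <- restore_cohort(x[keep, , drop = FALSE], sc)
  if (nrow(out) == 0L) warning("complete-case filter removed every subject")
  out
}

#' Analyte range filter
#'
#' Removes subjects whose CSF analyte values fall outside a plausible assay
#' range. By default only total tau is bounded, to the closed interval
#' [80, 1300] (values strictly below 80 or strictly above 1300 are excluded);
#' bounds for other analytes can be supplied but are deliberately not
#' invented. Missing analyte values are not treated as out of range here.
#'
#' @param x A `ktm_cohort`.
#' @param bounds Named list `analyte -> c(low, high)`.
#' @return The filtered `ktm_cohort`.
#' @export
filter_analyte_range <- function(x, bounds = list(TAU = c(80, 1300))) {
  stopifnot(inherits(x, "ktm_cohort"))
  sc <- cohort_schema(x)
  keep <- rep(TRUE, nrow(x))
  for (an in names(bounds)) {
    b <- bounds[[an]]
    if (length(b) != 2 || !is.numeric(b) || b[1] >= b[2]) {
      stop("invalid bounds for ", an, ": need c(low, high) with low < high",
           call. = FALSE)
    }
    if (!an %in% names(x)) {
      message("filter_analyte_range: column ", an, " not present, skipped")
      next
    }
    v <- x[[an]]
    out_of_range <- !is.na(v) & (v < b[1] | v > b[2])
    keep <- keep & !out_of_range
  }
  message("filter_analyte_range: dropped ", sum(!keep), " of ", nrow(x),
          " subjects")
  restore_cohort(x[keep, , drop = FALSE], sc)
}

#' Remove label-leaking biomarker columns
#'
#' Drops cognitive/clinical columns that are near-proxies of the diagnosis
#' label or of the MMSE target (ADAS, MoCA, CDR family by default), so the
#' longitudinal regression is not trivially biased. Names not present are
#' ignored with a log entry. If a dropped column belongs to the schema, the
#' schema is updated consistently.
#'
#' @param x A `ktm_cohort`.
#' @param drop_list Character vector of column names to remove.
#' @return The reduced `ktm_cohort`.
#' @export
drop_leakage_features <- function(x, drop_list = default_leakage_columns()) {
  stopifnot(inherits(x, "ktm_cohort"))
  sc <- cohort_schema(x)
  present <- intersect(drop_list, names(x))
  absent <- setdiff(drop_list, names(x))
  if (length(absent)) {
    message("drop_leakage_features: not present (ignored): ",
            paste(absent, collapse = ", "))
  }
  if (!length(present)) return(x)
  new_blocks <- lapply(sc, function(b) setdiff(b, present))
  new_blocks <- new_blocks[vapply(new_blocks, length, integer(1)) > 0]
  sc2 <- modality_schema(new_blocks)
  message("drop_leakage_features: removed ", paste(present, collapse = ", "))
  restore_cohort(x[, setdiff(names(x), present), drop = FALSE], sc2)
}

#' @rdname drop_leakage_features
#' @export
default_leakage_columns <- function() {
  c("ADAS11", "ADAS13", "MoCA", "CDR", "CDRSB")
}

#' Train-statistics z-scoring
#'
#' `zscore_fit()` computes per-feature mean and standard deviation on a
#' training partition only; `zscore_apply()` standardizes any cohort with
#' those statistics, so test data are transformed with training statistics
#' and never leak their own moments. Constant features get scale 1 (with a
#' warning) so they standardize to 0 rather than NaN.
#'
#' @param train A `ktm_cohort` (the training partition).
#' @return `zscore_fit()`: a `ktm_zscore` object (tibble of feature, mean,
#'   sd). `zscore_apply()`: the standardized `ktm_cohort`.
#' @export
zscore_fit <- function(train) {
  stopifnot(inherits(train, "ktm_cohort"))
  feats <- schema_features(cohort_schema(train))
  mu <- vapply(train[feats], mean, numeric(1), na.rm = TRUE)
  sg <- vapply(train[feats], stats::sd, numeric(1), na.rm = TRUE)
  const <- !is.na(sg) & sg == 0
  if (any(const)) {
    warning("constant feature(s), scale set to 1: ",
            paste(feats[const], collapse = ", "))
    sg[const] <- 1
  }
  structure(tibble::tibble(feature = feats, mean = unname(mu),
                           sd = unname(sg)),
            class = c("ktm_zscore", class(tibble::tibble())))
}

#' @rdname zscore_fit
#' @param x A `ktm_cohort` to standardize.
#' @param stats_ A `ktm_zscore` fitted on the training partition.
#' @export
zscore_apply <- function(x, stats_) {
  stopifnot(inherits(x, "ktm_cohort"), inherits(stats_, "ktm_zscore"))
  feats <- schema_features(cohort_schema(x))
  if (!setequal(feats, stats_$feature)) {
    stop("normalization stats do not match the cohort schema", call. = FALSE)
  }
  idx <- match(feats, stats_$feature)
  for (k in seq_along(feats)) {
    f <- feats[k]
    x[[f]] <- (x[[f]] - stats_$mean[idx[k]]) / stats_$sd[idx[k]]
  }
  x
}

#' @rdname zscore_fit
#' @param path File path for the JSON serialization
#'   (`feature -> {mean, sd}`).
#' @export
write_zscore <- function(stats_, path) {
  stopifnot(inherits(stats_, "ktm_zscore"))
  obj <- stats::setNames(
    lapply(seq_len(nrow(stats_)),
           function(i) list(mean = stats_$mean[i], sd = stats_$sd[i])),
    stats_$feature)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname zscore_fit
#' @export
read_zscore <- function(path) {
  obj <- jsonlite::read_json(path)
  structure(tibble::tibble(
    feature = names(obj),
    mean = unname(vapply(obj, function(e) as.numeric(e$mean), numeric(1))),
    sd = unname(vapply(obj, function(e) as.numeric(e$sd), numeric(1)))
  ), class = c("ktm_zscore", class(tibble::tibble())))
}

# Numeric matrices the network consumes, in schema order.
cohort_matrices <- function(x) {
  sc <- cohort_schema(x)
  list(
    features = as.matrix(x[, schema_features(sc), drop = FALSE]),
    mmse = as.matrix(x[, ktm_mmse_cols(), drop = FALSE]),
    onehot = one_hot_labels(x$LABEL_24M),
    labels = x$LABEL_24M,
    ids = x$SUBJECT_ID
  )
}
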