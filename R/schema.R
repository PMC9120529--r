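#' Modality schema
#'
#' A modality schema names the feature columns that make up each of the five
#' modality blocks (MRI, PET, COG, CSF, RF) and fixes their order. Block
#' widths drive the per-modality encoder sizes of the network, and the fused
#' representation is the concatenation of the blocks in schema order.
#'
#' @param blocks Named list of character vectors, one per modality, in the
#'   order the blocks are fused. Feature names must be unique across blocks
#'   and every block must contain at least one feature.
#' @return An object of class `ktm_schema`: a named list of character
#'   vectors with attribute bookkeeping for block widths.
#' @examples
#' sc <- modality_schema(list(MRI = c("HIPPO", "ICV"), CSF = "TAU"))
#' schema_widths(sc)
#' @export
modality_schema <- function(blocks) {
  if (!is.list(blocks) || is.null(names(blocks)) || any(names(blocks) == "")) {
    stop("`blocks` must be a named list of character vectors", call. = FALSE)
  }
  blocks <- lapply(blocks, as.character)
  widths <- vapply(blocks, length, integer(1))
  if (any(widths < 1L)) {
    stop("every modality block needs at least one feature", call. = FALSE)
  }
  feats <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(feats)) {
    stop("feature names must be unique across modalities: ",
         paste(unique(feats[duplicated(feats)]), collapse = ", "),
         call. = FALSE)
  }
  structure(blocks, class = "ktm_schema")
}

#' Default five-modality schema
#'
#' The standard multimodal feature set used throughout the package: 7 MRI
#' volumetric/thickness measures, 3 amyloid/metabolism PET values, 19
#' cognitive-test scores (RAVLT, FAQ and the Everyday Cognition scales), 3
#' CSF analytes and 4 risk factors (36 features in total). MMSE is never an
#' input feature; it is the regression target.
#'
#' @return A `ktm_schema` with blocks MRI (7), PET (3), COG (19), CSF (3),
#'   RF (4).
#' @export
default_schema <- function() {
  modality_schema(list(
    MRI = c("VENTRICLES", "HIPPOCAMPUS", "WHOLEBRAIN", "ENTORHINAL",
            "FUSIFORM", "MIDTEMP", "ICV"),
    PET = c("FDG", "PIB", "AV45"),
    COG = c("RAVLT_IMMEDIATE", "RAVLT_LEARNING", "RAVLT_FORGETTING",
            "RAVLT_PERC_FORGETTING", "FAQ",
            "ECOG_PT_MEM", "ECOG_PT_LANG", "ECOG_PT_VISSPAT", "ECOG_PT_PLAN",
            "ECOG_PT_ORGAN", "ECOG_PT_DIVATT", "ECOG_PT_TOTAL",
            "ECOG_SP_MEM", "ECOG_SP_LANG", "ECOG_SP_VISSPAT", "ECOG_SP_PLAN",
            "ECOG_SP_ORGAN", "ECOG_SP_DIVATT", "ECOG_SP_TOTAL"),
    CSF = c("ABETA", "PTAU", "TAU"),
    RF  = c("AGE", "GENDER", "EDUCATION", "APOE4")
  ))
}

#' @rdname modality_schema
#' @param schema A `ktm_schema`.
#' @export
schema_widths <- function(schema) {
  stopifnot(inherits(schema, "ktm_schema"))
  vapply(schema, length, integer(1))
}

#' @rdname modality_schema
#' @export
schema_features <- function(schema) {
  stopifnot(inherits(schema, "ktm_schema"))
  unlist(schema, use.names = FALSE)
}

#' Restrict a schema to a subset of its modalities
#'
#' @param schema A `ktm_schema`.
#' @param modalities Character vector of block names to keep, e.g.
#'   `c("MRI", "PET", "RF")`.
#' @return The reduced `ktm_schema`, blocks kept in their original order.
#' @export
schema_subset <- function(schema, modalities) {
  stopifnot(inherits(schema, "ktm_schema"))
  missing <- setdiff(modalities, names(schema))
  if (length(missing)) {
    stop("unknown modalities: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  modality_schema(schema[names(schema) %in% modalities])
}

#' @export
print.ktm_schema <- function(x, ...) {
  w <- schema_widths(x)
  cat("<ktm_schema> ", length(x), " modalities, ", sum(w),
      " features\n", sep = "")
  for (m in names(x)) {
    cat("  ", format(m, width = 4), " (", w[[m]], "): ",
        paste(x[[m]], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Fixed label and target orderings
#'
#' `ktm_classes()` returns the fixed 4-class diagnosis order used for
#' heads, one-hot encodings and confusion matrices; `ktm_mmse_cols()` the
#' MMSE target column names in timepoint order.
#'
#' @return A character vector.
#' @export
ktm_classes <- function() c("AD", "MCI-C", "MCI-NC", "CN")

#' @rdname ktm_classes
#' @export
ktm_mmse_cols <- function() c("MMSE_M0", "MMSE_M6", "MMSE_M12", "MMSE_M24")

#' One-hot encode diagnosis labels
#'
#' @param labels Character or factor vector with values among
#'   `"AD", "MCI-C", "MCI-NC", "CN"`.
#' @return An `n x 4` numeric matrix in the fixed class order; each row has
#'   exactly one 1.
#' @export
one_hot_labels <- function(labels) {
  cl <- ktm_classes()
  labels <- as.character(labels)
  bad <- setdiff(unique(labels[!is.na(labels)]), cl)
  if (length(bad)) {
    stop("labels outside the 4-class set: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- matrix(0, nrow = length(labels), ncol = length(cl),
                dimnames = list(NULL, cl))
  out[cbind(seq_along(labels), match(labels, cl))] <- 1
  out
}
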