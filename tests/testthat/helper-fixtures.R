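# Shared fixtures and independent brute-force oracles.

toy_csv_path <- function() {
  system.file("extdata", "toy_cohort.csv", package = "ktmnet",
              mustWork = TRUE)
}

# Two-modality schema small enough for finite-difference gradient checks.
tiny_schema <- function() {
  modality_schema(list(A = c("a1", "a2"), B = c("b1", "b2", "b3")))
}

# Matching network configuration: 3x3 map, 2 kernels per dilation,
# 2x2 valid feature extraction -> flatten width 2*2*3 = 12.
tiny_config <- function(...) {
  network_config(schema = tiny_schema(), gaussian_units = 9,
                 tensor_shape = c(3, 3), tconv_kernels_per_dilation = 2,
                 dilation_rates = c(1, 2), fe_filters = 3,
                 fe_kernel_size = c(2, 2), fe_padding = "valid",
                 dropout_rate = 0, ...)
}

# Cheap configuration on the full default schema, for fast pipeline tests.
tiny_default_config <- function(...) {
  network_config(schema = default_schema(), gaussian_units = 16,
                 tensor_shape = c(4, 4), tconv_kernels_per_dilation = 2,
                 dilation_rates = c(1, 2), fe_filters = 4,
                 fe_kernel_size = c(2, 2), fe_padding = "valid", ...)
}

# Hand-built cohort around the tiny schema.
tiny_cohort <- function(n = 24, seed = 5) {
  set.seed(seed)
  feats <- schema_features(tiny_schema())
  df <- tibble::tibble(SUBJECT_ID = sprintf("T%03d", seq_len(n)))
  for (f in feats) df[[f]] <- rnorm(n)
  for (cl in ktm_mmse_cols()) df[[cl]] <- sample(15:30, n, replace = TRUE)
  df$LABEL_24M <- rep(ktm_classes(), length.out = n)
  as_cohort(df, tiny_schema())
}

# A quickly trainable synthetic cohort on the full default schema.
small_default_cohort <- function(n = 120, seed = 3, effect = 1.5) {
  generate_cohort(synthetic_spec(n_subjects = n, feature_effect = effect,
                                 seed = seed))
}

# ---- brute-force oracles ---------------------------------------------------

oracle_mse <- function(y, y_hat) {
  s <- 0
  for (i in seq_len(nrow(y))) {
    for (j in seq_len(ncol(y))) s <- s + (y[i, j] - y_hat[i, j])^2
  }
  as.numeric(s / (nrow(y) * ncol(y)))
}

oracle_ce <- function(y, p, eps = 1e-7) {
  tot <- 0
  for (i in seq_len(nrow(y))) {
    for (j in seq_len(ncol(y))) {
      pij <- min(max(p[i, j], eps), 1 - eps)
      tot <- tot - y[i, j] * log(pij)
    }
  }
  as.numeric(tot / nrow(y))
}

oracle_rmse <- function(y, y_hat) {
  s <- 0
  for (i in seq_along(y)) s <- s + (y[i] - y_hat[i])^2
  as.numeric(sqrt(s / length(y)))
}

oracle_pearson <- function(y, y_hat) {
  my <- sum(y) / length(y)
  mh <- sum(y_hat) / length(y_hat)
  num <- sum((y_hat - mh) * (y - my))
  as.numeric(num / sqrt(sum((y_hat - mh)^2) * sum((y - my)^2)))
}

# Exhaustive Mann-Whitney pair counting with half-credit for ties.
oracle_auc <- function(scores, positive) {
  pos <- which(positive)
  neg <- which(!positive)
  tot <- 0
  for (i in pos) {
    for (j in neg) {
      tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    }
  }
  as.numeric(tot / (length(pos) * length(neg)))
}

oracle_accuracy <- function(truth, pred) {
  100 * sum(truth == pred) / length(truth)
}

# Random probability rows summing to 1.
random_probs <- function(n, k = 4) {
  p <- matrix(rexp(n * k), n, k)
  p / rowSums(p)
}

# independent dense/conv parameter arithmetic
count_params_oracle <- function(cfg) {
  w <- unname(schema_widths(cfg$schema))
  total <- sum(w * (2 * w) + 2 * w + (2 * w) * w + w)  # encoders
  fused <- sum(w)
  trunk <- fused
  if (cfg$variant %in% c("full", "de3", "single_regression",
                         "single_classification")) {
    total <- total + fused * cfg$gaussian_units + cfg$gaussian_units
    trunk <- cfg$gaussian_units
  }
  if (cfg$variant == "de2") {
    total <- total + fused * cfg$gaussian_units + cfg$gaussian_units
    trunk <- cfg$gaussian_units
  }
  if (cfg$variant %in% c("full", "single_regression",
                         "single_classification")) {
    taps <- prod(cfg$tconv_kernel_size)
    kpd <- cfg$tconv_kernels_per_dilation
    total <- total + length(cfg$dilation_rates) * (taps * kpd + kpd)
    depth <- kpd * length(cfg$dilation_rates)
    fe_taps <- prod(cfg$fe_kernel_size)
    total <- total + fe_taps * depth * cfg$fe_filters + cfg$fe_filters
    if (cfg$fe_padding == "valid") {
      hw <- cfg$tensor_shape - cfg$fe_kernel_size + 1L
    } else {
      hw <- cfg$tensor_shape
    }
    trunk <- prod(hw) * cfg$fe_filters
    if (!is.null(cfg$head_hidden_width)) {
      total <- total + trunk * cfg$head_hidden_width + cfg$head_hidden_width
      trunk <- cfg$head_hidden_width
    }
  }
  heads <- 0
  if (cfg$variant != "single_classification") heads <- heads + trunk * 4 + 4
  if (cfg$variant != "single_regression") heads <- heads + trunk * 4 + 4
  total + heads
}
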