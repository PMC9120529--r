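#' Synthetic cohort specification
#'
#' Parameters of the synthetic longitudinal-cohort generator. Defaults are
#' calibrated to the demographic structure of the 1,117-subject study
#' population: class proportions 157/191/441/328 (AD, MCI-C, MCI-NC, CN),
#' per-class baseline MMSE of 23.24 +/- 1.96, 27.23 +/- 1.75, 28.30 +/- 1.59
#' and 29.15 +/- 1.01, and a 24-month relative MMSE decline of 13% for AD
#' and 12.7% for MCI converters, with near-flat trajectories for stable MCI
#' and controls.
#'
#' @param n_subjects Number of subjects (>= 4 so every class is present).
#' @param class_proportions Length-4 numeric, sums to 1, order
#'   AD, MCI-C, MCI-NC, CN.
#' @param mmse_baseline 4 x 2 matrix (rows = classes) of baseline MMSE mean
#'   and sd.
#' @param decline_24m_frac Length-4 fractional MMSE decline over 24 months.
#' @param feature_effect Scalar class-separability knob: magnitude of the
#'   class-specific mean shifts of the feature blocks (in units of the
#'   within-class feature sd). 0 makes classes indistinguishable from
#'   features.
#' @param feature_scale Length-4 per-class sd multiplier on the feature
#'   blocks. Disease stages differ in biomarker dispersion, which also makes
#'   the optimal class boundary quadratic rather than linear.
#' @param noise_sd Per-visit MMSE observation noise sd (points). The default
#'   of 2 reflects short-interval retest variability in impaired cohorts.
#' @param within_modality_corr Equicorrelation of features inside each
#'   modality block.
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return A `ktm_synth_spec` list.
#' @export
synthetic_spec <- function(n_subjects = 1117,
                           class_proportions = c(157, 191, 441, 328) / 1117,
                           mmse_baseline = cbind(
                             mean = c(23.24, 27.23, 28.30, 29.15),
                             sd = c(1.96, 1.75, 1.59, 1.01)),
                           decline_24m_frac = c(0.13, 0.127, 0.01, 0),
                           feature_effect = 0.55,
                           feature_scale = c(1.35, 1.15, 1.0, 0.85),
                           noise_sd = 2,
                           within_modality_corr = 0.3,
                           seed = 1) {
  if (n_subjects < 4) {
    stop("n_subjects must be >= 4 so that all classes are represented",
         call. = FALSE)
  }
  if (length(class_proportions) != 4 ||
      abs(sum(class_proportions) - 1) > 1e-12 || any(class_proportions < 0)) {
    stop("class_proportions must be 4 non-negative values summing to 1",
         call. = FALSE)
  }
  mmse_baseline <- as.matrix(mmse_baseline)
  if (!all(dim(mmse_baseline) == c(4, 2)) || any(mmse_baseline[, 2] < 0)) {
    stop("mmse_baseline must be a 4 x 2 (mean, sd) matrix with sd >= 0",
         call. = FALSE)
  }
  if (any(decline_24m_frac < 0 | decline_24m_frac > 1)) {
    stop("decline_24m_frac entries must lie in [0, 1]", call. = FALSE)
  }
  if (noise_sd < 0 || within_modality_corr < 0 || within_modality_corr >= 1) {
    stop("need noise_sd >= 0 and within_modality_corr in [0, 1)",
         call. = FALSE)
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    class_proportions = as.numeric(class_proportions),
    mmse_baseline = mmse_baseline,
    decline_24m_frac = as.numeric(decline_24m_frac),
    feature_effect = feature_effect,
    feature_scale = as.numeric(feature_scale),
    noise_sd = noise_sd,
    within_modality_corr = within_modality_corr,
    seed = as.integer(seed)
  ), class = "ktm_synth_spec")
}

# Deterministic largest-remainder apportionment of n across proportions.
largest_remainder_counts <- function(n, proportions) {
  quota <- n * proportions
  base <- floor(quota)
  short <- n - sum(base)
  if (short > 0) {
    # break remainder ties by class order (first listed wins)
    ord <- order(quota - base, -seq_along(quota), decreasing = TRUE)
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  as.integer(base)
}

# Expected value of round(clip(N(mu, sd), 0, 30)) -- the observed scale of an
# integer MMSE with floor/ceiling effects.
discretized_mmse_mean <- function(mu, sd) {
  if (sd == 0) return(pmin(pmax(round(mu), 0), 30))
  v <- 0:30
  upper <- stats::pnorm((v + 0.5 - mu) / sd)
  lower <- stats::pnorm((v - 0.5 - mu) / sd)
  p <- upper - lower
  p[1] <- upper[1]            # everything below 0.5 folds into 0
  p[31] <- 1 - lower[31]      # everything above 29.5 folds into 30
  sum(v * p)
}

# Latent baseline mean whose discretized, clipped observation has the target
# mean (counters the MMSE ceiling at 30, which otherwise drags high-scoring
# classes below their nominal mean).
calibrate_latent_mean <- function(target, sd) {
  if (sd == 0) return(target)
  stats::uniroot(function(mu) discretized_mmse_mean(mu, sd) - target,
                 interval = c(target - 6, target + 10), tol = 1e-10)$root
}

# Plausible measurement units per default-schema feature (center, scale).
# Class structure is generated in standardized units and then mapped
# affinely onto these scales, so simulated CSVs look like real cohort
# extracts (CSF analytes in pg/mL, volumes in mm^3, ...) and the analyte
# range filters engage meaningfully. Unknown features default to (0, 1).
feature_units <- function(features) {
  units <- list(
    VENTRICLES = c(39000, 11000), HIPPOCAMPUS = c(6800, 1000),
    WHOLEBRAIN = c(1030000, 110000), ENTORHINAL = c(3500, 700),
    FUSIFORM = c(17000, 2500), MIDTEMP = c(19500, 3000),
    ICV = c(1530000, 160000),
    FDG = c(1.2, 0.15), PIB = c(1.5, 0.4), AV45 = c(1.2, 0.25),
    RAVLT_IMMEDIATE = c(35, 13), RAVLT_LEARNING = c(4.5, 2.8),
    RAVLT_FORGETTING = c(4.5, 2.5), RAVLT_PERC_FORGETTING = c(55, 35),
    FAQ = c(5, 7),
    ABETA = c(900, 350), PTAU = c(27, 12), TAU = c(300, 100),
    AGE = c(74, 7), GENDER = c(0.55, 0.5), EDUCATION = c(16, 2.8),
    APOE4 = c(0.7, 0.7)
  )
  center <- vapply(features, function(f) {
    if (startsWith(f, "ECOG_")) 1.9 else (units[[f]] %||% c(0, 1))[1]
  }, numeric(1))
  scale <- vapply(features, function(f) {
    if (startsWith(f, "ECOG_")) 0.8 else (units[[f]] %||% c(0, 1))[2]
  }, numeric(1))
  list(center = center, scale = scale)
}

# Class mean directions: rows of a 4x4 Hadamard matrix tiled across
# features, so all class pairs are equally separated and separation scales
# linearly with feature_effect.
class_mean_matrix <- function(effect, n_features) {
  h4 <- rbind(c(1, 1, 1, 1), c(1, -1, 1, -1), c(1, 1, -1, -1),
              c(1, -1, -1, 1))
  pat <- h4[, ((seq_len(n_features) - 1) %% 4) + 1, drop = FALSE]
  0.5 * effect * pat
}

# Cholesky factor of an equicorrelated block covariance.
equicorr_chol <- function(p, rho) {
  sigma <- matrix(rho, p, p)
  diag(sigma) <- 1
  chol(sigma)
}

#' Generate a synthetic cohort
#'
#' Draws a cohort table from the class-conditional model described by the
#' spec: per class, feature blocks are multivariate Gaussian with
#' equicorrelated within-block structure, class-specific mean shifts and a
#' class-specific dispersion scale; the MMSE trajectory is a latent baseline
#' draw declining linearly in time to `baseline * (1 - decline_24m_frac)` at
#' month 24, observed at each visit with Gaussian noise, clipped to [0, 30]
#' and rounded to integers. Latent baseline means are calibrated so the
#' *observed* (integer, ceiling-limited) per-class baseline means match the
#' spec. Identical spec (including seed) reproduces the table exactly.
#'
#' @param spec A [synthetic_spec()].
#' @param schema A [modality_schema()]; features are generated for every
#'   schema column.
#' @return A `ktm_cohort` tibble with `n_subjects` rows.
#' @export
generate_cohort <- function(spec, schema = default_schema()) {
  stopifnot(inherits(spec, "ktm_synth_spec"))
  set.seed(spec$seed)
  classes <- ktm_classes()
  counts <- largest_remainder_counts(spec$n_subjects, spec$class_proportions)
  feats <- schema_features(schema)
  p <- length(feats)
  mu <- class_mean_matrix(spec$feature_effect, p)
  widths <- schema_widths(schema)
  chols <- lapply(widths, equicorr_chol, rho = spec$within_modality_corr)
  months <- c(0, 6, 12, 24)

  rows <- vector("list", 4)
  for (k in 1:4) {
    nk <- counts[k]
    if (nk == 0L) next
    z <- matrix(stats::rnorm(nk * p), nk, p)
    # correlate within blocks, then scale and shift per class
    off <- 0L
    for (b in seq_along(widths)) {
      idx <- off + seq_len(widths[b])
      z[, idx] <- z[, idx, drop = FALSE] %*% chols[[b]]
      off <- off + widths[b]
    }
    x <- spec$feature_scale[k] * z +
      matrix(mu[k, ], nk, p, byrow = TRUE)
    # map standardized draws onto plausible measurement units
    un <- feature_units(feats)
    x <- x * matrix(un$scale, nk, p, byrow = TRUE) +
      matrix(un$center, nk, p, byrow = TRUE)
    colnames(x) <- feats

    sd_tot <- sqrt(spec$mmse_baseline[k, "sd"]^2 + spec$noise_sd^2)
    mu_lat <- calibrate_latent_mean(spec$mmse_baseline[k, "mean"], sd_tot)
    b0 <- stats::rnorm(nk, mu_lat, spec$mmse_baseline[k, "sd"])
    f <- spec$decline_24m_frac[k]
    traj <- outer(b0, 1 - f * months / 24) +
      matrix(stats::rnorm(nk * 4, 0, spec$noise_sd), nk, 4)
    traj <- round(pmin(pmax(traj, 0), 30))
    colnames(traj) <- ktm_mmse_cols()

    rows[[k]] <- tibble::tibble(
      SUBJECT_ID = sprintf("S%04d_%s", seq_len(nk), gsub("-", "", classes[k])),
      !!!tibble::as_tibble(x),
      !!!tibble::as_tibble(traj),
      LABEL_24M = classes[k]
    )
  }
  as_cohort(dplyr::bind_rows(rows), schema)
}

#' Per-class mean MMSE trajectories
#'
#' Summarizes a cohort as the class-by-timepoint matrix of mean MMSE, the
#' main calibration check of the generator (and the natural summary of
#' average decline trajectories). Classes absent from the table are reported
#' as missing.
#'
#' @param x A `ktm_cohort`.
#' @return A tibble with columns `class`, `MMSE_M0..MMSE_M24`, `n`, and
#'   `rel_decline_24m` (relative drop from baseline to month 24).
#' @export
summarize_trajectories <- function(x) {
  stopifnot(inherits(x, "ktm_cohort"))
  if (nrow(x) == 0L) stop("empty cohort", call. = FALSE)
  out <- tibble::tibble(class = ktm_classes())
  for (cl in ktm_mmse_cols()) {
    out[[cl]] <- vapply(ktm_classes(), function(k) {
      v <- x[[cl]][x$LABEL_24M == k]
      if (!length(v)) NA_real_ else mean(v)
    }, numeric(1))
  }
  out$n <- vapply(ktm_classes(),
                  function(k) sum(x$LABEL_24M == k), numeric(1))
  out$rel_decline_24m <- (out$MMSE_M0 - out$MMSE_M24) / out$MMSE_M0
  out
}

#' Bayes-optimal accuracy under the generative model
#'
#' Classifies feature rows with the true class-conditional Gaussian
#' densities and priors of a [synthetic_spec()] — the best any classifier
#' can do on this cohort. Used to pin the separability of a simulated
#' cohort independently of any trained network.
#'
#' @param x A `ktm_cohort` generated from `spec`.
#' @param spec The [synthetic_spec()] that generated it.
#' @param schema The schema used at generation time.
#' @return Overall accuracy (fraction in [0, 1]) of the Bayes rule on `x`.
#' @export
bayes_accuracy <- function(x, spec, schema = default_schema()) {
  stopifnot(inherits(x, "ktm_cohort"), inherits(spec, "ktm_synth_spec"))
  feats <- schema_features(schema)
  xm <- as.matrix(x[, feats, drop = FALSE])
  p <- ncol(xm)
  un <- feature_units(feats)
  xm <- (xm - matrix(un$center, nrow(xm), p, byrow = TRUE)) /
    matrix(un$scale, nrow(xm), p, byrow = TRUE)
  mu <- class_mean_matrix(spec$feature_effect, p)
  widths <- schema_widths(schema)
  sigma0 <- matrix(0, p, p)
  off <- 0L
  for (b in seq_along(widths)) {
    idx <- off + seq_len(widths[b])
    blk <- matrix(spec$within_modality_corr, widths[b], widths[b])
    diag(blk) <- 1
    sigma0[idx, idx] <- blk
    off <- off + widths[b]
  }
  prec0 <- solve(sigma0)
  logdet0 <- determinant(sigma0, logarithm = TRUE)$modulus
  scores <- matrix(0, nrow(xm), 4)
  for (k in 1:4) {
    s2 <- spec$feature_scale[k]^2
    d <- xm - matrix(mu[k, ], nrow(xm), p, byrow = TRUE)
    maha <- rowSums((d %*% prec0) * d) / s2
    scores[, k] <- log(spec$class_proportions[k]) -
      0.5 * (maha + p * log(s2) + logdet0)
  }
  pred <- ktm_classes()[max.col(scores, ties.method = "first")]
  mean(pred == as.character(x$LABEL_24M))
}
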