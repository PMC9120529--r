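#' Network configuration
#'
#' All architectural hyperparameters of the multitask network. The default
#' configuration realizes the reference design: per-modality linear
#' encoders (widths `n -> 2n -> n`), fusion by concatenation, a 100-unit
#' Gaussian RBF layer reshaped row-major to a 10 x 10 map, two stride-1
#' same-padding 3 x 3 convolution branches with dilation rates 1 and 2 (10
#' kernels each, concatenated to depth 20), a 64-filter ReLU convolution
#' with valid padding whose flattened output has width 8 * 8 * 64 = 4096,
#' and two task heads (4 ReLU regression outputs, 4 softmax class
#' probabilities) carrying an L1 weight penalty.
#'
#' The feature-extraction kernel defaults to 3 x 3 with valid padding so the
#' flattened width is exactly 4096, which the head dimensions depend on; a
#' 4 x 4 kernel (flattened width 7 * 7 * 64 = 3136) remains configurable.
#'
#' @param schema A [modality_schema()].
#' @param gaussian_units RBF units; must equal `prod(tensor_shape)`.
#' @param tensor_shape `c(H, W)` of the spatial map.
#' @param tconv_kernels_per_dilation Kernels per dilation branch.
#' @param tconv_kernel_size `c(kh, kw)` of the tensorization branches.
#' @param dilation_rates Integer dilation rates, one branch each.
#' @param fe_filters,fe_kernel_size,fe_padding Feature-extraction
#'   convolution: filter count, kernel size, `"valid"` or `"same"`.
#' @param dropout_rate Dropout fraction applied after the RBF layer, after
#'   the feature-extraction ReLU, and after the flatten, during training
#'   only.
#' @param head_hidden_width Optional shared dense ReLU layer between the
#'   flatten and the heads (the tunable width searched over
#'   {256, 128, 64, 32, 16, 8}); `NULL` for none.
#' @param l1_coeff L1 penalty coefficient on the head weights.
#' @param n_timepoints,n_classes Output arities (4 and 4).
#' @param variant Architecture variant; see [make_variant()]. `"full"` is
#'   the complete network.
#' @return A `ktm_config` list.
#' @export
network_config <- function(schema = default_schema(),
                           gaussian_units = 100,
                           tensor_shape = c(10, 10),
                           tconv_kernels_per_dilation = 10,
                           tconv_kernel_size = c(3, 3),
                           dilation_rates = c(1, 2),
                           fe_filters = 64,
                           fe_kernel_size = c(3, 3),
                           fe_padding = c("valid", "same"),
                           dropout_rate = 0.10,
                           head_hidden_width = NULL,
                           l1_coeff = 1e-4,
                           n_timepoints = 4,
                           n_classes = 4,
                           variant = "full") {
  fe_padding <- match.arg(fe_padding)
  stopifnot(inherits(schema, "ktm_schema"))
  if (gaussian_units != prod(tensor_shape)) {
    stop("gaussian_units (", gaussian_units, ") must equal prod(tensor_shape) (",
         prod(tensor_shape), ")", call. = FALSE)
  }
  variant <- match.arg(variant, c("full", "de1", "de2", "de3",
                                  "single_regression",
                                  "single_classification"))
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("dropout_rate must lie in [0, 1)", call. = FALSE)
  }
  structure(list(
    schema = schema,
    gaussian_units = as.integer(gaussian_units),
    tensor_shape = as.integer(tensor_shape),
    tconv_kernels_per_dilation = as.integer(tconv_kernels_per_dilation),
    tconv_kernel_size = as.integer(tconv_kernel_size),
    dilation_rates = as.integer(dilation_rates),
    fe_filters = as.integer(fe_filters),
    fe_kernel_size = as.integer(fe_kernel_size),
    fe_padding = fe_padding,
    dropout_rate = dropout_rate,
    head_hidden_width = head_hidden_width,
    l1_coeff = l1_coeff,
    n_timepoints = as.integer(n_timepoints),
    n_classes = as.integer(n_classes),
    variant = variant
  ), class = "ktm_config")
}

# Depth of the concatenated tensorization block.
tconv_depth <- function(cfg) {
  cfg$tconv_kernels_per_dilation * length(cfg$dilation_rates)
}

#' Assemble a multitask network
#'
#' Builds the computation graph and initializes all weights (seeded
#' variance-scaling uniform; RBF centers from a unit Gaussian, bandwidths
#' initialized to 1). The returned model is an untrained `ktm_model`; train
#' it with [ktm_train()].
#'
#' @param cfg A [network_config()].
#' @param seed Integer seed for weight initialization.
#' @return A `ktm_model`: configuration, stage descriptors, flat parameter
#'   list, and parameter count.
#' @export
assemble_model <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "ktm_config"))
  set.seed(seed)
  params <- list()
  stages <- list()
  widths <- schema_widths(cfg$schema)
  fused_width <- sum(widths)

  # per-modality encoders n -> 2n -> n, linear activation
  for (m in names(cfg$schema)) {
    n <- widths[[m]]
    params[[paste0("enc.", m, ".W1")]] <- glorot_uniform(c(n, 2 * n), n, 2 * n)
    params[[paste0("enc.", m, ".b1")]] <- numeric(2 * n)
    params[[paste0("enc.", m, ".W2")]] <- glorot_uniform(c(2 * n, n), 2 * n, n)
    params[[paste0("enc.", m, ".b2")]] <- numeric(n)
  }
  stages[[length(stages) + 1]] <- list(type = "encoders",
                                       modalities = names(cfg$schema),
                                       widths = unname(widths))

  trunk_width <- fused_width
  if (cfg$variant %in% c("full", "de3", "single_regression",
                         "single_classification")) {
    u <- cfg$gaussian_units
    params[["rbf.C"]] <- matrix(stats::rnorm(fused_width * u), fused_width, u)
    # bandwidths start at sqrt(d): squared distances between d-dimensional
    # standardized points concentrate around 2d, so sigma ~ sqrt(d) keeps
    # exp(-d2/(2 sigma^2)) near e^-1 instead of saturating at 0
    sigma0 <- sqrt(fused_width)
    params[["rbf.rho"]] <- rep(log(expm1(sigma0)), u)  # softplus^-1(sigma0)
    stages[[length(stages) + 1]] <- list(type = "rbf")
    stages[[length(stages) + 1]] <- list(type = "dropout",
                                         rate = cfg$dropout_rate)
    trunk_width <- u
  }
  if (cfg$variant == "de2") {
    u <- cfg$gaussian_units
    params[["de2.W"]] <- glorot_uniform(c(fused_width, u), fused_width, u)
    params[["de2.b"]] <- numeric(u)
    stages[[length(stages) + 1]] <- list(type = "dense", prefix = "de2",
                                         activation = "relu")
    trunk_width <- u
  }
  if (cfg$variant %in% c("full", "single_regression",
                         "single_classification")) {
    h <- cfg$tensor_shape[1]; w <- cfg$tensor_shape[2]
    kpd <- cfg$tconv_kernels_per_dilation
    plans <- lapply(cfg$dilation_rates, function(d) {
      conv_plan(h, w, cin = 1, cout = kpd,
                kh = cfg$tconv_kernel_size[1], kw = cfg$tconv_kernel_size[2],
                dilation = d, padding = "same")
    })
    for (i in seq_along(cfg$dilation_rates)) {
      taps <- plans[[i]]$taps
      params[[paste0("tconv.d", i, ".W")]] <-
        glorot_uniform(c(taps, 1, kpd), taps * 1, taps * kpd)
      params[[paste0("tconv.d", i, ".b")]] <- numeric(kpd)
    }
    stages[[length(stages) + 1]] <- list(type = "multiconv", plans = plans)
    depth <- tconv_depth(cfg)

    fe_plan <- conv_plan(h, w, cin = depth, cout = cfg$fe_filters,
                         kh = cfg$fe_kernel_size[1],
                         kw = cfg$fe_kernel_size[2],
                         dilation = 1, padding = cfg$fe_padding)
    taps <- fe_plan$taps
    params[["fe.W"]] <- glorot_uniform(c(taps, depth, cfg$fe_filters),
                                       taps * depth, taps * cfg$fe_filters)
    params[["fe.b"]] <- numeric(cfg$fe_filters)
    stages[[length(stages) + 1]] <- list(type = "conv", prefix = "fe",
                                         plan = fe_plan, activation = "relu")
    # dropout after the feature-extraction ReLU, and again after the
    # flatten (the flatten itself is the identity in this layout)
    stages[[length(stages) + 1]] <- list(type = "dropout",
                                         rate = cfg$dropout_rate)
    stages[[length(stages) + 1]] <- list(type = "dropout",
                                         rate = cfg$dropout_rate)
    trunk_width <- fe_plan$n_out * cfg$fe_filters

    if (!is.null(cfg$head_hidden_width)) {
      hw <- as.integer(cfg$head_hidden_width)
      params[["hidden.W"]] <- glorot_uniform(c(trunk_width, hw),
                                             trunk_width, hw)
      params[["hidden.b"]] <- numeric(hw)
      stages[[length(stages) + 1]] <- list(type = "dense", prefix = "hidden",
                                           activation = "relu")
      trunk_width <- hw
    }
  }

  has_r <- cfg$variant != "single_classification"
  has_c <- cfg$variant != "single_regression"
  if (has_r) {
    params[["head_r.W"]] <- glorot_uniform(c(trunk_width, cfg$n_timepoints),
                                           trunk_width, cfg$n_timepoints)
    params[["head_r.b"]] <- numeric(cfg$n_timepoints)
  }
  if (has_c) {
    params[["head_c.W"]] <- glorot_uniform(c(trunk_width, cfg$n_classes),
                                           trunk_width, cfg$n_classes)
    params[["head_c.b"]] <- numeric(cfg$n_classes)
  }

  structure(list(
    config = cfg,
    stages = stages,
    params = params,
    trunk_width = trunk_width,
    has_r = has_r,
    has_c = has_c,
    n_params = sum(vapply(params, length, numeric(1)))
  ), class = "ktm_model")
}

#' @export
print.ktm_model <- function(x, ...) {
  cat("<ktm_model> variant=", x$config$variant,
      ", ", x$n_params, " parameters, trunk width ", x$trunk_width,
      "\n", sep = "")
  invisible(x)
}

# Forward pass through the trunk and heads.
# x: b x sum(widths) matrix in schema order. Returns regression outputs,
# class probabilities, classification pre-activations, and per-stage caches.
ktm_forward <- function(model, x, training = FALSE, params = model$params,
                        trace = FALSE) {
  caches <- vector("list", length(model$stages))
  trace_outs <- if (trace) vector("list", length(model$stages))
  a <- x
  for (i in seq_along(model$stages)) {
    st <- model$stages[[i]]
    res <- switch(
      st$type,
      encoders = {
        outs <- vector("list", length(st$modalities))
        cc <- vector("list", length(st$modalities))
        off <- 0L
        for (k in seq_along(st$modalities)) {
          m <- st$modalities[k]
          n <- st$widths[k]
          xm <- a[, off + seq_len(n), drop = FALSE]
          f1 <- dense_forward(xm, params[[paste0("enc.", m, ".W1")]],
                              params[[paste0("enc.", m, ".b1")]], "linear")
          f2 <- dense_forward(f1$out, params[[paste0("enc.", m, ".W2")]],
                              params[[paste0("enc.", m, ".b2")]], "linear")
          outs[[k]] <- f2$out
          cc[[k]] <- list(c1 = f1$cache, c2 = f2$cache)
          off <- off + n
        }
        list(out = do.call(cbind, outs), cache = cc)
      },
      rbf = rbf_forward(a, params[["rbf.C"]], params[["rbf.rho"]]),
      dropout = dropout_forward(a, st$rate, training),
      dense = dense_forward(a, params[[paste0(st$prefix, ".W")]],
                            params[[paste0(st$prefix, ".b")]],
                            st$activation),
      conv = conv_forward(a, params[[paste0(st$prefix, ".W")]],
                          params[[paste0(st$prefix, ".b")]],
                          st$plan, st$activation),
      multiconv = {
        outs <- vector("list", length(st$plans))
        cc <- vector("list", length(st$plans))
        for (d in seq_along(st$plans)) {
          f <- conv_forward(a, params[[paste0("tconv.d", d, ".W")]],
                            params[[paste0("tconv.d", d, ".b")]],
                            st$plans[[d]], "linear")
          outs[[d]] <- f$out
          cc[[d]] <- f$cache
        }
        list(out = do.call(cbind, outs), cache = cc)
      },
      stop("unknown stage type: ", st$type)
    )
    caches[[i]] <- res$cache
    a <- res$out
    if (trace) trace_outs[[i]] <- a
  }
  yr <- zc <- probs <- NULL
  hr_cache <- hc_cache <- NULL
  if (model$has_r) {
    fr <- dense_forward(a, params[["head_r.W"]], params[["head_r.b"]], "relu")
    yr <- fr$out
    hr_cache <- fr$cache
  }
  if (model$has_c) {
    fc_ <- dense_forward(a, params[["head_c.W"]], params[["head_c.b"]],
                         "linear")
    zc <- fc_$out
    probs <- softmax_rows(zc)
    hc_cache <- fc_$cache
  }
  out <- list(yr = yr, zc = zc, probs = probs, trunk = a, caches = caches,
              hr_cache = hr_cache, hc_cache = hc_cache)
  if (trace) out$stage_outputs <- trace_outs
  out
}

# Backward pass. d_yr: gradient w.r.t. the regression head output (post
# ReLU); d_zc: gradient w.r.t. classification pre-activations (softmax and
# cross-entropy fold together there). Returns a flat named gradient list.
ktm_backward <- function(model, fwd, d_yr = NULL, d_zc = NULL,
                         params = model$params) {
  grads <- list()
  da <- matrix(0, nrow(fwd$trunk), ncol(fwd$trunk))
  if (model$has_r && !is.null(d_yr)) {
    bk <- dense_backward(d_yr, fwd$hr_cache, params[["head_r.W"]])
    grads[["head_r.W"]] <- bk$dW
    grads[["head_r.b"]] <- bk$db
    da <- da + bk$dx
  }
  if (model$has_c && !is.null(d_zc)) {
    bk <- dense_backward(d_zc, fwd$hc_cache, params[["head_c.W"]])
    grads[["head_c.W"]] <- bk$dW
    grads[["head_c.b"]] <- bk$db
    da <- da + bk$dx
  }
  for (i in rev(seq_along(model$stages))) {
    st <- model$stages[[i]]
    cache <- fwd$caches[[i]]
    da <- switch(
      st$type,
      encoders = {
        off <- 0L
        dxs <- vector("list", length(st$modalities))
        col0 <- 0L
        for (k in seq_along(st$modalities)) {
          m <- st$modalities[k]
          n <- st$widths[k]
          dblock <- da[, col0 + seq_len(n), drop = FALSE]
          b2 <- dense_backward(dblock, cache[[k]]$c2,
                               params[[paste0("enc.", m, ".W2")]])
          grads[[paste0("enc.", m, ".W2")]] <- b2$dW
          grads[[paste0("enc.", m, ".b2")]] <- b2$db
          b1 <- dense_backward(b2$dx, cache[[k]]$c1,
                               params[[paste0("enc.", m, ".W1")]])
          grads[[paste0("enc.", m, ".W1")]] <- b1$dW
          grads[[paste0("enc.", m, ".b1")]] <- b1$db
          dxs[[k]] <- b1$dx
          col0 <- col0 + n
        }
        do.call(cbind, dxs)
      },
      rbf = {
        bk <- rbf_backward(da, cache, params[["rbf.C"]], params[["rbf.rho"]])
        grads[["rbf.C"]] <- bk$dC
        grads[["rbf.rho"]] <- bk$drho
        bk$dx
      },
      dropout = dropout_backward(da, cache),
      dense = {
        bk <- dense_backward(da, cache, params[[paste0(st$prefix, ".W")]])
        grads[[paste0(st$prefix, ".W")]] <- bk$dW
        grads[[paste0(st$prefix, ".b")]] <- bk$db
        bk$dx
      },
      conv = {
        bk <- conv_backward(da, cache, params[[paste0(st$prefix, ".W")]],
                            st$plan)
        grads[[paste0(st$prefix, ".W")]] <- bk$dW
        grads[[paste0(st$prefix, ".b")]] <- bk$db
        bk$dx
      },
      multiconv = {
        dx <- NULL
        col0 <- 0L
        for (d in seq_along(st$plans)) {
          pl <- st$plans[[d]]
          wdt <- pl$n_out * pl$cout
          bk <- conv_backward(da[, col0 + seq_len(wdt), drop = FALSE],
                              cache[[d]],
                              params[[paste0("tconv.d", d, ".W")]], pl)
          grads[[paste0("tconv.d", d, ".W")]] <- bk$dW
          grads[[paste0("tconv.d", d, ".b")]] <- bk$db
          dx <- if (is.null(dx)) bk$dx else dx + bk$dx
          col0 <- col0 + wdt
        }
        dx
      }
    )
  }
  grads
}

#' Predict from a trained model
#'
#' @param object A `ktm_model`.
#' @param newdata A `ktm_cohort` (already standardized with the training
#'   z-scoring statistics) or a bare feature matrix in schema order.
#' @param ... Unused.
#' @return A tibble with `SUBJECT_ID` (when available), predicted MMSE
#'   columns `PRED_MMSE_M0..M24`, class-probability columns `PROB_<class>`
#'   and the argmax `PRED_CLASS` (lowest-index tie-break in the fixed class
#'   order).
#' @export
predict.ktm_model <- function(object, newdata, ...) {
  if (inherits(newdata, "ktm_cohort")) {
    ids <- newdata$SUBJECT_ID
    x <- as.matrix(newdata[, schema_features(object$config$schema),
                           drop = FALSE])
  } else {
    ids <- NULL
    x <- as.matrix(newdata)
  }
  fwd <- ktm_forward(object, x, training = FALSE)
  out <- tibble::tibble(.rows = nrow(x))
  if (!is.null(ids)) out$SUBJECT_ID <- ids
  if (object$has_r) {
    colnames(fwd$yr) <- paste0("PRED_", ktm_mmse_cols())
    out <- dplyr::bind_cols(out, tibble::as_tibble(fwd$yr))
  }
  if (object$has_c) {
    pr <- fwd$probs
    colnames(pr) <- paste0("PROB_", ktm_classes())
    out <- dplyr::bind_cols(out, tibble::as_tibble(pr))
    out$PRED_CLASS <- factor(ktm_classes()[max.col(pr, ties.method = "first")],
                             levels = ktm_classes())
  }
  out
}
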