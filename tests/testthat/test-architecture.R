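test_that("encoder widths and parameter counts match dense arithmetic", {
  m <- assemble_model(network_config(), seed = 1)
  # MRI block: 7 -> 14 -> 7
  expect_equal(dim(m$params[["enc.MRI.W1"]]), c(7, 14))
  expect_equal(dim(m$params[["enc.MRI.W2"]]), c(14, 7))
  # n_mod = 3 block carries 3*6+6 + 6*3+3 = 45 parameters
  n3 <- length(m$params[["enc.PET.W1"]]) + length(m$params[["enc.PET.b1"]]) +
    length(m$params[["enc.PET.W2"]]) + length(m$params[["enc.PET.b2"]])
  expect_equal(n3, 45)
  expect_equal(m$n_params, count_params_oracle(network_config()))
})

test_that("parameter counts match arithmetic across variants and configs", {
  cfgs <- list(
    network_config(variant = "de1"),
    network_config(variant = "de2"),
    network_config(variant = "de3"),
    network_config(variant = "single_regression"),
    network_config(variant = "single_classification"),
    network_config(head_hidden_width = 64),
    network_config(fe_kernel_size = c(4, 4)),
    tiny_config()
  )
  for (cfg in cfgs) {
    expect_equal(assemble_model(cfg, seed = 2)$n_params,
                 count_params_oracle(cfg))
  }
})

test_that("the shape chain holds on a forward pass of 8 subjects", {
  co <- small_default_cohort(20, seed = 8)
  coz <- zscore_apply(co, zscore_fit(co))  # the network consumes z-scores
  x <- as.matrix(coz[1:8, schema_features(default_schema())])
  m <- assemble_model(network_config(), seed = 1)
  fwd <- ktmnet:::ktm_forward(m, x, trace = TRUE)
  outs <- fwd$stage_outputs
  # encoders fuse to width 36
  expect_equal(ncol(outs[[1]]), 36)
  # gaussian layer: 100 units in (0, 1]
  g <- outs[[2]]
  expect_equal(ncol(g), 100)
  expect_true(all(g > 0 & g <= 1))
  # tensorization block: 10 x 10 x 20
  expect_equal(ncol(outs[[4]]), 10 * 10 * 20)
  # flattened feature extraction width 4096
  expect_equal(ncol(fwd$trunk), 4096)
  expect_equal(dim(fwd$yr), c(8, 4))
  expect_equal(dim(fwd$probs), c(8, 4))
  expect_true(all(abs(rowSums(fwd$probs) - 1) < 1e-6))
  expect_true(all(fwd$yr >= 0))
  expect_true(all(fwd$trunk >= 0))  # post-ReLU features
})

test_that("a 4x4 valid feature-extraction kernel flattens to 3136", {
  m <- assemble_model(network_config(fe_kernel_size = c(4, 4)), seed = 1)
  expect_equal(m$trunk_width, 7 * 7 * 64)
})

test_that("gaussian units obey the closed-form kernel", {
  centers <- matrix(c(1, 2, -1, 0, 3, 1), nrow = 3)  # 3 features, 2 units
  sig <- c(1, 2)
  rho <- log(expm1(sig))  # softplus inverse
  # x equal to a center -> that unit fires exactly 1
  f <- ktmnet:::rbf_forward(matrix(centers[, 1], 1), centers, rho)
  expect_equal(f$out[1, 1], 1, tolerance = 1e-12)
  # ||x - c||^2 = 2 sigma^2 -> e^-1
  x <- centers[, 2] + c(sqrt(2 * sig[2]^2), 0, 0)
  f2 <- ktmnet:::rbf_forward(matrix(x, 1), centers, rho)
  expect_equal(f2$out[1, 2], exp(-1), tolerance = 1e-10)
  # arbitrary inputs stay within (0, 1]
  set.seed(1)
  f3 <- ktmnet:::rbf_forward(matrix(rnorm(30), 10, 3), centers, rho)
  expect_true(all(f3$out > 0 & f3$out <= 1))
})

test_that("tensorize is a row-major reshape with an exact inverse", {
  v <- 1:100
  t_ <- tensorize(v)
  expect_equal(t_[1, 10], 10)
  expect_equal(t_[2, 1], 11)
  expect_equal(flatten_tensor(t_), v)
  m <- tensorize(rnorm(12), h = 3, w = 4)
  expect_equal(tensorize(flatten_tensor(m), 3, 4), m)
  expect_error(tensorize(1:99), "length-100")
})

test_that("convolution matches a nested-loop oracle", {
  oracle_conv <- function(x_img, w, dil, padding) {
    kh <- dim(w)[1]; kw <- dim(w)[2]
    h <- nrow(x_img); wd <- ncol(x_img)
    eff_h <- (kh - 1) * dil + 1; eff_w <- (kw - 1) * dil + 1
    if (padding == "same") {
      pad_t <- (eff_h - 1) %/% 2; pad_l <- (eff_w - 1) %/% 2
      h_out <- h; w_out <- wd
    } else {
      pad_t <- 0; pad_l <- 0
      h_out <- h - eff_h + 1; w_out <- wd - eff_w + 1
    }
    out <- matrix(0, h_out, w_out)
    for (r in 1:h_out) for (cc in 1:w_out) {
      acc <- 0
      for (i in 0:(kh - 1)) for (j in 0:(kw - 1)) {
        ri <- r + i * dil - pad_t
        ci <- cc + j * dil - pad_l
        if (ri >= 1 && ri <= h && ci >= 1 && ci <= wd) {
          acc <- acc + x_img[ri, ci] * w[i + 1, j + 1]
        }
      }
      out[r, cc] <- acc
    }
    out
  }
  set.seed(4)
  for (case in list(list(d = 1, p = "same"), list(d = 2, p = "same"),
                    list(d = 1, p = "valid"))) {
    img <- matrix(rnorm(100), 10, 10)
    w <- array(rnorm(9), c(3, 3))
    plan <- ktmnet:::conv_plan(10, 10, 1, 1, 3, 3, dilation = case$d,
                               padding = case$p)
    w_arr <- array(as.vector(t(w)), c(9, 1, 1))  # taps are row-major
    x_row <- matrix(flatten_tensor(img), 1)
    got <- ktmnet:::conv_forward(x_row, w_arr, 0, plan, "linear")$out
    want <- oracle_conv(img, w, case$d, case$p)
    expect_equal(as.vector(got), flatten_tensor(want), tolerance = 1e-12)
  }
})

test_that("degenerate convolution weights behave as expected", {
  plan <- ktmnet:::conv_plan(10, 10, 1, 1, 3, 3, 1, "same")
  x <- matrix(rnorm(100), 1)
  zero <- ktmnet:::conv_forward(x, array(0, c(9, 1, 1)), 0, plan, "linear")
  expect_true(all(zero$out == 0))
  # a kernel with 1 at the center tap replicates the input channel
  ident <- array(0, c(9, 1, 1)); ident[5, 1, 1] <- 1
  rep_ <- ktmnet:::conv_forward(x, ident, 0, plan, "linear")
  expect_equal(rep_$out, x, ignore_attr = TRUE)
  # kernels that do not fit the map are a config error
  expect_error(ktmnet:::conv_plan(3, 3, 1, 1, 5, 5, 1, "valid"),
               "does not fit")
})

test_that("zero-weight heads produce uniform class probabilities", {
  m <- assemble_model(tiny_config(), seed = 1)
  m$params[["head_c.W"]][] <- 0
  m$params[["head_c.b"]][] <- 0
  x <- matrix(rnorm(10), 2, 5)
  fwd <- ktmnet:::ktm_forward(m, x)
  expect_equal(fwd$probs, matrix(0.25, 2, 4), ignore_attr = TRUE)
})

test_that("inference passes are deterministic with dropout disabled", {
  m <- assemble_model(network_config(dropout_rate = 0.5), seed = 3)
  co <- small_default_cohort(10, seed = 4)
  x <- as.matrix(co[, schema_features(default_schema())])
  a <- ktmnet:::ktm_forward(m, x, training = FALSE)
  b <- ktmnet:::ktm_forward(m, x, training = FALSE)
  expect_identical(a$yr, b$yr)
  expect_identical(a$probs, b$probs)
})

test_that("config invariants are enforced", {
  expect_error(network_config(gaussian_units = 99), "prod")
  expect_error(network_config(dropout_rate = 1), "dropout_rate")
  expect_error(modality_schema(list()), "named list")
})
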