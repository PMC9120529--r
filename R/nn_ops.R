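# Low-level network operations with hand-written gradients.
#
# Activation layout convention: a batch activation is a plain numeric matrix
# of shape b x d. For spatial stages d = n_positions * n_channels in
# channel-major order (feature j = (channel-1)*n_positions + position), and
# positions enumerate the H x W grid row-major (position p sits at
# row (p-1) %/% W + 1, col (p-1) %% W + 1). Under this convention the
# flatten between the convolutional stack and the dense heads is the
# identity, and concatenating convolution branches along channels is cbind.

relu <- function(x) x * (x > 0)

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Tensorize a feature vector
#'
#' Row-major reshape of a length-`h*w` vector to an `h x w` matrix — the
#' reshaping step that turns the Gaussian-layer output into a spatial map
#' for the convolutional stack. `flatten_tensor()` is its exact inverse.
#'
#' @param v Numeric vector of length `h * w`.
#' @param h,w Target spatial dimensions.
#' @return An `h x w` matrix with `v` laid out row by row.
#' @export
tensorize <- function(v, h = 10, w = 10) {
  if (length(v) != h * w) {
    stop("tensorize: need a length-", h * w, " vector, got ", length(v),
         call. = FALSE)
  }
  matrix(v, nrow = h, ncol = w, byrow = TRUE)
}

#' @rdname tensorize
#' @param m A matrix produced by [tensorize()].
#' @export
flatten_tensor <- function(m) {
  as.vector(t(m))
}

# ---- convolution plans -----------------------------------------------------

# Precomputes, for every output position and kernel tap, the input position
# it reads (NA = zero padding). stride is 1 throughout; the stride-1
# "same"-padding transposed convolutions of the tensorization block span the
# same family of linear maps as ordinary convolutions with spatially flipped
# kernels, so a single conv primitive serves both.
conv_plan <- function(h_in, w_in, cin, cout, kh, kw, dilation = 1,
                      padding = c("same", "valid")) {
  padding <- match.arg(padding)
  eff_h <- (kh - 1) * dilation + 1
  eff_w <- (kw - 1) * dilation + 1
  if (padding == "same") {
    h_out <- h_in; w_out <- w_in
    pad_t <- (eff_h - 1) %/% 2
    pad_l <- (eff_w - 1) %/% 2
  } else {
    h_out <- h_in - eff_h + 1
    w_out <- w_in - eff_w + 1
    if (h_out < 1 || w_out < 1) {
      stop("convolution kernel (effective ", eff_h, "x", eff_w,
           ") does not fit the ", h_in, "x", w_in, " input", call. = FALSE)
    }
    pad_t <- 0L; pad_l <- 0L
  }
  n_out <- h_out * w_out
  taps <- kh * kw
  idx <- matrix(NA_integer_, n_out, taps)
  for (i in 0:(kh - 1)) {
    for (j in 0:(kw - 1)) {
      t_ <- i * kw + j + 1
      r0 <- rep(seq_len(h_out), each = w_out)
      c0 <- rep(seq_len(w_out), times = h_out)
      ri <- r0 + i * dilation - pad_t
      ci <- c0 + j * dilation - pad_l
      ok <- ri >= 1 & ri <= h_in & ci >= 1 & ci <= w_in
      idx[ok, t_] <- (ri[ok] - 1L) * w_in + ci[ok]
    }
  }
  # gather index into the zero-padded input (position n_in+1 holds the
  # padding zero), laid out output-position fastest then tap, so one
  # gather + one GEMM performs the whole convolution
  idx_vec <- as.integer(ifelse(is.na(idx), h_in * w_in + 1L, idx))
  list(h_in = h_in, w_in = w_in, n_in = h_in * w_in,
       h_out = h_out, w_out = w_out, n_out = n_out,
       cin = cin, cout = cout, taps = taps, idx = idx, idx_vec = idx_vec)
}

# X: b x (n_in*cin). W: taps x cin x cout. b_: cout.
# im2col + one GEMM: the gathered column matrix has rows (batch, output
# position) and columns (tap, channel), matching the linear layout of W.
conv_forward <- function(x, w, b_, plan, activation = c("linear", "relu")) {
  activation <- match.arg(activation)
  bsz <- nrow(x)
  xa <- x
  dim(xa) <- c(bsz, plan$n_in, plan$cin)
  xp <- array(0, c(bsz, plan$n_in + 1L, plan$cin))
  xp[, seq_len(plan$n_in), ] <- xa
  xcol <- xp[, plan$idx_vec, , drop = FALSE]
  dim(xcol) <- c(bsz * plan$n_out, plan$taps * plan$cin)
  wmat <- w
  dim(wmat) <- c(plan$taps * plan$cin, plan$cout)
  y <- xcol %*% wmat
  y <- y + rep(b_, each = nrow(y))
  mask <- NULL
  if (activation == "relu") {
    mask <- y > 0
    y <- y * mask
  }
  dim(y) <- c(bsz, plan$n_out * plan$cout)
  list(out = y, cache = list(xcol = xcol, mask = mask, bsz = bsz))
}

conv_backward <- function(dout, cache, w, plan) {
  bsz <- cache$bsz
  dy <- dout
  dim(dy) <- c(bsz * plan$n_out, plan$cout)
  if (!is.null(cache$mask)) dy <- dy * cache$mask
  db <- unname(colSums(dy))
  wmat <- w
  dim(wmat) <- c(plan$taps * plan$cin, plan$cout)
  dw <- crossprod(cache$xcol, dy)
  dim(dw) <- dim(w)
  dimnames(dw) <- NULL
  dxcol <- dy %*% t(wmat)
  dim(dxcol) <- c(bsz, plan$n_out, plan$taps, plan$cin)
  # scatter-add the column gradients back through the gather (positions are
  # unique within a tap, so indexed += is safe tap by tap)
  dxa <- array(0, c(bsz, plan$n_in, plan$cin))
  for (t_ in seq_len(plan$taps)) {
    sel <- plan$idx[, t_]
    valid <- which(!is.na(sel))
    if (!length(valid)) next
    tgt <- sel[valid]
    slab <- dxcol[, valid, t_, , drop = FALSE]
    dim(slab) <- c(bsz, length(valid), plan$cin)
    acc <- dxa[, tgt, , drop = FALSE] + slab
    dxa[, tgt, ] <- acc
  }
  dim(dxa) <- c(bsz, plan$n_in * plan$cin)
  list(dx = dxa, dW = dw, db = db)
}

# ---- Gaussian (RBF) layer --------------------------------------------------

# Unit j emits exp(-||x - c_j||^2 / (2 sigma_j^2)) with learnable center c_j
# and bandwidth sigma_j = softplus(rho_j) > 0 by construction.
rbf_forward <- function(x, centers, rho) {
  b <- nrow(x)
  u <- ncol(centers)
  d2 <- matrix(rowSums(x^2), b, u) +
    rep(colSums(centers^2), each = b) -
    2 * x %*% centers
  d2[d2 < 0] <- 0  # guard tiny negative rounding
  sig <- softplus(rho)
  inv2s2 <- 1 / (2 * sig^2)
  z <- exp(-d2 * rep(inv2s2, each = b))
  list(out = z, cache = list(x = x, d2 = d2, z = z, sig = sig))
}

rbf_backward <- function(dout, cache, centers, rho) {
  b <- nrow(cache$x)
  sig <- cache$sig
  dz <- dout * cache$z
  dd2 <- -dz * rep(1 / (2 * sig^2), each = b)
  dx <- 2 * (rowSums(dd2) * cache$x) - 2 * dd2 %*% t(centers)
  dc <- 2 * centers * rep(colSums(dd2), each = nrow(centers)) -
    2 * crossprod(cache$x, dd2)
  dimnames(dc) <- NULL
  dsig <- colSums(dz * cache$d2) / sig^3
  drho <- dsig * sigmoid(rho)
  list(dx = dx, dC = dc, drho = drho)
}

# ---- dense -----------------------------------------------------------------

dense_forward <- function(x, w, b_, activation = c("linear", "relu")) {
  activation <- match.arg(activation)
  z <- x %*% w + rep(b_, each = nrow(x))
  mask <- NULL
  if (activation == "relu") {
    mask <- z > 0
    z <- z * mask
  }
  list(out = z, cache = list(x = x, mask = mask))
}

dense_backward <- function(dout, cache, w) {
  dz <- if (is.null(cache$mask)) dout else dout * cache$mask
  dw <- crossprod(cache$x, dz)
  dimnames(dw) <- NULL
  list(dx = dz %*% t(w), dW = dw, db = unname(colSums(dz)))
}

# ---- dropout ---------------------------------------------------------------

# Inverted dropout; consumes the session RNG stream only when active, so a
# fixed seed fixes the masks.
dropout_forward <- function(x, rate, training) {
  if (!training || rate <= 0) {
    return(list(out = x, cache = list(mask = NULL)))
  }
  mask <- matrix(stats::runif(length(x)) >= rate, nrow(x), ncol(x)) /
    (1 - rate)
  list(out = x * mask, cache = list(mask = mask))
}

dropout_backward <- function(dout, cache) {
  if (is.null(cache$mask)) dout else dout * cache$mask
}

# ---- initializers ----------------------------------------------------------

glorot_uniform <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}
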