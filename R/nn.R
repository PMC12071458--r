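## Minimal neural-network primitives on BLAS matrix ops.
##
## Feature maps are stored as C x (L*B) matrices (channel-major, position
## fastest, then batch). 1-D convolutions use "same" zero padding
## (p = (k-1)/2) and stride s, so length L maps to L/s for even L; the
## transposed convolution is implemented as the exact adjoint (col2im of
## W^T u), which makes the decoder mirror the encoder lengths and keeps
## gradients symmetric.

nn_pad <- function(x, C, L, B, p) {
  Lp <- L + 2L * p
  xp <- matrix(0, C, Lp * B)
  cols <- rep(p + seq_len(L), B) + rep((seq_len(B) - 1L) * Lp, each = L)
  xp[, cols] <- x
  xp
}

nn_crop <- function(xp, C, L, B, p) {
  Lp <- L + 2L * p
  cols <- rep(p + seq_len(L), B) + rep((seq_len(B) - 1L) * Lp, each = L)
  xp[, cols, drop = FALSE]
}

nn_outlen <- function(L, k, s, p) (L + 2L * p - k) %/% s + 1L

## x: C x (L*B)  ->  (C*k) x (Lo*B) patch matrix
nn_im2col <- function(x, C, L, B, k, s) {
  p <- (k - 1L) %/% 2L
  Lo <- nn_outlen(L, k, s, p)
  Lp <- L + 2L * p
  xp <- nn_pad(x, C, L, B, p)
  m <- matrix(0, C * k, Lo * B)
  off <- rep((seq_len(B) - 1L) * Lp, each = Lo)
  for (j in seq_len(k)) {
    cols <- rep((seq_len(Lo) - 1L) * s + j, B) + off
    m[((j - 1L) * C + 1L):(j * C), ] <- xp[, cols, drop = FALSE]
  }
  m
}

## adjoint of nn_im2col: scatter-add patches back to a C x (L*B) map
nn_col2im <- function(m, C, L, B, k, s) {
  p <- (k - 1L) %/% 2L
  Lo <- nn_outlen(L, k, s, p)
  Lp <- L + 2L * p
  xp <- matrix(0, C, Lp * B)
  off <- rep((seq_len(B) - 1L) * Lp, each = Lo)
  for (j in seq_len(k)) {
    cols <- rep((seq_len(Lo) - 1L) * s + j, B) + off
    xp[, cols] <- xp[, cols, drop = FALSE] +
      m[((j - 1L) * C + 1L):(j * C), , drop = FALSE]
  }
  nn_crop(xp, C, L, B, p)
}

## Convolution: y = W %*% im2col(x) + b.  W: F x (C*k), b: F.
nn_conv_fwd <- function(x, W, b, C, L, B, k, s) {
  m <- nn_im2col(x, C, L, B, k, s)
  list(y = W %*% m + b, col = m)
}

nn_conv_bwd <- function(g, cache_col, W, C, L, B, k, s) {
  list(dx = nn_col2im(crossprod(W, g), C, L, B, k, s),
       dW = tcrossprod(g, cache_col),
       db = rowSums(g))
}

## Transposed convolution (adjoint): u has F channels at length Lo,
## y = col2im(W^T u) has C channels at length L = Lo * s.
nn_tconv_fwd <- function(u, W, b, C, L, B, k, s) {
  y <- nn_col2im(crossprod(W, u), C, L, B, k, s) + b
  y
}

nn_tconv_bwd <- function(g, u, W, C, L, B, k, s) {
  gcol <- nn_im2col(g, C, L, B, k, s)
  list(du = W %*% gcol,
       dW = tcrossprod(u, gcol),
       db = rowSums(g))
}

nn_relu <- function(x) (x > 0) * x
nn_relu_bwd <- function(g, x) g * (x > 0)

## Column-wise softmax with log-sum-exp stabilization.
nn_softmax <- function(z) {
  z <- sweep(z, 2L, apply(z, 2L, max), "-")
  e <- exp(z)
  sweep(e, 2L, colSums(e), "/")
}

## ---- Adam ----------------------------------------------------------------

adam_init <- function(params) {
  zero <- lapply(params, function(p) p * 0)
  list(m = zero, v = zero, t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      clip_norm = 5) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1L))))
  if (!is.finite(gn)) stop("non-finite gradient norm")
  if (gn > clip_norm) grads <- lapply(grads, function(g) g * (clip_norm / gn))
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

## He-scaled Gaussian init for a fan_in-column weight matrix.
nn_init_w <- function(nrow, ncol) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / ncol)), nrow, ncol)
}
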