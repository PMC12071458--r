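## The ICVAE network: a convolutional encoder and symmetric transposed-
## convolutional decoder over one-hot SMILES, with condition labels injected
## at both stages, and the shifted-prior objective
##   recon + beta * KL[ N(mu, diag sigma^2) || N(tau*c, I) ],
## which reduces to the plain conditional-VAE objective when all scaled
## labels are zero.
##
## Conditioned latent coordinate i (i <= P) carries property i on the
## [0, 500] label scale; the mu head output is multiplied by the latent
## range on those coordinates and z is divided by it before entering the
## decoder, so every trainable weight works on O(1) quantities. This is a
## pure reparameterization: mu, sigma, z and the KL are all on the label
## scale.

#' Assemble a model configuration
#'
#' @param vocab_size number of tokens (one-hot rows).
#' @param P number of conditioned properties (`P <= K`).
#' @param K latent dimension (default 128).
#' @param hidden_dim encoder/decoder dense width (default 292).
#' @param conv_filters filter counts of the three conv layers
#'   (default c(16, 32, 64)).
#' @param kernel odd convolution window along the sequence axis (default 11).
#' @param stride convolution stride (default 2).
#' @param max_len encoded SMILES length; must be divisible by
#'   `stride^3` (default 120).
#' @param beta KL weight (default 1).
#' @return list of class `icvae_config`.
#' @export
icvae_config <- function(vocab_size, P, K = 128L, hidden_dim = 292L,
                         conv_filters = c(16L, 32L, 64L), kernel = 11L,
                         stride = 2L, max_len = ICVAE_MAX_LEN, beta = 1) {
  stopifnot(P >= 1L, P <= K, vocab_size > 0L, length(conv_filters) == 3L,
            kernel %% 2L == 1L, max_len %% stride^3 == 0L, beta >= 0)
  structure(list(vocab_size = as.integer(vocab_size), P = as.integer(P),
                 K = as.integer(K), hidden_dim = as.integer(hidden_dim),
                 conv_filters = as.integer(conv_filters),
                 kernel = as.integer(kernel), stride = as.integer(stride),
                 max_len = as.integer(max_len), beta = beta,
                 latent_range = ICVAE_LATENT_RANGE),
            class = "icvae_config")
}

## Per-coordinate latent scale: label range on conditioned coords, 1 elsewhere.
latent_scale <- function(cfg) {
  a <- rep(1, cfg$K)
  a[seq_len(cfg$P)] <- cfg$latent_range
  a
}

icvae_lengths <- function(cfg) {
  s <- cfg$stride
  c(cfg$max_len, cfg$max_len %/% s, cfg$max_len %/% s^2, cfg$max_len %/% s^3)
}

#' Initialize network parameters
#'
#' He-scaled Gaussian weights and zero biases for every layer of the
#' encoder/decoder pair; useful for untrained-baseline diagnostics.
#'
#' @param cfg an [icvae_config()].
#' @param seed RNG seed for the draw.
#' @return named list of weight matrices and bias vectors.
#' @export
icvae_init_params <- function(cfg, seed = NULL) {
  with_seed(seed, {
    V <- cfg$vocab_size; P <- cfg$P; K <- cfg$K; H <- cfg$hidden_dim
    f <- cfg$conv_filters; k <- cfg$kernel
    L3 <- icvae_lengths(cfg)[4L]
    Cin <- V + P
    list(
      ec1_W = nn_init_w(f[1], Cin * k),  ec1_b = numeric(f[1]),
      ec2_W = nn_init_w(f[2], f[1] * k), ec2_b = numeric(f[2]),
      ec3_W = nn_init_w(f[3], f[2] * k), ec3_b = numeric(f[3]),
      ef1_W = nn_init_w(H, f[3] * L3 + P), ef1_b = numeric(H),
      emu_W = nn_init_w(K, H), emu_b = numeric(K),
      els_W = nn_init_w(K, H) * 0.1, els_b = numeric(K),
      df1_W = nn_init_w(H, K + P), df1_b = numeric(H),
      df2_W = nn_init_w(f[3] * L3, H), df2_b = numeric(f[3] * L3),
      dt3_W = nn_init_w(f[3], f[2] * k), dt3_b = numeric(f[2]),
      dt2_W = nn_init_w(f[2], f[1] * k), dt2_b = numeric(f[1]),
      dt1_W = nn_init_w(f[1], V * k),    dt1_b = numeric(V)
    )
  })
}

## Tile per-sample condition rows across all sequence positions.
tile_condition <- function(c_norm, L, B) {
  c_norm[, rep(seq_len(B), each = L), drop = FALSE]
}

## Full forward pass.
## x: V x (L*B) one-hot; labels: P x B scaled labels in [0, 500];
## eps: K x B (NULL = zeros, the deterministic z = mu evaluation path).
icvae_forward <- function(params, cfg, x, labels, eps = NULL) {
  V <- cfg$vocab_size; P <- cfg$P; K <- cfg$K
  f <- cfg$conv_filters; k <- cfg$kernel; s <- cfg$stride
  Ls <- icvae_lengths(cfg)
  B <- ncol(labels)
  stopifnot(nrow(x) == V, ncol(x) == Ls[1] * B, nrow(labels) == P)
  a <- latent_scale(cfg)
  c_norm <- labels / cfg$latent_range

  xin <- rbind(x, tile_condition(c_norm, Ls[1], B))
  cv1 <- nn_conv_fwd(xin, params$ec1_W, params$ec1_b, V + P, Ls[1], B, k, s)
  h1 <- nn_relu(cv1$y)
  cv2 <- nn_conv_fwd(h1, params$ec2_W, params$ec2_b, f[1], Ls[2], B, k, s)
  h2 <- nn_relu(cv2$y)
  cv3 <- nn_conv_fwd(h2, params$ec3_W, params$ec3_b, f[2], Ls[3], B, k, s)
  h3 <- nn_relu(cv3$y)
  fin <- rbind(matrix(h3, f[3] * Ls[4], B), c_norm)
  a4 <- params$ef1_W %*% fin + params$ef1_b
  h4 <- nn_relu(a4)
  mu_raw <- params$emu_W %*% h4 + params$emu_b
  mu <- mu_raw * a
  ls <- params$els_W %*% h4 + params$els_b
  sigma_raw <- exp(ls)
  sigma <- pmin(pmax(sigma_raw, 1e-3), 1e3)
  if (is.null(eps)) eps <- matrix(0, K, B)
  z <- mu + sigma * eps

  din <- rbind(z / a, c_norm)
  a5 <- params$df1_W %*% din + params$df1_b
  g1 <- nn_relu(a5)
  a6 <- params$df2_W %*% g1 + params$df2_b
  g2 <- nn_relu(a6)
  u3 <- matrix(g2, f[3], Ls[4] * B)
  a7 <- nn_tconv_fwd(u3, params$dt3_W, params$dt3_b, f[2], Ls[3], B, k, s)
  t3 <- nn_relu(a7)
  a8 <- nn_tconv_fwd(t3, params$dt2_W, params$dt2_b, f[1], Ls[2], B, k, s)
  t2 <- nn_relu(a8)
  logits <- nn_tconv_fwd(t2, params$dt1_W, params$dt1_b, V, Ls[1], B, k, s)
  probs <- nn_softmax(logits)

  list(mu = mu, sigma = sigma, z = z, eps = eps, probs = probs,
       cache = list(xin = xin, cv1 = cv1, cv2 = cv2, cv3 = cv3,
                    h1 = h1, h2 = h2, h3 = h3, fin = fin, a4 = a4, h4 = h4,
                    mu_raw = mu_raw, ls = ls, sigma_raw = sigma_raw,
                    din = din, a5 = a5, g1 = g1, a6 = a6, g2 = g2, u3 = u3,
                    a7 = a7, t3 = t3, a8 = a8, t2 = t2, B = B))
}

#' Draw latent vectors with the reparameterization trick
#'
#' Computes `z = mu + sigma * eps` elementwise, with `eps` either supplied
#' or drawn from N(0, 1) under `seed`.
#'
#' @param mu,sigma numeric vectors or matrices (K x B); `sigma > 0`.
#' @param eps same shape as `mu`, or `NULL` to draw.
#' @param seed RNG seed used when `eps` is drawn.
#' @return z with the shape of `mu`.
#' @export
reparameterize <- function(mu, sigma, eps = NULL, seed = NULL) {
  stopifnot(all(sigma > 0), length(mu) == length(sigma))
  if (is.null(eps))
    eps <- with_seed(seed, array(stats::rnorm(length(mu)), dim = dim(mu) %||%
                                   length(mu)))
  stopifnot(length(eps) == length(mu))
  mu + sigma * eps
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' KL divergence to a shifted standard-normal prior
#'
#' Closed form of `KL[N(mu, diag(sigma^2)) || N(prior_mean, I)]`, summed over
#' coordinates:
#' `sum_k ( -log sigma_k + (sigma_k^2 + (mu_k - m_k)^2 - 1) / 2 )`.
#' Zero exactly when `mu == prior_mean` and `sigma == 1`, and invariant to
#' translating `mu` and `prior_mean` together.
#'
#' @param mu,sigma numeric vectors or K x B matrices; `sigma > 0`.
#' @param prior_mean prior mean vector/matrix `m` (recycled over columns if a
#'   vector).
#' @return per-sample KL value(s), a length-B numeric (scalar for vectors).
#' @export
kl_shifted <- function(mu, sigma, prior_mean = 0) {
  if (any(sigma <= 0)) stop("sigma must be strictly positive")
  mu <- as.matrix(mu); sigma <- as.matrix(sigma)
  d <- mu - prior_mean
  colSums(-log(sigma) + (sigma^2 + d^2 - 1) / 2)
}

## Prior mean matrix (K x B): scaled labels on the conditioned coords.
prior_mean_of <- function(labels, cfg) {
  m <- matrix(0, cfg$K, ncol(labels))
  m[seq_len(cfg$P), ] <- labels
  m
}

## Loss on a forward pass: recon is per-sample categorical cross-entropy
## summed over the max_len positions, averaged over the batch (nats).
icvae_loss_terms <- function(fw, x, labels, cfg) {
  B <- fw$cache$B
  recon <- -sum(x * log(pmax(fw$probs, 1e-300))) / B
  kl <- mean(kl_shifted(fw$mu, fw$sigma, prior_mean_of(labels, cfg)))
  list(recon = recon, kl = kl, total = recon + cfg$beta * kl)
}

## Plain CVAE objective on the same weights: standard-normal prior (m = 0).
cvae_loss_terms <- function(fw, x, cfg) {
  B <- fw$cache$B
  recon <- -sum(x * log(pmax(fw$probs, 1e-300))) / B
  kl <- mean(kl_shifted(fw$mu, fw$sigma, 0))
  list(recon = recon, kl = kl, total = recon + cfg$beta * kl)
}

## Full backward pass; returns gradients for every parameter.
icvae_backward <- function(params, cfg, fw, x, labels) {
  V <- cfg$vocab_size; P <- cfg$P; K <- cfg$K
  f <- cfg$conv_filters; k <- cfg$kernel; s <- cfg$stride
  Ls <- icvae_lengths(cfg)
  ca <- fw$cache; B <- ca$B
  a <- latent_scale(cfg)

  ## reconstruction head
  dlogits <- (fw$probs - x) / B
  bw1 <- nn_tconv_bwd(dlogits, ca$t2, params$dt1_W, V, Ls[1], B, k, s)
  dt2 <- nn_relu_bwd(bw1$du, ca$a8)
  bw2 <- nn_tconv_bwd(dt2, ca$t3, params$dt2_W, f[1], Ls[2], B, k, s)
  dt3 <- nn_relu_bwd(bw2$du, ca$a7)
  bw3 <- nn_tconv_bwd(dt3, ca$u3, params$dt3_W, f[2], Ls[3], B, k, s)
  dg2 <- nn_relu_bwd(matrix(bw3$du, f[3] * Ls[4], B), ca$a6)
  dg1 <- nn_relu_bwd(crossprod(params$df2_W, dg2), ca$a5)
  ddin <- crossprod(params$df1_W, dg1)
  dz <- ddin[seq_len(K), , drop = FALSE] / a

  ## latent heads: decoder path + KL path
  m <- prior_mean_of(labels, cfg)
  dmu <- dz + cfg$beta * (fw$mu - m) / B
  dsigma <- dz * fw$eps + cfg$beta * (fw$sigma - 1 / fw$sigma) / B
  in_range <- (ca$sigma_raw > 1e-3) & (ca$sigma_raw < 1e3)
  dls <- dsigma * fw$sigma * in_range
  dmu_raw <- dmu * a

  dh4 <- nn_relu_bwd(crossprod(params$emu_W, dmu_raw) +
                       crossprod(params$els_W, dls), ca$a4)
  dfin <- crossprod(params$ef1_W, dh4)
  dh3 <- nn_relu_bwd(matrix(dfin[seq_len(f[3] * Ls[4]), , drop = FALSE],
                            f[3], Ls[4] * B), ca$cv3$y)
  bc3 <- nn_conv_bwd(dh3, ca$cv3$col, params$ec3_W, f[2], Ls[3], B, k, s)
  dh2 <- nn_relu_bwd(bc3$dx, ca$cv2$y)
  bc2 <- nn_conv_bwd(dh2, ca$cv2$col, params$ec2_W, f[1], Ls[2], B, k, s)
  dh1 <- nn_relu_bwd(bc2$dx, ca$cv1$y)
  bc1 <- nn_conv_bwd(dh1, ca$cv1$col, params$ec1_W, V + P, Ls[1], B, k, s)

  list(
    ec1_W = bc1$dW, ec1_b = bc1$db,
    ec2_W = bc2$dW, ec2_b = bc2$db,
    ec3_W = bc3$dW, ec3_b = bc3$db,
    ef1_W = tcrossprod(dh4, ca$fin), ef1_b = rowSums(dh4),
    emu_W = tcrossprod(dmu_raw, ca$h4), emu_b = rowSums(dmu_raw),
    els_W = tcrossprod(dls, ca$h4), els_b = rowSums(dls),
    df1_W = tcrossprod(dg1, ca$din), df1_b = rowSums(dg1),
    df2_W = tcrossprod(dg2, ca$g1), df2_b = rowSums(dg2),
    dt3_W = bw3$dW, dt3_b = rowSums(dt3),
    dt2_W = bw2$dW, dt2_b = rowSums(dt2),
    dt1_W = bw1$dW, dt1_b = rowSums(dlogits)
  )
}
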