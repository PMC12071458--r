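# Tiny architecture used to exercise the network machinery quickly.
tiny_cfg <- function(beta = 1) {
  icvae_config(vocab_size = 5L, P = 1L, K = 3L, hidden_dim = 7L,
               conv_filters = c(2L, 3L, 4L), kernel = 3L, max_len = 16L,
               beta = beta)
}

tiny_batch <- function(cfg, B = 4L, seed = 5, label_max = 500) {
  set.seed(seed)
  tok <- matrix(sample(seq_len(cfg$vocab_size), cfg$max_len * B, TRUE),
                cfg$max_len, B)
  list(x = icvae:::onehot_batch(tok, cfg$vocab_size),
       labels = matrix(runif(B, 0, label_max), cfg$P, B),
       eps = matrix(rnorm(cfg$K * B), cfg$K, B))
}

test_that("shifted KL matches its closed form and a Monte-Carlo oracle", {
  expect_equal(kl_shifted(rep(2, 4), rep(1, 4), rep(2, 4)), 0)
  expect_equal(kl_shifted(3, 1, 0), 4.5)        # (mu - m)^2 / 2
  expect_gt(kl_shifted(0, 2, 0), 0)

  # numeric-integration oracle for the K = 1 case
  kl_int <- function(mu, s, m) {
    integrand <- function(z)
      dnorm(z, mu, s) * (dnorm(z, mu, s, log = TRUE) -
                           dnorm(z, m, 1, log = TRUE))
    integrate(integrand, mu - 12 * s, mu + 12 * s, rel.tol = 1e-10)$value
  }
  expect_equal(kl_shifted(3, 1, 0), kl_int(3, 1, 0), tolerance = 1e-8)
  expect_equal(kl_shifted(-1.2, 0.4, 2.5), kl_int(-1.2, 0.4, 2.5),
               tolerance = 1e-8)

  # Monte-Carlo oracle E_q[log q - log p], a few K <= 4 triples
  set.seed(11)
  for (rep_i in 1:5) {
    K <- sample(1:4, 1)
    mu <- rnorm(K, 0, 2); s <- exp(rnorm(K, 0, 0.4)); m <- rnorm(K, 0, 2)
    n <- 1e5
    z <- matrix(rnorm(n * K, mu, s), K, n)
    lq <- colSums(matrix(dnorm(z, mu, s, log = TRUE), K, n))
    lp <- colSums(matrix(dnorm(z, m, 1, log = TRUE), K, n))
    mc <- mean(lq - lp); se <- sd(lq - lp) / sqrt(n)
    expect_lt(abs(kl_shifted(mu, s, m) - mc), 3 * se)
  }
  expect_error(kl_shifted(0, -1, 0), "positive")
})

test_that("shifted KL is invariant to joint translation of mu and prior", {
  set.seed(2)
  for (i in 1:20) {
    K <- sample(1:6, 1)
    mu <- rnorm(K); s <- exp(rnorm(K, 0, 0.5)); m <- rnorm(K)
    delta <- rnorm(K, 0, 5)
    expect_equal(kl_shifted(mu + delta, s, m + delta),
                 kl_shifted(mu, s, m), tolerance = 1e-10)
  }
})

test_that("reparameterization is z = mu + sigma * eps", {
  mu <- c(1, -2, 3); s <- c(0.5, 1, 2)
  expect_identical(reparameterize(mu, s, eps = c(0, 0, 0)), mu)
  expect_equal(reparameterize(mu, rep(1e-12, 3), eps = rnorm(3)), mu,
               tolerance = 1e-9)
  expect_identical(reparameterize(mu, s, seed = 4),
                   reparameterize(mu, s, seed = 4))
  # Monte-Carlo: sample mean of z is mu within 4 sigma / sqrt(n)
  n <- 1e5
  set.seed(9)
  eps <- matrix(rnorm(3 * n), 3, n)
  zs <- reparameterize(matrix(mu, 3, n), matrix(s, 3, n), eps = eps)
  expect_true(all(abs(rowMeans(zs) - mu) < 4 * s / sqrt(n)))
})

test_that("encoder and decoder are deterministic and batch-consistent", {
  cfg <- tiny_cfg()
  params <- icvae_init_params(cfg, seed = 1)
  b <- tiny_batch(cfg, B = 5L)
  fw1 <- icvae:::icvae_forward(params, cfg, b$x, b$labels, b$eps)
  fw2 <- icvae:::icvae_forward(params, cfg, b$x, b$labels, b$eps)
  expect_identical(fw1$mu, fw2$mu)
  expect_identical(fw1$probs, fw2$probs)
  expect_identical(dim(fw1$mu), c(cfg$K, 5L))
  expect_true(all(fw1$sigma > 0))
  expect_equal(fw1$z, fw1$mu + fw1$sigma * b$eps)
  # decoder columns are probability vectors
  expect_equal(colSums(fw1$probs), rep(1, ncol(fw1$probs)), tolerance = 1e-6)

  # batched forward equals per-sample forward
  for (i in 1:3) {
    cols <- ((i - 1L) * cfg$max_len + 1L):(i * cfg$max_len)
    fwi <- icvae:::icvae_forward(params, cfg, b$x[, cols, drop = FALSE],
                                 b$labels[, i, drop = FALSE],
                                 b$eps[, i, drop = FALSE])
    expect_equal(fwi$mu[, 1], fw1$mu[, i], tolerance = 1e-12)
    expect_equal(fwi$probs, fw1$probs[, cols], tolerance = 1e-12)
  }
})

test_that("with zero labels the objective equals the plain CVAE loss", {
  cfg <- tiny_cfg(beta = 0.8)
  params <- icvae_init_params(cfg, seed = 3)
  b <- tiny_batch(cfg, B = 6L)
  b$labels[] <- 0                               # tau * c = 0
  fw <- icvae:::icvae_forward(params, cfg, b$x, b$labels, b$eps)
  ic <- icvae:::icvae_loss_terms(fw, b$x, b$labels, cfg)
  cv <- icvae:::cvae_loss_terms(fw, b$x, cfg)
  expect_identical(ic$recon, cv$recon)          # term-by-term, bit-identical
  expect_identical(ic$kl, cv$kl)
  expect_identical(ic$total, cv$total)
})

test_that("batch KL is the mean of per-sample shifted KLs", {
  cfg <- tiny_cfg()
  params <- icvae_init_params(cfg, seed = 8)
  b <- tiny_batch(cfg, B = 6L)
  fw <- icvae:::icvae_forward(params, cfg, b$x, b$labels, b$eps)
  terms <- icvae:::icvae_loss_terms(fw, b$x, b$labels, cfg)
  m <- icvae:::prior_mean_of(b$labels, cfg)
  per_sample <- kl_shifted(fw$mu, fw$sigma, m)
  expect_equal(terms$kl, mean(per_sample))
})

test_that("a perfectly matched batch scores recon ~ 0 and kl == 0", {
  cfg <- tiny_cfg()
  b <- tiny_batch(cfg, B = 3L)
  m <- icvae:::prior_mean_of(b$labels, cfg)
  fw <- list(probs = pmin(pmax(b$x, 1e-12), 1), mu = m,
             sigma = matrix(1, cfg$K, 3L), cache = list(B = 3L))
  terms <- icvae:::icvae_loss_terms(fw, b$x, b$labels, cfg)
  expect_equal(terms$recon, 0, tolerance = 1e-8)
  expect_identical(terms$kl, 0)
})

test_that("analytic gradients agree with central differences", {
  cfg <- tiny_cfg(beta = 0.7)
  params <- icvae_init_params(cfg, seed = 2)
  # jitter away from exact-zero ReLU kinks left by zero-initialized biases
  set.seed(21)
  params <- lapply(params, function(p) p + rnorm(length(p), sd = 0.05))
  b <- tiny_batch(cfg, B = 3L, label_max = 5)
  lossfun <- function(p) {
    fw <- icvae:::icvae_forward(p, cfg, b$x, b$labels, b$eps)
    icvae:::icvae_loss_terms(fw, b$x, b$labels, cfg)$total
  }
  fw <- icvae:::icvae_forward(params, cfg, b$x, b$labels, b$eps)
  gr <- icvae:::icvae_backward(params, cfg, fw, b$x, b$labels)
  h <- 1e-6
  set.seed(22)
  for (nm in names(params)) {
    for (i in sample(length(params[[nm]]), min(4L, length(params[[nm]])))) {
      p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + h
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - h
      num <- (lossfun(p1) - lossfun(p2)) / (2 * h)
      expect_equal(gr[[nm]][i], num, tolerance = 5e-3,
                   label = paste("grad", nm, i))
    }
  }
})

test_that("loss and gradients stay finite over 100 optimizer steps", {
  cfg <- tiny_cfg()
  params <- icvae_init_params(cfg, seed = 4)
  opt <- icvae:::adam_init(params)
  set.seed(14)
  for (step in 1:100) {
    b <- tiny_batch(cfg, B = 8L, seed = step)
    fw <- icvae:::icvae_forward(params, cfg, b$x, b$labels, b$eps)
    terms <- icvae:::icvae_loss_terms(fw, b$x, b$labels, cfg)
    expect_true(is.finite(terms$total))
    gr <- icvae:::icvae_backward(params, cfg, fw, b$x, b$labels)
    expect_true(all(vapply(gr, function(g) all(is.finite(g)), logical(1L))))
    st <- icvae:::adam_step(params, gr, opt)
    params <- st$params; opt <- st$state
  }
})
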