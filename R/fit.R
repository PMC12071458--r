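## Model fitting: seeded 70/30 split, minibatch Adam training of the
## shifted-prior objective, per-epoch loss logging, and the S3 surface of
## the fitted "icvae" object.

## Named sub-seeds derived from one user seed (kept below 2^31).
derive_seeds <- function(seed) {
  with_seed(seed, {
    s <- sample.int(.Machine$integer.max - 1L, 4L)
    list(split = s[1L], init = s[2L], loop = s[3L], gen = s[4L])
  })
}

as_icvae_corpus <- function(corpus) {
  if (inherits(corpus, "icvae_corpus")) return(corpus)
  if (is.character(corpus)) {
    props <- compute_properties(corpus)
    return(structure(list(smiles = corpus,
                          properties = cbind(data.frame(smiles = corpus),
                                             props[ICVAE_PROPERTIES])),
                     class = "icvae_corpus"))
  }
  stop("corpus must be an icvae_corpus or a character vector of SMILES")
}

corpus_subset <- function(corpus, idx) {
  structure(list(smiles = corpus$smiles[idx],
                 properties = corpus$properties[idx, , drop = FALSE]),
            class = "icvae_corpus")
}

#' Split a corpus into training and test sets
#'
#' Deterministic under `seed`; the two parts are disjoint and exhaustive
#' with `floor(frac * n)` molecules in the training part.
#'
#' @param corpus an `icvae_corpus` or character vector of SMILES.
#' @param train_fraction fraction in (0, 1) (default 0.7).
#' @param seed integer seed.
#' @return list with elements `train` and `test` (same type as input) and
#'   attribute `"indices"`.
#' @export
split_corpus <- function(corpus, train_fraction = 0.7, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie strictly between 0 and 1")
  n <- if (is.character(corpus)) length(corpus) else length(corpus$smiles)
  if (n < 2L) stop("corpus must contain at least 2 molecules")
  n_train <- floor(train_fraction * n)
  perm <- with_seed(seed, sample.int(n))
  tr <- sort(perm[seq_len(n_train)])
  te <- sort(perm[-seq_len(n_train)])
  out <- if (is.character(corpus)) list(train = corpus[tr], test = corpus[te])
  else list(train = corpus_subset(corpus, tr), test = corpus_subset(corpus, te))
  attr(out, "indices") <- list(train = tr, test = te)
  out
}

## Token index matrix (max_len x N) for a set of SMILES under a vocabulary.
tokens_matrix <- function(smiles, vocab, max_len) {
  pad <- vocab_index(vocab, vocab$pad_token)
  term <- vocab_index(vocab, vocab$terminal_token)
  out <- matrix(pad, max_len, length(smiles))
  for (i in seq_along(smiles)) {
    idx <- vocab_index(vocab, smiles_tokenize(smiles[i]))
    if (length(idx) > max_len - 2L)
      stop("SMILES too long for max_len ", max_len, ": ", smiles[i])
    out[seq_len(length(idx) + 2L), i] <- c(term, idx, term)
  }
  out
}

## One-hot V x (L*B) matrix from token-index columns.
onehot_batch <- function(tok, V) {
  L <- nrow(tok); B <- ncol(tok)
  x <- matrix(0, V, L * B)
  x[cbind(as.vector(tok), seq_len(L * B))] <- 1
  x
}

#' Fit an interpretable conditional VAE on a SMILES corpus
#'
#' Trains the shifted-prior conditional VAE: the encoder/decoder pair is
#' conditioned on scaled property labels and the latent prior mean of
#' conditioned coordinate i is the scaled label `tau * (v - v_min)` of
#' property i, so after training those coordinates read out property values
#' linearly. Optimization is minibatch Adam with global gradient-norm
#' clipping at 5; all randomness (split, init, shuffling, latent noise)
#' derives from `seed`.
#'
#' @param corpus an `icvae_corpus` (see [generate_corpus()]) or character
#'   vector of SMILES (properties then computed via RDKit).
#' @param properties character vector naming the conditioned properties
#'   (subset of MW, logP, HBA, HBD, TPSA, QED, SAS).
#' @param K latent dimension.
#' @param epochs,batch_size,learning_rate,beta optimizer settings.
#' @param train_fraction fraction of molecules used for training.
#' @param seed master seed.
#' @param max_len encoded length (tokens + 2 terminals padded to this).
#' @param specs optional named list of [property_spec()]s; defaults to the
#'   training-split min/max range per property.
#' @param hidden_dim,conv_filters,kernel architecture knobs, see
#'   [icvae_config()].
#' @param verbose print per-epoch losses.
#' @return an object of class `icvae` with components `params`, `config`,
#'   `vocab`, `specs`, `loss_log` (epoch, train_recon, train_kl,
#'   test_total), `split`, `corpus`, `seed`.
#' @seealso [predict.icvae()], [simulate.icvae()], [evaluate_loss()],
#'   [linearity_report()]
#' @export
icvae <- function(corpus, properties = "HBA", K = 128L, epochs = 100L,
                  batch_size = 128L, learning_rate = 1e-3, beta = 1,
                  train_fraction = 0.7, seed = 1L, max_len = ICVAE_MAX_LEN,
                  specs = NULL, hidden_dim = 292L,
                  conv_filters = c(16L, 32L, 64L), kernel = 11L,
                  verbose = FALSE) {
  stopifnot(epochs >= 1L, batch_size >= 1L)
  corpus <- as_icvae_corpus(corpus)
  seeds <- derive_seeds(seed)
  halves <- split_corpus(corpus, train_fraction, seeds$split)
  vocab <- build_vocabulary(corpus$smiles)
  if (is.null(specs))
    specs <- fit_property_specs(halves$train$properties, properties)
  stopifnot(identical(names(specs), properties))
  cfg <- icvae_config(vocab_size = length(vocab), P = length(properties),
                      K = K, hidden_dim = hidden_dim,
                      conv_filters = conv_filters, kernel = kernel,
                      max_len = max_len, beta = beta)
  params <- icvae_init_params(cfg, seeds$init)

  tok_tr <- tokens_matrix(halves$train$smiles, vocab, max_len)
  tok_te <- tokens_matrix(halves$test$smiles, vocab, max_len)
  lab_tr <- t(condition_labels(halves$train$properties, specs))
  lab_te <- t(condition_labels(halves$test$properties, specs))

  n_tr <- ncol(tok_tr)
  opt <- adam_init(params)
  log <- data.frame(epoch = integer(), train_recon = numeric(),
                    train_kl = numeric(), test_total = numeric())
  with_seed(seeds$loop, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n_tr)
      starts <- seq(1L, n_tr, by = batch_size)
      rec_sum <- kl_sum <- 0
      for (bi in seq_along(starts)) {
        sel <- ord[starts[bi]:min(starts[bi] + batch_size - 1L, n_tr)]
        B <- length(sel)
        x <- onehot_batch(tok_tr[, sel, drop = FALSE], cfg$vocab_size)
        labels <- lab_tr[, sel, drop = FALSE]
        eps <- matrix(stats::rnorm(cfg$K * B), cfg$K, B)
        fw <- icvae_forward(params, cfg, x, labels, eps)
        terms <- icvae_loss_terms(fw, x, labels, cfg)
        if (!is.finite(terms$total))
          stop("non-finite loss at epoch ", ep, ", batch ", bi)
        rec_sum <- rec_sum + terms$recon * B
        kl_sum <- kl_sum + terms$kl * B
        grads <- icvae_backward(params, cfg, fw, x, labels)
        st <- adam_step(params, grads, opt, lr = learning_rate)
        params <- st$params; opt <- st$state
      }
      test <- batched_loss(params, cfg, tok_te, lab_te)
      log[ep, ] <- list(ep, rec_sum / n_tr, kl_sum / n_tr, test$total)
      if (verbose)
        message(sprintf("epoch %3d  recon %8.3f  kl %8.3f  test %8.3f",
                        ep, rec_sum / n_tr, kl_sum / n_tr, test$total))
    }
  })

  structure(list(params = params, config = cfg, vocab = vocab, specs = specs,
                 properties = properties, loss_log = log, corpus = corpus,
                 split = attr(halves, "indices"), seed = seed,
                 learning_rate = learning_rate, call = match.call()),
            class = "icvae")
}

## Deterministic (z = mu) loss over a set, in batches.
batched_loss <- function(params, cfg, tok, lab, batch_size = 256L) {
  n <- ncol(tok)
  if (n == 0L) stop("empty evaluation set")
  rec <- kl <- 0
  for (st in seq(1L, n, by = batch_size)) {
    sel <- st:min(st + batch_size - 1L, n)
    x <- onehot_batch(tok[, sel, drop = FALSE], cfg$vocab_size)
    fw <- icvae_forward(params, cfg, x, lab[, sel, drop = FALSE], eps = NULL)
    terms <- icvae_loss_terms(fw, x, lab[, sel, drop = FALSE], cfg)
    rec <- rec + terms$recon * length(sel)
    kl <- kl + terms$kl * length(sel)
  }
  list(recon = rec / n, kl = kl / n,
       total = rec / n + cfg$beta * kl / n)
}

#' Evaluate the objective of a fitted model on a molecule set
#'
#' Deterministic: the decoder is evaluated at `z = mu`. Returns the loss
#' breakdown (reconstruction nats summed over positions, KL to the shifted
#' prior, and their beta-weighted total), averaged over molecules.
#'
#' @param object a fitted `icvae`.
#' @param corpus an `icvae_corpus`, character vector of SMILES, or `NULL`
#'   for the model's held-out test split.
#' @return list with `recon`, `kl`, `total`.
#' @export
evaluate_loss <- function(object, corpus = NULL) {
  stopifnot(inherits(object, "icvae"))
  corpus <- if (is.null(corpus))
    corpus_subset(object$corpus, object$split$test)
  else as_icvae_corpus(corpus)
  if (!length(corpus$smiles)) stop("empty evaluation set")
  tok <- tokens_matrix(corpus$smiles, object$vocab, object$config$max_len)
  lab <- t(condition_labels(corpus$properties, object$specs))
  batched_loss(object$params, object$config, tok, lab)
}

#' Compare test loss across latent dimensions
#'
#' Refits the model for each value of `K` (all other settings shared) and
#' records the final-epoch losses, the scaled-down analogue of comparing
#' held-out loss across latent sizes.
#'
#' @param corpus corpus passed to [icvae()].
#' @param K_values integer vector of latent dimensions.
#' @param ... further arguments to [icvae()].
#' @return data.frame with one row per K: `K`, `train_recon`, `train_kl`,
#'   `test_total`.
#' @export
icvae_k_sweep <- function(corpus, K_values = c(8L, 32L, 128L), ...) {
  rows <- lapply(K_values, function(kk) {
    fit <- icvae(corpus, K = kk, ...)
    tail_row <- fit$loss_log[nrow(fit$loss_log), ]
    data.frame(K = kk, train_recon = tail_row$train_recon,
               train_kl = tail_row$train_kl,
               test_total = tail_row$test_total)
  })
  do.call(rbind, rows)
}

## ---- S3 methods ----------------------------------------------------------

#' @export
print.icvae <- function(x, ...) {
  cfg <- x$config
  cat("Interpretable conditional VAE (shifted latent prior)\n")
  cat(sprintf("  conditioned on: %s\n", paste(x$properties, collapse = ", ")))
  cat(sprintf("  K = %d latent dims, vocab %d tokens, max length %d\n",
              cfg$K, cfg$vocab_size, cfg$max_len))
  cat(sprintf("  trained %d epochs on %d molecules (%d held out)\n",
              nrow(x$loss_log), length(x$split$train), length(x$split$test)))
  if (nrow(x$loss_log)) {
    last <- x$loss_log[nrow(x$loss_log), ]
    cat(sprintf("  final losses: recon %.3f, kl %.3f, test total %.3f\n",
                last$train_recon, last$train_kl, last$test_total))
  }
  invisible(x)
}

#' @export
summary.icvae <- function(object, ...) {
  print(object)
  cat("\nProperty conditioning:\n")
  for (sp in object$specs) print(sp)
  cat("\nLatent linearity on the held-out split:\n")
  tab <- embed_corpus(object, corpus_subset(object$corpus,
                                            object$split$test))
  for (i in seq_along(object$properties)) {
    rep <- linearity_report(tab, object$properties[i], i)
    cat(sprintf("  %s ~ mu_%d: slope %.3f, r %.3f, R^2 %.3f\n",
                object$properties[i], i, rep$slope, rep$pearson_r,
                rep$r_squared))
  }
  invisible(object)
}

#' @export
coef.icvae <- function(object, ...) object$params

#' Latent embedding or reconstruction for new molecules
#'
#' `type = "latent"` returns the posterior means mu (one row per molecule,
#' K columns; sigma attached as attribute). `type = "reconstruction"`
#' greedy-decodes each molecule from its posterior mean.
#'
#' @param object a fitted `icvae`.
#' @param newdata `icvae_corpus` or character vector of SMILES; default the
#'   held-out test split.
#' @param type "latent" or "reconstruction".
#' @param ... unused.
#' @export
predict.icvae <- function(object, newdata = NULL,
                          type = c("latent", "reconstruction"), ...) {
  type <- match.arg(type)
  corpus <- if (is.null(newdata))
    corpus_subset(object$corpus, object$split$test)
  else as_icvae_corpus(newdata)
  tok <- tokens_matrix(corpus$smiles, object$vocab, object$config$max_len)
  lab <- t(condition_labels(corpus$properties, object$specs))
  enc <- encode_batch(object, tok, lab)
  if (type == "latent") {
    mu <- t(enc$mu)
    rownames(mu) <- corpus$smiles
    attr(mu, "sigma") <- t(enc$sigma)
    return(mu)
  }
  probs <- decode_batch(object, enc$mu, lab)
  vapply(seq_along(corpus$smiles), function(i)
    decode_one_hot(probs[[i]], object$vocab, "greedy"), character(1L))
}

## mu/sigma for token/label batches (columns = molecules).
encode_batch <- function(object, tok, lab, batch_size = 256L) {
  cfg <- object$config
  n <- ncol(tok)
  mu <- matrix(0, cfg$K, n); sigma <- matrix(0, cfg$K, n)
  for (st in seq(1L, n, by = batch_size)) {
    sel <- st:min(st + batch_size - 1L, n)
    x <- onehot_batch(tok[, sel, drop = FALSE], cfg$vocab_size)
    fw <- icvae_forward(object$params, cfg, x, lab[, sel, drop = FALSE])
    mu[, sel] <- fw$mu; sigma[, sel] <- fw$sigma
  }
  list(mu = mu, sigma = sigma)
}

## Decoder-only pass: per-molecule score matrices (V x max_len).
decode_batch <- function(object, z, lab, batch_size = 256L) {
  cfg <- object$config
  n <- ncol(z)
  out <- vector("list", n)
  for (st in seq(1L, n, by = batch_size)) {
    sel <- st:min(st + batch_size - 1L, n)
    probs <- icvae_decode_probs(object$params, cfg,
                                z[, sel, drop = FALSE],
                                lab[, sel, drop = FALSE])
    for (j in seq_along(sel))
      out[[sel[j]]] <- probs[, ((j - 1L) * cfg$max_len + 1L):
                                 (j * cfg$max_len), drop = FALSE]
  }
  out
}

## Decoder forward only (no encoder): z K x B, labels P x B.
icvae_decode_probs <- function(params, cfg, z, labels) {
  f <- cfg$conv_filters; k <- cfg$kernel; s <- cfg$stride
  Ls <- icvae_lengths(cfg)
  B <- ncol(z)
  a <- latent_scale(cfg)
  c_norm <- labels / cfg$latent_range
  din <- rbind(z / a, c_norm)
  g1 <- nn_relu(params$df1_W %*% din + params$df1_b)
  g2 <- nn_relu(params$df2_W %*% g1 + params$df2_b)
  u3 <- matrix(g2, f[3], Ls[4] * B)
  t3 <- nn_relu(nn_tconv_fwd(u3, params$dt3_W, params$dt3_b,
                             f[2], Ls[3], B, k, s))
  t2 <- nn_relu(nn_tconv_fwd(t3, params$dt2_W, params$dt2_b,
                             f[1], Ls[2], B, k, s))
  nn_softmax(nn_tconv_fwd(t2, params$dt1_W, params$dt1_b,
                          cfg$vocab_size, Ls[1], B, k, s))
}

#' Save / load a fitted model checkpoint
#'
#' The checkpoint is a single RDS archive holding weights, configuration,
#' property specs and vocabulary; loading restores bit-identical forward
#' passes.
#'
#' @param object a fitted `icvae`.
#' @param path file path.
#' @export
save_icvae <- function(object, path) {
  stopifnot(inherits(object, "icvae"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_icvae
#' @export
load_icvae <- function(path) {
  object <- readRDS(path)
  if (!inherits(object, "icvae")) stop("not an icvae checkpoint: ", path)
  object
}
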