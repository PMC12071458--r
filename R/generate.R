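## Controlled generation: latent vectors are built directly from target
## property values (z = tau*c + eps on the conditioned coordinates, standard
## normal elsewhere) and decoded under the same condition labels; property
## grids sweep targets across a range at equal sampling size per step.

#' Build latent vectors for target property values
#'
#' Conditioned coordinate i is set to the scaled label of target property i
#' plus N(0, noise_scale^2) noise; the remaining `K - P` coordinates are
#' drawn from the standard-normal prior. With `noise_scale = 0` the
#' conditioned coordinates equal the scaled targets exactly.
#'
#' @param targets named numeric vector of desired property values
#'   (property units), one per conditioned property, in spec order.
#' @param specs named list of [property_spec()]s (the model's conditioning).
#' @param K latent dimension.
#' @param n number of latent vectors.
#' @param noise_scale standard deviation of the conditioned-coordinate
#'   noise (default 1, matching the prior).
#' @param seed RNG seed.
#' @return K x n matrix of latent vectors.
#' @export
make_latent <- function(targets, specs, K, n = 1L, noise_scale = 1,
                        seed = NULL) {
  stopifnot(n >= 1L, noise_scale >= 0)
  bad <- setdiff(names(targets), names(specs))
  if (length(bad))
    stop("unknown conditioned property: ", paste(bad, collapse = ", "))
  stopifnot(identical(sort(names(targets)), sort(names(specs))))
  P <- length(specs)
  if (P > K) stop("more conditioned properties than latent dimensions")
  labels <- vapply(names(specs),
                   function(nm) scale_property(targets[[nm]], specs[[nm]]),
                   numeric(1L))
  with_seed(seed, {
    z <- matrix(stats::rnorm(K * n), K, n)
    z[seq_len(P), ] <- labels +
      matrix(stats::rnorm(P * n, sd = noise_scale), P, n)
    z
  })
}

#' Generate molecules at target property values
#'
#' Draws `n` latent vectors via [make_latent()], decodes them with the
#' scaled targets as condition labels, checks validity, and (for valid
#' molecules) computes the achieved property values via RDKit.
#'
#' @param object a fitted `icvae`.
#' @param targets named numeric vector of desired property values; must
#'   name exactly the model's conditioned properties.
#' @param n molecules to generate.
#' @param noise_scale conditioned-coordinate noise s.d. (default 1).
#' @param decode_mode `"greedy"` or `"sample"`.
#' @param temperature sampling temperature (sample mode).
#' @param seed RNG seed; fixes both latents and sampling decodes.
#' @param achieved compute achieved properties of valid molecules
#'   (default TRUE).
#' @return data.frame with one row per generated molecule: `smiles`,
#'   `valid`, one `target_<p>` and one `achieved_<p>` column per property
#'   (NA where invalid).
#' @export
generate_molecules <- function(object, targets, n = 100L, noise_scale = 1,
                               decode_mode = c("greedy", "sample"),
                               temperature = 1, seed = NULL,
                               achieved = TRUE) {
  stopifnot(inherits(object, "icvae"))
  decode_mode <- match.arg(decode_mode)
  specs <- object$specs
  if (!setequal(names(targets), names(specs)))
    stop("targets must name exactly the conditioned properties: ",
         paste(names(specs), collapse = ", "))
  targets <- targets[names(specs)]
  z <- make_latent(targets, specs, object$config$K, n = n,
                   noise_scale = noise_scale, seed = seed)
  labels <- matrix(vapply(names(specs), function(nm)
    scale_property(targets[[nm]], specs[[nm]]), numeric(1L)),
    nrow = length(specs), ncol = n)
  probs <- decode_batch(object, z, labels)
  dec_seed <- if (is.null(seed)) NULL else seed + 1L
  smiles <- vapply(seq_len(n), function(i)
    decode_one_hot(probs[[i]], object$vocab, decode_mode,
                   temperature = temperature,
                   rng_seed = if (is.null(dec_seed)) NULL
                   else (dec_seed + i) %% .Machine$integer.max),
    character(1L))
  out <- data.frame(smiles = smiles, valid = FALSE,
                    stringsAsFactors = FALSE)
  for (nm in names(specs)) out[[paste0("target_", nm)]] <- targets[[nm]]
  res <- chem_call(ifelse(nzchar(smiles), smiles, "*INVALID*"), "props")
  out$valid <- res$valid & nzchar(smiles)
  if (achieved) {
    for (nm in names(specs))
      out[[paste0("achieved_", nm)]] <-
        ifelse(out$valid, res[[nm]], NA_real_)
  }
  out
}

#' @rdname generate_molecules
#' @param nsim number of molecules (alias of `n` for the S3 generic).
#' @param ... passed on to [generate_molecules()].
#' @export
simulate.icvae <- function(object, nsim = 1L, seed = NULL, ...) {
  generate_molecules(object, n = nsim, seed = seed, ...)
}

#' Expand a property grid into target steps
#'
#' A grid is a named list of `c(start, stop, step)` triples. A single
#' property yields `seq(start, stop, by = step)`. Two or more properties
#' are varied simultaneously (paired steps, not a cross product): the
#' number of paired steps is the largest individual step count and each
#' property is spaced evenly from its start to its stop over that count.
#'
#' @param grid named list of numeric `c(start, stop, step)` vectors.
#' @return data.frame with one column per property and one row per step.
#' @examples
#' nrow(sweep_grid(list(MW = c(210, 490, 20))))            # 15
#' nrow(sweep_grid(list(HBD = c(0, 5, 1))))                # 6
#' nrow(sweep_grid(list(MW = c(170, 350, 10), TPSA = c(10, 90, 10))))  # 19
#' @export
sweep_grid <- function(grid) {
  if (!length(grid) || is.null(names(grid)))
    stop("empty grid: supply named c(start, stop, step) triples")
  counts <- vapply(grid, function(g) {
    stopifnot(length(g) == 3L, g[3] > 0, g[2] > g[1])
    as.integer(floor((g[2] - g[1]) / g[3] + 1e-9)) + 1L
  }, integer(1L))
  n_steps <- max(counts)
  cols <- lapply(grid, function(g) {
    if (length(grid) == 1L) seq(g[1], g[2], by = g[3])
    else seq(g[1], g[2], length.out = n_steps)
  })
  as.data.frame(cols)
}

#' Sweep generation across a property grid
#'
#' Generates `n` molecules at every step of the grid (equal sampling size
#' per step) and returns the long-format table of targets, decoded SMILES,
#' validity, achieved values and absolute errors. No rows are filtered; the
#' `within_bound` column marks molecules whose absolute error is below
#' `error_bound` (default: one grid step) on every swept property.
#'
#' @param object a fitted `icvae`; the grid must cover exactly its
#'   conditioned properties.
#' @param grid named list of `c(start, stop, step)` triples
#'   (see [sweep_grid()]).
#' @param n molecules per step.
#' @param noise_scale,decode_mode,temperature,seed as in
#'   [generate_molecules()].
#' @param error_bound named numeric of per-property acceptance bounds;
#'   defaults to each property's grid step.
#' @return long data.frame: `step`, `target_<p>`, `smiles`, `valid`,
#'   `achieved_<p>`, `abs_error_<p>`, `within_bound`.
#' @export
property_sweep <- function(object, grid, n = 30L, noise_scale = 1,
                           decode_mode = "greedy", temperature = 1,
                           seed = NULL, error_bound = NULL) {
  stopifnot(inherits(object, "icvae"))
  steps <- sweep_grid(grid)
  if (!setequal(names(steps), names(object$specs)))
    stop("grid must cover exactly the conditioned properties: ",
         paste(names(object$specs), collapse = ", "))
  if (is.null(error_bound))
    error_bound <- vapply(grid, function(g) g[3], numeric(1L))
  rows <- lapply(seq_len(nrow(steps)), function(i) {
    targets <- unlist(steps[i, , drop = FALSE])
    g <- generate_molecules(object, targets, n = n,
                            noise_scale = noise_scale,
                            decode_mode = decode_mode,
                            temperature = temperature,
                            seed = if (is.null(seed)) NULL
                            else (seed + 131L * i) %% .Machine$integer.max)
    cbind(step = i, g)
  })
  out <- do.call(rbind, rows)
  ok <- rep(TRUE, nrow(out))
  for (nm in names(steps)) {
    err <- abs(out[[paste0("achieved_", nm)]] - out[[paste0("target_", nm)]])
    out[[paste0("abs_error_", nm)]] <- err
    ok <- ok & !is.na(err) & err < error_bound[[nm]]
  }
  out$within_bound <- ok
  out
}
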