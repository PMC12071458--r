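## Latent-space diagnostics: embed a corpus at the posterior means and
## quantify the linear property-to-latent mapping that conditioning on a
## shifted prior is meant to produce.

#' Embed a corpus in latent space
#'
#' Runs the encoder (posterior means, no sampling, hence deterministic) on
#' every molecule and tabulates properties, scaled labels and latent means.
#'
#' @param object a fitted `icvae`.
#' @param corpus `icvae_corpus` or character vector; default the model's
#'   held-out test split.
#' @return data.frame of class `icvae_embedding`: columns `smiles`, the
#'   property values, `label_<p>` scaled labels and `mu_1 .. mu_K`;
#'   attribute `"properties"` records the conditioned property order.
#' @export
embed_corpus <- function(object, corpus = NULL) {
  stopifnot(inherits(object, "icvae"))
  corpus <- if (is.null(corpus))
    corpus_subset(object$corpus, object$split$test)
  else as_icvae_corpus(corpus)
  tok <- tokens_matrix(corpus$smiles, object$vocab, object$config$max_len)
  lab <- t(condition_labels(corpus$properties, object$specs))
  enc <- encode_batch(object, tok, lab)
  if (!all(is.finite(enc$mu))) stop("non-finite latent means")
  out <- data.frame(smiles = corpus$smiles, stringsAsFactors = FALSE)
  for (nm in names(object$specs)) out[[nm]] <- corpus$properties[[nm]]
  for (i in seq_along(object$specs))
    out[[paste0("label_", names(object$specs)[i])]] <- lab[i, ]
  mu <- t(enc$mu)
  colnames(mu) <- paste0("mu_", seq_len(object$config$K))
  out <- cbind(out, mu)
  attr(out, "properties") <- names(object$specs)
  class(out) <- c("icvae_embedding", "data.frame")
  out
}

#' Regress a latent dimension on a scaled property label
#'
#' Ordinary least squares of the latent mean `mu_dim` on the scaled label
#' of `property`. A slope near 1 with high correlation is the signature of
#' the shifted prior: the conditioned coordinate reads the property out
#' linearly on the label scale.
#'
#' @param table an `icvae_embedding` from [embed_corpus()].
#' @param property conditioned property name.
#' @param dim latent dimension index (default: the property's own
#'   conditioned coordinate).
#' @return list with `slope`, `intercept`, `pearson_r`, `r_squared`.
#' @export
linearity_report <- function(table, property,
                             dim = match(property,
                                         attr(table, "properties"))) {
  stopifnot(inherits(table, "icvae_embedding"))
  lab_col <- paste0("label_", property)
  if (!lab_col %in% names(table)) stop("property not in table: ", property)
  x <- table[[lab_col]]
  y <- table[[paste0("mu_", dim)]]
  if (length(unique(table[[property]])) < 3L)
    stop("need at least 3 distinct property values for a linearity report")
  if (stats::sd(x) == 0) stop("degenerate regression: constant label column")
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       pearson_r = stats::cor(x, y),
       r_squared = summary(fit)$r.squared)
}

#' Two-property latent map with module lengths
#'
#' For a model conditioned on (at least) two properties, min-max normalizes
#' the two conditioned latent coordinates to \[0, 1\] over the table and
#' reports each molecule's module length `sqrt(x^2 + y^2)`.
#'
#' @param table an `icvae_embedding`.
#' @param property_x,property_y conditioned property names.
#' @return data.frame: `smiles`, `x`, `y` (normalized), `module_length`.
#' @export
pair_map <- function(table, property_x, property_y) {
  stopifnot(inherits(table, "icvae_embedding"))
  props <- attr(table, "properties")
  for (p in c(property_x, property_y))
    if (!p %in% props)
      stop("property not conditioned in this model: ", p)
  norm01 <- function(v) {
    if (max(v) == min(v)) return(rep(0, length(v)))
    (v - min(v)) / (max(v) - min(v))
  }
  x <- norm01(table[[paste0("mu_", match(property_x, props))]])
  y <- norm01(table[[paste0("mu_", match(property_y, props))]])
  data.frame(smiles = table$smiles, x = x, y = y,
             module_length = sqrt(x^2 + y^2),
             stringsAsFactors = FALSE)
}

#' Latent scatter of a fitted model
#'
#' Plots the first two latent dimensions of the held-out split colored by
#' the (first) conditioned property.
#'
#' @param x a fitted `icvae`.
#' @param property property used for coloring (default the first
#'   conditioned one).
#' @param ... passed to [graphics::plot()].
#' @export
plot.icvae <- function(x, property = x$properties[1L], ...) {
  tab <- embed_corpus(x)
  v <- tab[[property]]
  pal <- grDevices::hcl.colors(100, "Blue-Red 3")
  col <- pal[1 + round(99 * (v - min(v)) / max(1e-12, diff(range(v))))]
  y2 <- if (x$config$K >= 2L) tab$mu_2 else tab$mu_1
  graphics::plot(tab$mu_1, y2, col = col, pch = 16,
                 xlab = "latent dim 1", ylab = "latent dim 2", ...)
  invisible(tab)
}
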