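## Generative-chemistry evaluation metrics (MOSES-style): Valid, Unique@1k,
## Novelty, SNN, Frag, IntDiv. Fingerprints are Morgan circular, radius 2,
## 1024 bits; fragments are BRICS; all set comparisons run on canonical
## SMILES.

#' Fraction of chemically valid SMILES
#'
#' A string is valid iff it parses and sanitizes under RDKit (valence and
#' aromaticity checks). Returns the fraction and the canonicalized valid
#' subset.
#'
#' @param smiles character vector of generated SMILES.
#' @return list with `fraction` and `canonical` (character vector).
#' @export
validity <- function(smiles) {
  if (!length(smiles)) stop("empty SMILES list")
  res <- chem_call(ifelse(nzchar(smiles), smiles, "*INVALID*"), "canon")
  ok <- res$valid & nzchar(smiles)
  list(fraction = mean(ok), canonical = res$canonical[ok])
}

#' Fraction of unique molecules among the first k
#'
#' @param canonical character vector of valid canonical SMILES, in
#'   generation order.
#' @param k window size (default 1000).
#' @return `|distinct among first min(k, n)| / min(k, n)`.
#' @export
uniqueness_at_k <- function(canonical, k = 1000L) {
  if (!length(canonical)) stop("empty molecule list")
  head_n <- utils::head(canonical, k)
  length(unique(head_n)) / length(head_n)
}

#' Fraction of generated molecules absent from the training set
#'
#' @param canonical generated valid canonical SMILES.
#' @param training_set canonical SMILES the model was trained on.
#' @return fraction in \[0, 1\].
#' @export
novelty <- function(canonical, training_set) {
  if (!length(canonical) || !length(training_set))
    stop("empty molecule list")
  mean(!(canonical %in% training_set))
}

## Tanimoto similarities between two fingerprint matrices (rows =
## molecules): returns the n_a x n_b similarity matrix via bit-count
## algebra on 0/1 matrices.
tanimoto_matrix <- function(fa, fb) {
  common <- tcrossprod(fa, fb)              # intersection counts
  na_ <- rowSums(fa); nb_ <- rowSums(fb)
  denom <- outer(na_, nb_, "+") - common
  sim <- common / denom
  sim[denom == 0] <- 0                      # two empty fingerprints
  sim
}

fingerprints_of <- function(canonical) {
  res <- chem_call(canonical, "fp")
  if (any(!res$valid))
    warning("skipping ", sum(!res$valid), " molecule(s) without fingerprints")
  chem_fp_matrix(res$bits[res$valid]) * 1
}

#' Similarity to nearest neighbor (SNN)
#'
#' Mean, over generated molecules, of the maximum Tanimoto similarity
#' (Morgan radius-2 1024-bit fingerprints) to any molecule of the
#' reference set.
#'
#' @param generated,reference character vectors of valid canonical SMILES.
#' @return mean nearest-neighbor Tanimoto in \[0, 1\].
#' @export
snn <- function(generated, reference) {
  if (!length(generated) || !length(reference))
    stop("empty molecule list")
  sim <- tanimoto_matrix(fingerprints_of(generated),
                         fingerprints_of(reference))
  mean(apply(sim, 1L, max))
}

brics_fragments <- function(canonical) {
  res <- chem_call(canonical, "brics")
  frags <- strsplit(res$fragments[res$valid], ";", fixed = TRUE)
  unlist(frags)
}

#' Fragment similarity (Frag)
#'
#' Cosine similarity between the BRICS-fragment frequency vectors of two
#' molecule sets, over the union fragment vocabulary. Defined as 1 when
#' neither set yields any fragment.
#'
#' @param generated,reference character vectors of valid canonical SMILES.
#' @return cosine similarity in \[0, 1\].
#' @export
fragment_similarity <- function(generated, reference) {
  if (!length(generated) || !length(reference))
    stop("empty molecule list")
  fg <- brics_fragments(generated)
  fr <- brics_fragments(reference)
  if (!length(fg) && !length(fr)) return(1)
  vocab <- union(fg, fr)
  cg <- as.numeric(table(factor(fg, levels = vocab)))
  cr <- as.numeric(table(factor(fr, levels = vocab)))
  denom <- sqrt(sum(cg^2)) * sqrt(sum(cr^2))
  if (denom == 0) return(0)
  sum(cg * cr) / denom
}

#' Internal diversity (IntDiv)
#'
#' One minus the mean pairwise Tanimoto similarity over all unordered pairs
#' of distinct generated molecules (self-pairs excluded).
#'
#' @param generated character vector (>= 2) of valid canonical SMILES.
#' @return value in \[0, 1\].
#' @export
internal_diversity <- function(generated) {
  if (length(generated) < 2L)
    stop("internal diversity needs at least 2 molecules")
  fp <- fingerprints_of(generated)
  sim <- tanimoto_matrix(fp, fp)
  n <- nrow(sim)
  1 - sum(sim[upper.tri(sim)]) / (n * (n - 1) / 2)
}

#' Full metrics report for a generated molecule set
#'
#' Composes validity, Unique@k, Novelty (vs the training set), SNN and Frag
#' (vs the reference/test set) and IntDiv into one report.
#'
#' @param generated raw generated SMILES (possibly invalid).
#' @param training_set SMILES of the training corpus.
#' @param reference_set SMILES of the reference (held-out test) corpus.
#' @param k Unique@k window (default 1000).
#' @return object of class `icvae_metrics`: list with `valid`,
#'   `unique_at_1k`, `novelty`, `snn`, `frag`, `intdiv`, `n_generated`,
#'   `n_valid`.
#' @export
moses_report <- function(generated, training_set, reference_set, k = 1000L) {
  if (!length(generated) || !length(training_set) || !length(reference_set))
    stop("empty molecule list")
  val <- validity(generated)
  train_can <- validity(training_set)$canonical
  ref_can <- validity(reference_set)$canonical
  gen <- val$canonical
  rep <- list(
    valid = val$fraction,
    unique_at_1k = if (length(gen)) uniqueness_at_k(gen, k) else NA_real_,
    novelty = if (length(gen)) novelty(gen, train_can) else NA_real_,
    snn = if (length(gen)) snn(gen, ref_can) else NA_real_,
    frag = if (length(gen)) fragment_similarity(gen, ref_can) else NA_real_,
    intdiv = if (length(gen) >= 2L) internal_diversity(gen) else NA_real_,
    n_generated = length(generated),
    n_valid = length(gen))
  class(rep) <- "icvae_metrics"
  rep
}

#' @export
print.icvae_metrics <- function(x, ...) {
  cat("Generation metrics (", x$n_valid, "/", x$n_generated,
      " valid)\n", sep = "")
  cat(sprintf(
    "  Valid %.3f  Unique@1k %.3f  Novelty %.3f  SNN %.3f  Frag %.3f  IntDiv %.3f\n",
    x$valid, x$unique_at_1k, x$novelty, x$snn, x$frag, x$intdiv))
  invisible(x)
}
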