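# Shared fixtures, built once per test run and memoized. Everything is
# generated in code (no stored data): the synthetic corpus is the package's
# own fixture generator, and the models are scaled-down training runs.

.fixture_env <- new.env(parent = emptyenv())

memoize <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, builder(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# The full 2,000-molecule synthetic corpus of the scaled-down study.
fixture_corpus <- function() {
  memoize("corpus", function() generate_corpus(2000, seed = 42))
}

# A small sub-corpus for fast unit tests.
small_corpus <- function(n = 300L) {
  corp <- fixture_corpus()
  structure(list(smiles = corp$smiles[seq_len(n)],
                 properties = corp$properties[seq_len(n), , drop = FALSE]),
            class = "icvae_corpus")
}

# A quickly trained model: small corpus, short SMILES budget, few epochs.
# Good enough to exercise every code path; not the study-condition run.
mini_fit <- function() {
  memoize("mini_fit", function() {
    corp <- small_corpus()
    keep <- vapply(corp$smiles,
                   function(s) length(smiles_tokenize(s)) <= 30L,
                   logical(1L))
    corp <- structure(list(smiles = corp$smiles[keep],
                           properties = corp$properties[keep, , drop = FALSE]),
                      class = "icvae_corpus")
    icvae(corp, properties = "HBA", K = 4L, epochs = 5L, batch_size = 64L,
          max_len = 48L, seed = 7L)
  })
}

# The scaled-down study-condition model: full corpus, K = 8, conditioned on
# HBA, 30 epochs, seed 42. Used by the acceptance-level checks.
study_fit <- function() {
  memoize("study_fit", function()
    icvae(fixture_corpus(), properties = "HBA", K = 8L, epochs = 30L,
          seed = 42L))
}

# Independent brute-force Tanimoto between two 0/1 fingerprint rows.
oracle_tanimoto <- function(a, b) {
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) 0 else inter / uni
}

# Fingerprint matrix fetched straight from the RDKit backend.
oracle_fp <- function(canonical) {
  res <- icvae:::chem_call(canonical, "fp")
  icvae:::chem_fp_matrix(res$bits)
}
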