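test_that("tokenizer splits atomic symbols, halogens and bracket atoms", {
  expect_identical(smiles_tokenize("CCO"), c("C", "C", "O"))
  expect_identical(smiles_tokenize("CCl"), c("C", "Cl"))
  expect_identical(smiles_tokenize("BrCBr"), c("Br", "C", "Br"))

  # brute-force oracle: the same split computed by a plain regex walk
  oracle_tokenize <- function(s) {
    out <- character(); i <- 1L
    while (i <= nchar(s)) {
      rest <- substring(s, i)
      tok <- if (startsWith(rest, "[")) {
        sub("^(\\[[^]]*\\]).*$", "\\1", rest)
      } else if (startsWith(rest, "Cl") || startsWith(rest, "Br")) {
        substring(rest, 1L, 2L)
      } else substring(rest, 1L, 1L)
      out <- c(out, tok); i <- i + nchar(tok)
    }
    out
  }
  for (s in c("c1ccccc1C(=O)[O-]", "C[N+](C)(C)C", "Clc1ccc(Br)cc1",
              "CC(=O)O[C@@H]1CC[NH3+]1")) {
    toks <- smiles_tokenize(s)
    expect_identical(toks, oracle_tokenize(s))
    expect_identical(paste(toks, collapse = ""), s)
  }
  expect_true("[O-]" %in% smiles_tokenize("c1ccccc1C(=O)[O-]"))
})

test_that("tokenizer is concatenation-faithful on the fixture corpus", {
  smiles <- fixture_corpus()$smiles
  recomposed <- vapply(smiles,
                       function(s) paste(smiles_tokenize(s), collapse = ""),
                       character(1L), USE.NAMES = FALSE)
  expect_identical(recomposed, smiles)
})

test_that("malformed and unknown-token inputs raise informative errors", {
  expect_error(smiles_tokenize("C[NH2"), "unbalanced")
  expect_error(smiles_tokenize(""), "empty")
  v <- build_vocabulary(c("CCO", "CCN"))
  expect_error(encode_one_hot("CCS", v), "unknown token.*'S'")
})

test_that("vocabulary build is deterministic and order-independent", {
  v <- build_vocabulary(c("CCO", "CCN"))
  expect_s3_class(v, "icvae_vocab")
  expect_identical(length(v), 5L)
  expect_setequal(v$tokens, c("C", "O", "N", v$pad_token, v$terminal_token))
  expect_error(build_vocabulary(character()), "empty")

  smiles <- fixture_corpus()$smiles
  v1 <- build_vocabulary(smiles)
  v2 <- build_vocabulary(rev(smiles))
  v3 <- build_vocabulary(sample(smiles))
  expect_identical(v1, v2)
  expect_identical(v1, v3)
})

test_that("vocabulary JSON serialization round-trips", {
  v <- build_vocabulary(fixture_corpus()$smiles[1:50])
  path <- withr::local_tempfile(fileext = ".json")
  write_vocabulary(v, path)
  expect_identical(read_vocabulary(path), v)
})

test_that("one-hot encoding follows the terminal/pad layout contract", {
  v <- build_vocabulary(c("CCO", "CCN"))
  e <- encode_one_hot("CCO", v, max_len = 120L)
  m <- e$matrix
  expect_identical(dim(m), c(5L, 120L))
  expect_true(all(colSums(m) == 1))            # column stochasticity, exact
  expect_identical(e$length, 5L)
  term_row <- match(v$terminal_token, v$tokens)
  pad_row <- match(v$pad_token, v$tokens)
  expect_equal(unname(which(m[, 1] == 1)), term_row)  # E at the front
  expect_equal(unname(which(m[, 5] == 1)), term_row)  # E at the back
  expect_identical(unname(m["C", 2:3]), c(1, 1))
  expect_identical(unname(m["O", 4]), 1)
  expect_true(all(m[pad_row, 6:120] == 1))     # pad tail

  long <- paste(rep("C", 119), collapse = "")
  expect_error(encode_one_hot(long, v), "119 tokens")
  ok <- paste(rep("C", 118), collapse = "")
  expect_identical(encode_one_hot(ok, v)$length, 120L)
})

test_that("encode -> greedy decode is the identity on fixture molecules", {
  corp <- fixture_corpus()
  v <- build_vocabulary(corp$smiles)
  for (s in corp$smiles[seq(1, 2000, by = 40)]) {
    e <- encode_one_hot(s, v)
    expect_identical(decode_one_hot(e$matrix, v, "greedy"), s)
  }
})

test_that("decoding handles ties, sampling seeds and bad scores", {
  v <- build_vocabulary(c("CCO", "CCN"))
  # uniform scores: greedy picks the lowest index everywhere; position 1 is
  # skipped and reading stops when pads/terminals are filtered out
  u <- matrix(1, 5, 10)
  expect_identical(decode_one_hot(u, v, "greedy"), "")
  # force column-wise argmax ties between two token rows
  m <- matrix(0, 5, 6)
  ci <- match("C", v$tokens); oi <- match("O", v$tokens)
  ti <- match(v$terminal_token, v$tokens)
  m[ti, 1] <- 1
  m[c(ci, oi), 2] <- 1                       # tie: lower row index wins
  m[ci, 3] <- 1
  m[ti, 4:6] <- 1
  expect_identical(decode_one_hot(m, v, "greedy"),
                   paste0(v$tokens[min(ci, oi)], "C"))

  e <- encode_one_hot("CCO", v)
  soft <- e$matrix * 0.9 + 0.02
  s1 <- decode_one_hot(soft, v, "sample", temperature = 2, rng_seed = 11)
  s2 <- decode_one_hot(soft, v, "sample", temperature = 2, rng_seed = 11)
  expect_identical(s1, s2)                   # seeded determinism

  bad <- e$matrix; bad[1, 1] <- NaN
  expect_error(decode_one_hot(bad, v), "non-finite")
  expect_error(decode_one_hot(e$matrix, v, temperature = 0), "temperature")
})
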