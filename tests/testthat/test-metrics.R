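# Small molecule sets with hand-checkable metric values.
gen3 <- c("CCO", "CCN", "c1ccccc1O")
ref3 <- c("CCO", "CCCC", "c1ccccc1N")

test_that("validity applies the sanitization contract and canonicalizes", {
  v <- validity(c("CCO", "C(C)(C)(C)(C)C"))     # pentavalent carbon invalid
  expect_equal(v$fraction, 0.5)
  expect_identical(v$canonical, "CCO")
  expect_equal(validity(c("not_a_smiles"))$fraction, 0)
  all_ok <- validity(gen3)
  expect_equal(all_ok$fraction, 1)
  # canonicalization collapses alternative atom orderings
  expect_equal(validity(c("OCC", "CCO"))$canonical[1],
               validity(c("OCC", "CCO"))$canonical[2])
  expect_error(validity(character()), "empty")
})

test_that("uniqueness counts distinct canonicals within the first k", {
  expect_equal(uniqueness_at_k(c("CCO", "CCO", "CCN"), k = 3), 2 / 3)
  expect_equal(uniqueness_at_k(rep("CCO", 5)), 1 / 5)
  expect_equal(uniqueness_at_k(c("A", "B", "C")), 1)
  expect_equal(uniqueness_at_k(letters[1:10], k = 4), 1)
})

test_that("novelty is the fraction absent from the training set", {
  expect_equal(novelty(c("CCO", "CCN"), c("CCO")), 0.5)
  expect_equal(novelty(c("CCO", "CCN"), c("CCO", "CCN", "CCC")), 0)
  expect_equal(novelty(c("CCF", "CCI"), c("CCO")), 1)
})

test_that("SNN equals a brute-force nearest-neighbor oracle", {
  expect_equal(snn(gen3, gen3), 1)             # self nearest neighbor
  # single vs single is the plain pairwise Tanimoto
  fp <- oracle_fp(c("CCO", "CCCC"))
  expect_equal(snn("CCO", "CCCC"), oracle_tanimoto(fp[1, ], fp[2, ]))
  # 3 x 3: exhaustive double loop over the fingerprints
  fg <- oracle_fp(gen3); fr <- oracle_fp(ref3)
  want <- mean(vapply(1:3, function(i)
    max(vapply(1:3, function(j) oracle_tanimoto(fg[i, ], fr[j, ]),
               numeric(1L))), numeric(1L)))
  expect_equal(snn(gen3, ref3), want)
  expect_lte(snn(gen3, ref3), 1)
})

test_that("fragment similarity equals a hand-enumerated cosine", {
  expect_equal(fragment_similarity(gen3, gen3), 1)
  # molecules without cleavable bonds contribute themselves as their only
  # fragment, so distinct alkanes share nothing
  expect_equal(fragment_similarity("CC", "CCC"), 0)

  oracle_frag_cosine <- function(a, b) {
    fa <- unlist(strsplit(icvae:::chem_call(a, "brics")$fragments, ";"))
    fb <- unlist(strsplit(icvae:::chem_call(b, "brics")$fragments, ";"))
    if (!length(fa) && !length(fb)) return(1)
    vocab <- union(fa, fb)
    ca <- as.numeric(table(factor(fa, levels = vocab)))
    cb <- as.numeric(table(factor(fb, levels = vocab)))
    d <- sqrt(sum(ca^2)) * sqrt(sum(cb^2))
    if (d == 0) 0 else sum(ca * cb) / d
  }
  a <- c("c1ccccc1C(=O)NCC", "CCOC(=O)c1ccccc1")
  b <- c("c1ccccc1C(=O)NC", "CCCNC(=O)CC")
  expect_equal(fragment_similarity(a, b), oracle_frag_cosine(a, b))
  # sets sharing no fragment at all
  expect_equal(fragment_similarity("c1ccccc1C(=O)NCC", "CCCCOCCCC"), 0)
})

test_that("internal diversity matches an all-pairs oracle", {
  expect_equal(internal_diversity(rep("CCO", 3)), 0)
  fp <- oracle_fp(c("CCO", "CCCC"))
  expect_equal(internal_diversity(c("CCO", "CCCC")),
               1 - oracle_tanimoto(fp[1, ], fp[2, ]))
  four <- c("CCO", "CCCC", "c1ccccc1O", "CCN")
  fps <- oracle_fp(four)
  sims <- c()
  for (i in 1:3) for (j in (i + 1):4)
    sims <- c(sims, oracle_tanimoto(fps[i, ], fps[j, ]))
  expect_equal(internal_diversity(four), 1 - mean(sims))
  expect_error(internal_diversity("CCO"), "at least 2")
})

test_that("metrics are permutation-invariant and duplicate-monotone", {
  perm <- c(2, 3, 1)
  expect_equal(snn(gen3[perm], ref3[perm]), snn(gen3, ref3))
  expect_equal(fragment_similarity(gen3[perm], ref3),
               fragment_similarity(gen3, ref3))
  expect_equal(internal_diversity(gen3[perm]), internal_diversity(gen3))
  expect_equal(novelty(gen3[perm], ref3), novelty(gen3, ref3))
  # adding an exact duplicate never increases internal diversity
  expect_lte(internal_diversity(c(gen3, gen3[1])), internal_diversity(gen3))
})

test_that("the composed report equals its standalone components", {
  gen_raw <- c(gen3, "C(C)(C)(C)(C)C")
  rep <- moses_report(gen_raw, training_set = c("CCO", "CCCC"),
                      reference_set = ref3, k = 2L)
  val <- validity(gen_raw)
  expect_equal(rep$valid, val$fraction)
  expect_equal(rep$unique_at_1k, uniqueness_at_k(val$canonical, 2L))
  expect_equal(rep$novelty,
               novelty(val$canonical, validity(c("CCO", "CCCC"))$canonical))
  expect_equal(rep$snn, snn(val$canonical, validity(ref3)$canonical))
  expect_equal(rep$frag,
               fragment_similarity(val$canonical, validity(ref3)$canonical))
  expect_equal(rep$intdiv, internal_diversity(val$canonical))
  expect_identical(rep$n_generated, 4L)
  expect_identical(rep$n_valid, 3L)

  # identity composition: generated == training == reference
  same <- moses_report(gen3, gen3, gen3)
  expect_equal(same$valid, 1)
  expect_equal(same$snn, 1)
  expect_equal(same$frag, 1)
  expect_equal(same$novelty, 0)
})
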