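## Synthetic SMILES corpus generator. A fragment grammar (alkyl chains,
## carbo-/heterocycles, ether/amine/hydroxyl/carbonyl/carboxyl/amide/nitrile
## substituents) is composed by seeded sampling into chain SMILES that are
## valid by construction, then the realized descriptor spread is enforced by
## stratified selection: every HBA level 0..6 and HBD level 0..4 is
## represented and MW spans at least [60, 350], emulating a drug-like ZINC
## subset at small scale.

fixture_grammar <- function() {
  list(
    plain_int  = c("C", "CC", "CCC", "C(C)", "CC(C)", "c1ccccc1",
                   "C1CCCC1", "C1CCCCC1"),
    hetero_int = c("O", "N", "C(=O)", "N(C)", "OCC", "C(=O)N", "OC(=O)",
                   "C1CCOCC1", "C1CCNCC1", "c1ccncc1"),
    plain_term = c("C", "CC", "C(C)C", "F", "Cl", "Br"),
    hetero_term = c("O", "N", "OC", "C(=O)O", "C(=O)N", "C#N", "N(C)C",
                    "S(=O)(=O)N")
  )
}

## Renumber ring-closure digits across stacked ring templates. Every ring
## template opens and closes inside its own unit, so digits may be reused
## once closed; cycling through 1..9 keeps adjacent rings distinct.
assign_ring_digits <- function(units) {
  digit <- 0L
  vapply(units, function(u) {
    if (grepl("1", u, fixed = TRUE)) {
      digit <<- digit %% 9L + 1L
      gsub("1", as.character(digit), u, fixed = TRUE)
    } else u
  }, character(1L), USE.NAMES = FALSE)
}

fixture_candidate <- function(h, s, grammar) {
  n_het <- min(h, s)
  ints <- c(if (n_het > 0L)
              sample(grammar$hetero_int, n_het, replace = TRUE),
            if (s - n_het > 0L)
              sample(grammar$plain_int, s - n_het, replace = TRUE))
  ints <- sample(ints)
  term <- if (h > s && stats::runif(1) < 0.8)
    sample(grammar$hetero_term, 1L) else sample(grammar$plain_term, 1L)
  paste(assign_ring_digits(c(ints, term)), collapse = "")
}

#' Generate a synthetic drug-like SMILES corpus
#'
#' Deterministically (under `seed`) composes valid SMILES from a fragment
#' grammar and selects `n` of them so that hydrogen-bond acceptor counts 0-6
#' each fill at least `ceiling(n / 50)` slots, donor counts 0-4 are all
#' represented, and molecular weight spans at least \[60, 350\]. All
#' molecules sanitize under RDKit and have at most `max_tokens` tokens.
#'
#' @param n corpus size (>= 100).
#' @param seed integer seed; identical seeds give byte-identical corpora.
#' @param max_tokens per-molecule token budget (default 40).
#' @return an object of class `icvae_corpus`: a list with `smiles`
#'   (character) and `properties` (data.frame with columns smiles, MW, logP,
#'   HBA, HBD, TPSA, QED, SAS).
#' @examples \dontrun{corp <- generate_corpus(200, seed = 1)}
#' @export
generate_corpus <- function(n, seed = 42L, max_tokens = 40L) {
  if (n < 100L) stop("corpus size must be at least 100")
  grammar <- fixture_grammar()
  cand <- with_seed(seed, {
    m <- 3L * n
    h <- sample(0L:7L, m, replace = TRUE)        # intended heteroatom load
    s <- pmax(1L, stats::rpois(m, lambda = 1.2 + h / 2) +
                    sample(0L:2L, m, replace = TRUE))
    big <- sample.int(m, ceiling(m / 10))        # push MW past 350
    s[big] <- s[big] + 6L
    vapply(seq_len(m), function(i)
      fixture_candidate(h[i], s[i], grammar), character(1L))
  })
  cand <- unique(cand)
  cand <- cand[vapply(cand, function(x) length(smiles_tokenize(x)),
                      integer(1L)) <= max_tokens]
  props <- chem_call(cand, "props")
  props <- props[props$valid, , drop = FALSE]

  quota <- ceiling(n / 50)
  take <- logical(nrow(props))
  for (lev in 0:6) {                             # HBA strata
    idx <- which(props$HBA == lev)
    if (length(idx) < quota)
      stop("unsatisfiable property spread: HBA level ", lev, " has only ",
           length(idx), " candidates (need ", quota, ")")
    take[idx[seq_len(quota)]] <- TRUE
  }
  for (lev in 0:4) {                             # HBD representation
    idx <- which(props$HBD == lev)
    if (!length(idx))
      stop("unsatisfiable property spread: no candidate with HBD ", lev)
    take[idx[1L]] <- TRUE
  }
  take[which.min(props$MW)] <- TRUE
  take[which.max(props$MW)] <- TRUE
  if (min(props$MW) > 60 || max(props$MW) < 350)
    stop("unsatisfiable property spread: MW range [",
         round(min(props$MW)), ", ", round(max(props$MW)),
         "] does not cover [60, 350]")
  pool <- which(!take)
  need <- n - sum(take)
  if (need > length(pool))
    stop("not enough distinct candidates: need ", n, ", have ",
         sum(take) + length(pool))
  take[pool[seq_len(need)]] <- TRUE
  sel <- props[take, , drop = FALSE][seq_len(n), , drop = FALSE]
  tab <- data.frame(smiles = sel$smiles, MW = sel$MW, logP = sel$logP,
                    HBA = sel$HBA, HBD = sel$HBD, TPSA = sel$TPSA,
                    QED = sel$QED, SAS = sel$SAS,
                    stringsAsFactors = FALSE)
  structure(list(smiles = tab$smiles, properties = tab),
            class = "icvae_corpus")
}

#' @export
print.icvae_corpus <- function(x, ...) {
  cat("Synthetic SMILES corpus:", length(x$smiles), "molecules\n")
  cat(sprintf("  MW [%0.1f, %0.1f], HBA %d-%d, HBD %d-%d\n",
              min(x$properties$MW), max(x$properties$MW),
              min(x$properties$HBA), max(x$properties$HBA),
              min(x$properties$HBD), max(x$properties$HBD)))
  invisible(x)
}

#' Read and write corpus files
#'
#' A corpus on disk is a directory holding `corpus.smi` (one SMILES per
#' line; `#` lines are comments) and `properties.csv` (columns smiles, MW,
#' logP, HBA, HBD, TPSA, QED, SAS). `read_corpus(write_corpus(x, d))`
#' restores `x` exactly.
#'
#' @param corpus an `icvae_corpus`.
#' @param dir directory path (created if absent).
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "icvae_corpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(corpus$smiles, file.path(dir, "corpus.smi"))
  utils::write.csv(corpus$properties, file.path(dir, "properties.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(dir) {
  smi_path <- file.path(dir, "corpus.smi")
  csv_path <- file.path(dir, "properties.csv")
  smiles <- read_smiles(smi_path)
  props <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  expected <- c("smiles", "MW", "logP", "HBA", "HBD", "TPSA", "QED", "SAS")
  if (!identical(names(props), expected))
    stop("properties.csv must have columns ", paste(expected, collapse = ","))
  structure(list(smiles = smiles, properties = props),
            class = "icvae_corpus")
}

#' Read a plain-text SMILES file
#'
#' One molecule per line; blank lines and lines starting with `#` are
#' skipped. Malformed (non-ASCII) lines raise a line-numbered error.
#'
#' @param path file path.
#' @return character vector of SMILES.
#' @export
read_smiles <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  bad <- which(keep & grepl("[^\x20-\x7e]", lines))
  if (length(bad))
    stop("malformed SMILES line ", bad[1L], " in ", path)
  trimws(lines[keep])
}
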