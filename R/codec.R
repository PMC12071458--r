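## SMILES codec: tokenization, fixed-size one-hot encoding, and decoding.
##
## Strings are framed as [terminal, tokens..., terminal, pad...] in a
## vocab_size x max_len one-hot matrix; the same terminal token 'E' marks
## both ends and a dedicated pad token fills the tail.

ICVAE_PAD <- "_"
ICVAE_TERMINAL <- "E"
ICVAE_MAX_LEN <- 120L

#' Tokenize a SMILES string
#'
#' Splits a SMILES string into atomic-symbol tokens: every bracketed atom
#' expression `[...]` is one token, the two-character organic-subset halogens
#' `Cl` and `Br` are single tokens, and every other character is its own
#' token. Concatenating the returned tokens reproduces the input exactly.
#'
#' @param smiles a single non-empty SMILES string.
#' @return character vector of tokens.
#' @examples
#' smiles_tokenize("CCO")
#' smiles_tokenize("c1ccccc1C(=O)[O-]")
#' @export
smiles_tokenize <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (!nzchar(smiles)) stop("malformed SMILES: empty string")
  n_open <- lengths(regmatches(smiles, gregexpr("\\[", smiles)))
  n_close <- lengths(regmatches(smiles, gregexpr("\\]", smiles)))
  toks <- regmatches(smiles, gregexpr("\\[[^][]*\\]|Cl|Br|.", smiles))[[1L]]
  if (n_open != n_close || any(toks %in% c("[", "]")))
    stop("malformed SMILES: unbalanced brackets in '", smiles, "'")
  toks
}

#' Build a token vocabulary from a SMILES corpus
#'
#' Collects every token observed in the corpus, sorts them (so repeated
#' builds on permuted corpora are identical), and prepends the pad and
#' terminal special tokens.
#'
#' @param corpus character vector of SMILES strings.
#' @param extra_tokens optional tokens to include beyond those observed.
#' @return an object of class `icvae_vocab`.
#' @export
build_vocabulary <- function(corpus, extra_tokens = character()) {
  if (length(corpus) == 0L) stop("empty corpus: cannot build a vocabulary")
  observed <- unique(unlist(lapply(corpus, smiles_tokenize)))
  observed <- sort(unique(c(observed, extra_tokens)), method = "radix")
  if (any(observed %in% c(ICVAE_PAD, ICVAE_TERMINAL)))
    stop("corpus tokens collide with the reserved pad/terminal tokens")
  vocab <- list(tokens = c(ICVAE_PAD, ICVAE_TERMINAL, observed),
                pad_token = ICVAE_PAD, terminal_token = ICVAE_TERMINAL)
  class(vocab) <- "icvae_vocab"
  vocab
}

#' @export
print.icvae_vocab <- function(x, ...) {
  cat("SMILES token vocabulary:", length(x$tokens), "tokens",
      sprintf("(pad '%s', terminal '%s')\n", x$pad_token, x$terminal_token))
  cat(" ", paste(x$tokens, collapse = " "), "\n")
  invisible(x)
}

#' @export
length.icvae_vocab <- function(x) length(x$tokens)

vocab_index <- function(vocab, tokens) {
  idx <- match(tokens, vocab$tokens)
  if (anyNA(idx)) {
    bad <- unique(tokens[is.na(idx)])
    stop("unknown token(s) not in vocabulary: ",
         paste0("'", bad, "'", collapse = ", "))
  }
  idx
}

#' Serialize / restore a vocabulary as JSON
#'
#' @param vocab an `icvae_vocab`.
#' @param path file path.
#' @export
write_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "icvae_vocab"))
  jsonlite::write_json(list(tokens = vocab$tokens, pad_token = vocab$pad_token,
                            terminal_token = vocab$terminal_token),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  vocab <- list(tokens = as.character(x$tokens), pad_token = x$pad_token,
                terminal_token = x$terminal_token)
  class(vocab) <- "icvae_vocab"
  vocab
}

#' One-hot encode a SMILES string
#'
#' Frames the token sequence with the terminal token at both ends, pads to
#' `max_len`, and returns the vocab_size x max_len one-hot matrix. Every
#' column sums to exactly 1.
#'
#' @param smiles a SMILES string of at most `max_len - 2` tokens.
#' @param vocab an `icvae_vocab` containing every token of `smiles`.
#' @param max_len total encoded length including the two terminals
#'   (default 120).
#' @return an object of class `icvae_encoded` with fields `matrix`, `length`
#'   (real positions incl. terminals) and `source`.
#' @export
encode_one_hot <- function(smiles, vocab, max_len = ICVAE_MAX_LEN) {
  stopifnot(inherits(vocab, "icvae_vocab"))
  toks <- smiles_tokenize(smiles)
  if (length(toks) > max_len - 2L)
    stop("SMILES too long: ", length(toks), " tokens exceed the ",
         max_len - 2L, "-token limit")
  seq_tokens <- c(vocab$terminal_token, toks, vocab$terminal_token)
  rows <- c(vocab_index(vocab, seq_tokens),
            rep(vocab_index(vocab, vocab$pad_token),
                max_len - length(seq_tokens)))
  m <- matrix(0, nrow = length(vocab$tokens), ncol = max_len,
              dimnames = list(vocab$tokens, NULL))
  m[cbind(rows, seq_len(max_len))] <- 1
  structure(list(matrix = m, length = length(seq_tokens), source = smiles),
            class = "icvae_encoded")
}

#' Decode per-position scores back into a SMILES string
#'
#' Greedy mode takes the arg-max token at each position (ties resolved to the
#' lowest vocabulary index); sample mode draws each position from the
#' temperature-scaled renormalized scores. Reading stops at the first
#' terminal token after the leading one; pad tokens never appear in output.
#'
#' @param columns numeric matrix, vocab_size rows x max_len columns, of
#'   non-negative per-position scores (columns need not be normalized).
#' @param vocab the `icvae_vocab` the scores are indexed by.
#' @param mode `"greedy"` or `"sample"`.
#' @param temperature positive sampling temperature (sample mode).
#' @param rng_seed integer seed used in sample mode for reproducibility.
#' @return a SMILES string (possibly empty).
#' @export
decode_one_hot <- function(columns, vocab, mode = c("greedy", "sample"),
                           temperature = 1, rng_seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(vocab, "icvae_vocab"),
            is.matrix(columns), nrow(columns) == length(vocab$tokens))
  if (!all(is.finite(columns))) stop("non-finite scores in decode input")
  if (temperature <= 0) stop("temperature must be positive")
  pick <- if (mode == "greedy") {
    apply(columns, 2L, which.max)
  } else {
    draw_one <- function(p) {
      lp <- log(pmax(p, 1e-300)) / temperature
      w <- exp(lp - max(lp))
      sample.int(length(p), 1L, prob = w / sum(w))
    }
    with_seed(rng_seed, apply(columns, 2L, draw_one))
  }
  term <- vocab_index(vocab, vocab$terminal_token)
  pad <- vocab_index(vocab, vocab$pad_token)
  body <- pick[-1L]                       # position 1 is the leading terminal
  stop_at <- which(body == term)
  if (length(stop_at)) body <- body[seq_len(stop_at[1L] - 1L)]
  body <- body[body != pad & body != term]
  paste(vocab$tokens[body], collapse = "")
}

## Run expr under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}
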