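#' @keywords internal
#' Locate the Python interpreter carrying RDKit.
chem_python <- function() {
  py <- Sys.getenv("ICVAE_PYTHON", unset = "")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) stop("no python interpreter found; RDKit backend unavailable")
  py
}

chem_script <- function() {
  p <- system.file("python", "icvae_chem.py", package = "icvae")
  if (!nzchar(p)) {
    # during devtools::load_all() the inst/ prefix is still present
    p <- file.path("inst", "python", "icvae_chem.py")
  }
  if (!file.exists(p)) stop("cannot locate icvae_chem.py backend script")
  normalizePath(p)
}

#' Run one batched RDKit call.
#'
#' All chemistry in the package (descriptor calculation, validity checking,
#' canonicalization, Morgan fingerprints, BRICS fragmentation) funnels through
#' this single subprocess entry point so that a corpus costs one interpreter
#' start-up, not one per molecule.
#'
#' @param smiles character vector of SMILES strings.
#' @param cmd one of "props", "canon", "fp", "brics".
#' @return data.frame with columns `smiles`, `valid` (logical) and the
#'   command-specific payload columns.
#' @keywords internal
chem_call <- function(smiles, cmd = c("props", "canon", "fp", "brics")) {
  cmd <- match.arg(cmd)
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  inf <- tempfile("icvae_smi_"); onf <- tempfile("icvae_out_")
  on.exit(unlink(c(inf, onf)), add = TRUE)
  writeLines(smiles, inf)
  status <- system2(chem_python(), c(shQuote(chem_script()), cmd,
                                     shQuote(inf), shQuote(onf)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L || !file.exists(onf))
    stop("RDKit backend call failed (command '", cmd, "', status ", status, ")")
  cols <- switch(cmd,
    props = c("smiles", "valid", "canonical", "MW", "logP", "HBA", "HBD",
              "TPSA", "QED", "SAS"),
    canon = c("smiles", "valid", "canonical"),
    fp    = c("smiles", "valid", "bits"),
    brics = c("smiles", "valid", "fragments"))
  out <- utils::read.table(onf, sep = "\t", quote = "", comment.char = "",
                           col.names = cols, colClasses = "character",
                           fill = TRUE, na.strings = NULL)
  if (nrow(out) != length(smiles))
    stop("RDKit backend returned ", nrow(out), " rows for ",
         length(smiles), " molecules")
  out$valid <- out$valid == "1"
  if (cmd == "props") {
    for (p in c("MW", "logP", "HBA", "HBD", "TPSA", "QED", "SAS"))
      out[[p]] <- suppressWarnings(as.numeric(out[[p]]))
  }
  out
}

#' Parse a Morgan fingerprint bitstring column into a logical matrix.
#' @keywords internal
chem_fp_matrix <- function(bits) {
  stopifnot(all(nchar(bits) == 1024L))
  m <- vapply(strsplit(bits, "", fixed = TRUE),
              function(x) x == "1", logical(1024L))
  t(m)  # one row per molecule, 1024 columns
}
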