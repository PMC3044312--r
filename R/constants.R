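#' @keywords internal
"_PACKAGE"

## Amino-acid alphabet in PSI-BLAST PSSM column order; used for profile
## matrices, contact matrices and Cbeta-level potential types throughout.
AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA_3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V")

AA_1TO3 <- stats::setNames(names(AA_3TO1), unname(AA_3TO1))

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "CB")

.pkg_cache <- new.env(parent = emptyenv())

#' BLOSUM62 submatrix over the 20 standard amino acids
#'
#' Returns the 20x20 BLOSUM62 substitution matrix in PSSM column order,
#' used as the fallback profile when no PSSM is supplied.
#'
#' @return integer matrix with dimnames `AA_ORDER` x `AA_ORDER`.
#' @keywords internal
blosum62_matrix <- function() {
  if (is.null(.pkg_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$blosum62 <- e$BLOSUM62[AA_ORDER, AA_ORDER]
  }
  .pkg_cache$blosum62
}

## split a string into single characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
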