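#' Query profile objects
#'
#' Holds the query sequence, an n x 20 position-specific profile (log-odds,
#' columns in PSI-BLAST order `ARNDCQEGHILKMFPSTWYV`), and optional predicted
#' structural annotation strings. When predictions are not available they
#' default to all-coil / all-exposed / all-undefined, which contribute
#' nothing to the corresponding local score components.
#'
#' @param sequence 1-letter amino-acid string (uppercased; unknown letters
#'   become X).
#' @param profile n x 20 numeric matrix, or NULL for the BLOSUM62 fallback
#'   (row for residue a = the BLOSUM62 column of a; zero row for X).
#' @param predicted_ss,predicted_burial,predicted_cle optional strings of
#'   length n over H/E/C, B/E, and the 16-letter structural alphabet.
#' @return object of class `query_profile` with fields `sequence`, `n`,
#'   `aa`, `profile`, `predicted_ss`, `predicted_burial`, `predicted_cle`.
#' @export
query_profile <- function(sequence, profile = NULL, predicted_ss = NULL,
                          predicted_burial = NULL, predicted_cle = NULL) {
  sequence <- toupper(sequence)
  aa <- chars(sequence)
  aa[!aa %in% AA_ORDER] <- "X"
  sequence <- paste(aa, collapse = "")
  n <- length(aa)
  if (n == 0L) stopf("zero-length query sequence")
  if (is.null(profile)) {
    b62 <- blosum62_matrix()
    profile <- matrix(0, n, 20, dimnames = list(NULL, AA_ORDER))
    known <- aa %in% AA_ORDER
    profile[known, ] <- t(b62[, aa[known], drop = FALSE])
  }
  profile <- as.matrix(profile)
  if (nrow(profile) != n || ncol(profile) != 20)
    stopf("profile must be %d x 20 (got %d x %d)", n, nrow(profile), ncol(profile))
  colnames(profile) <- AA_ORDER
  check_ann <- function(x, default, name) {
    if (is.null(x)) return(strrep(default, n))
    if (nchar(x) != n) stopf("%s length != query length", name)
    x
  }
  structure(
    list(sequence = sequence, n = n, aa = aa, profile = profile,
         predicted_ss = check_ann(predicted_ss, "C", "predicted_ss"),
         predicted_burial = check_ann(predicted_burial, "E", "predicted_burial"),
         predicted_cle = check_ann(predicted_cle, "-", "predicted_cle")),
    class = "query_profile")
}

#' @export
print.query_profile <- function(x, ...) {
  cat(sprintf("query_profile: %d residues\n seq: %s%s\n", x$n,
              substr(x$sequence, 1, 60), if (x$n > 60) "..." else ""))
  invisible(x)
}

#' Read a query sequence from FASTA
#'
#' Uses the first record; a warning is raised if the file holds more.
#' Unknown letters (including gap characters) map to X. The returned profile
#' is the BLOSUM62 fallback; replace it with [read_pssm()] output when a
#' PSSM is available.
#'
#' @param path FASTA file path.
#' @return a [query_profile()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stopf("FASTA parse error in %s: %s",
                                            path, conditionMessage(e)))
  if (length(set) == 0L) stopf("no FASTA records in %s", path)
  if (length(set) > 1L)
    warnf("%s has %d records; using the first", path, length(set))
  seq <- as.character(set[[1]])
  if (nchar(seq) == 0L) stopf("zero-length sequence in %s", path)
  query_profile(seq)
}

#' Read a PSI-BLAST ASCII PSSM
#'
#' Parses the classic `psiblast -out_ascii_pssm` dialect: header lines, then
#' one row per residue starting with the position index and residue letter
#' followed by 20 integer log-odds (any trailing columns are ignored).
#'
#' @param path PSSM file path.
#' @param sequence optional query sequence to cross-check row letters and
#'   row count against.
#' @return n x 20 numeric matrix in `ARNDCQEGHILKMFPSTWYV` column order.
#' @export
read_pssm <- function(path, sequence = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path)
  row_re <- "^\\s*([0-9]+)\\s+([A-Za-z])((\\s+-?[0-9]+){20})"
  hits <- regmatches(lines, regexec(row_re, lines))
  keep <- which(lengths(hits) > 0)
  if (length(keep) == 0L) stopf("no PSSM rows found in %s", path)
  idx <- integer(0); letters_seen <- character(0)
  scores <- matrix(NA_real_, length(keep), 20, dimnames = list(NULL, AA_ORDER))
  for (r in seq_along(keep)) {
    h <- hits[[keep[r]]]
    vals <- suppressWarnings(as.numeric(strsplit(trimws(h[4]), "\\s+")[[1]]))
    if (length(vals) != 20 || anyNA(vals))
      stopf("malformed PSSM row at line %d of %s", keep[r], path)
    idx[r] <- as.integer(h[2])
    letters_seen[r] <- toupper(h[3])
    scores[r, ] <- vals
  }
  if (any(idx != seq_along(idx)))
    stopf("PSSM rows are not consecutively numbered from 1 in %s", path)
  if (!is.null(sequence)) {
    aa <- chars(toupper(sequence))
    if (length(aa) != nrow(scores))
      stopf("PSSM has %d rows but sequence has %d residues",
            nrow(scores), length(aa))
    bad <- which(letters_seen != aa & aa != "X")
    if (length(bad))
      stopf("PSSM residue letters disagree with sequence at position(s) %s",
            paste(utils::head(bad, 5), collapse = ", "))
  }
  scores
}

#' Read prediction strings (one string per line)
#'
#' Plain-text predictions for the query: line 1 = secondary structure,
#' line 2 = burial, optional line 3 = structural-alphabet letters.
#'
#' @param path file path.
#' @return list with `ss`, `burial`, `cle` (NULL when absent).
#' @export
read_predictions <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) stopf("empty prediction file: %s", path)
  list(ss = lines[1],
       burial = if (length(lines) >= 2) lines[2] else NULL,
       cle = if (length(lines) >= 3) lines[3] else NULL)
}

#' Read a single-chain template from a PDB file
#'
#' First MODEL only; ATOM records with blank or 'A' altloc. Residues lacking
#' any of N, CA, C are dropped with a warning. Insertion codes are preserved
#' in the residue ordering.
#'
#' @param path PDB file path.
#' @param chain chain identifier (default first chain in file).
#' @return a `template` (annotations unfilled; run
#'   [derive_template_features()] to fill them).
#' @export
read_pdb_template <- function(path, chain = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = TRUE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain %in% chain, , drop = FALSE]
  if (nrow(at) == 0L) stopf("chain '%s' not found in %s", chain, path)
  at$insert[is.na(at$insert)] <- ""
  key <- paste(at$resno, at$insert, sep = "_")
  ukey <- unique(key)
  m <- length(ukey)
  xyz <- lapply(BACKBONE_ATOMS, function(a) matrix(NA_real_, m, 3))
  names(xyz) <- BACKBONE_ATOMS
  aa <- character(m)
  for (i in seq_len(m)) {
    rows <- at[key == ukey[i], , drop = FALSE]
    aa[i] <- AA_3TO1[rows$resid[1]]
    if (is.na(aa[i])) aa[i] <- "X"
    for (a in BACKBONE_ATOMS) {
      j <- which(rows$elety == a)
      if (length(j))
        xyz[[a]][i, ] <- c(rows$x[j[1]], rows$y[j[1]], rows$z[j[1]])
    }
  }
  ok <- !is.na(xyz$N[, 1]) & !is.na(xyz$CA[, 1]) & !is.na(xyz$C[, 1])
  if (any(!ok))
    warnf("dropping %d residue(s) missing backbone atoms in %s",
          sum(!ok), path)
  if (!any(ok)) stopf("no residues with complete backbone in chain '%s'", chain)
  xyz <- lapply(xyz, function(mat) mat[ok, , drop = FALSE])
  ## drop any stray CB recorded for glycine
  gly <- aa[ok] == "G"
  xyz$CB[gly, ] <- NA_real_
  tmpl <- new_template(chain_id = chain, resno = seq_len(sum(ok)),
                       aa = aa[ok], xyz = xyz)
  ## original PDB numbering (with insertion codes) kept for reporting
  tmpl$pdb_resno <- ukey[ok]
  tmpl
}
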