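#' Build the partial decoy of an alignment
#'
#' The partial decoy keeps exactly the matched residues of the alignment:
#' residue identities come from the query, coordinates (N, CA, C, O, Cbeta)
#' are copied verbatim from the paired template residues. This is what makes
#' the global energy depend on the alignment: moving a match changes which
#' query residue type sits at which template position. Special cases: a
#' glycine query residue carries no Cbeta even if the template residue has
#' one; a non-glycine query residue threaded onto a glycine template residue
#' gets an ideal Cbeta constructed from the backbone (1.521 Angstrom,
#' near-tetrahedral).
#'
#' @param a an `alignment_map`.
#' @param template a `template`.
#' @param query a `query_profile`.
#' @return object of class `partial_decoy` with fields `s` (query
#'   positions), `aa` (query residue types), `xyz` (list of k x 3 matrices)
#'   and `pairs` (the match-state data.frame used). An all-gap alignment
#'   yields an empty (k = 0) decoy.
#' @export
build_partial_decoy <- function(a, template, query) {
  ms <- match_states(a)
  k <- nrow(ms)
  xyz <- lapply(BACKBONE_ATOMS, function(at)
    template$xyz[[at]][ms$t, , drop = FALSE])
  names(xyz) <- BACKBONE_ATOMS
  aa <- query$aa[ms$s]
  if (k > 0) {
    need_cb <- aa != "G" & is.na(xyz$CB[, 1])
    for (i in which(need_cb))
      xyz$CB[i, ] <- place_cb(xyz$N[i, ], xyz$CA[i, ], xyz$C[i, ])
    xyz$CB[aa == "G", ] <- NA_real_
  }
  structure(list(s = ms$s, aa = aa, xyz = xyz, pairs = ms, k = k),
            class = "partial_decoy")
}

#' @export
print.partial_decoy <- function(x, ...) {
  cat(sprintf("partial_decoy: %d residues (query positions %s%s)\n", x$k,
              paste(utils::head(x$s, 8), collapse = ","),
              if (x$k > 8) ",..." else ""))
  invisible(x)
}

#' Randomly excise residues from a structure
#'
#' Retains exactly `round(keep_fraction * m)` residues, chosen uniformly
#' without replacement; residue order is preserved. Works on both
#' `template` and `partial_decoy` objects. Used by the partial-structure
#' discrimination experiment.
#'
#' @param structure a `template` or `partial_decoy`.
#' @param keep_fraction fraction of residues to keep, in (0, 1\].
#' @param seed integer seed (local to the call).
#' @param keep_idx optional explicit index set overriding the random draw
#'   (so native and decoys can share one excision).
#' @return structure of the same class with the selected residues.
#' @export
excise_random <- function(structure, keep_fraction, seed = 1L,
                          keep_idx = NULL) {
  m <- if (inherits(structure, "template")) structure$m else structure$k
  if (is.null(keep_idx)) {
    if (keep_fraction <= 0 || keep_fraction > 1)
      stopf("keep_fraction must be in (0, 1]")
    n_keep <- round(keep_fraction * m)
    if (n_keep < 1L) stopf("excision would leave zero residues")
    keep_idx <- sort(with_seed(seed, sample.int(m, n_keep)))
  }
  subset_structure(structure, keep_idx)
}

## evaluate expr under a temporary RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

subset_structure <- function(structure, idx) {
  xyz <- lapply(structure$xyz, function(mat) mat[idx, , drop = FALSE])
  if (inherits(structure, "template")) {
    out <- new_template(structure$chain_id, structure$resno[idx],
                        structure$aa[idx], xyz,
                        ss = NULL, burial = NULL, cle = NULL)
  } else {
    out <- structure(list(s = structure$s[idx], aa = structure$aa[idx],
                          xyz = xyz, pairs = structure$pairs[idx, , drop = FALSE],
                          k = length(idx)),
                     class = "partial_decoy")
  }
  out
}

#' Write a partial decoy as a minimal PDB file
#'
#' ATOM records for N, CA, C, O and (non-glycine) CB, residue numbering
#' equal to the query positions, chain A, terminated by TER/END.
#'
#' @param decoy a non-empty `partial_decoy`.
#' @param path output path.
#' @export
write_decoy_pdb <- function(decoy, path) {
  if (decoy$k == 0L) stopf("cannot write an empty decoy")
  xyz <- numeric(0); resno <- integer(0); resid <- character(0)
  elety <- character(0)
  for (i in seq_len(decoy$k)) {
    for (at in BACKBONE_ATOMS) {
      co <- decoy$xyz[[at]][i, ]
      if (anyNA(co)) next
      xyz <- c(xyz, co)
      resno <- c(resno, decoy$s[i])
      resid <- c(resid, AA_1TO3[decoy$aa[i]] %|na|% "UNK")
      elety <- c(elety, at)
    }
  }
  bio3d::write.pdb(file = path, xyz = xyz, resno = resno, resid = resid,
                   elety = elety, chain = rep("A", length(resno)),
                   eleno = seq_along(resno), end = TRUE)
  invisible(path)
}

`%|na|%` <- function(a, b) ifelse(is.na(a), b, a)

#' Coordinates of a structure as one matrix
#' @param structure `template` or `partial_decoy`.
#' @param atoms atom names to include.
#' @return matrix with one row per present atom, plus attributes `residue`
#'   (residue index within the structure) and `atom` (atom name).
#' @keywords internal
structure_coords <- function(structure, atoms = BACKBONE_ATOMS) {
  rows <- list(); res <- integer(0); atn <- character(0)
  m <- if (inherits(structure, "template")) structure$m else structure$k
  for (at in atoms) {
    mat <- structure$xyz[[at]]
    ok <- !is.na(mat[, 1])
    rows[[at]] <- mat[ok, , drop = FALSE]
    res <- c(res, which(ok))
    atn <- c(atn, rep(at, sum(ok)))
  }
  out <- do.call(rbind, rows)
  attr(out, "residue") <- res
  attr(out, "atom") <- atn
  out
}
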