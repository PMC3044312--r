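#' Template structure objects
#'
#' A template is one protein chain with backbone (N, CA, C, O) and Cbeta
#' coordinates plus three per-residue structural annotation strings:
#' secondary structure (`ss`, H/E/C), burial class (`burial`, B = buried,
#' E = exposed) and a structural-alphabet string (`cle`). Coordinates are
#' stored as five m x 3 matrices with `NA` rows for absent atoms (Cbeta for
#' glycine, O occasionally missing in real files).
#'
#' @param chain_id single character chain identifier.
#' @param resno integer residue identifiers, strictly increasing (insertion
#'   codes are folded into the ordering by the PDB reader).
#' @param aa character vector of 1-letter residue types (X for unknown).
#' @param xyz named list of m x 3 matrices for N, CA, C, O, CB.
#' @param ss,burial,cle optional annotation strings of length m; filled by
#'   [derive_template_features()] when omitted.
#'
#' @return object of class `template` with fields `chain_id`, `m`, `resno`,
#'   `aa`, `seq`, `xyz` (list of matrices), `ss`, `burial`, `cle`.
#' @export
new_template <- function(chain_id, resno, aa, xyz,
                         ss = NULL, burial = NULL, cle = NULL) {
  m <- length(resno)
  if (m == 0L) stopf("template has zero residues")
  if (length(aa) != m) stopf("aa length != number of residues")
  if (any(diff(resno) <= 0)) stopf("residue numbering must be strictly increasing")
  for (at in c("N", "CA", "C")) {
    if (is.null(xyz[[at]]) || nrow(xyz[[at]]) != m)
      stopf("missing or wrong-sized %s coordinate matrix", at)
    if (anyNA(xyz[[at]]))
      stopf("every residue needs N, CA and C coordinates (%s has NA)", at)
  }
  for (at in c("O", "CB")) {
    if (is.null(xyz[[at]])) xyz[[at]] <- matrix(NA_real_, m, 3)
    if (nrow(xyz[[at]]) != m) stopf("%s coordinate matrix has wrong size", at)
  }
  cb_missing <- is.na(xyz$CB[, 1])
  if (any(cb_missing & aa != "G"))
    stopf("Cbeta absent for non-glycine residue(s): %s",
          paste(resno[cb_missing & aa != "G"], collapse = ", "))
  obj <- structure(
    list(chain_id = chain_id, m = m, resno = as.integer(resno),
         aa = aa, seq = paste(aa, collapse = ""),
         xyz = xyz[BACKBONE_ATOMS],
         ss = ss %||% NULL, burial = burial %||% NULL, cle = cle %||% NULL),
    class = "template")
  for (f in c("ss", "burial", "cle")) {
    v <- obj[[f]]
    if (!is.null(v) && nchar(v) != m) stopf("%s string length != m", f)
  }
  obj
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.template <- function(x, ...) {
  cat(sprintf("template chain %s: %d residues\n", x$chain_id, x$m))
  cat(" seq:", substr(x$seq, 1, 60), if (x$m > 60) "..." else "", "\n")
  if (!is.null(x$ss)) cat(" ss :", substr(x$ss, 1, 60), "\n")
  invisible(x)
}

## Representative side-chain point: CB, falling back to CA (glycine).
cb_or_ca <- function(template) {
  out <- template$xyz$CB
  miss <- is.na(out[, 1])
  out[miss, ] <- template$xyz$CA[miss, , drop = FALSE]
  out
}

#' Backbone dihedral angles of a template
#'
#' @param template a `template`.
#' @return data.frame with columns `phi` and `psi` in degrees; `NA` where
#'   undefined (phi at the first residue, psi at the last).
#' @export
backbone_dihedrals <- function(template) {
  m <- template$m
  if (m < 3L) stopf("need at least 3 residues to define dihedrals")
  N <- template$xyz$N; CA <- template$xyz$CA; C <- template$xyz$C
  phi <- psi <- rep(NA_real_, m)
  for (i in seq_len(m)) {
    if (i > 1L)
      phi[i] <- dihedral_angle(C[i - 1, ], N[i, ], CA[i, ], C[i, ])
    if (i < m)
      psi[i] <- dihedral_angle(N[i, ], CA[i, ], C[i, ], N[i + 1, ])
  }
  data.frame(phi = phi, psi = psi)
}

## 16-letter (phi, psi) grid alphabet: 4 x 4 cells of 90 degrees, letters
## A..P; '-' where either angle is undefined (chain termini).
CLE_LETTERS <- LETTERS[1:16]

cle_letter <- function(phi, psi) {
  if (is.na(phi) || is.na(psi)) return("-")
  bin <- function(a) min(3L, max(0L, as.integer(floor((a + 180) / 90))))
  CLE_LETTERS[bin(phi) * 4L + bin(psi) + 1L]
}

ss_state <- function(phi, psi) {
  if (is.na(phi) || is.na(psi)) return("C")
  if (phi > 179.999) phi <- -180   # +180 and -180 are the same angle
  if (phi >= -100 && phi <= -30 && psi >= -80 && psi <= -5) return("H")
  if (phi >= -180 && phi <= -90 &&
      ((psi >= 90 && psi <= 180) || (psi >= -180 && psi <= -170))) return("E")
  "C"
}

## collapse H/E runs shorter than 3 to coil
smooth_ss <- function(states, min_run = 3L) {
  r <- rle(states)
  r$values[r$lengths < min_run & r$values != "C"] <- "C"
  inverse.rle(r)
}

#' Derive structural annotations for a template
#'
#' Fills the `ss`, `burial` and `cle` fields from coordinates alone:
#' \itemize{
#' \item `ss`: 3-state string from backbone (phi, psi) windows
#'   (H: phi in \[-100, -30\] and psi in \[-80, -5\];
#'    E: phi in \[-180, -90\] and psi in \[90, 180\] or \[-180, -170\];
#'    else C), with H/E runs shorter than 3 residues relabelled C.
#' \item `burial`: contact number = count of other Cbeta atoms (CA for
#'   glycine) within `burial_cutoff` Angstrom; B where the count is at least
#'   the chain median, E otherwise.
#' \item `cle`: 16-letter structural alphabet from a fixed 4 x 4 grid of
#'   90-degree (phi, psi) cells; '-' at termini where dihedrals are
#'   undefined.
#' }
#' Deterministic, and invariant under rigid-body motion of the coordinates.
#'
#' @param template a `template`.
#' @param burial_cutoff contact-number distance cutoff in Angstrom.
#' @return the template with `ss`, `burial` and `cle` filled.
#' @export
derive_template_features <- function(template, burial_cutoff = 10) {
  m <- template$m
  if (m < 3L) stopf("template too short to annotate (m = %d < 3)", m)
  di <- backbone_dihedrals(template)
  ss <- smooth_ss(mapply(ss_state, di$phi, di$psi))
  cle <- mapply(cle_letter, di$phi, di$psi)
  cb <- cb_or_ca(template)
  d <- as.matrix(stats::dist(cb))
  contacts <- rowSums(d <= burial_cutoff) - 1L
  burial <- ifelse(contacts >= stats::median(contacts), "B", "E")
  template$ss <- paste(ss, collapse = "")
  template$burial <- paste(burial, collapse = "")
  template$cle <- paste(cle, collapse = "")
  template
}

#' Write a 4-line annotation file (sequence / ss / burial / cle)
#'
#' @param template annotated `template`.
#' @param path output file path.
#' @export
write_template_features <- function(template, path) {
  if (is.null(template$ss))
    template <- derive_template_features(template)
  writeLines(c(template$seq, template$ss, template$burial, template$cle), path)
  invisible(path)
}
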