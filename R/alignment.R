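#' Alignment mappings
#'
#' A query-template alignment is represented as a non-decreasing mapping
#' `A` from template positions 1..m to query positions 0..n, where 0 is the
#' sentinel query position encoding template residues gapped at the left
#' end. Several template positions may map to the same query position; only
#' the smallest such template position is a *match state*, the rest are
#' template-side gaps. Query positions absent from the image are query-side
#' insertions.
#'
#' @param map integer vector of length m with values in \[0, n\].
#' @param n query length.
#' @return object of class `alignment_map` with fields `map`, `m`, `n`.
#' @export
alignment_map <- function(map, n) {
  map <- as.integer(map)
  a <- structure(list(map = map, m = length(map), n = as.integer(n)),
                 class = "alignment_map")
  v <- validate_alignment(a)
  if (!v$ok) stopf("invalid alignment mapping: %s", v$message)
  a
}

#' Validate an alignment mapping (report style)
#'
#' @param a an `alignment_map` (or a bare list with map/m/n fields).
#' @return list with `ok` (logical), and on failure `position` of the first
#'   violation and a `message`.
#' @export
validate_alignment <- function(a) {
  map <- a$map
  if (length(map) == 0L)
    return(list(ok = FALSE, position = 0L, message = "empty mapping"))
  bad <- which(map < 0L | map > a$n)
  if (length(bad))
    return(list(ok = FALSE, position = bad[1],
                message = sprintf("value %d out of [0, %d] at position %d",
                                  map[bad[1]], a$n, bad[1])))
  dec <- which(diff(map) < 0L)
  if (length(dec))
    return(list(ok = FALSE, position = dec[1] + 1L,
                message = sprintf("mapping decreases at position %d", dec[1] + 1L)))
  list(ok = TRUE)
}

#' @export
print.alignment_map <- function(x, ...) {
  cat(sprintf("alignment_map m=%d n=%d: %s\n", x$m, x$n,
              paste(x$map, collapse = " ")))
  invisible(x)
}

#' @export
format.alignment_map <- function(x, ...) paste(x$map, collapse = ",")

#' Match states of an alignment
#'
#' For each query position s > 0 in the image of the mapping, the smallest
#' template position mapped to s is the match; remaining template positions
#' mapped to s are template-side gaps.
#'
#' @param a an `alignment_map`.
#' @return data.frame with integer columns `t` and `s`, strictly increasing
#'   in both; zero rows for an all-gap alignment.
#' @export
match_states <- function(a) {
  v <- validate_alignment(a)
  if (!v$ok) stopf("invalid alignment: %s", v$message)
  keep <- a$map > 0L & !duplicated(a$map)
  data.frame(t = which(keep), s = a$map[keep])
}

#' Number of match states
#' @param a an `alignment_map`.
#' @export
match_size <- function(a) {
  sum(a$map > 0L & !duplicated(a$map))
}

## Canonical column list of the gapped form: between consecutive match
## states, template deletions are emitted before query insertions. Each
## column is (t, s) with 0 marking a gap in that row.
alignment_columns <- function(a) {
  ms <- match_states(a)
  cols_t <- integer(0); cols_s <- integer(0)
  pt <- 0L; ps <- 0L
  emit_region <- function(t_hi, s_hi) {
    ts <- if (t_hi > pt) (pt + 1L):t_hi else integer(0)
    ss <- if (s_hi > ps) (ps + 1L):s_hi else integer(0)
    cols_t <<- c(cols_t, ts, rep(0L, length(ss)))
    cols_s <<- c(cols_s, rep(0L, length(ts)), ss)
  }
  for (k in seq_len(nrow(ms))) {
    emit_region(ms$t[k] - 1L, ms$s[k] - 1L)
    cols_t <- c(cols_t, ms$t[k]); cols_s <- c(cols_s, ms$s[k])
    pt <- ms$t[k]; ps <- ms$s[k]
  }
  emit_region(a$m, a$n)
  data.frame(t = cols_t, s = cols_s)
}

#' Convert an alignment mapping to gapped strings
#'
#' @param a an `alignment_map`.
#' @param template_seq template sequence (length m).
#' @param query_seq query sequence (length n).
#' @return character vector of two equal-length gapped strings,
#'   `c(template_row, query_row)`.
#' @export
to_gapped_strings <- function(a, template_seq, query_seq) {
  if (nchar(template_seq) != a$m) stopf("template sequence length != m")
  if (nchar(query_seq) != a$n) stopf("query sequence length != n")
  cols <- alignment_columns(a)
  tch <- chars(template_seq); qch <- chars(query_seq)
  trow <- ifelse(cols$t > 0L, tch[pmax(cols$t, 1L)], "-")
  qrow <- ifelse(cols$s > 0L, qch[pmax(cols$s, 1L)], "-")
  c(paste(trow, collapse = ""), paste(qrow, collapse = ""))
}

#' Recover an alignment mapping from gapped strings
#'
#' Inverse of [to_gapped_strings()] on the alignment space: template
#' positions in gap columns map to the last matched query position (0 before
#' the first match).
#'
#' @param rows character vector of two equal-length gapped strings.
#' @return an `alignment_map`.
#' @export
from_gapped_strings <- function(rows) {
  if (length(rows) != 2L) stopf("need exactly two gapped rows")
  tr <- chars(rows[1]); qr <- chars(rows[2])
  if (length(tr) != length(qr)) stopf("gapped rows have unequal length")
  map <- integer(0); s <- 0L; last <- 0L
  for (i in seq_along(tr)) {
    tgap <- tr[i] == "-"; qgap <- qr[i] == "-"
    if (tgap && qgap) stopf("column %d has a gap in both rows", i)
    if (!qgap) s <- s + 1L
    if (!tgap) {
      map <- c(map, if (qgap) last else s)
      if (!qgap) last <- s
    }
  }
  alignment_map(map, n = s)
}

#' Count gap openings and gap columns
#'
#' In the canonical gapped form, GO is the number of maximal gap runs over
#' both rows and GE the total number of gapped columns (an opened gap of
#' length L contributes GO = 1, GE = L). With `free_query_ends = TRUE`
#' (the threading default) query-side insertions before the first or after
#' the last match state are not counted; template-side gaps are always
#' counted.
#'
#' @param a an `alignment_map`.
#' @param free_query_ends logical.
#' @return list with integers `go` and `ge`.
#' @export
count_gaps <- function(a, free_query_ends = TRUE) {
  cols <- alignment_columns(a)
  if (nrow(cols) == 0L) return(list(go = 0L, ge = 0L))
  del <- cols$s == 0L            # gap in query row (template residue)
  ins <- cols$t == 0L            # gap in template row (query residue)
  if (free_query_ends) {
    matches <- which(!del & !ins)
    if (length(matches) == 0L) {
      ins[] <- FALSE             # everything is terminal on the query side
    } else {
      ins[seq_len(nrow(cols)) < matches[1]] <- FALSE
      ins[seq_len(nrow(cols)) > matches[length(matches)]] <- FALSE
    }
  }
  runs <- function(x) sum(rle(x)$values)
  list(go = runs(del) + runs(ins), ge = as.integer(sum(del) + sum(ins)))
}

#' Alignment accuracy against a reference
#'
#' Fraction of reference match states (t, s) for which the test alignment
#' has a match state (t, s') with |s' - s| <= tolerance. The strict
#' exact accuracy is `tolerance = 0`; the relaxed variant uses
#' `tolerance = 4`.
#'
#' @param test,reference `alignment_map`s over the same template and query.
#' @param tolerance non-negative integer.
#' @return fraction in \[0, 1\].
#' @export
alignment_accuracy <- function(test, reference, tolerance = 0L) {
  if (test$m != reference$m || test$n != reference$n)
    stopf("test and reference alignments have different dimensions")
  ref <- match_states(reference)
  if (nrow(ref) == 0L) stopf("reference alignment has no match states")
  tst <- match_states(test)
  s_of_t <- rep(NA_integer_, test$m)
  s_of_t[tst$t] <- tst$s
  ok <- !is.na(s_of_t[ref$t]) & abs(s_of_t[ref$t] - ref$s) <= tolerance
  mean(ok)
}

#' Enumerate the whole alignment space (test oracle)
#'
#' All non-decreasing mappings from 1..m to 0..n. There are
#' choose(m + n, m) of them; refuses when that exceeds `guard`.
#'
#' @param m,n template and query lengths.
#' @param guard maximum space size.
#' @return list of `alignment_map`s.
#' @export
enumerate_all_alignments <- function(m, n, guard = 1e6) {
  total <- choose(m + n, m)
  if (total > guard)
    stopf("alignment space too large to enumerate (%g > %g)", total, guard)
  ## bijection: strictly increasing c in 1..(m+n) of size m  <->  a_i = c_i - i
  combos <- utils::combn(m + n, m)
  lapply(seq_len(ncol(combos)), function(j)
    alignment_map(combos[, j] - seq_len(m), n = n))
}

#' Write an alignment as 2-record gapped FASTA
#' @param a an `alignment_map`.
#' @param template_seq,query_seq sequences.
#' @param path output file.
#' @param ids record identifiers.
#' @export
write_alignment_fasta <- function(a, template_seq, query_seq, path,
                                  ids = c("template", "query")) {
  rows <- to_gapped_strings(a, template_seq, query_seq)
  writeLines(c(paste0(">", ids[1]), rows[1], paste0(">", ids[2]), rows[2]),
             path)
  invisible(path)
}

## hashable key for dedup / set comparisons
alignment_key <- function(a) paste(a$map, collapse = ",")
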