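#' Distance-dependent pair potential tables
#'
#' A binned (atom-type-pair x distance-bin) energy table with a DFIRE-style
#' finite-ideal-gas reference state. Two typing schemes are supported:
#' `"res_atom"` (residue type x atom name over N, CA, C, O, CB; 100 types)
#' and `"cb"` (one Cbeta-level point per residue, CA for glycine; 20 types).
#' Energies are zero at and beyond `r_cut` by construction.
#'
#' @param scheme atom typing scheme.
#' @param r_cut distance cutoff in Angstrom.
#' @param n_bins number of equal-width distance bins on (0, r_cut\].
#' @param alpha_exp reference-state distance exponent (the DFIRE-style
#'   `r^alpha` volume correction).
#' @param eta energy scale of the log-ratio.
#' @param energies optional pre-filled types x types x bins array
#'   (defaults to all zeros).
#' @return object of class `pair_potential`.
#' @export
pair_potential <- function(scheme = c("res_atom", "cb"), r_cut = 15,
                           n_bins = 30, alpha_exp = 1.61, eta = 0.01,
                           energies = NULL) {
  scheme <- match.arg(scheme)
  types <- if (scheme == "cb") AA_ORDER
           else as.vector(outer(AA_ORDER, BACKBONE_ATOMS, paste, sep = "."))
  nt <- length(types)
  edges <- seq(0, r_cut, length.out = n_bins + 1)
  if (is.null(energies))
    energies <- array(0, dim = c(nt, nt, n_bins),
                      dimnames = list(types, types, NULL))
  stopifnot(all(dim(energies) == c(nt, nt, n_bins)))
  structure(list(scheme = scheme, types = types, bin_edges = edges,
                 r_cut = r_cut, n_bins = n_bins, alpha_exp = alpha_exp,
                 eta = eta, energies = energies),
            class = "pair_potential")
}

#' @export
print.pair_potential <- function(x, ...) {
  cat(sprintf("pair_potential (%s): %d types, %d bins to %.1f A, alpha=%.2f, eta=%g\n",
              x$scheme, length(x$types), x$n_bins, x$r_cut, x$alpha_exp, x$eta))
  invisible(x)
}

## per-atom typed coordinate list of a structure under a scheme;
## `position` carries the sequence separation coordinate (template residue
## index for templates, query position for decoys).
typed_atoms <- function(structure, scheme) {
  is_tmpl <- inherits(structure, "template")
  pos <- if (is_tmpl) seq_len(structure$m) else structure$s
  if (scheme == "cb") {
    co <- cb_or_ca(structure)
    ok <- structure$aa %in% AA_ORDER
    list(coords = co[ok, , drop = FALSE], type = structure$aa[ok],
         position = pos[ok])
  } else {
    co <- structure_coords(structure)
    res <- attr(co, "residue"); atn <- attr(co, "atom")
    aa <- structure$aa[res]
    ok <- aa %in% AA_ORDER
    list(coords = co[ok, , drop = FALSE],
         type = paste(aa[ok], atn[ok], sep = "."),
         position = pos[res][ok])
  }
}

## cb_or_ca also works for decoys (same xyz layout)
## (defined in template.R; relies only on $xyz)

pair_observations <- function(structure, table, min_separation) {
  ta <- typed_atoms(structure, table$scheme)
  na <- nrow(ta$coords)
  if (na < 2L) return(NULL)
  d <- as.matrix(stats::dist(ta$coords))
  sep <- abs(outer(ta$position, ta$position, "-"))
  sel <- upper.tri(d) & d < table$r_cut & d > 0 & sep >= min_separation
  if (!any(sel)) return(NULL)
  ij <- which(sel, arr.ind = TRUE)
  bin <- pmin(table$n_bins,
              pmax(1L, findInterval(d[sel], table$bin_edges,
                                    rightmost.closed = TRUE)))
  data.frame(type_a = ta$type[ij[, 1]], type_b = ta$type[ij[, 2]], bin = bin)
}

#' Estimate a pair potential from a set of structures
#'
#' Counts atom-type-pair observations in distance bins over the given
#' structures and converts them to energies with the DFIRE-style reference
#' state: `E(a, b, k) = -eta * log((N(a,b,k) + pc) / (f_k * (N(a,b,K) + pc)))`
#' where `f_k = (r_k / r_K)^alpha_exp` compares bin k's center to the last
#' (reference) bin K, and `pc` is an additive pseudocount. Type pairs with
#' no observations at all get a zero energy row.
#'
#' @param structures list of `template` objects.
#' @param table a `pair_potential` giving the binning/typing spec (its
#'   energies are ignored).
#' @param min_separation minimum residue separation of counted pairs.
#' @param pseudocount additive pseudocount.
#' @return the `pair_potential` with estimated energies.
#' @export
estimate_potential <- function(structures, table = pair_potential(),
                               min_separation = 2L, pseudocount = 0.5) {
  if (length(structures) == 0L) stopf("need at least one structure")
  nt <- length(table$types)
  counts <- array(0, dim = c(nt, nt, table$n_bins),
                  dimnames = dimnames(table$energies) %||%
                    list(table$types, table$types, NULL))
  tindex <- stats::setNames(seq_len(nt), table$types)
  acc <- numeric(nt * nt * table$n_bins)
  for (st in structures) {
    obs <- pair_observations(st, table, min_separation)
    if (is.null(obs)) next
    ia <- tindex[obs$type_a]; ib <- tindex[obs$type_b]
    lin <- (obs$bin - 1L) * nt * nt + (ib - 1L) * nt + ia
    acc <- acc + tabulate(lin, nbins = length(acc))
  }
  counts[] <- acc
  ## symmetrize; equal-type pairs double, which cancels in the N_k / N_K ratio
  counts <- counts + aperm(counts, c(2, 1, 3))
  centers <- (table$bin_edges[-1] + table$bin_edges[-(table$n_bins + 1)]) / 2
  fk <- (centers / centers[table$n_bins])^table$alpha_exp
  E <- array(0, dim = dim(counts), dimnames = dimnames(counts))
  for (i in seq_len(nt)) for (j in seq_len(nt)) {
    nij <- counts[i, j, ]
    if (sum(nij) == 0) next
    E[i, j, ] <- -table$eta *
      log((nij + pseudocount) / (fk * (nij[table$n_bins] + pseudocount)))
  }
  table$energies <- E
  table
}

#' Energy of a (partial) structure under a pair potential
#'
#' Sum of table lookups over all qualifying atom pairs: each unordered pair
#' counted once, distance below `r_cut`, and residue separation (query
#' positions for a decoy) at least `min_separation`. An empty structure has
#' undefined energy (`+Inf` sentinel).
#'
#' @param decoy a `partial_decoy` or `template`.
#' @param table a `pair_potential`.
#' @param min_separation minimum sequence separation.
#' @return total energy (scalar).
#' @export
decoy_energy <- function(decoy, table, min_separation = 2L) {
  k <- if (inherits(decoy, "template")) decoy$m else decoy$k
  if (k == 0L) return(Inf)
  obs <- pair_observations(decoy, table, min_separation)
  if (is.null(obs)) return(0)
  tindex <- stats::setNames(seq_along(table$types), table$types)
  sum(table$energies[cbind(tindex[obs$type_a], tindex[obs$type_b], obs$bin)])
}

#' Normalized global score G(A)
#'
#' Pair-potential energy of the partial decoy built from the alignment,
#' divided by the match-state size. `+Inf` sentinel for alignments without
#' match states.
#'
#' @param a an `alignment_map`.
#' @param template a `template`.
#' @param query a `query_profile`.
#' @param table a `pair_potential`.
#' @param min_separation minimum query-position separation of counted pairs.
#' @return normalized global score (scalar).
#' @export
global_score <- function(a, template, query, table, min_separation = 2L) {
  k <- match_size(a)
  if (k == 0L) return(Inf)
  decoy <- build_partial_decoy(a, template, query)
  decoy_energy(decoy, table, min_separation) / k
}

#' Contact model for the contact-preference baseline score
#'
#' @param C 20 x 20 symmetric preference matrix (rows/cols in
#'   `ARNDCQEGHILKMFPSTWYV` order).
#' @param cutoff Cbeta contact distance cutoff (Angstrom).
#' @param min_separation minimum template residue separation.
#' @return object of class `contact_model`.
#' @export
contact_model <- function(C, cutoff = 8, min_separation = 4L) {
  C <- as.matrix(C)
  stopifnot(all(dim(C) == c(20, 20)))
  if (max(abs(C - t(C))) > 1e-9) stopf("contact matrix must be symmetric")
  dimnames(C) <- list(AA_ORDER, AA_ORDER)
  structure(list(C = C, cutoff = cutoff, min_separation = min_separation),
            class = "contact_model")
}

#' Template contact map
#'
#' Boolean matrix delta(i, j): TRUE iff the Cbeta (CA for glycine) distance
#' is at most `cutoff` and |i - j| >= `min_separation`.
#'
#' @param template a `template`.
#' @param cutoff distance cutoff (Angstrom).
#' @param min_separation minimum residue separation.
#' @return m x m logical matrix (symmetric, FALSE diagonal band).
#' @export
contact_map <- function(template, cutoff = 8, min_separation = 4L) {
  d <- as.matrix(stats::dist(cb_or_ca(template)))
  sep <- abs(outer(seq_len(template$m), seq_len(template$m), "-"))
  d <= cutoff & sep >= min_separation
}

#' Row-softmax profile probabilities
#'
#' Converts the log-odds profile to per-position 20-dim probability vectors
#' (max-shifted softmax), used by the contact-preference score.
#'
#' @param query a `query_profile`.
#' @return n x 20 row-stochastic matrix.
#' @export
profile_probabilities <- function(query) {
  p <- query$profile
  p <- exp(p - apply(p, 1, max))
  p / rowSums(p)
}

#' Contact-preference baseline score S_p(A)
#'
#' The distance-independent global baseline: over template contacts
#' delta(i, j) whose both ends are match states, sums
#' `Pair(A(i), A(j)) = P_{A(i)}' C P_{A(j)}` with P the query profile
#' probability vectors, negated (minimization convention) and divided by
#' the match-state size. Contacts with an unmatched end contribute nothing.
#'
#' @param a an `alignment_map`.
#' @param template a `template`.
#' @param query a `query_profile`.
#' @param model a `contact_model`.
#' @return normalized score (scalar); `+Inf` for empty alignments.
#' @export
contact_preference_score <- function(a, template, query, model) {
  ms <- match_states(a)
  if (nrow(ms) == 0L) return(Inf)
  cm <- contact_map(template, model$cutoff, model$min_separation)
  P <- profile_probabilities(query)
  s_of_t <- rep(NA_integer_, template$m)
  s_of_t[ms$t] <- ms$s
  total <- 0
  idx <- which(cm & upper.tri(cm), arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    si <- s_of_t[idx[r, 1]]; sj <- s_of_t[idx[r, 2]]
    if (is.na(si) || is.na(sj)) next
    total <- total + drop(P[si, ] %*% model$C %*% P[sj, ])
  }
  -total / nrow(ms)
}

#' Serialize / load a potential table as tab-separated text
#'
#' Columns: type_a, type_b, bin_lo, bin_hi, energy; zero entries omitted.
#' A header line `# scheme r_cut n_bins alpha_exp eta` carries the table
#' metadata.
#'
#' @param table a `pair_potential`.
#' @param path file path.
#' @export
write_potential <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s %g %d %g %g", table$scheme, table$r_cut,
                     table$n_bins, table$alpha_exp, table$eta), con)
  nz <- which(table$energies != 0, arr.ind = TRUE)
  lo <- table$bin_edges[nz[, 3]]; hi <- table$bin_edges[nz[, 3] + 1]
  df <- data.frame(type_a = table$types[nz[, 1]], type_b = table$types[nz[, 2]],
                   bin_lo = lo, bin_hi = hi,
                   energy = table$energies[nz])
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_potential
#' @export
read_potential <- function(path) {
  header <- strsplit(sub("^#\\s*", "", readLines(path, n = 1)), "\\s+")[[1]]
  tab <- pair_potential(scheme = header[1], r_cut = as.numeric(header[2]),
                        n_bins = as.integer(header[3]),
                        alpha_exp = as.numeric(header[4]),
                        eta = as.numeric(header[5]))
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1,
                          stringsAsFactors = FALSE)
  if (nrow(df)) {
    ia <- match(df$type_a, tab$types); ib <- match(df$type_b, tab$types)
    bin <- pmin(tab$n_bins, pmax(1L, findInterval(
      (df$bin_lo + df$bin_hi) / 2, tab$bin_edges, rightmost.closed = TRUE)))
    tab$energies[cbind(ia, ib, bin)] <- df$energy
  }
  tab
}
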