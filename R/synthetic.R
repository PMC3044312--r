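## Synthetic toy structures and threading pairs. These are geometric
## idealizations (ideal bond geometry, planted alignments, planted energy
## patterns), sufficient to exercise every algorithmic property of the
## package without any external structure database.

IDEAL_GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  a_n_ca_c = 111.0, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.5,
  omega = 180)

motif_angles <- function(n, motif) {
  phi_psi <- switch(motif,
    helix = list(phi = rep(-57, n), psi = rep(-47, n)),
    strand = list(phi = rep(-120, n), psi = rep(120, n)),
    extended = list(phi = rep(-180, n), psi = rep(180, n)),
    mixed = {
      states <- rep(c(rep("H", 8), rep("E", 6)), length.out = n)
      list(phi = ifelse(states == "H", -57, -120),
           psi = ifelse(states == "H", -47, 120))
    },
    stopf("unknown motif '%s'", motif))
  phi_psi
}

#' Generate an ideal toy structure
#'
#' Builds a backbone from fixed ideal bond lengths and angles with (phi,
#' psi) set by the motif (helix: -57/-47; strand: -120/+120; extended:
#' -180/180; mixed: alternating helix/strand runs), places O and ideal
#' Cbeta atoms, and samples residue types uniformly under the seed.
#'
#' @param n number of residues (>= 4).
#' @param motif one of "helix", "strand", "extended", "mixed".
#' @param seed integer seed for the residue types.
#' @param aa optional explicit residue types (overrides sampling).
#' @param path optional PDB output path.
#' @return an annotated `template`.
#' @export
make_ideal_structure <- function(n, motif = "helix", seed = 1L, aa = NULL,
                                 path = NULL) {
  if (n < 4L) stopf("need at least 4 residues (got %d)", n)
  g <- IDEAL_GEOM
  ang <- motif_angles(n, motif)
  N <- CA <- C <- O <- CB <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  th <- (180 - g$a_n_ca_c) * pi / 180
  C[1, ] <- CA[1, ] + g$b_ca_c * c(cos(th), sin(th), 0)
  for (i in 2:n) {
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                         g$b_c_n, g$a_ca_c_n, ang$psi[i - 1])
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                          g$b_n_ca, g$a_c_n_ca, g$omega)
    C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                         g$b_ca_c, g$a_n_ca_c, ang$phi[i])
  }
  for (i in 1:n)
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                         g$b_c_o, g$a_ca_c_o, ang$psi[i] - 180)
  if (is.null(aa))
    aa <- with_seed(seed, sample(AA_ORDER, n, replace = TRUE))
  for (i in 1:n)
    if (aa[i] != "G") CB[i, ] <- place_cb(N[i, ], CA[i, ], C[i, ])
  tmpl <- new_template("A", seq_len(n), aa,
                       list(N = N, CA = CA, C = C, O = O, CB = CB))
  tmpl <- derive_template_features(tmpl)
  if (!is.null(path)) write_template_pdb(tmpl, path)
  tmpl
}

#' Write a template as a minimal PDB file
#' @param template a `template`.
#' @param path output path.
#' @export
write_template_pdb <- function(template, path) {
  xyz <- numeric(0); resno <- integer(0); resid <- character(0)
  elety <- character(0)
  for (i in seq_len(template$m)) {
    for (at in BACKBONE_ATOMS) {
      co <- template$xyz[[at]][i, ]
      if (anyNA(co)) next
      xyz <- c(xyz, co)
      resno <- c(resno, template$resno[i])
      resid <- c(resid, AA_1TO3[template$aa[i]] %|na|% "UNK")
      elety <- c(elety, at)
    }
  }
  bio3d::write.pdb(file = path, xyz = xyz, resno = resno, resid = resid,
                   elety = elety, chain = rep(template$chain_id, length(resno)),
                   eleno = seq_along(resno), end = TRUE)
  invisible(path)
}

#' Write a query profile as a PSI-BLAST-dialect ASCII PSSM
#' @param query a `query_profile`.
#' @param path output path.
#' @export
write_pssm <- function(query, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("", "Last position-specific scoring matrix computed",
               paste(c("   ", AA_ORDER), collapse = "  ")), con)
  for (i in seq_len(query$n))
    writeLines(paste(c(sprintf("%5d %s", i, query$aa[i]),
                       sprintf("%3d", round(query$profile[i, ]))),
                     collapse = " "), con)
  invisible(path)
}

#' Generate noisy decoys of a structure
#'
#' Each decoy adds isotropic per-atom Gaussian noise to the backbone and O
#' coordinates and re-idealizes the Cbeta from the perturbed backbone; the
#' sequence is unchanged.
#'
#' @param native a `template`.
#' @param count number of decoys.
#' @param noise_sigma per-coordinate noise standard deviation (Angstrom).
#' @param seed integer seed.
#' @return list of `template`s.
#' @export
make_decoy_set <- function(native, count = 100L, noise_sigma = 1,
                           seed = 1L) {
  if (count < 1L) stopf("count must be >= 1")
  if (noise_sigma <= 0) stopf("noise_sigma must be > 0")
  m <- native$m
  with_seed(seed, {
    lapply(seq_len(count), function(d) {
      xyz <- native$xyz
      for (at in c("N", "CA", "C", "O"))
        xyz[[at]] <- xyz[[at]] + matrix(stats::rnorm(3 * m, 0, noise_sigma), m, 3)
      for (i in seq_len(m))
        if (native$aa[i] != "G")
          xyz$CB[i, ] <- place_cb(xyz$N[i, ], xyz$CA[i, ], xyz$C[i, ])
      new_template(native$chain_id, native$resno, native$aa, xyz)
    })
  })
}

#' Generate a synthetic threading pair with a known reference alignment
#'
#' Builds a mixed-motif template, deletes a central segment to form the
#' query (so the reference alignment has one template-side gap of
#' `n_delete` residues), perturbs the remaining coordinates into a "true"
#' query structure, mutates the sequence down to the requested identity,
#' and emits a softened point-mass profile plus structure-derived
#' predictions for the query.
#'
#' @param seed integer seed.
#' @param m template length.
#' @param identity fraction of matched positions keeping the template
#'   residue type.
#' @param n_delete length of the deleted (template-side gap) segment.
#' @param noise_sigma coordinate noise of the true query structure.
#' @return list with `template`, `query` (a `query_profile`), `reference`
#'   (an `alignment_map`), and `query_structure` (the true coordinates).
#' @export
make_threading_pair <- function(seed = 1L, m = 30L, identity = 0.6,
                                n_delete = 3L, noise_sigma = 0.3) {
  seed <- as.integer(seed) %% 2000000000L  # room for the +1..+3 sub-seeds
  template <- make_ideal_structure(m, "mixed", seed = seed)
  if (n_delete > 0L) {
    del_start <- max(2L, (m - n_delete) %/% 2L)
    deleted <- del_start:(del_start + n_delete - 1L)
    matched_t <- setdiff(seq_len(m), deleted)
  } else {
    matched_t <- seq_len(m)
  }
  n <- length(matched_t)
  ## reference mapping: matched positions in order; gapped positions carry
  ## the last matched query position
  map <- integer(m); last <- 0L; s <- 0L
  for (t in seq_len(m)) {
    if (t %in% matched_t) { s <- s + 1L; map[t] <- s; last <- s }
    else map[t] <- last
  }
  reference <- alignment_map(map, n)
  ## true query structure: template coordinates at matched positions + noise
  q_aa <- template$aa[matched_t]
  mut <- with_seed(seed + 1L, stats::runif(n) > identity)
  q_aa[mut] <- with_seed(seed + 2L, vapply(which(mut), function(i)
    sample(setdiff(AA_ORDER, q_aa[i]), 1L), character(1)))
  xyz <- lapply(template$xyz, function(mat) mat[matched_t, , drop = FALSE])
  if (noise_sigma > 0) {
    with_seed(seed + 3L, {
      for (at in c("N", "CA", "C", "O"))
        xyz[[at]] <- xyz[[at]] + matrix(stats::rnorm(3 * n, 0, noise_sigma), n, 3)
    })
  }
  xyz$CB <- matrix(NA_real_, n, 3)
  for (i in seq_len(n))
    if (q_aa[i] != "G") xyz$CB[i, ] <- place_cb(xyz$N[i, ], xyz$CA[i, ], xyz$C[i, ])
  query_structure <- derive_template_features(
    new_template("Q", seq_len(n), q_aa, xyz))
  profile <- matrix(0, n, 20, dimnames = list(NULL, AA_ORDER))
  profile[cbind(seq_len(n), match(q_aa, AA_ORDER))] <- 5
  query <- query_profile(paste(q_aa, collapse = ""), profile = profile,
                         predicted_ss = query_structure$ss,
                         predicted_burial = query_structure$burial,
                         predicted_cle = query_structure$cle)
  list(template = template, query = query, reference = reference,
       query_structure = query_structure)
}

#' A constructed pair where the global item rescues the alignment
#'
#' Six-residue toy: the profile slightly favors a diagonal-shifted
#' alignment, so the local-score optimum misses the reference (identity)
#' alignment entirely; the template carries exactly one close residue pair
#' whose query residues are cysteines under the identity alignment, and the
#' planted Cbeta potential rewards a C-C contact at that distance. Under
#' the combined score the identity alignment wins, demonstrating that the
#' distance-dependent global item can rescue locally suboptimal pairs.
#'
#' @return list with `template`, `query`, `reference`, `table` (planted
#'   `pair_potential`), `weights`, and the `omega_L` to use.
#' @export
make_rescue_pair <- function() {
  t_aa <- c("L", "V", "I", "F", "M", "W")
  centers <- rbind(c(0, 40, 0), c(0, 0, 0), c(0, 80, 0),
                   c(0, 120, 0), c(5, 0, 0), c(0, 160, 0))
  m <- 6L
  N <- CA <- C <- O <- CB <- matrix(NA_real_, m, 3)
  for (i in seq_len(m)) {
    CA[i, ] <- centers[i, ]
    N[i, ] <- centers[i, ] + c(-1.2, 0.3, 0)
    C[i, ] <- centers[i, ] + c(1.2, 0.4, 0)
    O[i, ] <- centers[i, ] + c(1.2, 1.6, 0)
    CB[i, ] <- centers[i, ] + c(0, -1.5, 0.3)
  }
  template <- derive_template_features(
    new_template("A", seq_len(m), t_aa, list(N = N, CA = CA, C = C, O = O, CB = CB)))
  q_aa <- c("A", "C", "A", "A", "C", "A")
  profile <- matrix(0, m, 20, dimnames = list(NULL, AA_ORDER))
  for (s in seq_len(m)) {
    profile[s, t_aa[s]] <- 10                       # identity: good
    if (s < m) profile[s, t_aa[s + 1L]] <- 13       # shift: slightly better
  }
  query <- query_profile(paste(q_aa, collapse = ""), profile = profile)
  weights <- local_weights(w_m = 1, w_ss = 0, w_cle = 0, w_sa = 0,
                           w_go = 3, w_ge = 0.5)
  table <- pair_potential(scheme = "cb")
  ## the template's close pair sits at exactly 5.0 A (residues 2 and 5)
  bins <- 10:11                                     # 4.5-5.5 A
  table$energies[, , bins] <- 2
  ci <- match("C", table$types)
  table$energies[ci, ci, bins] <- -3
  list(template = template, query = query,
       reference = alignment_map(1:6, 6), table = table,
       weights = weights, omega_L = 0.2)
}
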