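# Shared test fixtures; everything is generated in code.

# a random valid non-decreasing mapping
rand_map <- function(m, n) {
  alignment_map(sort(sample(0:n, m, replace = TRUE)), n)
}

# a random valid mapping guaranteed to have at least one match state
rand_map_matched <- function(m, n) {
  repeat {
    a <- rand_map(m, n)
    if (match_size(a) > 0L) return(a)
  }
}

# annotated toy template of length m (ideal mixed-motif chain)
toy_template <- function(m, seed = 1, motif = "mixed") {
  make_ideal_structure(m, motif, seed = seed)
}

# query with a random profile (scores the local item non-trivially)
toy_query <- function(n, seed = 1) {
  set.seed(seed)
  aa <- sample(pdthread:::AA_ORDER, n, replace = TRUE)
  query_profile(paste(aa, collapse = ""),
                profile = matrix(stats::rnorm(n * 20, 0, 3), n, 20))
}

# weights isolating the mutation term
mutation_only_weights <- function(w_go = 3, w_ge = 0.5, ...) {
  local_weights(w_m = 1, w_ss = 0, w_cle = 0, w_sa = 0,
                w_go = w_go, w_ge = w_ge, ...)
}

# brute-force minimum of the raw local score over the whole space for a
# hand-set score matrix W (template/query are not consulted when W is given)
brute_force_raw_min <- function(W, weights) {
  sp <- enumerate_all_alignments(nrow(W), ncol(W))
  scores <- vapply(sp, local_score_raw, numeric(1), template = NULL,
                   query = NULL, weights = weights, W = W)
  list(min = min(scores), space = sp, scores = scores)
}

key_set <- function(alns) sort(vapply(alns, pdthread:::alignment_key, character(1)))

# a "comb" of isolated residue pairs at controlled distances: pair j sits in
# its own cluster (clusters > 1000 A apart, far beyond any cutoff), partners
# are C index positions apart so the default min_separation admits them; the
# counted pair distances are then exactly `distances`
comb_structure <- function(distances, aa = "A") {
  C <- length(distances)
  pts <- matrix(0, 2 * C, 3)
  for (j in seq_len(C)) {
    pts[j, ] <- c(j * 1000, 0, 0)
    pts[C + j, ] <- c(j * 1000 + distances[j], 0, 0)
  }
  point_cloud_structure(pts, rep(aa, 2 * C))
}

# a "point cloud" pseudo-structure for the cb potential scheme: only the
# CB coordinates matter there, the backbone atoms are dummies
point_cloud_structure <- function(points, aa) {
  m <- nrow(points)
  new_template("A", seq_len(m), aa,
               list(N = points + matrix(rep(c(-1.2, 0, 0), each = m), m, 3),
                    CA = points,
                    C = points + matrix(rep(c(1.2, 0, 0), each = m), m, 3),
                    O = matrix(NA_real_, m, 3),
                    CB = points))
}
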