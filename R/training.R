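#' Training points for the local-item weight
#'
#' For one query-template pair with a positive alignment (normalized scores
#' `L_pos`, `G_pos`) and several negatives, each negative contributes one
#' point `x = L_pos - L_neg`, `y = G_neg - G_pos`; the weight training then
#' asks for the positive slope with the most points above it, i.e. the count
#' of pairs with `omega * (L_pos - L_neg) < G_neg - G_pos`.
#'
#' @param L_pos,G_pos normalized local/global scores of the positive.
#' @param L_neg,G_neg numeric vectors over the negatives.
#' @param pair_id optional identifier.
#' @return data.frame with columns `x`, `y` (and `pair_id`).
#' @export
training_points <- function(L_pos, G_pos, L_neg, G_neg, pair_id = NA) {
  if (length(L_neg) == 0L) stopf("need at least one negative alignment")
  data.frame(x = L_pos - L_neg, y = G_neg - G_pos, pair_id = pair_id)
}

#' Train the local-item weight by slope maximization
#'
#' Finds a strictly positive `omega` maximizing `|H|`, the number of points
#' with `omega * x < y`. The count only changes at the slopes `y / x` of the
#' points themselves, so an exact search over those candidate slopes (each
#' nudged to both sides), the interiors between consecutive candidates, and
#' outer brackets suffices. Ties go to the smallest maximizing candidate.
#'
#' @param points data.frame with numeric columns `x` and `y`.
#' @return list with `omega` (> 0) and `H` (the achieved count).
#' @export
train_omega <- function(points) {
  x <- points$x; y <- points$y
  if (length(x) == 0L) stopf("need at least one point")
  rs <- y / x
  rs <- sort(unique(rs[is.finite(rs) & x != 0 & rs > 0]))
  eps <- 1e-9
  if (length(rs) == 0L) {
    cands <- 1
  } else {
    mids <- if (length(rs) > 1) (rs[-1] + rs[-length(rs)]) / 2 else numeric(0)
    cands <- sort(unique(c(rs * (1 - eps), rs * (1 + eps), mids,
                           rs[1] / 2, rs[length(rs)] * 2)))
    cands <- cands[cands > 0]
  }
  counts <- vapply(cands, function(w) sum(w * x < y), numeric(1))
  best <- max(counts)
  omega <- min(cands[counts == best])
  if (best == 0)
    warnf("no positive slope separates any pair; returning omega = %g with |H| = 0",
          omega)
  list(omega = omega, H = as.integer(best))
}

## match-state overlap similarity (shared / union)
alignment_similarity <- function(a, b) {
  ka <- paste(match_states(a)$t, match_states(a)$s)
  kb <- paste(match_states(b)$t, match_states(b)$s)
  if (length(ka) == 0L && length(kb) == 0L) return(1)
  length(intersect(ka, kb)) / length(union(ka, kb))
}

#' Select negative alignments for weight training
#'
#' Greedy clustering by match-state overlap removes redundant candidates
#' (similarity >= `similarity_threshold` joins an existing cluster), then
#' negatives are drawn uniformly among the representatives whose quality is
#' more than `quality_gap` below the reference quality.
#'
#' @param candidates list of `alignment_map`s.
#' @param qualities numeric vector of candidate qualities in \[0, 1\].
#' @param reference_quality quality of the positive alignment.
#' @param count number of negatives to draw.
#' @param similarity_threshold clustering threshold.
#' @param quality_gap minimum quality deficit of an eligible negative.
#' @param seed integer seed.
#' @return list of selected `alignment_map`s with attribute `quality`;
#'   empty (with a warning) when nothing is eligible.
#' @export
select_negatives <- function(candidates, qualities, reference_quality,
                             count = 10L, similarity_threshold = 0.8,
                             quality_gap = 0.2, seed = 1L) {
  stopifnot(length(candidates) == length(qualities))
  reps <- integer(0)
  for (i in seq_along(candidates)) {
    dup <- any(vapply(reps, function(r)
      alignment_similarity(candidates[[i]], candidates[[r]]) >=
        similarity_threshold, logical(1)))
    if (!dup) reps <- c(reps, i)
  }
  eligible <- reps[reference_quality - qualities[reps] > quality_gap]
  if (length(eligible) == 0L) {
    warnf("no eligible negative alignments (quality gap > %g)", quality_gap)
    return(list())
  }
  take <- if (length(eligible) <= count) eligible else
    with_seed(seed, sort(sample(eligible, count)))
  out <- candidates[take]
  attr(out, "quality") <- qualities[take]
  out
}

#' Select the easy-pair gate theta from training records
#'
#' Records pair the normalized local score of the DP optimum with its
#' quality gap to the reference alignment. After sorting by local score,
#' theta is the largest score whose running mean of quality gaps (over all
#' records up to and including it) has stayed below `gap_limit`; `-Inf`
#' when even the first record fails.
#'
#' @param records data.frame with columns `L` (normalized local score) and
#'   `gap` (reference quality minus DP-optimum quality).
#' @param gap_limit tolerated mean quality gap.
#' @return theta (scalar; possibly `-Inf`).
#' @export
select_theta <- function(records, gap_limit = 0.1) {
  if (nrow(records) < 2L) stopf("need at least two records")
  ord <- order(records$L)
  L <- records$L[ord]
  cm <- cumsum(records$gap[ord]) / seq_along(ord)
  bad <- which(cm >= gap_limit)
  if (length(bad) == 0L) return(L[length(L)])
  if (bad[1] == 1L) return(-Inf)
  L[bad[1] - 1L]
}

#' TM-score kernel from a distance vector
#'
#' The length-normalized structural similarity given per-pair distances
#' after superposition: `sum(1 / (1 + (d / d0)^2)) / L_target` with
#' `d0 = max(1.24 (L_target - 15)^(1/3) - 1.8, 0.5)`.
#'
#' @param d distances in Angstrom over the matched pairs.
#' @param L_target normalizing length (the query length).
#' @return score in (0, 1\].
#' @export
tm_score_from_distances <- function(d, L_target) {
  d0 <- tm_d0(L_target)
  sum(1 / (1 + (d / d0)^2)) / L_target
}

tm_d0 <- function(L_target) {
  if (L_target > 15) max(1.24 * (L_target - 15)^(1 / 3) - 1.8, 0.5) else 0.5
}

#' TM-score-style alignment quality
#'
#' Measures how well the alignment superposes the true query structure onto
#' the template: over the matched CA pairs, an iterative superposition
#' (seed fragments of decreasing length, Kabsch fits on the close subset,
#' repeated until the subset is stable) maximizes the TM-score kernel with
#' `L_target` = query length. Deterministic.
#'
#' @param a an `alignment_map`.
#' @param query_structure `template` holding the true query coordinates
#'   (length n).
#' @param template the threading `template` (length m).
#' @return quality in (0, 1\].
#' @export
tm_quality <- function(a, query_structure, template) {
  if (query_structure$m != a$n || template$m != a$m)
    stopf("structure lengths do not match the alignment dimensions")
  ms <- match_states(a)
  K <- nrow(ms)
  if (K < 3L) stopf("need at least 3 match states for a superposition")
  fixed <- template$xyz$CA[ms$t, , drop = FALSE]
  mobile <- query_structure$xyz$CA[ms$s, , drop = FALSE]
  Ln <- a$n
  d0 <- tm_d0(Ln)
  best <- 0
  L_init <- K
  while (L_init >= 4L || L_init == K) {
    step <- max(1L, L_init %/% 4L)
    for (start in seq(1L, K - L_init + 1L, by = step)) {
      idx <- start:(start + L_init - 1L)
      for (it in 1:20) {
        fit <- kabsch_fit(mobile[idx, , drop = FALSE],
                          fixed[idx, , drop = FALSE])
        ## transform all mobile points with the fitted rigid body
        cm <- colMeans(mobile[idx, , drop = FALSE])
        cf <- colMeans(fixed[idx, , drop = FALSE])
        allm <- sweep(sweep(mobile, 2, cm) %*% t(fit$rotation), 2, cf, FUN = "+")
        d <- sqrt(rowSums((allm - fixed)^2))
        best <- max(best, tm_score_from_distances(d, Ln))
        d_cut <- d0
        repeat {
          sel <- which(d < d_cut)
          if (length(sel) >= 3L) break
          d_cut <- d_cut + 0.5
        }
        if (length(sel) == length(idx) && all(sel == idx)) break
        idx <- sel
      }
    }
    if (L_init <= 4L) break
    L_init <- max(4L, L_init %/% 2L)
  }
  best
}

#' Partial-structure discrimination experiment
#'
#' For each retention fraction and trial, excises the same random residue
#' set from the native structure and from every decoy, evaluates the pair
#' potential on the partial structures, and records whether the partial
#' native is the strict energy minimum. Reported per fraction as the mean
#' indicator over trials.
#'
#' @param native a `template`.
#' @param decoys list of `template`s of the same length.
#' @param table a `pair_potential`.
#' @param keep_fractions fractions of residues retained.
#' @param trials trials per fraction.
#' @param seed integer seed (bit-reproducible results for equal seeds).
#' @param min_separation sequence-separation floor for the energy.
#' @return data.frame with columns `keep_fraction` and `accuracy`.
#' @export
partial_discrimination <- function(native, decoys, table,
                                   keep_fractions = c(1, 0.9, 0.8, 0.7, 0.6, 0.5),
                                   trials = 10L, seed = 1L,
                                   min_separation = 2L) {
  if (length(decoys) == 0L) stopf("need at least one decoy")
  if (any(vapply(decoys, function(d) d$m, numeric(1)) != native$m))
    stopf("decoys must have the same length as the native structure")
  if (trials < 1L) stopf("trials must be >= 1")
  acc <- numeric(length(keep_fractions))
  for (fi in seq_along(keep_fractions)) {
    f <- keep_fractions[fi]
    wins <- logical(trials)
    for (tr in seq_len(trials)) {
      n_keep <- max(1L, round(f * native$m))
      keep_idx <- sort(with_seed((seed %% 100000L) * 10000L + fi * 100L + tr,
                                 sample.int(native$m, n_keep)))
      e_nat <- decoy_energy(subset_structure(native, keep_idx), table,
                            min_separation)
      e_dec <- vapply(decoys, function(d)
        decoy_energy(subset_structure(d, keep_idx), table, min_separation),
        numeric(1))
      wins[tr] <- all(e_nat < e_dec)
    }
    acc[fi] <- mean(wins)
  }
  data.frame(keep_fraction = keep_fractions, accuracy = acc)
}
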