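#' Local search parameters
#'
#' @param alpha multiplicative acceptance factor (>= 0): a move to the best
#'   neighbor is accepted only if `(1 + alpha) * shifted(new) <
#'   shifted(current)`. `alpha = 0` accepts any strict improvement.
#' @param k neighborhood order (>= 1): neighbors may reroute template
#'   positions onto at most `k` new query positions.
#' @param max_iterations hard iteration cap (the strict-decrease criterion
#'   already guarantees termination on the finite space).
#' @param score_shift positivity shift: scores enter the multiplicative test
#'   as `score - score_shift + 1`, so `score_shift` should be a lower bound
#'   on the achievable score. Irrelevant when `alpha = 0`.
#' @return object of class `search_params`.
#' @export
search_params <- function(alpha = 0.01, k = 1L, max_iterations = 200L,
                          score_shift = 0) {
  if (alpha < 0) stopf("alpha must be >= 0")
  if (k < 1L) stopf("k must be >= 1")
  structure(list(alpha = alpha, k = as.integer(k),
                 max_iterations = as.integer(max_iterations),
                 score_shift = score_shift),
            class = "search_params")
}

## fast exact enumeration for k = 1: reassign one interval of template
## positions to a single new query value u; validity requires every earlier
## position to map <= u and every later one >= u.
neighborhood_k1 <- function(a) {
  m <- a$m; n <- a$n; map <- a$map
  seen <- new.env(parent = emptyenv())
  out <- list(a)
  assign(alignment_key(a), TRUE, envir = seen)
  for (u in 0:n) {
    le <- which(map <= u)            # prefix constraint: a(i-1) <= u
    ge <- which(map >= u)            # suffix constraint: a(j+1) >= u
    i_max <- if (length(le)) max(le) + 1L else 1L
    j_min <- if (length(ge)) min(ge) - 1L else m
    for (i in seq_len(min(i_max, m))) {
      for (j in max(i, j_min, 1L):m) {
        if (j < i) next
        if (i > 1L && map[i - 1L] > u) break
        if (j < m && map[j + 1L] < u) next
        new_map <- map
        new_map[i:j] <- u
        key <- paste(new_map, collapse = ",")
        if (!exists(key, envir = seen)) {
          assign(key, TRUE, envir = seen)
          out[[length(out) + 1L]] <- alignment_map(new_map, n)
        }
      }
    }
  }
  out
}

## generic enumeration for k >= 2: for each candidate value set U, walk the
## positions left to right keeping only non-decreasing choices from
## {a(t)} union U.
neighborhood_generic <- function(a, k) {
  m <- a$m; n <- a$n; map <- a$map
  kk <- min(k, n + 1L)
  combos <- utils::combn(0:n, kk)
  seen <- new.env(parent = emptyenv())
  out <- list()
  emit <- function(v) {
    key <- paste(v, collapse = ",")
    if (!exists(key, envir = seen)) {
      assign(key, TRUE, envir = seen)
      out[[length(out) + 1L]] <<- alignment_map(v, n)
    }
  }
  for (cset in seq_len(ncol(combos))) {
    U <- combos[, cset]
    walk <- function(t, prev, acc) {
      if (t > m) { emit(acc); return(invisible()) }
      for (v in sort(unique(c(map[t], U)))) {
        if (v >= prev) walk(t + 1L, v, c(acc, v))
      }
    }
    walk(1L, 0L, integer(0))
  }
  out
}

#' The k-neighborhood of an alignment
#'
#' All valid alignments differing from `a` only in that some template
#' positions are rerouted onto a set of at most `k` new query positions
#' (`a` itself included). `k = 1` uses an exact interval-based enumeration;
#' larger `k` enumerates candidate value sets directly and is intended for
#' small instances.
#'
#' @param a an `alignment_map`.
#' @param k neighborhood order (>= 1).
#' @return list of `alignment_map`s, each appearing once.
#' @export
neighborhood <- function(a, k = 1L) {
  if (k < 1L) stopf("k must be >= 1")
  if (k == 1L) neighborhood_k1(a) else neighborhood_generic(a, k)
}

#' Brute-force neighborhood (test oracle)
#'
#' Filters the fully enumerated alignment space by the defining predicate:
#' the set of new values (those where the neighbor differs from `a`) has at
#' most `k` distinct members.
#'
#' @param a an `alignment_map`.
#' @param k neighborhood order (>= 1).
#' @param guard maximum space size for the enumeration.
#' @return list of `alignment_map`s.
#' @export
neighborhood_oracle <- function(a, k, guard = 1e6) {
  if (k < 1L) stopf("k must be >= 1")
  space <- enumerate_all_alignments(a$m, a$n, guard = guard)
  Filter(function(b) {
    diffs <- b$map[b$map != a$map]
    length(unique(diffs)) <= k
  }, space)
}

lex_less <- function(x, y) {
  d <- which(x != y)
  length(d) > 0L && x[d[1]] < y[d[1]]
}

#' Local search over alignment neighborhoods
#'
#' Iteratively replaces the current alignment by the best alignment in its
#' k-neighborhood, accepting the move only when the positivity-shifted score
#' drops by more than the factor `1 + alpha`. Ties in the neighborhood
#' argmin go to the lexicographically smallest mapping. Terminates at the
#' first rejected move (or `max_iterations`).
#'
#' @param a0 starting `alignment_map`.
#' @param score_fn function taking an `alignment_map` and returning a finite
#'   score (may return `+Inf` for degenerate alignments other than `a0`).
#' @param params a [search_params()].
#' @return the final `alignment_map`, with attributes `score` (its score),
#'   `trajectory` (accepted scores including the start) and `iterations`.
#' @export
local_search <- function(a0, score_fn, params = search_params()) {
  s0 <- score_fn(a0)
  if (!is.finite(s0)) stopf("score of the starting alignment is not finite")
  shift <- function(x) x - params$score_shift + 1
  cur <- a0; cur_score <- s0
  trajectory <- s0
  iter <- 0L
  repeat {
    if (iter >= params$max_iterations) break
    nb <- neighborhood(cur, params$k)
    best <- NULL; best_score <- Inf
    for (b in nb) {
      sc <- score_fn(b)
      if (sc < best_score ||
          (sc == best_score && !is.null(best) && lex_less(b$map, best$map))) {
        best <- b; best_score <- sc
      }
    }
    if (is.null(best)) break
    if ((1 + params$alpha) * shift(best_score) < shift(cur_score)) {
      cur <- best; cur_score <- best_score
      trajectory <- c(trajectory, cur_score)
      iter <- iter + 1L
    } else break
  }
  attr(cur, "score") <- cur_score
  attr(cur, "trajectory") <- trajectory
  attr(cur, "iterations") <- iter
  cur
}

#' Threading driver
#'
#' The full pipeline: (1) dynamic programming under the local score yields
#' the optimum `A_L` and up to `candidates` suboptimal seeds; (2) if the
#' normalized local score of `A_L` is below `theta` the pair is "easy" and
#' `A_L` is returned as is; (3) otherwise every seed is refined by
#' [local_search()] under the combined objective
#' `omega_L * L(A) + G(A)` (both terms normalized by match-state size) and
#' the best result is returned. The shipped `theta` and `omega_L` defaults
#' are meaningful only with a comparably scaled scoring; pass explicit
#' values when using custom weights.
#'
#' @param query a `query_profile`.
#' @param template a `template` (annotated automatically if needed).
#' @param table a `pair_potential` for the global term.
#' @param theta normalized-local-score gate for "easy" pairs.
#' @param omega_L weight of the local item in the combined score.
#' @param weights a `local_weights`.
#' @param params a [search_params()]; its `score_shift` is replaced by a
#'   per-instance lower bound computed from the score matrix and table.
#' @param candidates number of DP seeds for the search stage.
#' @param seed integer seed for the candidate sampling.
#' @param min_separation sequence-separation floor of the global term.
#' @return list with `alignment` (`A_O`), `breakdown` (a
#'   [score_breakdown()]), `provenance` (`"easy"` or `"searched"`),
#'   `dp_alignment` (`A_L`), `dp_normalized` (its normalized local score)
#'   and `n_candidates`.
#' @export
thread <- function(query, template, table, theta = -87, omega_L = 0.0047,
                   weights = local_weights(), params = search_params(),
                   candidates = 100L, seed = 1L, min_separation = 2L) {
  if (is.null(template$ss)) template <- derive_template_features(template)
  W <- position_score_matrix(template, query, weights)
  opt <- dp_optimal(template, query, weights, W = W)
  if (opt$normalized < theta) {
    return(list(alignment = opt$alignment,
                breakdown = score_breakdown(opt$alignment, template, query,
                                            weights, table, omega_L),
                provenance = "easy",
                dp_alignment = opt$alignment, dp_normalized = opt$normalized,
                n_candidates = 0L))
  }
  seeds <- dp_candidates(template, query, weights, count = candidates,
                         seed = seed, W = W)
  memo <- new.env(parent = emptyenv())
  score_fn <- function(a) {
    key <- alignment_key(a)
    if (exists(key, envir = memo)) return(get(key, envir = memo))
    k <- match_size(a)
    val <- if (k == 0L) Inf else
      omega_L * local_score(a, template, query, weights, W = W) +
        global_score(a, template, query, table, min_separation)
    assign(key, val, envir = memo)
    val
  }
  ## per-instance lower bound for the positivity shift
  atoms_sq <- if (table$scheme == "cb") 1 else length(BACKBONE_ATOMS)^2
  lb <- omega_L * min(0, min(W)) +
    min(0, min(table$energies)) * atoms_sq * min(template$m, query$n)
  params$score_shift <- lb
  best <- NULL; best_score <- Inf
  for (s in seeds) {
    if (!is.finite(score_fn(s))) next
    res <- local_search(s, score_fn, params)
    sc <- attr(res, "score")
    if (sc < best_score ||
        (sc == best_score && !is.null(best) && lex_less(res$map, best$map))) {
      best <- res; best_score <- sc
    }
  }
  if (is.null(best)) {
    ## every seed lacked match states (degenerate instance): fall back to A_L
    best <- opt$alignment
  }
  list(alignment = best,
       breakdown = score_breakdown(best, template, query, weights,
                                   table, omega_L),
       provenance = "searched",
       dp_alignment = opt$alignment, dp_normalized = opt$normalized,
       n_candidates = length(seeds))
}
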