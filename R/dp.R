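## Three-state affine-gap dynamic programming over the alignment space.
## States: M (template position matched), D (template position unmatched =
## gap in the query row), I (query position skipped = gap in the template
## row). A gap run of length L costs w_go + L * w_ge, matching count_gaps();
## with free_query_ends, I runs before any or after all template consumption
## are free. The DP minimizes the *raw* (unnormalized) local score; the
## normalized score is reported alongside since the theta gate compares
## normalized values.

dp_matrices <- function(W, weights) {
  m <- nrow(W); n <- ncol(W)
  open <- weights$w_go + weights$w_ge
  ext <- weights$w_ge
  free <- weights$free_query_ends
  BIG <- Inf
  M <- D <- I <- matrix(BIG, m + 1, n + 1)
  M[1, 1] <- 0
  iopen <- function(i) if (free && (i == 0L || i == m)) 0 else open
  iext <- function(i) if (free && (i == 0L || i == m)) 0 else ext
  for (ii in 1:(m + 1)) {
    i <- ii - 1L
    for (jj in 1:(n + 1)) {
      j <- jj - 1L
      if (i >= 1L) {
        D[ii, jj] <- min(M[ii - 1, jj] + open, I[ii - 1, jj] + open,
                         D[ii - 1, jj] + ext)
      }
      if (j >= 1L) {
        I[ii, jj] <- min(M[ii, jj - 1] + iopen(i), D[ii, jj - 1] + iopen(i),
                         I[ii, jj - 1] + iext(i))
      }
      if (i >= 1L && j >= 1L) {
        M[ii, jj] <- W[i, j] + min(M[ii - 1, jj - 1], D[ii - 1, jj - 1],
                                   I[ii - 1, jj - 1])
      }
    }
  }
  list(M = M, D = D, I = I, open = open, ext = ext, free = free,
       m = m, n = n, iopen = iopen, iext = iext)
}

## convert a forward move list (rows of type/i/j) to an alignment mapping
moves_to_map <- function(moves, m, n) {
  map <- integer(m)
  last <- 0L
  for (r in seq_len(nrow(moves))) {
    ty <- moves$type[r]; i <- moves$i[r]; j <- moves$j[r]
    if (ty == "M") { map[i] <- j; last <- j }
    else if (ty == "D") map[i] <- last
  }
  alignment_map(map, n)
}

## deterministic traceback; tie order M > D > I ("prefer match, then
## template gap, then query gap")
dp_traceback <- function(dp, W) {
  m <- dp$m; n <- dp$n
  finals <- c(M = dp$M[m + 1, n + 1], D = dp$D[m + 1, n + 1],
              I = dp$I[m + 1, n + 1])
  state <- names(finals)[which.min(finals)]
  i <- m; j <- n
  moves <- list()
  while (i > 0L || j > 0L) {
    moves[[length(moves) + 1L]] <- list(type = state, i = i, j = j)
    if (state == "M") {
      target <- dp$M[i + 1, j + 1] - W[i, j]
      prev <- c(M = dp$M[i, j], D = dp$D[i, j], I = dp$I[i, j])
      i <- i - 1L; j <- j - 1L
    } else if (state == "D") {
      prev <- c(M = dp$M[i, j + 1] + dp$open, D = dp$D[i, j + 1] + dp$ext,
                I = dp$I[i, j + 1] + dp$open)
      target <- dp$D[i + 1, j + 1]
      i <- i - 1L
    } else {
      prev <- c(M = dp$M[i + 1, j] + dp$iopen(i), D = dp$D[i + 1, j] + dp$iopen(i),
                I = dp$I[i + 1, j] + dp$iext(i))
      target <- dp$I[i + 1, j + 1]
      j <- j - 1L
    }
    if (i == 0L && j == 0L) break
    tol <- 1e-9 * max(1, abs(target))
    ok <- names(prev)[is.finite(prev) & abs(prev - target) < tol]
    state <- ok[1]  # M, D, I order
  }
  df <- do.call(rbind, lapply(rev(moves), as.data.frame))
  df$type <- as.character(df$type)
  df
}

#' Optimal local-score alignment by dynamic programming
#'
#' Computes `argmin` of the raw (unnormalized) local score under the affine
#' gap model, with deterministic tie-breaking (match preferred over template
#' gap over query gap).
#'
#' @param template annotated `template`.
#' @param query a `query_profile`.
#' @param weights a `local_weights`.
#' @param W optional precomputed [position_score_matrix()].
#' @return list with `alignment` (an `alignment_map`), `raw` (optimal raw
#'   score) and `normalized` (raw / match-state size; `+Inf` if the optimum
#'   has no match states).
#' @export
dp_optimal <- function(template, query, weights = local_weights(), W = NULL) {
  if (is.null(W)) W <- position_score_matrix(template, query, weights)
  dp <- dp_matrices(W, weights)
  moves <- dp_traceback(dp, W)
  a <- moves_to_map(moves, dp$m, dp$n)
  raw <- min(dp$M[dp$m + 1, dp$n + 1], dp$D[dp$m + 1, dp$n + 1],
             dp$I[dp$m + 1, dp$n + 1])
  k <- match_size(a)
  list(alignment = a, raw = raw,
       normalized = if (k > 0) raw / k else Inf)
}

logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  mx <- max(x)
  if (!is.finite(mx)) return(-Inf)
  mx + log(sum(exp(x - mx)))
}

## log partition matrices for Boltzmann-weighted paths at temperature tau
dp_partition <- function(W, weights, tau) {
  m <- nrow(W); n <- ncol(W)
  open <- weights$w_go + weights$w_ge
  ext <- weights$w_ge
  free <- weights$free_query_ends
  iopen <- function(i) if (free && (i == 0L || i == m)) 0 else open
  iext <- function(i) if (free && (i == 0L || i == m)) 0 else ext
  M <- D <- I <- matrix(-Inf, m + 1, n + 1)
  M[1, 1] <- 0
  for (ii in 1:(m + 1)) {
    i <- ii - 1L
    for (jj in 1:(n + 1)) {
      j <- jj - 1L
      if (i >= 1L)
        D[ii, jj] <- logsumexp(c(M[ii - 1, jj] - open / tau,
                                 I[ii - 1, jj] - open / tau,
                                 D[ii - 1, jj] - ext / tau))
      if (j >= 1L)
        I[ii, jj] <- logsumexp(c(M[ii, jj - 1] - iopen(i) / tau,
                                 D[ii, jj - 1] - iopen(i) / tau,
                                 I[ii, jj - 1] - iext(i) / tau))
      if (i >= 1L && j >= 1L)
        M[ii, jj] <- -W[i, j] / tau +
          logsumexp(c(M[ii - 1, jj - 1], D[ii - 1, jj - 1], I[ii - 1, jj - 1]))
    }
  }
  list(M = M, D = D, I = I, iopen = iopen, iext = iext,
       open = open, ext = ext, m = m, n = n, tau = tau)
}

sample_path <- function(pp, W) {
  m <- pp$m; n <- pp$n; tau <- pp$tau
  pick <- function(logw, labels) {
    mx <- max(logw)
    if (!is.finite(mx)) return(labels[1])
    p <- exp(logw - mx); p <- p / sum(p)
    labels[sample.int(length(labels), 1L, prob = p)]
  }
  state <- pick(c(pp$M[m + 1, n + 1], pp$D[m + 1, n + 1], pp$I[m + 1, n + 1]),
                c("M", "D", "I"))
  i <- m; j <- n
  moves <- list()
  while (i > 0L || j > 0L) {
    moves[[length(moves) + 1L]] <- list(type = state, i = i, j = j)
    if (state == "M") {
      lw <- c(M = pp$M[i, j], D = pp$D[i, j], I = pp$I[i, j])
      i <- i - 1L; j <- j - 1L
    } else if (state == "D") {
      lw <- c(M = pp$M[i, j + 1] - pp$open / tau,
              D = pp$D[i, j + 1] - pp$ext / tau,
              I = pp$I[i, j + 1] - pp$open / tau)
      i <- i - 1L
    } else {
      lw <- c(M = pp$M[i + 1, j] - pp$iopen(i) / tau,
              D = pp$D[i + 1, j] - pp$iopen(i) / tau,
              I = pp$I[i + 1, j] - pp$iext(i) / tau)
      j <- j - 1L
    }
    if (i == 0L && j == 0L) break
    state <- pick(lw, names(lw))
  }
  df <- do.call(rbind, lapply(rev(moves), as.data.frame))
  df$type <- as.character(df$type)
  df
}

#' Suboptimal alignment candidates from the dynamic programming table
#'
#' Draws Boltzmann-weighted suboptimal paths through the DP table by
#' seeded stochastic traceback at a fixed temperature, de-duplicates them,
#' always includes the exact optimum, and returns the `count` best by raw
#' local score (best first). Tiny instances with fewer distinct alignments
#' than `count` return everything reachable.
#'
#' @inheritParams dp_optimal
#' @param count maximum number of candidates.
#' @param seed integer seed for the stochastic traceback.
#' @param temperature Boltzmann temperature on the raw-score scale.
#' @param oversample how many paths to draw per requested candidate.
#' @return list of `alignment_map`s with attribute `scores` (raw local
#'   scores, non-decreasing).
#' @export
dp_candidates <- function(template, query, weights = local_weights(),
                          count = 100L, seed = 1L, temperature = 1,
                          W = NULL, oversample = 6L) {
  if (count < 1L) stopf("count must be >= 1")
  if (is.null(W)) W <- position_score_matrix(template, query, weights)
  best <- dp_optimal(template, query, weights, W = W)
  pp <- dp_partition(W, weights, temperature)
  seen <- new.env(parent = emptyenv())
  out <- list(best$alignment)
  assign(alignment_key(best$alignment), TRUE, envir = seen)
  with_seed(seed, {
    for (draw in seq_len(count * oversample)) {
      a <- moves_to_map(sample_path(pp, W), pp$m, pp$n)
      key <- alignment_key(a)
      if (!exists(key, envir = seen)) {
        assign(key, TRUE, envir = seen)
        out[[length(out) + 1L]] <- a
      }
      if (length(out) >= 3L * count) break
    }
  })
  scores <- vapply(out, local_score_raw, numeric(1),
                   template = template, query = query, weights = weights, W = W)
  ord <- order(scores)
  keep <- ord[seq_len(min(count, length(out)))]
  res <- out[keep]
  attr(res, "scores") <- scores[keep]
  res
}
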