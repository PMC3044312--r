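#' Local score weights
#'
#' Weights of the local score components: mutation (profile) score,
#' secondary-structure agreement, burial agreement, structural-alphabet
#' agreement, and the affine gap model (gap-open, gap-extend). The shipped
#' defaults are working placeholders on the package's own score scale and
#' are fully overridable (from code or a JSON config via
#' [read_local_weights()]).
#'
#' @param w_m,w_ss,w_cle,w_sa non-negative component weights.
#' @param w_go,w_ge non-negative gap-open / gap-extend weights.
#' @param free_query_ends logical, passed to [count_gaps()].
#' @return object of class `local_weights`.
#' @export
local_weights <- function(w_m = 1, w_ss = 0.5, w_cle = 0.5, w_sa = 0.2,
                          w_go = 3, w_ge = 0.5, free_query_ends = TRUE) {
  w <- list(w_m = w_m, w_ss = w_ss, w_cle = w_cle, w_sa = w_sa,
            w_go = w_go, w_ge = w_ge, free_query_ends = isTRUE(free_query_ends))
  num <- unlist(w[1:6])
  if (any(!is.finite(num))) stopf("weights must be finite")
  if (w$w_go < 0 || w$w_ge < 0) stopf("gap weights must be non-negative")
  structure(w, class = "local_weights")
}

#' Read / write local weights as JSON
#' @param path JSON file with any subset of the weight fields.
#' @return a `local_weights`.
#' @export
read_local_weights <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(local_weights, cfg[names(cfg) %in%
                             names(formals(local_weights))])
}

#' @rdname read_local_weights
#' @param weights a `local_weights`.
#' @export
write_local_weights <- function(weights, path) {
  jsonlite::write_json(unclass(weights), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

## CLE substitution fallback: identity matrix over the structural alphabet;
## '-' (undefined) matches nothing.
cle_substitution <- function(a, b) as.numeric(a == b & a != "-")

#' Per-position local score components
#'
#' Components of aligning template position `t` to query position `s`,
#' under the package's minimization convention (lower is better):
#' mutation = -profile\[s, aa(template, t)\] (0 when the template residue is
#' unknown), ss = 0 on agreement else 1, sa likewise, and
#' cle = -substitution(template cle letter, predicted query cle letter)
#' with an identity fallback matrix.
#'
#' @param t,s 1-based template and query positions.
#' @param template annotated `template`.
#' @param query a `query_profile`.
#' @return named numeric vector `c(mutation, ss, sa, cle)`.
#' @export
position_local_score <- function(t, s, template, query) {
  if (t < 1L || t > template$m) stopf("template position %d out of range", t)
  if (s < 1L || s > query$n) stopf("query position %d out of range", s)
  if (is.null(template$ss)) template <- derive_template_features(template)
  taa <- template$aa[t]
  mutation <- if (taa %in% AA_ORDER) -unname(query$profile[s, taa]) else 0
  ss <- as.numeric(substr(template$ss, t, t) != substr(query$predicted_ss, s, s))
  sa <- as.numeric(substr(template$burial, t, t) !=
                   substr(query$predicted_burial, s, s))
  cle <- -cle_substitution(substr(template$cle, t, t),
                           substr(query$predicted_cle, s, s))
  c(mutation = mutation, ss = ss, sa = sa, cle = cle)
}

#' Weighted per-position score matrix
#'
#' The m x n matrix of weighted local scores for every (t, s) pair: the
#' quantity summed over match states by [local_score()] and minimized by
#' the dynamic program.
#'
#' @param template annotated `template`.
#' @param query a `query_profile`.
#' @param weights a `local_weights`.
#' @return m x n numeric matrix.
#' @export
position_score_matrix <- function(template, query, weights) {
  if (is.null(template$ss)) template <- derive_template_features(template)
  m <- template$m; n <- query$n
  known <- template$aa %in% AA_ORDER
  mut <- matrix(0, m, n)
  if (any(known))
    mut[known, ] <- -t(query$profile[, template$aa[known], drop = FALSE])
  tss <- chars(template$ss); qss <- chars(query$predicted_ss)
  tsa <- chars(template$burial); qsa <- chars(query$predicted_burial)
  tcl <- chars(template$cle); qcl <- chars(query$predicted_cle)
  ss <- outer(tss, qss, "!=") * 1
  sa <- outer(tsa, qsa, "!=") * 1
  cle <- -outer(tcl, qcl, function(a, b) as.numeric(a == b & a != "-"))
  weights$w_m * mut + weights$w_ss * ss + weights$w_sa * sa + weights$w_cle * cle
}

#' Normalized local score L(A)
#'
#' Sum of weighted per-position scores over match states plus the gap
#' penalty `w_go * GO + w_ge * GE`, divided by the match-state size.
#' Alignments without match states get the `+Inf` sentinel (worst score).
#'
#' @param a an `alignment_map`.
#' @param template annotated `template`.
#' @param query a `query_profile`.
#' @param weights a `local_weights`.
#' @param W optional precomputed [position_score_matrix()].
#' @return normalized local score (scalar).
#' @export
local_score <- function(a, template, query, weights = local_weights(),
                        W = NULL) {
  raw <- local_score_raw(a, template, query, weights, W)
  k <- match_size(a)
  if (k == 0L) return(Inf)
  raw / k
}

#' @rdname local_score
#' @return `local_score_raw()`: the unnormalized sum (0 match states give
#'   the bare gap penalty).
#' @export
local_score_raw <- function(a, template, query, weights = local_weights(),
                            W = NULL) {
  if (is.null(W)) W <- position_score_matrix(template, query, weights)
  ms <- match_states(a)
  g <- count_gaps(a, weights$free_query_ends)
  pos <- if (nrow(ms)) sum(W[cbind(ms$t, ms$s)]) else 0
  pos + weights$w_go * g$go + weights$w_ge * g$ge
}

#' Full score breakdown of an alignment
#'
#' Reports the unweighted component sums over match states, the gap counts,
#' the normalized local and global scores, and the combined objective
#' `omega_L * L(A) + G(A)`.
#'
#' @inheritParams local_score
#' @param table optional `pair_potential` for the global term.
#' @param omega_L weight of the local item in the combined score.
#' @return one-row data.frame of class `score_breakdown`.
#' @export
score_breakdown <- function(a, template, query, weights = local_weights(),
                            table = NULL, omega_L = 1) {
  ms <- match_states(a)
  k <- nrow(ms)
  comp <- c(mutation = 0, ss = 0, sa = 0, cle = 0)
  if (k > 0)
    comp <- rowSums(vapply(seq_len(k), function(i)
      position_local_score(ms$t[i], ms$s[i], template, query),
      c(mutation = 0, ss = 0, sa = 0, cle = 0)))
  g <- count_gaps(a, weights$free_query_ends)
  local_total <- local_score(a, template, query, weights)
  global_total <- if (!is.null(table))
    global_score(a, template, query, table) else NA_real_
  out <- data.frame(
    s_m = comp[["mutation"]], s_ss = comp[["ss"]], s_sa = comp[["sa"]],
    s_cle = comp[["cle"]], go = g$go, ge = g$ge, match_size = k,
    local_total = local_total, global_total = global_total,
    combined = if (is.na(global_total)) omega_L * local_total
               else omega_L * local_total + global_total)
  class(out) <- c("score_breakdown", class(out))
  out
}
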