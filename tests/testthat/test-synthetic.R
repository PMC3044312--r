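test_that("ideal structures are deterministic and geometrically sane", {
  a <- make_ideal_structure(15, "helix", seed = 42)
  b <- make_ideal_structure(15, "helix", seed = 42)
  expect_identical(a$xyz, b$xyz)
  expect_identical(a$seq, b$seq)
  c <- make_ideal_structure(15, "helix", seed = 43)
  expect_false(identical(a$seq, c$seq))
  ## bond lengths match the ideal constants everywhere
  g <- pdthread:::IDEAL_GEOM
  for (i in 1:15) {
    expect_equal(sqrt(sum((a$xyz$CA[i, ] - a$xyz$N[i, ])^2)), g$b_n_ca,
                 tolerance = 1e-9)
    expect_equal(sqrt(sum((a$xyz$C[i, ] - a$xyz$CA[i, ])^2)), g$b_ca_c,
                 tolerance = 1e-9)
    expect_equal(sqrt(sum((a$xyz$O[i, ] - a$xyz$C[i, ])^2)), g$b_c_o,
                 tolerance = 1e-9)
  }
  expect_error(make_ideal_structure(3, "helix"), "at least 4")
  expect_error(make_ideal_structure(10, "nope"), "unknown motif")
})

test_that("a helix is compact relative to a strand of equal length", {
  hel <- make_ideal_structure(16, "helix", seed = 1)
  str <- make_ideal_structure(16, "strand", seed = 1)
  span <- function(t) max(dist(t$xyz$CA))
  expect_lt(span(hel), span(str))
})

test_that("decoy sets perturb coordinates but keep sequence and geometry rules", {
  native <- make_ideal_structure(12, "mixed", seed = 44)
  decoys <- make_decoy_set(native, count = 5, noise_sigma = 1, seed = 9)
  expect_equal(length(decoys), 5L)
  for (d in decoys) {
    expect_identical(d$aa, native$aa)
    rmsd <- sqrt(mean(rowSums((d$xyz$CA - native$xyz$CA)^2)))
    expect_gt(rmsd, 0.2)
    expect_lt(rmsd, 6)
    ## CB stays ideal after re-idealization
    for (i in which(d$aa != "G"))
      expect_equal(sqrt(sum((d$xyz$CB[i, ] - d$xyz$CA[i, ])^2)), 1.521,
                   tolerance = 1e-6)
  }
  ## reproducible under the seed; noise grows with sigma
  decoys2 <- make_decoy_set(native, count = 5, noise_sigma = 1, seed = 9)
  expect_identical(decoys[[3]]$xyz, decoys2[[3]]$xyz)
  small <- make_decoy_set(native, count = 5, noise_sigma = 0.05, seed = 9)
  rms <- function(set) mean(vapply(set, function(d)
    sqrt(mean(rowSums((d$xyz$CA - native$xyz$CA)^2))), numeric(1)))
  expect_lt(rms(small), rms(decoys))
  expect_error(make_decoy_set(native, count = 0), "count")
  expect_error(make_decoy_set(native, noise_sigma = 0), "noise_sigma")
})

test_that("threading pairs plant a recoverable reference alignment", {
  pair <- make_threading_pair(seed = 45, m = 26, identity = 0.7,
                              n_delete = 4, noise_sigma = 0.2)
  expect_equal(pair$template$m, 26L)
  expect_equal(pair$query$n, 22L)
  expect_true(validate_alignment(pair$reference)$ok)
  ## the reference has exactly one template-side gap run of n_delete columns
  g <- count_gaps(pair$reference)
  expect_equal(g$go, 1L)
  expect_equal(g$ge, 4L)
  expect_equal(match_size(pair$reference), 22L)
  ## matched residues carry template coordinates up to the planted noise
  ms <- match_states(pair$reference)
  d <- sqrt(rowSums((pair$template$xyz$CA[ms$t, ] -
                       pair$query_structure$xyz$CA[ms$s, ])^2))
  expect_lt(max(d), 1.5)
  ## with full sequence identity the point-mass profile lets plain DP
  ## recover the reference exactly; mutations can cost a few positions
  easy <- make_threading_pair(seed = 45, m = 26, identity = 1,
                              n_delete = 4, noise_sigma = 0.2)
  opt <- dp_optimal(easy$template, easy$query, local_weights())
  expect_equal(alignment_accuracy(opt$alignment, easy$reference), 1)
  opt2 <- dp_optimal(pair$template, pair$query, local_weights())
  expect_gte(alignment_accuracy(opt2$alignment, pair$reference, 4),
             alignment_accuracy(opt2$alignment, pair$reference, 0))
  ## determinism
  pair2 <- make_threading_pair(seed = 45, m = 26, identity = 0.7,
                               n_delete = 4, noise_sigma = 0.2)
  expect_identical(pair$query$sequence, pair2$query$sequence)
  expect_identical(pair$reference$map, pair2$reference$map)
})

test_that("the rescue fixture is wired the way its contract promises", {
  fix <- make_rescue_pair()
  expect_equal(fix$template$m, 6L)
  expect_equal(fix$query$n, 6L)
  ## exactly one template residue pair within the potential cutoff
  d <- as.matrix(dist(pdthread:::cb_or_ca(fix$template)))
  close <- which(d > 0 & d < fix$table$r_cut, arr.ind = TRUE)
  close <- close[close[, 1] < close[, 2], , drop = FALSE]
  expect_equal(nrow(close), 1L)
  expect_equal(unname(close[1, ]), c(2L, 5L))
  ## under the identity alignment those two query residues are C and C,
  ## and the planted table rewards exactly that contact
  expect_identical(fix$query$aa[c(2, 5)], c("C", "C"))
  expect_lt(global_score(fix$reference, fix$template, fix$query, fix$table),
            0)
  ## the shifted local optimum scores better than the reference under L alone
  opt <- dp_optimal(fix$template, fix$query, fix$weights)
  expect_lt(opt$normalized,
            local_score(fix$reference, fix$template, fix$query, fix$weights))
})

test_that("PDB and PSSM fixture files reload into equivalent objects", {
  dir <- tempfile(); dir.create(dir)
  tmpl <- make_ideal_structure(10, "mixed", seed = 46,
                               path = file.path(dir, "t.pdb"))
  back <- read_pdb_template(file.path(dir, "t.pdb"))
  expect_identical(back$aa, tmpl$aa)
  expect_equal(back$xyz$CA, tmpl$xyz$CA, tolerance = 2e-3, ignore_attr = TRUE)
  pair <- make_threading_pair(seed = 47, m = 20)
  write_pssm(pair$query, file.path(dir, "q.pssm"))
  prof <- read_pssm(file.path(dir, "q.pssm"), sequence = pair$query$sequence)
  expect_equal(unname(prof), unname(pair$query$profile))
})
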