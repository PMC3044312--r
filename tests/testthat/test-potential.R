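test_that("pair_potential tables have the documented shape", {
  ra <- pair_potential("res_atom")
  expect_equal(length(ra$types), 100L)
  expect_equal(dim(ra$energies), c(100L, 100L, 30L))
  cb <- pair_potential("cb", r_cut = 12, n_bins = 24)
  expect_equal(length(cb$types), 20L)
  expect_equal(cb$bin_edges[1], 0)
  expect_equal(cb$bin_edges[25], 12)
})

test_that("decoy_energy is a plain sum of table lookups", {
  ## three residues; only the (1, 3) pair is within cutoff and separation
  pts <- rbind(c(0, 0, 0), c(1000, 0, 0), c(4.9, 0, 0))
  tmpl <- point_cloud_structure(pts, c("A", "A", "A"))
  q <- query_profile("ACD")
  a <- alignment_map(1:3, 3)
  table <- pair_potential("cb")                # bin width 0.5: 4.9 A = bin 10
  table$energies["A", "D", 10] <- -0.7
  table$energies["D", "A", 10] <- -0.7
  d <- build_partial_decoy(a, tmpl, q)
  expect_equal(decoy_energy(d, table), -0.7)
  expect_equal(global_score(a, tmpl, q, table), -0.7 / 3)
  ## raising min_separation excludes the pair
  expect_equal(decoy_energy(d, table, min_separation = 3), 0)
  ## single residue and beyond-cutoff cases
  one <- build_partial_decoy(alignment_map(c(1, 1, 1), 3), tmpl, q)
  expect_equal(decoy_energy(one, table), 0)
  far <- point_cloud_structure(rbind(c(0, 0, 0), c(50, 0, 0), c(100, 0, 0)),
                               c("A", "A", "A"))
  dfar <- build_partial_decoy(a, far, q)
  expect_equal(decoy_energy(dfar, table), 0)
  ## empty decoy: undefined-energy sentinel
  empty <- build_partial_decoy(alignment_map(rep(0, 3), 3), tmpl, q)
  expect_identical(decoy_energy(empty, table), Inf)
  expect_identical(global_score(alignment_map(rep(0, 3), 3), tmpl, q, table),
                   Inf)
})

test_that("decoy energy is invariant under rigid transforms", {
  tmpl <- toy_template(12, seed = 21)
  q <- toy_query(10, seed = 22)
  a <- alignment_map(c(0, 1, 2, 3, 3, 5, 6, 7, 9, 10, 10, 10), 10)
  set.seed(23)
  table <- pair_potential("res_atom")
  table$energies[] <- rnorm(length(table$energies), 0, 0.2)
  e0 <- global_score(a, tmpl, q, table)
  R <- pdthread:::rotation_matrix(c(3, 1, -2), 119)
  xyz <- lapply(tmpl$xyz, function(mat) {
    ok <- !is.na(mat[, 1])
    mat[ok, ] <- pdthread:::rigid_transform(mat[ok, , drop = FALSE], R,
                                            c(7, -13, 21))
    mat
  })
  moved <- new_template(tmpl$chain_id, tmpl$resno, tmpl$aa, xyz)
  expect_equal(global_score(a, moved, q, table), e0, tolerance = 1e-9)
})

test_that("the global score is the decoy energy normalized by match size", {
  tmpl <- toy_template(8, seed = 24)
  q <- toy_query(7, seed = 25)
  set.seed(26)
  table <- pair_potential("cb")
  table$energies[] <- rnorm(length(table$energies), 0, 0.3)
  for (trial in 1:20) {
    a <- rand_map_matched(8, 7)
    d <- build_partial_decoy(a, tmpl, q)
    expect_equal(global_score(a, tmpl, q, table),
                 decoy_energy(d, table) / match_size(a))
  }
  ## a zero table scores every alignment 0
  zero <- pair_potential("cb")
  expect_equal(global_score(alignment_map(1:8, 8), toy_template(8, seed = 24),
                            toy_query(8, seed = 31), zero), 0)
})

test_that("estimated potentials are symmetric with zero rows when unobserved", {
  set.seed(27)
  pts <- matrix(rnorm(3 * 40, 0, 5), 40, 3)
  st <- point_cloud_structure(pts, sample(c("A", "C", "D"), 40, TRUE))
  tab <- estimate_potential(list(st), pair_potential("cb"))
  expect_equal(tab$energies, aperm(tab$energies, c(2, 1, 3)))
  expect_true(all(tab$energies[, "W", ] == 0))   # W never observed
  expect_true(any(tab$energies["A", "C", ] != 0))
  expect_error(estimate_potential(list()), "at least one structure")
})

test_that("planted distance enrichment yields negative estimated energies", {
  ## A-A pairs heavily enriched in the 4.5-5.0 A bin against a sparse
  ## background in three other bins (the last is the reference bin)
  distances <- c(rep(4.75, 25), rep(8.25, 5), rep(11.25, 5), rep(14.75, 5))
  structures <- lapply(1:10, function(i) comb_structure(distances))
  tab <- estimate_potential(structures, pair_potential("cb"),
                            min_separation = 2L)
  e_aa <- tab$energies["A", "A", ]
  expect_lt(e_aa[10], 0)                       # the enriched 4.5-5.0 bin
  expect_equal(which.min(e_aa), 10L)
  ## the background bins with equal counts order by the reference-state
  ## volume factor: closer bins get lower energy at equal occupancy
  expect_lt(e_aa[17], e_aa[23])                # 8.25 A vs 11.25 A bin
})

test_that("potential tables round-trip through the TSV serialization", {
  set.seed(29)
  tab <- pair_potential("cb", r_cut = 10, n_bins = 20, alpha_exp = 1.4,
                        eta = 0.02)
  idx <- cbind(sample(20, 50, TRUE), sample(20, 50, TRUE), sample(20, 50, TRUE))
  tab$energies[idx] <- round(rnorm(50), 6)
  path <- tempfile(fileext = ".tsv")
  write_potential(tab, path)
  got <- read_potential(path)
  expect_identical(got$scheme, "cb")
  expect_equal(got$r_cut, 10)
  expect_equal(got$n_bins, 20L)
  expect_equal(got$alpha_exp, 1.4)
  expect_equal(got$eta, 0.02)
  expect_equal(got$energies, tab$energies)
})

test_that("contact maps and the contact-preference baseline do the arithmetic", {
  pts <- rbind(c(0, 0, 0), c(100, 0, 0), c(200, 0, 0), c(300, 0, 0),
               c(0, 5, 0))                     # residues 1 and 5 in contact
  tmpl <- point_cloud_structure(pts, rep("A", 5))
  cm <- contact_map(tmpl, cutoff = 8, min_separation = 4)
  expect_true(cm[1, 5] && cm[5, 1])
  expect_equal(sum(cm), 2)
  ## adjacent residues never contact even when close
  pts2 <- rbind(c(0, 0, 0), c(3, 0, 0), c(6, 0, 0), c(9, 0, 0), c(12, 0, 0))
  cm2 <- contact_map(point_cloud_structure(pts2, rep("A", 5)),
                     cutoff = 8, min_separation = 4)
  expect_equal(sum(cm2), 0)
  ## point-mass profiles make the preference score a single matrix entry
  C <- matrix(0, 20, 20)
  C[1, 5] <- C[5, 1] <- 2                      # A-C preference
  model <- contact_model(C, cutoff = 8, min_separation = 4)
  prof <- matrix(0, 5, 20)
  prof[, 1] <- -1000
  prof[1, 1] <- 1000                           # position 1 is surely A
  prof[5, 5] <- 1000                           # position 5 is surely C
  q <- query_profile("AAAAC", profile = prof)
  a <- alignment_map(1:5, 5)
  expect_equal(contact_preference_score(a, tmpl, q, model), -2 / 5,
               tolerance = 1e-9)
  ## unmatched contact ends contribute nothing
  a2 <- alignment_map(c(1, 2, 3, 4, 4), 5)     # residue 5 is not a match
  expect_equal(contact_preference_score(a2, tmpl, q, model), 0)
  expect_identical(contact_preference_score(alignment_map(rep(0, 5), 5),
                                            tmpl, q, model), Inf)
  expect_error(contact_model(matrix(rnorm(400), 20, 20)), "symmetric")
})

test_that("profile probabilities are row-stochastic softmaxes", {
  q <- toy_query(6, seed = 30)
  P <- profile_probabilities(q)
  expect_equal(rowSums(P), rep(1, 6))
  expect_true(all(P > 0))
  ## an overwhelming log-odds entry becomes a point mass
  q$profile[2, ] <- 0; q$profile[2, 7] <- 1000
  P2 <- profile_probabilities(q)
  expect_equal(unname(P2[2, 7]), 1)
})
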