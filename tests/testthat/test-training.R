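test_that("training points encode the pairwise separation inequality", {
  pts <- training_points(L_pos = -5, G_pos = -2,
                         L_neg = c(-3, -6), G_neg = c(-1, -2.5),
                         pair_id = "p1")
  expect_equal(pts$x, c(-2, 1))
  expect_equal(pts$y, c(1, -0.5))
  expect_error(training_points(-5, -2, numeric(0), numeric(0)),
               "at least one negative")
})

test_that("train_omega solves a hand-checkable instance", {
  ## omega < 0.5 satisfies the first two points, nothing satisfies the third
  pts <- data.frame(x = c(1, 1, 2), y = c(1, 0.5, -1))
  res <- train_omega(pts)
  expect_equal(res$H, 2L)
  expect_lt(res$omega, 0.5)
  expect_gt(res$omega, 0)
  expect_equal(sum(res$omega * pts$x < pts$y), res$H)
  ## all-hopeless set: warns and reports zero
  expect_warning(res0 <- train_omega(data.frame(x = c(1, 2), y = c(-1, -1))),
                 "no positive slope")
  expect_equal(res0$H, 0L)
})

test_that("train_omega matches a dense grid on lattice-valued points", {
  ## integer-valued points make the candidate slopes well separated, so a
  ## sufficiently fine grid provably attains the exact maximum
  set.seed(81)
  for (trial in 1:20) {
    np <- sample(5:15, 1)
    pts <- data.frame(x = sample(-6:6, np, replace = TRUE),
                      y = sample(-6:6, np, replace = TRUE))
    res <- train_omega(pts)
    grid <- seq(1e-4, 7, length.out = 20000)
    grid_best <- max(vapply(grid, function(w) sum(w * pts$x < pts$y),
                            numeric(1)))
    got <- suppressWarnings(train_omega(pts))
    expect_equal(got$H, as.integer(grid_best))
    expect_equal(sum(got$omega * pts$x < pts$y), got$H)
    expect_gt(got$omega, 0)
  }
})

test_that("negative selection clusters by overlap and respects the quality gap", {
  base <- alignment_map(1:6, 6)
  near <- alignment_map(c(1, 2, 3, 4, 5, 5), 6)   # 5 shared matches of 6
  far1 <- alignment_map(c(0, 0, 1, 2, 3, 4), 6)
  far2 <- alignment_map(c(2, 3, 4, 5, 6, 6), 6)
  cands <- list(base, near, far1, far2)
  quals <- c(0.9, 0.85, 0.3, 0.4)
  sel <- select_negatives(cands, quals, reference_quality = 0.9,
                          count = 10, similarity_threshold = 0.8,
                          quality_gap = 0.2, seed = 3)
  ## near is clustered into base; base/near fail the quality gap
  keys <- key_set(sel)
  expect_identical(keys, key_set(list(far1, far2)))
  expect_equal(sort(attr(sel, "quality")), c(0.3, 0.4))
  expect_warning(sel0 <- select_negatives(cands, quals, reference_quality = 0.4),
                 "no eligible")
  expect_equal(length(sel0), 0L)
  ## sampling under a seed is reproducible
  many <- lapply(0:6, function(i) alignment_map(1:6 + i, 12))
  q2 <- rep(0.1, length(many))
  s1 <- select_negatives(many, q2, 0.9, count = 4, seed = 11)
  s2 <- select_negatives(many, q2, 0.9, count = 4, seed = 11)
  expect_identical(key_set(s1), key_set(s2))
  expect_equal(length(s1), 4L)
})

test_that("select_theta applies the cumulative-mean gap rule", {
  rec <- data.frame(L = c(-100, -95, -90, -80), gap = c(0, 0.05, 0.1, 0.3))
  ## running means: 0, .025, .05, .1125 -> first failure at the 4th record
  expect_equal(select_theta(rec, gap_limit = 0.1), -90)
  ## never failing: the largest L
  rec2 <- data.frame(L = c(-5, -9, -7), gap = c(0.01, 0, 0.02))
  expect_equal(select_theta(rec2, gap_limit = 0.1), -5)
  ## failing immediately: -Inf
  rec3 <- data.frame(L = c(-9, -5), gap = c(0.5, 0))
  expect_identical(select_theta(rec3, gap_limit = 0.1), -Inf)
  expect_error(select_theta(data.frame(L = 1, gap = 0)), "at least two")
})

test_that("the TM-score kernel has its closed-form landmarks", {
  expect_equal(pdthread:::tm_d0(15), 0.5)
  expect_equal(pdthread:::tm_d0(100), 1.24 * 85^(1 / 3) - 1.8)
  d0 <- pdthread:::tm_d0(40)
  expect_equal(tm_score_from_distances(rep(0, 40), 40), 1)
  expect_equal(tm_score_from_distances(rep(d0, 40), 40), 0.5)
  expect_equal(tm_score_from_distances(rep(0, 20), 40), 0.5)
})

test_that("tm_quality is 1 on self and rigidly moved self-pairs", {
  tmpl <- make_ideal_structure(20, "mixed", seed = 82)
  a <- alignment_map(1:20, 20)
  expect_equal(tm_quality(a, tmpl, tmpl), 1, tolerance = 1e-9)
  R <- pdthread:::rotation_matrix(c(0, 1, 1), 142)
  xyz <- lapply(tmpl$xyz, function(mat) {
    ok <- !is.na(mat[, 1])
    mat[ok, ] <- pdthread:::rigid_transform(mat[ok, , drop = FALSE], R,
                                            c(4, 44, -4))
    mat
  })
  moved <- new_template("A", tmpl$resno, tmpl$aa, xyz)
  expect_equal(tm_quality(a, moved, tmpl), 1, tolerance = 1e-6)
  expect_error(tm_quality(alignment_map(c(1, 1, 1, rep(1, 17)), 20),
                          tmpl, tmpl), "at least 3 match states")
})

test_that("tm_quality penalizes wrong alignments of the same structures", {
  pair <- make_threading_pair(seed = 83, m = 24, n_delete = 2,
                              noise_sigma = 0.2)
  good <- tm_quality(pair$reference, pair$query_structure, pair$template)
  shifted_map <- pmax(pair$reference$map - 5, 0)
  bad <- tm_quality(alignment_map(shifted_map, pair$reference$n),
                    pair$query_structure, pair$template)
  ## d0 is small at this length, so even 0.2 A noise caps the score well
  ## below 1; the shifted alignment must still score clearly worse
  expect_gt(good, 0.6)
  expect_gt(good, bad)
})

test_that("partial discrimination separates a native from scaled decoys", {
  ## a two-band table that rewards native-like short distances
  set.seed(84)
  native <- point_cloud_structure(matrix(rnorm(36, 0, 2.2), 12, 3),
                                  rep("A", 12))
  decoys <- lapply(1:8, function(i)
    point_cloud_structure(native$xyz$CB * 2.2 +
                            matrix(rnorm(36, 0, 0.1), 12, 3),
                          rep("A", 12)))
  table <- pair_potential("cb")
  table$energies[, , 1:15] <- -1               # < 7.5 A: favorable
  table$energies[, , 16:30] <- 1
  res <- partial_discrimination(native, decoys, table,
                                keep_fractions = c(1, 0.75, 0.5),
                                trials = 6, seed = 7)
  expect_equal(res$accuracy, c(1, 1, 1))
  ## bit-reproducible under the seed
  res2 <- partial_discrimination(native, decoys, table,
                                 keep_fractions = c(1, 0.75, 0.5),
                                 trials = 6, seed = 7)
  expect_identical(res, res2)
  expect_error(partial_discrimination(native, list(), table), "at least one")
})
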