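test_that("mc_score identities and the worked two-cluster example hold", {
  a <- matrix(c(0, 0, 2, 0), ncol = 2, byrow = TRUE)
  b <- matrix(c(10, 0, 12, 0), ncol = 2, byrow = TRUE)
  s <- mc_score(a, b, standardize = FALSE)
  expect_equal(s$dist_inter, 10)
  expect_equal(s$dist_intra_1, 2)
  expect_equal(s$dist_intra_2, 2)
  expect_equal(s$score, exp(-10), tolerance = 1e-12)
  # identical clusters -> 1
  expect_equal(mc_score(a, a, standardize = FALSE)$score, 1)
  # two distinct singletons -> degenerate 0; coincident singletons -> 1
  expect_equal(mc_score(rbind(c(0, 0)), rbind(c(1, 1)),
                        standardize = FALSE)$score, 0)
  expect_equal(mc_score(rbind(c(1, 1)), rbind(c(1, 1)),
                        standardize = FALSE)$score, 1)
  expect_error(mc_score(a, matrix(0, 2, 3)), "dimensions differ")
})

test_that("mc_score is symmetric, permutation-invariant and monotone", {
  set.seed(2)
  a <- matrix(rnorm(40), ncol = 4)
  b <- matrix(rnorm(40, 2), ncol = 4)
  expect_equal(mc_score(a, b)$score, mc_score(b, a)$score)
  perm <- sample(4)
  expect_equal(mc_score(a[, perm], b[, perm], standardize = FALSE)$score,
               mc_score(a, b, standardize = FALSE)$score)
  # increasing inter-center distance with intra spread fixed lowers it
  shifts <- c(0.5, 1, 2, 4, 8)
  scores <- vapply(shifts, function(s)
    mc_score(a, sweep(a, 2, rep(s, 4), "+"), standardize = FALSE)$score,
    numeric(1))
  expect_true(all(diff(scores) < 0))
})

test_that("score_matrix is symmetric with unit diagonal; ratios behave", {
  set.seed(3)
  groups <- lapply(1:4, function(i) matrix(rnorm(60, i), ncol = 3))
  m <- score_matrix(groups)
  expect_equal(unclass(m), t(unclass(m)), ignore_attr = TRUE)
  expect_equal(diag(m), rep(1, 4), ignore_attr = TRUE)
  # identical groups: all scores 1, all ratios 1
  same <- lapply(1:3, function(i) groups[[1]])
  ms <- score_matrix(same)
  expect_equal(as.numeric(ms), rep(1, 9))
  r <- ratio_matrix(ms, ms)
  expect_equal(as.numeric(r$ratio), rep(1, 9))
  # zero m-score entries are flagged undefined
  r2 <- ratio_matrix(ms, ms * 0)
  expect_true(all(is.na(r2$ratio[row(r2$ratio) != col(r2$ratio)])))
})

test_that("c/m ratios fall below 1 for same-morphology, distinct-target groups", {
  tp <- toy_panel(n_per = 6, seed = 31)
  atlas <- tp$atlas
  targets <- list(2L, 3L, 502L, 503L, c(2L, 3L), c(2L, 502L))
  neurons <- list()
  key <- character(0)
  for (g in seq_along(targets)) {
    for (i in 1:6) {
      id <- sprintf("g%d_n%d", g, i)
      neurons[[id]] <- resample_morphology(grow_neuron(
        toy_spec(1L, paste0("g", g), targets[[g]]), atlas,
        seed = 7000 + 97 * g + i, neuron_id = id), 10)
      key <- c(key, paste0("g", g))
    }
  }
  mfeat <- feature_table(neurons, compartment = "dendrite")
  fcols <- c("tips", "total_length", "max_path_distance",
             "n_bifurcations", "max_branch_order",
             "avg_bifurcation_angle_remote")
  conn <- connectivity_matrix(neurons, tp$panel, atlas, alpha = 3)
  m_groups <- lapply(split(seq_along(key), key), function(i)
    as.matrix(mfeat[i, fcols]))
  c_groups <- lapply(split(seq_along(key), key), function(i)
    barcode_matrix(conn)[i, , drop = FALSE])
  rat <- ratio_matrix(score_matrix(c_groups), score_matrix(m_groups))
  expect_gt(rat$frac_lt_1, 0.9)
})

test_that("anatomy distance reduces to squared Euclidean under identity", {
  d <- anatomy_distance(rbind(c(0, 0, 0), c(3, 4, 0)), diag(3))
  expect_equal(d[1, 2], 25)
  expect_equal(diag(d), c(0, 0), ignore_attr = TRUE)
  # translation invariance
  set.seed(4)
  s <- matrix(rnorm(30), ncol = 3)
  cv <- crossprod(matrix(rnorm(9), 3)) + diag(0.5, 3)
  expect_equal(anatomy_distance(s, cv),
               anatomy_distance(sweep(s, 2, c(5, -2, 7), "+"), cv))
  # sqrt mode
  expect_equal(anatomy_distance(rbind(c(0, 0, 0), c(3, 4, 0)), diag(3),
                                sqrt = TRUE)[1, 2], 5)
})

test_that("soma distance maps mirror somas before measuring", {
  atlas <- toy_atlas()
  p <- c(200, 300, 150)
  somas <- rbind(a = p, b = mirror_point(rbind(p), atlas)[1, ])
  d <- soma_distance_map(somas, 1L, atlas)
  expect_equal(d[1, 2], 0)
  expect_equal(attr(d, "mirrored"), TRUE)
  # two distinct somas give a symmetric nonnegative map with zero diagonal
  somas2 <- rbind(a = c(200, 300, 150), b = c(230, 280, 160),
                  c = c(210, 310, 140))
  d2 <- soma_distance_map(somas2, 1L, atlas)
  expect_equal(unclass(d2), t(unclass(d2)), ignore_attr = TRUE)
  expect_true(all(d2 >= 0))
})

test_that("dmap-similarity correlations behave as designed", {
  set.seed(6)
  n <- 35
  x <- matrix(rnorm(3 * n), ncol = 3)
  dmap <- as.matrix(dist(x))^2
  sim <- exp(-dmap / stats::median(dmap))
  expect_lt(dmap_similarity_correlation(dmap, sim), 0)
  expect_equal(dmap_similarity_correlation(dmap, dmap), 1)
  shuf <- sample(n)
  expect_lt(abs(dmap_similarity_correlation(dmap, sim[shuf, shuf])), 0.1)
  expect_warning(dmap_similarity_correlation(dmap, dmap * 0), "constant")
})

test_that("SVM overlap separates the separable and confuses the identical", {
  set.seed(7)
  a <- matrix(rnorm(100), ncol = 2)
  b <- matrix(rnorm(100), ncol = 2) + 25  # >= 5 sigma margin
  expect_equal(svm_overlap(a, b), 0)
  expect_message(o <- svm_overlap(a, a), "identical rows")
  expect_gt(o, 40)
  expect_lt(o, 60)
})

test_that("appending connectivity PCs shrinks pairwise SVM overlap", {
  tp <- toy_panel(n_per = 6, seed = 41)
  atlas <- tp$atlas
  targets <- list(2L, 3L, 502L)
  neurons <- list()
  key <- integer(0)
  for (g in 1:3) {
    for (i in 1:12) {
      id <- sprintf("s%d_n%d", g, i)
      neurons[[id]] <- resample_morphology(grow_neuron(
        toy_spec(1L, paste0("s", g), targets[[g]]), atlas,
        seed = 5000 + 131 * g + i, neuron_id = id), 10)
      key <- c(key, g)
    }
  }
  mfeat <- as.matrix(feature_table(neurons, "dendrite")[,
    c("total_length", "max_branch_order")])
  conn <- barcode_matrix(connectivity_matrix(neurons, tp$panel, atlas,
                                             alpha = 3))
  aug <- pca_augment(mfeat, conn, n_components = 3)
  pairs <- utils::combn(3, 2)
  before <- after <- numeric(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    i <- key == pairs[1, p]
    j <- key == pairs[2, p]
    before[p] <- svm_overlap(mfeat[i, ], mfeat[j, ])
    after[p] <- svm_overlap(aug[i, ], aug[j, ])
  }
  expect_lt(max(after), max(before))
  expect_true(all(after <= before))
})
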