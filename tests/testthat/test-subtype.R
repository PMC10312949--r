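# synthetic two-pattern barcode cohort with controllable soma segregation;
# segregation in [0, 1] slides the two soma clouds apart along y
synthetic_bundle_inputs <- function(n_per = 12, segregation = 1, seed = 1,
                                    noise = 0.15) {
  withr::with_seed(seed, {
    pattern <- rbind(c(10, 0, 2, 0, 0, 0), c(0, 0, 2, 10, 0, 0))
    b <- do.call(rbind, lapply(1:2, function(g)
      pmax(pattern[rep(g, n_per), ] +
             matrix(rnorm(6 * n_per, sd = noise * 10), ncol = 6), 0)))
    rownames(b) <- sprintf("n%02d", seq_len(2 * n_per))
    soma_y <- c(rnorm(n_per, 300 - 60 * segregation, 15),
                rnorm(n_per, 300 + 60 * segregation, 15))
    somas <- cbind(rnorm(2 * n_per, 200, 15), soma_y,
                   rnorm(2 * n_per, 150, 15))
    rownames(somas) <- rownames(b)
    list(barcodes = b, somas = somas,
         labels = rep(1:2, each = n_per))
  })
}

test_that("affinity bundle identities: MDA kernel, bounds, diagonal", {
  set.seed(5)
  b <- matrix(runif(60), ncol = 6)
  n <- nrow(b)
  # coincident somas: MD = 0 everywhere -> MDA = 1, A = MC
  dmap0 <- matrix(0, n, n)
  bun0 <- build_affinity(b, dmap0)
  expect_equal(bun0$MDA, matrix(1, n, n), ignore_attr = TRUE)
  expect_equal(unname(bun0$A[row(bun0$A) != col(bun0$A)]),
               unname(bun0$MC[row(bun0$MC) != col(bun0$MC)]))
  # spread somas: normalized MD hits 1 somewhere -> MDA entry exp(-1)
  dmap <- as.matrix(dist(matrix(rnorm(3 * n), ncol = 3)))^2
  bun <- build_affinity(b, dmap)
  expect_equal(min(bun$MDA[row(bun$MDA) != col(bun$MDA)]), exp(-1))
  expect_true(all(bun$MDA > exp(-1) - 1e-12 & bun$MDA <= 1))
  expect_true(all(bun$A <= bun$MC + 1e-12))
  expect_true(all(bun$A >= 0 & bun$A <= 1 + 1e-12))
  expect_equal(unclass(bun$A), t(unclass(bun$A)), ignore_attr = TRUE)
  expect_equal(unique(diag(bun$A)), max(bun$A))
  # all-zero barcode rows are excluded with a message
  b2 <- b
  b2[3, ] <- 0
  expect_message(bz <- build_affinity(b2, dmap), "all-zero")
  expect_equal(length(bz$ids), n - 1)
})

test_that("the Calinski-Harabasz index matches its closed formula", {
  set.seed(8)
  x <- rbind(matrix(rnorm(30), ncol = 3), matrix(rnorm(30, 5), ncol = 3))
  lab <- rep(1:2, each = 10)
  got <- calinski_harabasz(x, lab)
  # independent route via total scatter decomposition: B = T - W
  tot <- sum(sweep(x, 2, colMeans(x))^2)
  w <- sum(vapply(1:2, function(g) {
    xg <- x[lab == g, ]
    sum(sweep(xg, 2, colMeans(xg))^2)
  }, numeric(1)))
  expect_equal(got, ((tot - w) / 1) / (w / 18))
  expect_true(is.nan(calinski_harabasz(x, rep(1, 20))))
})

test_that("planted subtypes are recovered with the CH-selected k = 2", {
  inp <- synthetic_bundle_inputs(n_per = 12, segregation = 1, seed = 3)
  dmap <- anatomy_distance(inp$somas, diag(3) * 30^2)
  bundle <- build_affinity(inp$barcodes, dmap)
  res <- subtype_clusters(bundle)
  expect_equal(res$k, 2)
  expect_gte(ari(res$labels, inp$labels), 0.9)
  expect_s3_class(tidy(res), "tbl_df")
  expect_equal(nrow(tidy(res)), 24)
})

test_that("i.i.d. noise barcodes yield a flat CH curve", {
  withr::with_seed(11, {
    b <- matrix(runif(40 * 8), ncol = 8)
    somas <- matrix(rnorm(120, 300, 30), ncol = 3)
  })
  rownames(b) <- rownames(somas) <- sprintf("n%02d", 1:40)
  bundle <- build_affinity(b, anatomy_distance(somas, diag(3) * 900))
  res <- subtype_clusters(bundle)
  expect_lt(max(res$ch$ch) / stats::median(res$ch$ch), 2)
})

test_that("clustering is equivariant under neuron reordering", {
  inp <- synthetic_bundle_inputs(n_per = 10, seed = 9)
  dmap <- anatomy_distance(inp$somas, diag(3) * 900)
  res1 <- subtype_clusters(build_affinity(inp$barcodes, dmap))
  perm <- withr::with_seed(2, sample(20))
  res2 <- subtype_clusters(build_affinity(inp$barcodes[perm, ],
                                          dmap[perm, perm]))
  expect_equal(ari(res1$labels[perm], res2$labels), 1)
})

test_that("soma segregation never hurts planted-label recovery", {
  for (seed in 1:5) {
    aris <- vapply(c(0, 0.5, 1), function(s) {
      inp <- synthetic_bundle_inputs(n_per = 10, segregation = s,
                                     seed = 50 + seed, noise = 0.6)
      dmap <- anatomy_distance(inp$somas, diag(3) * 900)
      res <- subtype_clusters(build_affinity(inp$barcodes, dmap),
                              k_range = 2:4)
      ari(res$labels, inp$labels)
    }, numeric(1))
    expect_true(all(diff(aris) >= -1e-9))
  }
})

test_that("soma mirroring removes the spurious hemisphere bipartition", {
  atlas <- toy_atlas()
  withr::with_seed(13, {
    n <- 20
    # one shared connectivity pattern (plus noise): hemispheres are NOT
    # distinguishable by barcode, only by raw soma position
    b_half <- pmax(matrix(rep(c(10, 2, 8, 0, 5, 1), each = n), ncol = 6) +
                     matrix(rnorm(n * 6, sd = 0.5), ncol = 6), 0)
    somas_left <- cbind(runif(n, 170, 180), runif(n, 290, 310),
                        runif(n, 145, 155))
  })
  # duplicate the cohort into both hemispheres with identical barcodes
  b <- rbind(b_half, b_half)
  somas <- rbind(somas_left, mirror_point(somas_left, atlas))
  rownames(b) <- rownames(somas) <- sprintf("n%02d", 1:(2 * n))
  hemi <- rep(1:2, each = n)
  cv <- diag(3) * 50^2
  # raw somas: hemisphere split is the top bipartition
  raw <- subtype_clusters(build_affinity(b, anatomy_distance(somas, cv)),
                          k_range = 2)
  expect_equal(ari(raw$labels, hemi), 1)
  # mirrored somas: twins coincide, the split cannot be hemispheric
  mir <- anatomy_distance(mirror_to_hemisphere(somas, atlas, "left"), cv)
  rownames(mir) <- colnames(mir) <- rownames(b)
  fixed <- subtype_clusters(build_affinity(b, mir), k_range = 2)
  expect_lt(ari(fixed$labels, hemi), 0.2)
})

test_that("subtype reports keep the books straight", {
  inp <- synthetic_bundle_inputs(n_per = 8, seed = 21)
  dmap <- anatomy_distance(inp$somas, diag(3) * 900)
  res <- subtype_clusters(build_affinity(inp$barcodes, dmap))
  colnames(inp$barcodes) <- paste0("d", 1:6)
  rpt <- subtype_report(res, inp$barcodes, somas = inp$somas, top_n = 3)
  expect_equal(sum(rpt$size), length(res$labels))
  expect_equal(lengths(rpt$top_targets), rep(3, nrow(rpt)),
               ignore_attr = TRUE)
  # planted top target: pattern 1 peaks at d1, pattern 2 at d4
  g1 <- rpt$top_targets[[which(rpt$subtype ==
                                 res$labels[["n01"]])]][1]
  expect_equal(g1, "d1")
})
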