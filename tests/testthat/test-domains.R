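planted_blobs <- function(k, n_per, sep = 10, sd = 1, seed = 1) {
  withr::with_seed(seed, {
    centers <- matrix(c(0, 0, 0, sep, 0, 0, 0, sep, 0), ncol = 3,
                      byrow = TRUE)[seq_len(k), , drop = FALSE]
    pts <- do.call(rbind, lapply(seq_len(k), function(i)
      sweep(matrix(rnorm(3 * n_per, sd = sd), ncol = 3), 2,
            centers[i, ], "+")))
    list(points = pts, labels = rep(seq_len(k), each = n_per))
  })
}

test_that("BIC model selection recovers planted cluster counts", {
  b3 <- planted_blobs(3, 100, sep = 10, sd = 1, seed = 5)
  fit <- fit_gmm_bic(b3$points, k_range = 1:6, seed = 1)
  expect_equal(fit$k, 3)
  expect_gte(ari(fit$classification, b3$labels), 0.95)
  b1 <- planted_blobs(1, 300, seed = 6)
  expect_equal(fit_gmm_bic(b1$points, k_range = 1:6, seed = 1)$k, 1)
})

test_that("the selected fit maximizes BIC over the whole candidate grid", {
  b <- planted_blobs(2, 80, seed = 3)
  fit <- fit_gmm_bic(b$points, k_range = 1:4, seed = 1)
  expect_equal(fit$bic, max(fit$bic_table, na.rm = TRUE))
  # independent single-component spherical oracle: ML Gaussian with one
  # shared variance; p = 3 (mean) + 1 (variance)
  x <- b$points
  n <- nrow(x)
  vhat <- sum(sweep(x, 2, colMeans(x))^2) / (3 * n)
  ll <- sum(vapply(1:3, function(j)
    sum(dnorm(x[, j], colMeans(x)[j], sqrt(vhat), log = TRUE)),
    numeric(1)))
  expect_equal(fit$bic_table["1", "EII"], 2 * ll - 4 * log(n),
               tolerance = 1e-6)
})

test_that("identical seeds give identical fits", {
  b <- planted_blobs(3, 60, seed = 11)
  f1 <- fit_gmm_bic(b$points, seed = 4)
  f2 <- fit_gmm_bic(b$points, seed = 4)
  expect_identical(f1$bic, f2$bic)
  expect_identical(f1$classification, f2$classification)
  expect_s3_class(tidy(f1), "tbl_df")
  expect_equal(sum(tidy(f1)$weight), 1, tolerance = 1e-8)
  expect_equal(glance(f1)$k, f1$k)
})

test_that("domain kind follows the strict-majority soma rule", {
  set.seed(8)
  cloud <- matrix(runif(300, 0, 10), ncol = 3)
  sh <- alpha_shape(cloud, alpha = Inf)
  somas <- rbind(inA = c(5, 5, 5), inB = c(4, 6, 5), out = c(50, 50, 50),
                 out2 = c(60, 50, 50))
  nodes_in <- rep(c("inA", "inB"), each = 10)
  nodes_out <- rep(c("out", "out2"), each = 10)
  expect_equal(classify_domain_kind(nodes_in, somas, sh), "dendritic")
  expect_equal(classify_domain_kind(nodes_out, somas, sh), "axonal")
  # exactly 50% inside -> axonal (ties are not a majority)
  expect_equal(classify_domain_kind(c(nodes_in, nodes_out), somas, sh),
               "axonal")
})

test_that("pooled dendritic domains mirror into an empty hemisphere", {
  atlas <- toy_atlas()
  plan <- list(list(spec = toy_spec(1L, "c", integer()), count = 6))
  manifest <- generate_cohort(plan, atlas, seed = 9,
                              dir = withr::local_tempdir())
  neurons <- lapply(manifest$path, function(p)
    resample_morphology(read_swc(p), 10))
  dd <- pooled_dendrite_domain(neurons, atlas, s_type = 1L, alpha = 3)
  expect_named(dd, c("left", "right"))
  expect_equal(dd$left$kind, "dendritic")
  # cohort lives on the left; right is the mirrored copy
  expect_equal(length(dd$right$mask$lin), length(dd$left$mask$lin))
  expect_identical(sort(mirror_mask(dd$left$mask, atlas)$lin),
                   dd$right$mask$lin)
  # all dendritic nodes fall inside the left shape
  pool <- arborcode:::pool_coordinates(neurons, atlas, "dendrite")
  expect_true(all(in_shape(dd$left$shape, pool$points)))
  expect_equal(dd$left$volume_mm3,
               length(dd$left$mask$lin) * (25e-3)^3)
})

test_that("panel assembly keeps order and index round-trips to masks", {
  atlas <- toy_atlas()
  doms <- list(random_box_domain("a", atlas, 1),
               random_box_domain("b", atlas, 2),
               random_box_domain("c", atlas, 3, hemisphere = "right"))
  panel <- build_panel(doms, atlas)
  expect_equal(panel$table$domain_id, c("a", "b", "c"))
  rebuilt <- panel_masks(panel)
  for (i in 1:3) expect_identical(rebuilt[[i]], doms[[i]]$mask$lin)
  # disjoint shapes never share a voxel index entry
  if (anyDuplicated(c(doms[[1]]$mask$lin, doms[[3]]$mask$lin)) == 0) {
    lin2 <- panel$index_lin[panel$index_dom %in% c(1, 3)]
    expect_equal(anyDuplicated(lin2), 0)
  }
  expect_error(arbor_domain("e", 1L, "dendritic", "left", 1, NULL,
                            voxel_mask(integer(0), dim(atlas$labels), 25),
                            c(0, 0, 0)), "empty")
})

test_that("detected axonal territories track the planted target count", {
  cohort <- toy_projection_cohort(n_per = 10, seed = 14)
  neurons <- lapply(cohort$neurons, resample_morphology, step = 10)
  det <- suppressWarnings(
    detect_arbor_domains(neurons, cohort$atlas, s_type = 1L,
                         alpha = 3, k_range = 1:6, seed = 2))
  kinds <- vapply(det$domains, function(d) d$kind, character(1))
  expect_gte(sum(kinds == "dendritic"), 1)
  # two planted distinct targets (TGA, TGB), tolerance +-1; mixture
  # components of one projection system merge into territories
  terr <- axonal_territories(det$domains)
  expect_gte(attr(terr, "n_territories"), 1)
  expect_lte(attr(terr, "n_territories"), 3)
  expect_equal(nrow(terr), sum(kinds == "axonal"))
})

test_that("domain voxel counts are mirror-symmetric on a symmetric atlas", {
  atlas <- toy_atlas()
  n <- resample_morphology(
    grow_neuron(toy_spec(1L, "c", integer()), atlas, seed = 10), 10)
  nm <- mirror_neuron(n, atlas)
  d1 <- pooled_dendrite_domain(list(n), atlas, 1L, alpha = 3)
  d2 <- pooled_dendrite_domain(list(nm), atlas, 1L, alpha = 3)
  expect_equal(length(d1$left$mask$lin), length(d2$right$mask$lin))
})
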