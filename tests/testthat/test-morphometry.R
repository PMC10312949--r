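path_neuron <- function(xs, type = 3L) {
  n <- length(xs)
  neuron_morphology(tibble::tibble(
    node_id = seq_len(n), type = c(1L, rep(type, n - 1)), x = xs, y = 0,
    z = 0, radius = 1, parent_id = c(-1L, seq_len(n - 1))), "path")
}

test_that("resampling splits long edges and preserves structure and length", {
  n <- path_neuron(c(0, 100))
  r <- resample_morphology(n, step = 10)
  expect_equal(nrow(r$nodes), 11)
  el <- sort(unique(round(arborcode:::edge_lengths(r$nodes)[-1], 9)))
  expect_equal(el, 10)
  # short edges untouched
  n2 <- path_neuron(c(0, 7))
  expect_equal(nrow(resample_morphology(n2, 10)$nodes), 2)
  # length conservation on a random synthetic neuron
  nr <- grow_neuron(toy_spec(1L, "c", 2L), toy_atlas(), seed = 3)
  f0 <- compute_features(nr, "whole")
  f1 <- compute_features(resample_morphology(nr, 10), "whole")
  expect_equal(f1$total_length, f0$total_length, tolerance = 1e-6)
  expect_equal(f1$tips, f0$tips)
  expect_equal(f1$max_branch_order, f0$max_branch_order)
  expect_equal(f1$max_path_distance, f0$max_path_distance,
               tolerance = 1e-6)
})

test_that("features on hand-built trees match geometry", {
  p <- path_neuron(c(0, 10, 20))
  f <- compute_features(p, "whole")
  expect_equal(f$tips, 1)
  expect_equal(f$total_length, 20)
  expect_equal(f$max_branch_order, 0)
  expect_equal(f$n_bifurcations, 0)
  # symmetric Y with a 90-degree opening
  y <- neuron_morphology(tibble::tibble(
    node_id = 1:4, type = c(1L, 3L, 3L, 3L),
    x = c(0, 10, 20, 20), y = c(0, 0, 10, -10), z = 0, radius = 1,
    parent_id = c(-1L, 1L, 2L, 2L)), "Y")
  fy <- compute_features(y, "whole")
  expect_equal(fy$avg_bifurcation_angle_remote, 90)
  expect_equal(fy$tips, 2)
  expect_equal(fy$n_bifurcations, 1)
  expect_equal(fy$max_branch_order, 1)
  # perfect binary tree, depth 2: stem + 2 bifurcation levels
  bt <- binary_tree_neuron(depth = 2, edge_len = 10)
  fb <- compute_features(bt, "whole")
  expect_equal(fb$tips, 4)
  expect_equal(fb$n_bifurcations, 3)
  expect_equal(fb$max_branch_order, 2)
  expect_equal(fb$avg_bifurcation_angle_remote, 60)
  # empty compartment flagged
  fa <- compute_features(bt, "axon")
  expect_true(fa$empty)
  expect_equal(fa$total_length, 0)
})

test_that("features agree with a brute-force path-enumeration oracle", {
  brute <- function(n) {
    nd <- n$nodes
    pos <- match(nd$parent_id, nd$node_id)
    kids <- lapply(seq_len(nrow(nd)), function(i) which(pos == i))
    root <- which(is.na(pos))
    elen <- arborcode:::edge_lengths(nd)
    paths <- list()
    walk <- function(i, acc) {
      acc <- c(acc, i)
      if (length(kids[[i]]) == 0) {
        paths[[length(paths) + 1]] <<- acc
      } else {
        for (k in kids[[i]]) walk(k, acc)
      }
    }
    walk(root, integer(0))
    tip_paths <- paths[vapply(paths, function(p) p[length(p)] != root,
                              logical(1))]
    nbif <- sum(lengths(kids) >= 2 & seq_along(kids) != root)
    list(
      tips = length(tip_paths),
      total_length = sum(elen),
      max_path_distance = max(vapply(tip_paths, function(p)
        sum(elen[p[-1]]), numeric(1))),
      n_bifurcations = nbif,
      max_branch_order = max(vapply(tip_paths, function(p) {
        sum(lengths(kids)[p[-length(p)]] >= 2 &
              p[-length(p)] != root)
      }, numeric(1))))
  }
  set.seed(42)
  for (rep in 1:8) {
    nd <- tibble::tibble(node_id = 1L, type = 1L, x = 0, y = 0, z = 0,
                         radius = 1, parent_id = -1L)
    for (i in 2:20) {
      nd <- dplyr::bind_rows(nd, tibble::tibble(
        node_id = i, type = 3L, x = runif(1, -50, 50),
        y = runif(1, -50, 50), z = runif(1, -50, 50), radius = 1,
        parent_id = sample(i - 1, 1)))
    }
    n <- neuron_morphology(nd, "rand")
    f <- compute_features(n, "whole")
    o <- brute(n)
    expect_equal(f$tips, o$tips)
    expect_equal(f$total_length, o$total_length)
    expect_equal(f$max_path_distance, o$max_path_distance)
    expect_equal(f$n_bifurcations, o$n_bifurcations)
    expect_equal(f$max_branch_order, o$max_branch_order)
  }
})

test_that("QC keep rule reproduces hand-computed keep/discard cases", {
  iv <- qc_intervals()  # tips [7,143], len [700,13615], path [108,1382],
  # angle [35,129], order [3,32]; keep iff >= 4 within
  cases <- tibble::tibble(
    tips  = c(50,  5,   7, 143, 144,  50,  50,  6,   7,  50),
    total_length = c(5000, 500, 700, 13615, 5000, 699, 5000, 600, 700, 5000),
    max_path_distance = c(500, 500, 108, 1382, 500, 500, 107, 100, 108, 1383),
    avg_bifurcation_angle_remote = c(70, 70, 35, 129, 70, 70, 70, 30, 35, 130),
    max_branch_order = c(10, 10, 3, 32, 10, 10, 10, 2, 3, 33))
  # hand count of in-interval features per row:
  expected_within <- c(5, 3, 5, 5, 4, 4, 4, 0, 5, 2)
  got <- qc_pass(cases, iv)
  expect_equal(got$n_within, as.integer(expected_within))
  expect_equal(got$pass, expected_within >= 4)
})

test_that("among passing candidates the greatest-length tracing is kept", {
  short <- binary_tree_neuron(3, 60, id = "short")   # length 900
  long <- binary_tree_neuron(3, 90, id = "long")     # length 1350
  bad <- path_neuron(c(0, 10, 20))                   # fails most intervals
  res <- qc_filter(list(short, bad, long))
  expect_equal(res$kept$neuron_id, "long")
  expect_equal(sum(res$table$pass), 2)
  # all failing -> none
  expect_null(qc_filter(list(bad))$kept)
  expect_null(qc_filter(list())$kept)
})

test_that("relaxing QC intervals never discards a previously kept neuron", {
  cands <- list(binary_tree_neuron(3, 60), binary_tree_neuron(4, 40),
                binary_tree_neuron(2, 120), path_neuron(seq(0, 800, 40)))
  strict <- qc_intervals()
  relaxed <- strict
  relaxed$intervals <- lapply(strict$intervals, function(r)
    c(r[1] * 0.5, r[2] * 2))
  kept_strict <- qc_pass(feature_table(cands), strict)$pass
  kept_relaxed <- qc_pass(feature_table(cands), relaxed)$pass
  expect_true(all(kept_relaxed[kept_strict]))
})

test_that("projection matrix attributes axonal length to regions", {
  atlas <- toy_atlas()
  n <- resample_morphology(grow_neuron(toy_spec(1L, "c", 2L), atlas,
                                       seed = 8), 10)
  pm <- projection_matrix(list(n), atlas, compartment = "axon")
  ax_len <- compute_features(n, "axon")$total_length
  vals <- as.numeric(pm[1, setdiff(names(pm), "neuron_id")])
  expect_equal(sum(vals), ax_len, tolerance = 1e-6)
  expect_gt(pm$r2[1], 0)  # arbor sits in its target region
  # no axon -> zero row
  n0 <- grow_neuron(toy_spec(1L, "c", integer()), atlas, seed = 8)
  pm0 <- projection_matrix(list(n0), atlas)
  expect_equal(sum(as.numeric(pm0[1, -1])), 0)
})

test_that("a straight axon crossing two half-boxes splits its length evenly", {
  # two abutting boxes, each 10 voxels wide in x
  spec <- toy_atlas_spec(
    tibble::tibble(id = c(1L, 2L), name = c("a", "b"), shape = "box",
                   cx = c(7, 17), cy = 12, cz = 6, rx = 5, ry = 5, rz = 5),
    grid_shape = c(24L, 24L, 24L), voxel_size = 25, mirror_axis = 3)
  atlas <- build_toy_atlas(spec)
  xs <- c(50, seq(60, 540, by = 20))  # straight line through both boxes
  nd <- tibble::tibble(node_id = seq_along(xs),
                       type = c(1L, rep(2L, length(xs) - 1)), x = xs,
                       y = 300, z = 150, radius = 1,
                       parent_id = c(-1L, seq_len(length(xs) - 1)))
  n <- resample_morphology(neuron_morphology(nd, "ax"), 10)
  pm <- projection_matrix(list(n), atlas)
  expect_lt(abs(pm$r1 - pm$r2), 10 + 1e-9)
})
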