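# Shared toy world: a 40 x 24 x 24 voxel mirrored atlas (25 um voxels,
# mirror axis 3) with a soma region (SOM) and two projection targets
# (TGA, TGB) per hemisphere, plus cohort builders around it.

toy_atlas <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      regions <- tibble::tibble(
        id = c(1L, 2L, 3L),
        name = c("SOM", "TGA", "TGB"),
        shape = "box",
        cx = c(8, 30, 30), cy = c(12, 6, 18), cz = c(6, 6, 6),
        rx = 3, ry = 3, rz = 3)
      spec <- toy_atlas_spec(regions, grid_shape = c(40L, 24L, 24L),
                             voxel_size = 25, mirror_axis = 3)
      cache <<- build_toy_atlas(spec)
    }
    cache
  }
})

# spec factory with test-friendly defaults (short arbors keep runtimes low)
toy_spec <- function(s_type, c_subtype, targets, soma_window = NULL,
                     nodes_max = 150L, dendrite_spread_um = 60,
                     axon_arbor_spread_um = 25) {
  planted_neuron_spec(
    s_type, c_subtype, axon_targets = targets,
    dendrite_spread_um = dendrite_spread_um,
    axon_arbor_spread_um = axon_arbor_spread_um,
    nodes_max = nodes_max, bifurcation_prob = 0.06, step_um = 10,
    n_stems = 4L, soma_window = soma_window)
}

# two projection subtypes sharing the SOM s-type; optional spatial
# segregation of their somas along the y axis of the soma box
toy_projection_cohort <- function(n_per = 10, seed = 42,
                                  segregate = FALSE,
                                  dir = withr::local_tempdir(
                                    .local_envir = parent.frame())) {
  atlas <- toy_atlas()
  w1 <- if (segregate) rbind(c(0, 0, 0), c(39, 10, 23)) else NULL
  w2 <- if (segregate) rbind(c(0, 13, 0), c(39, 23, 23)) else NULL
  plan <- list(
    list(spec = toy_spec(1L, "cA", 2L, soma_window = w1), count = n_per),
    list(spec = toy_spec(1L, "cB", 3L, soma_window = w2), count = n_per))
  manifest <- generate_cohort(plan, atlas, seed = seed, dir = dir)
  neurons <- lapply(manifest$path, read_swc)
  names(neurons) <- manifest$neuron_id
  list(atlas = atlas, manifest = manifest, neurons = neurons, dir = dir)
}

# dendrite-resident cohorts in the two target regions; their pooled
# dendritic domains form the barcode panel of the toy world
toy_panel <- function(n_per = 6, seed = 7, alpha = 3,
                      dir = withr::local_tempdir(
                        .local_envir = parent.frame())) {
  atlas <- toy_atlas()
  plan <- list(
    list(spec = toy_spec(2L, "resA", integer()), count = n_per),
    list(spec = toy_spec(3L, "resB", integer()), count = n_per))
  manifest <- generate_cohort(plan, atlas, seed = seed, dir = dir)
  neurons <- lapply(manifest$path, function(p)
    resample_morphology(read_swc(p), 10))
  names(neurons) <- manifest$neuron_id
  doms <- c(
    pooled_dendrite_domain(neurons[manifest$s_type == 2L], atlas, 2L,
                           alpha = alpha),
    pooled_dendrite_domain(neurons[manifest$s_type == 3L], atlas, 3L,
                           alpha = alpha))
  list(atlas = atlas, panel = whole_brain_panel(list(), doms, atlas),
       domains = doms)
}

# deterministic symmetric binary tree: one stem from the soma, then
# `depth` levels of clean bifurcations at +-half_angle degrees in the
# x-y plane; every edge has length edge_len
binary_tree_neuron <- function(depth, edge_len, half_angle = 30,
                               type = 3L, id = "btree") {
  rows <- list(tibble::tibble(node_id = 1L, type = 1L, x = 0, y = 0, z = 0,
                              radius = 1, parent_id = -1L))
  nid <- 2L
  rows[[2]] <- tibble::tibble(node_id = 2L, type = type, x = edge_len,
                              y = 0, z = 0, radius = 1, parent_id = 1L)
  queue <- list(list(id = 2L, x = edge_len, y = 0, theta = 0, level = 1L))
  while (length(queue) > 0) {
    cur <- queue[[1]]
    queue <- queue[-1]
    if (cur$level > depth) next
    for (sgn in c(-1, 1)) {
      th <- cur$theta + sgn * half_angle * pi / 180
      nid <- nid + 1L
      x <- cur$x + edge_len * cos(th)
      y <- cur$y + edge_len * sin(th)
      rows[[length(rows) + 1]] <- tibble::tibble(
        node_id = nid, type = type, x = x, y = y, z = 0, radius = 1,
        parent_id = cur$id)
      queue[[length(queue) + 1]] <- list(id = nid, x = x, y = y,
                                         theta = th, level = cur$level + 1L)
    }
  }
  neuron_morphology(dplyr::bind_rows(rows), neuron_id = id)
}

# brute-force convex-hull membership by exhaustive facet enumeration
hull_membership_oracle <- function(pts, query) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  tri <- utils::combn(n, 3)
  planes <- list()
  for (c1 in seq_len(ncol(tri))) {
    a <- pts[tri[1, c1], ]
    u <- pts[tri[2, c1], ] - a
    v <- pts[tri[3, c1], ] - a
    nrm <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
             u[1] * v[2] - u[2] * v[1])
    if (sqrt(sum(nrm^2)) < 1e-12) next
    s <- pts %*% nrm - sum(nrm * a)
    if (all(s <= 1e-9)) {
      planes[[length(planes) + 1]] <- c(nrm, sum(nrm * a))
    } else if (all(s >= -1e-9)) {
      planes[[length(planes) + 1]] <- c(-nrm, -sum(nrm * a))
    }
  }
  pm <- do.call(rbind, planes)
  apply(as.matrix(query), 1, function(x)
    all(pm[, 1:3] %*% x - pm[, 4] <= 1e-7))
}

# random voxel-box arbor_domain for panel oracle tests
random_box_domain <- function(id, atlas, seed, hemisphere = "left") {
  withr::with_seed(seed, {
    dims <- dim(atlas$labels)
    zmax <- if (hemisphere == "left") dims[3] / 2 - 1 else dims[3] - 1
    zmin <- if (hemisphere == "left") 0 else dims[3] / 2
    lo <- c(sample(0:(dims[1] - 5), 1), sample(0:(dims[2] - 5), 1),
            sample(zmin:(zmax - 4), 1))
    sz <- sample(2:4, 3, replace = TRUE)
    grid <- as.matrix(expand.grid(lo[1]:(lo[1] + sz[1]),
                                  lo[2]:(lo[2] + sz[2]),
                                  lo[3]:(lo[3] + sz[3])))
    lin <- sort(grid[, 1] + dims[1] * (grid[, 2] + dims[2] * grid[, 3]))
    arbor_domain(id, 0L, "dendritic", hemisphere, alpha = NA,
                 shape = NULL,
                 mask = voxel_mask(lin, dims, atlas$voxel_size),
                 centroid = colMeans(grid))
  })
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
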