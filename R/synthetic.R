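#' Specify a planted synthetic neuron
#'
#' Describes one neuron population for the synthetic cohort generator: where
#' the soma sits (its s-type region), which regions its axon targets (the
#' planted connectivity subtype), and the geometry of its arbors. The growth
#' model is a directed random walk with per-step Gaussian angular noise and
#' Bernoulli bifurcations - plausible arbor point clouds, not biophysics.
#'
#' @param s_type Region id in which the soma is placed.
#' @param c_subtype Planted connectivity-subtype label (any scalar).
#' @param axon_targets Integer vector of target region ids (may be empty for
#'   dendrite-only neurons; 1-3 targets emulate long-range projections).
#' @param dendrite_spread_um Target RMS distance of dendritic nodes to the
#'   soma (um). Default 75.
#' @param axon_arbor_spread_um RMS spread of each terminal axonal arbor
#'   around its target center (um). Default 50.
#' @param nodes_max Hard node cap per subtree (dendritic tree, and each
#'   axonal subtree). Default 250.
#' @param bifurcation_prob Per-step branch probability. Default 0.06.
#' @param step_um Growth step length (um). Default 10, matching the pipeline
#'   resampling step.
#' @param n_stems Number of primary branches leaving the soma (or the axon
#'   arrival point). Default 4.
#' @param soma_window Optional 2 x 3 matrix `rbind(lo, hi)` of voxel-unit
#'   bounds restricting where within the soma region this population's
#'   somas may be placed (used to plant spatially segregated subtypes).
#' @return A `planted_neuron_spec`.
#' @export
planted_neuron_spec <- function(s_type, c_subtype = "c0",
                                axon_targets = integer(),
                                dendrite_spread_um = 75,
                                axon_arbor_spread_um = 50,
                                nodes_max = 250L,
                                bifurcation_prob = 0.06,
                                step_um = 10,
                                n_stems = 4L,
                                soma_window = NULL) {
  stopifnot(dendrite_spread_um > 0, axon_arbor_spread_um > 0,
            nodes_max >= 1, bifurcation_prob >= 0, bifurcation_prob <= 1,
            step_um > 0, n_stems >= 1)
  structure(
    list(s_type = as.integer(s_type), c_subtype = c_subtype,
         axon_targets = as.integer(axon_targets),
         dendrite_spread_um = dendrite_spread_um,
         axon_arbor_spread_um = axon_arbor_spread_um,
         nodes_max = as.integer(nodes_max),
         bifurcation_prob = bifurcation_prob,
         step_um = step_um, n_stems = as.integer(n_stems),
         soma_window = soma_window),
    class = "planted_neuron_spec"
  )
}

rand_unit <- function(n = 1) {
  v <- matrix(rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

clamp_to_volume <- function(p, atlas) {
  lim <- atlas$origin + dim(atlas$labels) * atlas$voxel_size
  eps <- 1e-3
  for (j in 1:3) p[, j] <- pmin(pmax(p[, j], atlas$origin[j] + eps),
                                lim[j] - eps)
  p
}

# Directed random-walk arbor around `center`. Branch lengths are drawn so the
# node cloud's RMS distance to `center` targets `spread` (straight radial
# branch of length L has RMS L/sqrt(3)). Returns positions + local parents
# (0 = attachment point).
grow_arbor <- function(center, spread, step, bifurcation_prob, nodes_max,
                       n_stems, angle_sd = 0.25) {
  target_len <- function() max(2 * step, sqrt(3) * spread * rnorm(1, 1, 0.1))
  pos <- matrix(numeric(0), ncol = 3)
  parent <- integer(0)
  # each active branch: current position, direction, remaining length,
  # parent node index (0 = attachment)
  branches <- lapply(seq_len(n_stems), function(i) {
    list(p = center, d = rand_unit()[1, ], rem = target_len(), par = 0L)
  })
  while (length(branches) > 0 && nrow(pos) < nodes_max) {
    nxt <- list()
    for (b in branches) {
      if (nrow(pos) >= nodes_max) break
      d <- b$d + angle_sd * rnorm(3)
      d <- d / sqrt(sum(d^2))
      p <- b$p + step * d
      pos <- rbind(pos, p)
      parent <- c(parent, b$par)
      id <- nrow(pos)
      rem <- b$rem - step
      if (rem > 0) {
        nxt[[length(nxt) + 1]] <- list(p = p, d = d, rem = rem, par = id)
        if (runif(1) < bifurcation_prob) {
          d2 <- d + 0.8 * rnorm(3)
          d2 <- d2 / sqrt(sum(d2^2))
          nxt[[length(nxt) + 1]] <-
            list(p = p, d = d2, rem = rem * runif(1, 0.5, 1), par = id)
        }
      }
    }
    branches <- nxt
  }
  dimnames(pos) <- NULL
  list(pos = pos, parent = parent)
}

# straight, low-tortuosity path from `from` towards `to`, step length `step`
grow_path <- function(from, to, step, angle_sd = 0.03) {
  pos <- matrix(numeric(0), ncol = 3)
  p <- from
  repeat {
    v <- to - p
    dist <- sqrt(sum(v^2))
    if (dist <= step) break
    d <- v / dist + angle_sd * rnorm(3)
    d <- d / sqrt(sum(d^2))
    p <- p + step * d
    pos <- rbind(pos, p)
  }
  dimnames(pos) <- NULL
  pos
}

#' Grow one synthetic neuron
#'
#' Node 1 is the soma (type 1). A dendritic random tree (type 3) surrounds
#' the soma with RMS node distance ~= `dendrite_spread_um`; per axon target,
#' one axonal subtree (type 2) runs on a low-tortuosity path from the soma to
#' the target-region center and ends in a random arbor of spread
#' `axon_arbor_spread_um` centered there. Deterministic given `seed`.
#'
#' @param spec A [planted_neuron_spec()].
#' @param atlas An `annotation_volume` containing the soma and target regions.
#' @param seed Integer seed.
#' @param soma_um Optional soma position (um); defaults to the center voxel
#'   of the soma region.
#' @param neuron_id Identifier string.
#' @return A [neuron_morphology()].
#' @export
grow_neuron <- function(spec, atlas, seed, soma_um = NULL,
                        neuron_id = "neuron") {
  stopifnot(inherits(spec, "planted_neuron_spec"))
  if (!any(atlas$labels == spec$s_type)) {
    abort(paste0("soma region ", spec$s_type, " not present in atlas"))
  }
  for (tg in spec$axon_targets) {
    if (!any(atlas$labels == tg)) {
      abort(paste0("axon target region ", tg, " not present in atlas"))
    }
  }
  withr::with_seed(seed, {
    if (is.null(soma_um)) {
      rv <- region_voxels(spec$s_type, atlas)
      soma_um <- voxel_center(rv[ceiling(nrow(rv) / 2), , drop = FALSE],
                              atlas)[1, ]
    }
    soma_um <- as.numeric(soma_um)
    nodes <- tibble::tibble(node_id = 1L, type = 1L, x = soma_um[1],
                            y = soma_um[2], z = soma_um[3], radius = 5,
                            parent_id = -1L)
    add_subtree <- function(nodes, arb, type, attach_id) {
      if (nrow(arb$pos) == 0) return(nodes)
      p <- clamp_to_volume(arb$pos, atlas)
      base <- nrow(nodes)
      ids <- base + seq_len(nrow(p))
      par <- ifelse(arb$parent == 0L, attach_id, base + arb$parent)
      dplyr::bind_rows(nodes, tibble::tibble(
        node_id = as.integer(ids), type = as.integer(type),
        x = p[, 1], y = p[, 2], z = p[, 3], radius = 1,
        parent_id = as.integer(par)))
    }
    den <- grow_arbor(soma_um, spec$dendrite_spread_um, spec$step_um,
                      spec$bifurcation_prob, spec$nodes_max, spec$n_stems)
    nodes <- add_subtree(nodes, den, 3L, 1L)
    for (tg in spec$axon_targets) {
      rv <- region_voxels(tg, atlas)
      ctr <- colMeans(voxel_center(rv, atlas))
      path <- grow_path(soma_um, ctr, spec$step_um)
      path_arb <- list(pos = path, parent = c(0L, seq_len(max(0, nrow(path) - 1))))
      n_before <- nrow(nodes)
      nodes <- add_subtree(nodes, path_arb, 2L, 1L)
      attach <- if (nrow(nodes) > n_before) nrow(nodes) else 1L
      arb <- grow_arbor(ctr, spec$axon_arbor_spread_um, spec$step_um,
                        spec$bifurcation_prob, spec$nodes_max, spec$n_stems)
      nodes <- add_subtree(nodes, arb, 2L, attach)
    }
    neuron_morphology(nodes, neuron_id = neuron_id,
                      metadata = list(s_type = spec$s_type,
                                      c_subtype = spec$c_subtype,
                                      seed = seed))
  })
}

#' Generate a synthetic cohort of SWC files with ground truth
#'
#' Places the requested number of somas of each population on distinct voxel
#' centers of its s-type region, grows each neuron, writes one SWC file per
#' neuron under `dir`, and returns (and writes as JSON) a ground-truth
#' manifest. Deterministic given `seed`.
#'
#' @param plan A list of `list(spec = planted_neuron_spec, count = n)`
#'   entries, or a tibble with list-column `spec` and column `count`.
#' @param atlas An `annotation_volume`.
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @return A tibble manifest: `neuron_id`, `s_type`, `c_subtype`,
#'   `soma_x/y/z`, `axon_targets` (list-column), `path`. Written alongside
#'   the SWC files as `manifest.json`.
#' @export
generate_cohort <- function(plan, atlas, seed, dir) {
  if (is.data.frame(plan)) {
    plan <- purrr::map2(plan$spec, plan$count,
                        function(s, n) list(spec = s, count = n))
  }
  stopifnot(length(plan) > 0)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  idx <- 0L
  used <- list()  # per-region soma voxel rows already taken
  for (p in seq_along(plan)) {
    pop <- plan[[p]]
    spec <- pop$spec
    count <- pop$count
    stopifnot(inherits(spec, "planted_neuron_spec"), count >= 1)
    rv <- region_voxels(spec$s_type, atlas)
    if (!is.null(spec$soma_window)) {
      w <- spec$soma_window
      ok <- rv[, 1] >= w[1, 1] & rv[, 1] <= w[2, 1] &
        rv[, 2] >= w[1, 2] & rv[, 2] <= w[2, 2] &
        rv[, 3] >= w[1, 3] & rv[, 3] <= w[2, 3]
      rv <- rv[ok, , drop = FALSE]
    }
    key <- as.character(spec$s_type)
    free <- setdiff(seq_len(nrow(rv)), used[[key]])
    if (length(free) < count) {
      abort(paste0("region ", spec$s_type, " has ", length(free),
                   " free voxels; cannot place ", count, " distinct somas"))
    }
    pick <- free[withr::with_seed(
      as.integer((as.double(seed) + 104729 * p) %% 2147483647),
                                  sample(length(free), count))]
    used[[key]] <- c(used[[key]], pick)
    soma_pos <- voxel_center(rv[pick, , drop = FALSE], atlas)
    for (i in seq_len(count)) {
      idx <- idx + 1L
      nid <- sprintf("n%04d", idx)
      n_seed <- as.integer((as.double(seed) * 131071 + idx) %% 2147483647)
      nrn <- grow_neuron(spec, atlas, seed = n_seed,
                         soma_um = soma_pos[i, ], neuron_id = nid)
      path <- file.path(dir, paste0(nid, ".swc"))
      write_swc(nrn, path)
      rows[[idx]] <- tibble::tibble(
        neuron_id = nid, s_type = spec$s_type, c_subtype = spec$c_subtype,
        soma_x = soma_pos[i, 1], soma_y = soma_pos[i, 2],
        soma_z = soma_pos[i, 3],
        axon_targets = list(spec$axon_targets), path = path)
    }
  }
  manifest <- dplyr::bind_rows(rows)
  mj <- manifest
  mj$path <- basename(mj$path)
  jsonlite::write_json(mj, file.path(dir, "manifest.json"), digits = NA,
                       auto_unbox = FALSE)
  manifest
}
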