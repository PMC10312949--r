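#' Resample a morphology to a maximum edge length
#'
#' Inserts equally spaced nodes on every parent-child segment longer than
#' `step`, so that all edges are at most `step` um. Original branch points,
#' tips and the root are preserved exactly; inserted nodes lie on the
#' original segments (linear interpolation, including radius). Total cable
#' length is conserved.
#'
#' @param n A [neuron_morphology()].
#' @param step Maximum edge length, um. Default 10.
#' @return A resampled [neuron_morphology()] with renumbered node ids.
#' @export
resample_morphology <- function(n, step = 10) {
  stopifnot(inherits(n, "neuron_morphology"), step > 0)
  nd <- n$nodes
  pos <- match(nd$parent_id, nd$node_id)
  out_x <- nd$x; out_y <- nd$y; out_z <- nd$z
  new_rows <- list()
  # map original node_id -> id in output (originals keep their ids; inserted
  # nodes get ids above the original maximum)
  next_id <- max(nd$node_id) + 1L
  parent_new <- nd$parent_id
  for (i in seq_len(nrow(nd))) {
    pi <- pos[i]
    if (is.na(pi)) next
    d <- c(nd$x[i] - nd$x[pi], nd$y[i] - nd$y[pi], nd$z[i] - nd$z[pi])
    len <- sqrt(sum(d^2))
    if (len <= step) next
    k <- ceiling(len / step) - 1L  # nodes to insert
    f <- seq_len(k) / (k + 1L)
    ids <- next_id + seq_len(k) - 1L
    next_id <- next_id + k
    new_rows[[length(new_rows) + 1]] <- tibble::tibble(
      node_id = as.integer(ids), type = nd$type[i],
      x = nd$x[pi] + f * d[1], y = nd$y[pi] + f * d[2],
      z = nd$z[pi] + f * d[3],
      radius = nd$radius[pi] + f * (nd$radius[i] - nd$radius[pi]),
      parent_id = as.integer(c(nd$node_id[pi], ids[-k])))
    parent_new[i] <- ids[k]
  }
  nd$parent_id <- as.integer(parent_new)
  all_nodes <- dplyr::bind_rows(nd, dplyr::bind_rows(new_rows))
  # renumber 1..N in a parent-before-child order (originals first is fine:
  # inserted parents have larger ids, so sort by id after remap via match)
  neuron_morphology(renumber_nodes(all_nodes), neuron_id = n$neuron_id,
                    metadata = c(n$metadata, list(resample_step = step)))
}

renumber_nodes <- function(nodes) {
  new_id <- seq_len(nrow(nodes))
  map <- setNames(new_id, as.character(nodes$node_id))
  nodes$node_id <- new_id
  nonroot <- nodes$parent_id != -1
  nodes$parent_id[nonroot] <-
    as.integer(map[as.character(nodes$parent_id[nonroot])])
  nodes
}

#' Morphometric features of one compartment
#'
#' Computes the L-Measure-style panel used throughout the package: `tips`,
#' `total_length` (um), `max_path_distance` (um), `n_bifurcations`,
#' `max_branch_order` (root order 0, +1 per bifurcation on the root path),
#' `avg_bifurcation_angle_remote` (degrees; the angle at each bifurcation
#' subtended by the next remote points - following bifurcation or tip - of
#' its child branches), `max_euclidean_distance` to the root, and bounding
#' box extents.
#'
#' @param n A [neuron_morphology()].
#' @param compartment "whole" (default), "dendrite" or "axon".
#' @return One-row tibble of features plus `compartment` and `empty` flag.
#'   An empty compartment yields all-zero features with `empty = TRUE`.
#' @export
compute_features <- function(n, compartment = c("whole", "dendrite", "axon")) {
  compartment <- match.arg(compartment)
  nd <- compartment_nodes(n, compartment)
  zero <- tibble::tibble(
    neuron_id = n$neuron_id, compartment = compartment, tips = 0,
    total_length = 0, max_path_distance = 0, n_bifurcations = 0,
    max_branch_order = 0, avg_bifurcation_angle_remote = 0,
    max_euclidean_distance = 0, bbox_width = 0, bbox_height = 0,
    bbox_depth = 0, empty = TRUE)
  if (nrow(nd) <= 1) return(zero)
  pos <- match(nd$parent_id, nd$node_id)
  root <- which(is.na(pos))
  kids <- children_index(nd)
  n_children <- integer(nrow(nd))
  got <- as.integer(names(kids))
  n_children[got] <- lengths(kids)
  elen <- edge_lengths(nd)
  tips <- which(n_children == 0 & seq_len(nrow(nd)) != root)
  bifs <- which(n_children >= 2 & seq_len(nrow(nd)) != root)
  # path distance from root and branch order, by a rootward sweep
  ord <- order_topologically(nd, pos, root)
  pathd <- numeric(nrow(nd))
  border <- integer(nrow(nd))
  for (i in ord) {
    p <- pos[i]
    if (is.na(p)) next
    pathd[i] <- pathd[p] + elen[i]
    # the root (soma) never counts as a bifurcation, however many stems
    border[i] <- border[p] + as.integer(p %in% bifs)
  }
  # remote bifurcation angles
  angles <- numeric(0)
  xyz <- cbind(nd$x, nd$y, nd$z)
  for (b in bifs) {
    ch <- kids[[as.character(b)]]
    rp <- lapply(ch, function(ci) {
      cur <- ci
      while (n_children[cur] == 1) cur <- kids[[as.character(cur)]]
      xyz[cur, ] - xyz[b, ]
    })
    prs <- utils::combn(length(rp), 2)
    for (cix in seq_len(ncol(prs))) {
      v1 <- rp[[prs[1, cix]]]; v2 <- rp[[prs[2, cix]]]
      cosang <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
      angles <- c(angles, acos(pmin(1, pmax(-1, cosang))) * 180 / pi)
    }
  }
  rootd <- sqrt(rowSums(sweep(xyz, 2, xyz[root, ])^2))
  mpd <- if (length(tips)) max(pathd[tips]) else max(pathd)
  tibble::tibble(
    neuron_id = n$neuron_id, compartment = compartment,
    tips = length(tips), total_length = sum(elen),
    max_path_distance = mpd,
    n_bifurcations = length(bifs),
    max_branch_order = max(border),
    avg_bifurcation_angle_remote = if (length(angles)) mean(angles) else 0,
    max_euclidean_distance = max(rootd),
    bbox_width = diff(range(nd$x)), bbox_height = diff(range(nd$y)),
    bbox_depth = diff(range(nd$z)), empty = FALSE)
}

# positions in parent-before-child order
order_topologically <- function(nd, pos, root) {
  n <- nrow(nd)
  depth <- rep(NA_integer_, n)
  depth[root] <- 0L
  remaining <- setdiff(seq_len(n), root)
  while (length(remaining) > 0) {
    ready <- remaining[!is.na(depth[pos[remaining]])]
    if (length(ready) == 0) abort("disconnected node table")
    depth[ready] <- depth[pos[ready]] + 1L
    remaining <- setdiff(remaining, ready)
  }
  order(depth)
}

#' Feature table for many neurons
#'
#' @param neurons List of [neuron_morphology()].
#' @param compartment Passed to [compute_features()].
#' @return Tibble with one row per neuron.
#' @export
feature_table <- function(neurons, compartment = "whole") {
  dplyr::bind_rows(lapply(neurons, compute_features,
                          compartment = compartment))
}

#' Default dendritic quality-control intervals
#'
#' The closed feature intervals regarded as realistic for automated dendritic
#' tracings: Tips \[7, 143\], Length \[700, 13615\] um, Max Path Distance
#' \[108, 1382\] um, Average Bifurcation Angle Remote \[35, 129\] degrees,
#' Max Branch Order \[3, 32\].
#'
#' @param min_features_within A candidate is kept iff at least this many of
#'   the five features fall within their intervals. Default 4.
#' @return A `qc_intervals` object (named list of c(min, max) + threshold).
#' @export
qc_intervals <- function(min_features_within = 4L) {
  stopifnot(min_features_within >= 0, min_features_within <= 5)
  structure(
    list(intervals = list(
      tips = c(7, 143),
      total_length = c(700, 13615),
      max_path_distance = c(108, 1382),
      avg_bifurcation_angle_remote = c(35, 129),
      max_branch_order = c(3, 32)),
      min_features_within = as.integer(min_features_within)),
    class = "qc_intervals")
}

#' Apply QC intervals to a feature table
#'
#' Counts, per row, how many of the five QC features fall inside their
#' closed intervals and applies the keep rule (`n_within >=
#' min_features_within`).
#'
#' @param features Tibble with the five QC feature columns (as produced by
#'   [feature_table()]).
#' @param intervals A [qc_intervals()].
#' @return `features` with `n_within` and `pass` columns appended.
#' @export
qc_pass <- function(features, intervals = qc_intervals()) {
  iv <- intervals$intervals
  within <- sapply(names(iv), function(f) {
    features[[f]] >= iv[[f]][1] & features[[f]] <= iv[[f]][2]
  })
  if (is.null(dim(within))) within <- matrix(within, nrow = 1)
  features$n_within <- as.integer(rowSums(within))
  features$pass <- features$n_within >= intervals$min_features_within
  features
}

#' Quality-control filter over candidate tracings of one soma
#'
#' A candidate passes iff at least `min_features_within` of the five QC
#' features lie inside their closed intervals; among passing candidates the
#' one with greatest total length is kept. Used to pick one tracing per soma
#' from a set of automated reconstructions run at different background
#' thresholds.
#'
#' @param candidates List of [neuron_morphology()] traced from the same soma.
#' @param intervals A [qc_intervals()] (default).
#' @param compartment Compartment on which features are computed ("whole").
#' @return List with `kept` (the selected neuron, or NULL if all fail) and
#'   `table`: per-candidate tibble of features, `n_within` and `pass`.
#' @export
qc_filter <- function(candidates, intervals = qc_intervals(),
                      compartment = "whole") {
  if (length(candidates) == 0) {
    return(list(kept = NULL, table = tibble::tibble()))
  }
  feats <- qc_pass(feature_table(candidates, compartment = compartment),
                   intervals)
  kept <- NULL
  if (any(feats$pass)) {
    ok <- which(feats$pass)
    kept <- candidates[[ok[which.max(feats$total_length[ok])]]]
  }
  list(kept = kept, table = feats)
}

#' Per-region axonal projection length matrix
#'
#' Attributes each parent-child edge's length to the atlas region of the
#' child node's voxel; nodes outside the volume fall into the dedicated
#' `unlabeled` column (region 0). Row sums equal the compartment's total
#' cable length. Neurons should be resampled first so the attribution error
#' is bounded by the resampling step.
#'
#' @param neurons List of [neuron_morphology()].
#' @param atlas An `annotation_volume`.
#' @param compartment "axon" (default), "dendrite" or "whole".
#' @return Wide tibble: `neuron_id` plus one numeric column per region id
#'   (`r<ID>`; `r0` = unlabeled), values in um.
#' @export
projection_matrix <- function(neurons, atlas, compartment = "axon") {
  region_ids <- sort(unique(atlas$regions$id))
  cols <- paste0("r", c(0, region_ids))
  rows <- lapply(neurons, function(n) {
    nd <- compartment_nodes(n, compartment)
    out <- setNames(as.list(numeric(length(cols))), cols)
    if (nrow(nd) > 1) {
      elen <- edge_lengths(nd)
      keep <- elen > 0
      reg <- region_of(cbind(nd$x, nd$y, nd$z)[keep, , drop = FALSE], atlas)
      # drop the soma-anchored edge when it connects compartments
      if (compartment != "whole") {
        own <- nd$type[keep] %in% (if (compartment == "axon") 2 else c(3, 4))
        reg <- reg[own]; el <- elen[keep][own]
      } else el <- elen[keep]
      agg <- tapply(el, reg, sum)
      out[paste0("r", names(agg))] <- as.numeric(agg)
    }
    tibble::as_tibble(c(list(neuron_id = n$neuron_id), out))
  })
  dplyr::bind_rows(rows)
}
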