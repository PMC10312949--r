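#' Gaussian-mixture clustering of pooled arbor coordinates with BIC selection
#'
#' Fits Gaussian mixture models over a grid of component counts and
#' covariance families and returns the fit maximizing the Bayesian
#' Information Criterion, `BIC = 2 ln L - p ln n` (the `mclust` sign
#' convention: larger is better). Deterministic given `seed`.
#'
#' @param points n x 3 matrix of pooled node coordinates (voxel units by
#'   pipeline convention, but any units work).
#' @param k_range Candidate component counts. Default 1:9.
#' @param model_names Candidate `mclust` covariance families (spherical /
#'   diagonal / ellipsoidal, equal or varying); `NULL` (default) uses the
#'   full `mclust` default set.
#' @param seed Integer seed (EM initialization).
#' @return A `gmm_fit`: selected `k`, `model`, `bic`, log-likelihood,
#'   per-point `classification`, mixture `parameters` and the full BIC
#'   table. Has [tidy()] and [glance()] methods.
#' @export
fit_gmm_bic <- function(points, k_range = 1:9, model_names = NULL, seed = 1) {
  p <- as.matrix(points)
  stopifnot(ncol(p) == 3, nrow(p) >= max(k_range))
  fit <- withr::with_seed(seed, suppressWarnings(
    mclust::Mclust(p, G = k_range, modelNames = model_names,
                   verbose = FALSE)))
  if (is.null(fit)) {
    inform("fit_gmm_bic: unregularized fit failed; retrying with a conjugate prior (degenerate point cloud)")
    fit <- withr::with_seed(seed, suppressWarnings(
      mclust::Mclust(p, G = k_range, modelNames = model_names,
                     prior = mclust::priorControl(), verbose = FALSE)))
  }
  if (is.null(fit)) abort("GMM fitting failed for all candidate models")
  structure(
    list(k = fit$G, model = fit$modelName, bic = as.numeric(fit$bic),
         loglik = fit$loglik, n = fit$n, df = fit$df,
         classification = as.integer(fit$classification),
         parameters = fit$parameters, bic_table = fit$BIC,
         data = p),
    class = "gmm_fit")
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat("<gmm_fit> k = ", x$k, " (", x$model, "), BIC = ",
      format(x$bic, digits = 6), ", n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' @export
glance.gmm_fit <- function(x, ...) {
  tibble::tibble(k = x$k, model = x$model, bic = x$bic, loglik = x$loglik,
                 df = x$df, n = x$n)
}

#' @export
tidy.gmm_fit <- function(x, ...) {
  mu <- x$parameters$mean
  tibble::tibble(
    component = seq_len(x$k),
    weight = x$parameters$pro,
    mean_x = mu[1, ], mean_y = mu[2, ], mean_z = mu[3, ],
    size = as.integer(tabulate(x$classification, nbins = x$k)))
}

#' Classify an arbor domain as dendritic or axonal
#'
#' A domain is dendritic iff strictly more than half of its member nodes
#' belong to neurons whose soma lies inside the domain's alpha-shape;
#' otherwise it is axonal (ties go to axonal).
#'
#' @param node_neuron_ids Character vector: parent neuron of each member
#'   node.
#' @param somas Matrix of soma positions (same units as the shape), with
#'   rownames = neuron ids.
#' @param shape The domain's [alpha_shape()].
#' @return "dendritic" or "axonal".
#' @export
classify_domain_kind <- function(node_neuron_ids, somas, shape) {
  ids <- unique(node_neuron_ids)
  inside <- in_shape(shape, somas[ids, , drop = FALSE])
  names(inside) <- ids
  frac <- mean(inside[node_neuron_ids])
  if (frac > 0.5) "dendritic" else "axonal"
}

#' Construct an arbor domain
#'
#' @param domain_id Identifier string.
#' @param s_type Source soma-region id.
#' @param kind "dendritic" or "axonal".
#' @param hemisphere "left" or "right".
#' @param alpha Alpha-shape radius parameter (voxel units).
#' @param shape The [alpha_shape()] (may be NULL for mirrored copies).
#' @param mask The domain's [voxel_mask()].
#' @param centroid Member-node centroid (voxel units).
#' @param n_nodes Number of member nodes.
#' @return An `arbor_domain`.
#' @export
arbor_domain <- function(domain_id, s_type, kind, hemisphere, alpha, shape,
                         mask, centroid, n_nodes = NA_integer_) {
  if (length(mask$lin) == 0) {
    abort(paste0("domain ", domain_id, " has an empty voxel mask"))
  }
  structure(
    list(domain_id = domain_id, s_type = s_type, kind = kind,
         hemisphere = hemisphere, alpha = alpha, shape = shape, mask = mask,
         volume_mm3 = mask_volume_mm3(mask), centroid = centroid,
         n_nodes = n_nodes),
    class = "arbor_domain")
}

#' @export
print.arbor_domain <- function(x, ...) {
  cat("<arbor_domain> ", x$domain_id, " (", x$kind, ", ", x$hemisphere,
      "): ", length(x$mask$lin), " voxels, ",
      format(x$volume_mm3, digits = 4), " mm^3\n", sep = "")
  invisible(x)
}

# pooled node coordinates of a neuron list, voxel units, with per-node
# parent-neuron ids; soma nodes excluded from pooling (they are anchors,
# not arbor)
pool_coordinates <- function(neurons, atlas,
                             compartment = c("whole", "dendrite", "axon")) {
  compartment <- match.arg(compartment)
  pieces <- lapply(neurons, function(n) {
    nd <- compartment_nodes(n, compartment)
    nd <- nd[nd$type != 1, , drop = FALSE]
    if (nrow(nd) == 0) return(NULL)
    cbind(nd$x, nd$y, nd$z)
  })
  ids <- rep(vapply(neurons, function(n) n$neuron_id, character(1)),
             vapply(pieces, function(p) if (is.null(p)) 0L else nrow(p),
                    integer(1)))
  xyz <- do.call(rbind, pieces)
  if (is.null(xyz)) xyz <- matrix(numeric(0), ncol = 3)
  list(points = sweep(xyz, 2, atlas$origin) / atlas$voxel_size,
       neuron_id = ids)
}

soma_matrix_vox <- function(neurons, atlas) {
  s <- t(vapply(neurons, soma_position, numeric(3)))
  rownames(s) <- vapply(neurons, function(n) n$neuron_id, character(1))
  sweep(s, 2, atlas$origin) / atlas$voxel_size
}

#' Detect GMM arbor domains for one s-type
#'
#' Pools the (resampled) node coordinates of all neurons of one
#' soma-location type, clusters them with [fit_gmm_bic()], encloses each
#' cluster in an alpha-shape, classifies it dendritic vs axonal by the
#' majority-soma rule, and voxelizes it onto the atlas grid.
#'
#' @param neurons List of [neuron_morphology()] of one s-type (resampled).
#' @param atlas An `annotation_volume`.
#' @param s_type Soma-region id (used in domain ids).
#' @param alpha Alpha-shape parameter in voxel units. Default 0.4.
#' @param k_range,model_names,seed Passed to [fit_gmm_bic()].
#' @param max_points Deterministic subsample cap on pooled nodes before
#'   clustering. Default 6000.
#' @return List with `domains` (list of [arbor_domain()]) and `fit` (the
#'   `gmm_fit`).
#' @export
detect_arbor_domains <- function(neurons, atlas, s_type, alpha = 0.4,
                                 k_range = 1:9, model_names = NULL,
                                 seed = 1, max_points = 6000) {
  pool <- pool_coordinates(neurons, atlas, "whole")
  if (nrow(pool$points) < 5) abort("too few pooled nodes to form domains")
  if (nrow(pool$points) > max_points) {
    keep <- withr::with_seed(seed, sample(nrow(pool$points), max_points))
    pool$points <- pool$points[keep, , drop = FALSE]
    pool$neuron_id <- pool$neuron_id[keep]
  }
  fit <- fit_gmm_bic(pool$points, k_range = k_range,
                     model_names = model_names, seed = seed)
  somas <- soma_matrix_vox(neurons, atlas)
  mid <- dim(atlas$labels)[atlas$mirror_axis] / 2
  domains <- list()
  for (g in seq_len(fit$k)) {
    sel <- fit$classification == g
    pts <- pool$points[sel, , drop = FALSE]
    shape <- alpha_shape(pts, alpha = alpha)
    mask <- voxelize(shape, atlas)
    if (length(mask$lin) == 0) {
      warn(paste0("cluster ", g, " of s-type ", s_type,
                  " produced an empty voxel mask; domain dropped"))
      next
    }
    kind <- classify_domain_kind(pool$neuron_id[sel], somas, shape)
    ctr <- colMeans(pts)
    hemi <- if (ctr[atlas$mirror_axis] < mid) "left" else "right"
    did <- paste0("s", s_type, "_g", g, "_", substr(hemi, 1, 1))
    domains[[did]] <- arbor_domain(did, s_type, kind, hemi, alpha, shape,
                                   mask, ctr, n_nodes = sum(sel))
  }
  list(domains = domains, fit = fit)
}

#' Distinct axonal territories of a domain set
#'
#' Groups the axonal domains of one s-type into connected territories:
#' two domains belong to the same territory when their voxel masks overlap
#' or abut (within one voxel, 26-neighborhood). Mixture model selection
#' legitimately splits one elongated or heavy-tailed axonal cloud (an axon
#' corridor plus its terminal arbor) into several Gaussian components; the
#' territory count is the scale at which "how many distinct places does
#' this s-type project to" is answered.
#'
#' @param domains List of [arbor_domain()]s (non-axonal entries ignored).
#' @return Tibble with `domain_id` and `territory` (component label), plus
#'   attribute `n_territories`.
#' @export
axonal_territories <- function(domains) {
  ax <- domains[vapply(domains, function(d) d$kind == "axonal",
                       logical(1))]
  if (length(ax) == 0) {
    out <- tibble::tibble(domain_id = character(0), territory = integer(0))
    attr(out, "n_territories") <- 0L
    return(out)
  }
  dims <- ax[[1]]$mask$dims
  dil <- lapply(ax, function(d) dilate_lin(d$mask$lin, dims))
  parent <- seq_along(ax)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_along(ax)) {
    for (j in seq_len(i - 1)) {
      if (length(intersect(dil[[i]], ax[[j]]$mask$lin)) > 0) {
        parent[find(i)] <- find(j)
      }
    }
  }
  comp <- vapply(seq_along(ax), find, integer(1))
  lab <- match(comp, unique(comp))
  out <- tibble::tibble(
    domain_id = vapply(ax, function(d) d$domain_id, character(1)),
    territory = lab)
  attr(out, "n_territories") <- length(unique(lab))
  out
}

# 26-neighborhood dilation of a 0-based linear voxel index set
dilate_lin <- function(lin, dims) {
  idx <- voxel_unlinear(lin, dims)
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out <- lapply(seq_len(nrow(shifts)), function(s) {
    m <- sweep(idx, 2, shifts[s, ], "+")
    ok <- m[, 1] >= 0 & m[, 1] < dims[1] & m[, 2] >= 0 & m[, 2] < dims[2] &
      m[, 3] >= 0 & m[, 3] < dims[3]
    voxel_linear(m[ok, , drop = FALSE], dims)
  })
  sort(unique(unlist(out)))
}

#' Pooled dendritic domain of an s-type, per hemisphere
#'
#' Pools all dendritic node coordinates of the s-type's neurons separately
#' per hemisphere (no mixture clustering) and encloses each pool in an
#' alpha-shape. A hemisphere with no nodes receives the mirrored copy of
#' the other hemisphere's domain, so homologous contralateral regions are
#' always represented.
#'
#' @inheritParams detect_arbor_domains
#' @return Named list of two dendritic [arbor_domain()]s ("left", "right").
#' @export
pooled_dendrite_domain <- function(neurons, atlas, s_type, alpha = 0.4) {
  pool <- pool_coordinates(neurons, atlas, "dendrite")
  if (nrow(pool$points) == 0) abort("no dendritic nodes to pool")
  mid <- dim(atlas$labels)[atlas$mirror_axis] / 2
  side <- ifelse(pool$points[, atlas$mirror_axis] < mid, "left", "right")
  out <- list()
  for (h in c("left", "right")) {
    pts <- pool$points[side == h, , drop = FALSE]
    if (nrow(pts) == 0) next
    shape <- alpha_shape(pts, alpha = alpha)
    mask <- voxelize(shape, atlas)
    if (length(mask$lin) == 0) next
    did <- paste0("s", s_type, "_den_", substr(h, 1, 1))
    out[[h]] <- arbor_domain(did, s_type, "dendritic", h, alpha, shape,
                             mask, colMeans(pts), n_nodes = nrow(pts))
  }
  if (length(out) == 0) abort("no non-empty hemisphere pool for s-type")
  for (h in c("left", "right")) {
    if (!is.null(out[[h]])) next
    other <- out[[setdiff(c("left", "right"), h)]]
    ctr <- other$centroid
    ctr[atlas$mirror_axis] <- dim(atlas$labels)[atlas$mirror_axis] -
      ctr[atlas$mirror_axis]
    out[[h]] <- arbor_domain(
      paste0("s", s_type, "_den_", substr(h, 1, 1)), s_type, "dendritic",
      h, alpha, shape = NULL, mask = mirror_mask(other$mask, atlas),
      centroid = ctr, n_nodes = other$n_nodes)
  }
  out[c("left", "right")]
}

#' Assemble an ordered dendritic-domain panel
#'
#' The panel fixes the barcode column order and carries a per-voxel index
#' (which domains cover each voxel) so barcodes can be computed in one
#' traversal. Domains may overlap.
#'
#' @param domains List of dendritic [arbor_domain()]s, in the order the
#'   barcode should use.
#' @param atlas The `annotation_volume` the masks live on.
#' @return A `domain_panel`: `domains`, summary `table` (tibble), index
#'   vectors, and grid geometry.
#' @export
build_panel <- function(domains, atlas) {
  stopifnot(length(domains) > 0)
  dims <- dim(atlas$labels)
  for (d in domains) {
    if (!identical(d$mask$dims, as.integer(dims))) {
      abort("domain mask geometry does not match the atlas grid")
    }
  }
  tab <- dplyr::bind_rows(lapply(domains, function(d) tibble::tibble(
    domain_id = d$domain_id, s_type = d$s_type, kind = d$kind,
    hemisphere = d$hemisphere, n_voxels = length(d$mask$lin),
    volume_mm3 = d$volume_mm3)))
  index_lin <- unlist(lapply(domains, function(d) d$mask$lin),
                      use.names = FALSE)
  index_dom <- rep(seq_along(domains),
                   vapply(domains, function(d) length(d$mask$lin),
                          integer(1)))
  o <- order(index_lin)
  structure(
    list(domains = domains, table = tab, index_lin = index_lin[o],
         index_dom = index_dom[o], dims = as.integer(dims),
         voxel_size = atlas$voxel_size),
    class = "domain_panel")
}

#' @export
print.domain_panel <- function(x, ...) {
  cat("<domain_panel> ", nrow(x$table), " dendritic domains (",
      sum(x$table$hemisphere == "left"), " left / ",
      sum(x$table$hemisphere == "right"), " right), mean volume ",
      format(mean(x$table$volume_mm3), digits = 4), " mm^3\n", sep = "")
  invisible(x)
}

#' @export
tidy.domain_panel <- function(x, ...) x$table

#' Reconstruct per-domain masks from the panel index (round-trip check)
#' @param panel A [build_panel()] result.
#' @return List of sorted 0-based linear index vectors, in panel order.
#' @export
panel_masks <- function(panel) {
  out <- rep(list(integer(0)), nrow(panel$table))
  sp <- split(panel$index_lin, panel$index_dom)
  for (nm in names(sp)) out[[as.integer(nm)]] <- sort(sp[[nm]])
  names(out) <- panel$table$domain_id
  out
}

#' Whole-brain panel from per-hemisphere domain lists
#'
#' Concatenates, per hemisphere, the pooled dendrite-cohort domains followed
#' by the s-type dendritic domains; the barcode dimension is therefore
#' `2 * (n_den + n_stype)`. With the study-scale panel of 19 pooled
#' dendritic domains and 56 s-type domains per hemisphere this yields a
#' 150-dimensional barcode.
#'
#' @param den_domains List of dendritic [arbor_domain()]s from the pooled
#'   dendrite cohort (both hemispheres present).
#' @param stype_domains List of dendritic s-type [arbor_domain()]s (both
#'   hemispheres).
#' @param atlas The `annotation_volume`.
#' @return A `domain_panel` in the declared order: left den, left s-type,
#'   right den, right s-type.
#' @export
whole_brain_panel <- function(den_domains, stype_domains, atlas) {
  pick <- function(lst, h) lst[vapply(lst, function(d) d$hemisphere,
                                      character(1)) == h]
  ordered <- c(pick(den_domains, "left"), pick(stype_domains, "left"),
               pick(den_domains, "right"), pick(stype_domains, "right"))
  if (length(ordered) == 0) {
    abort("no domains supplied; downstream barcode computation refused")
  }
  build_panel(ordered, atlas)
}

#' Barcode dimensionality of a panel
#'
#' Either pass a built `domain_panel`, or the per-hemisphere domain counts
#' (`n_den` pooled-dendrite + `n_stype` s-type domains) to get the
#' structural dimension `2 * (n_den + n_stype)`.
#'
#' @param panel A `domain_panel`, or the per-hemisphere count of
#'   pooled-dendrite domains.
#' @param n_stype Per-hemisphere count of s-type dendritic domains (when
#'   `panel` is a count).
#' @return Integer dimension.
#' @export
barcode_dimension <- function(panel, n_stype = NULL) {
  if (inherits(panel, "domain_panel")) return(nrow(panel$table))
  stopifnot(is.numeric(panel), !is.null(n_stype))
  as.integer(2 * (panel + n_stype))
}
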