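#' Voxel mask of one neuron's compartment alpha-shape
#'
#' Builds the alpha-shape of the neuron's (resampled) compartment nodes in
#' atlas voxel units and voxelizes it. With fewer than 5 compartment nodes
#' the dilated-point fallback of [alpha_shape()] applies; a neuron with no
#' compartment nodes yields an empty mask.
#'
#' @param n A [neuron_morphology()] (resampled).
#' @param atlas An `annotation_volume`.
#' @param alpha Alpha parameter, voxel units. Default 0.4.
#' @param compartment "axon" (default; outgoing-connection semantics),
#'   "dendrite" or "whole".
#' @return A [voxel_mask()].
#' @export
neuron_mask <- function(n, atlas, alpha = 0.4, compartment = "axon") {
  nd <- compartment_nodes(n, compartment)
  if (compartment != "whole") nd <- nd[nd$type != 1, , drop = FALSE]
  if (nrow(nd) == 0) {
    return(voxel_mask(integer(0), dim(atlas$labels), atlas$voxel_size))
  }
  pts <- sweep(cbind(nd$x, nd$y, nd$z), 2, atlas$origin) / atlas$voxel_size
  inb <- pts >= 0 & sweep(pts, 2, dim(atlas$labels), "<")
  if (!any(rowSums(inb) == 3)) {
    warn(paste0("neuron ", n$neuron_id, " lies entirely outside the volume"))
    return(voxel_mask(integer(0), dim(atlas$labels), atlas$voxel_size))
  }
  shape <- alpha_shape(pts, alpha = alpha)
  mk <- voxelize(shape, atlas)
  # thin (near 1-D) stretches of an arbor contribute no tetrahedra to the
  # alpha-complex; the mask still must cover every compartment node
  node_lin <- voxel_linear(floor(pts[rowSums(inb) == 3, , drop = FALSE]),
                           dim(atlas$labels))
  voxel_mask(sort(unique(c(mk$lin, node_lin))), mk$dims, mk$voxel_size)
}

#' Connectivity barcode of one neuron mask against a domain panel
#'
#' Entry d is the number of voxels shared by the neuron mask and panel
#' domain d, computed by one traversal of the panel's per-voxel domain
#' index.
#'
#' @param mask A [voxel_mask()] (the neuron's).
#' @param panel A [build_panel()] / [whole_brain_panel()] result.
#' @param normalize "count" (raw overlap voxel counts, default) or "mm3"
#'   (scaled by voxel volume).
#' @return Named numeric vector, one entry per panel domain, in panel order.
#' @export
barcode <- function(mask, panel, normalize = c("count", "mm3")) {
  normalize <- match.arg(normalize)
  if (!identical(mask$dims, panel$dims) ||
      !isTRUE(all.equal(mask$voxel_size, panel$voxel_size))) {
    abort("mask and panel do not share atlas geometry")
  }
  hit <- panel$index_lin %in% mask$lin
  v <- tabulate(panel$index_dom[hit], nbins = nrow(panel$table))
  v <- as.numeric(v)
  if (normalize == "mm3") v <- v * (panel$voxel_size * 1e-3)^3
  setNames(v, panel$table$domain_id)
}

#' Connectivity matrix of a cohort
#'
#' One row per neuron, one column per panel domain (in panel order), entries
#' = overlap voxel counts between the neuron's compartment alpha-shape mask
#' and each dendritic domain.
#'
#' @param neurons List of (resampled) [neuron_morphology()].
#' @param panel A `domain_panel`.
#' @param atlas An `annotation_volume`.
#' @param alpha Alpha parameter for the per-neuron masks (voxel units).
#' @param compartment Compartment for the neuron masks ("axon" default).
#' @param normalize "count" or "mm3" (see [barcode()]).
#' @return Tibble: `neuron_id` plus one numeric column per domain id.
#' @export
connectivity_matrix <- function(neurons, panel, atlas, alpha = 0.4,
                                compartment = "axon",
                                normalize = "count") {
  rows <- lapply(neurons, function(n) {
    m <- neuron_mask(n, atlas, alpha = alpha, compartment = compartment)
    b <- barcode(m, panel, normalize = normalize)
    tibble::as_tibble(c(list(neuron_id = n$neuron_id), as.list(b)))
  })
  dplyr::bind_rows(rows)
}

#' Numeric barcode matrix from a connectivity tibble
#' @param conn A [connectivity_matrix()] tibble.
#' @return Numeric matrix with neuron_id rownames.
#' @export
barcode_matrix <- function(conn) {
  m <- as.matrix(conn[, setdiff(names(conn), "neuron_id"), drop = FALSE])
  rownames(m) <- conn$neuron_id
  m
}

#' Hemisphere-swap permutation of a panel
#'
#' The column permutation that maps each domain to its mirrored twin (same
#' s-type, same kind ordering, opposite hemisphere). On a mirror-symmetric
#' atlas, mirroring a neuron permutes its barcode by exactly this
#' permutation.
#'
#' @param panel A `domain_panel` built by [whole_brain_panel()].
#' @return Integer permutation vector.
#' @export
hemisphere_swap_permutation <- function(panel) {
  tab <- panel$table
  key <- sub("_(l|r)$", "", tab$domain_id)
  twin_h <- ifelse(tab$hemisphere == "left", "right", "left")
  match(paste(key, twin_h), paste(key, tab$hemisphere))
}
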