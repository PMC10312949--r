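#' Describe a toy mirrored-hemisphere annotation atlas
#'
#' Builds the specification for a synthetic annotation volume: a 3-D integer
#' label grid with a declared mid-sagittal mirror plane, standing in for a
#' reference space such as the Allen CCFv3 at 25 um. Regions are declared as
#' geometric primitives (boxes or ellipsoids) on one hemisphere; each is
#' automatically twinned with a mirrored copy (same name, opposite hemisphere,
#' id shifted by `twin_offset`) so that every region has a homologous
#' contralateral partner.
#'
#' @param regions A data frame with one row per base-hemisphere region and
#'   columns `id` (positive integer, unique), `name`, `shape` ("box" or
#'   "ellipsoid"), `cx`, `cy`, `cz` (primitive center, in voxel units) and
#'   `rx`, `ry`, `rz` (half-extent / semi-axis per axis, in voxels).
#' @param grid_shape Integer vector of length 3: grid size in voxels.
#' @param voxel_size Isotropic voxel edge length in micrometres (default 25).
#' @param mirror_axis Axis index (1-3) whose grid midplane is the sagittal
#'   mirror plane. Default 3.
#' @param twin_offset Integer added to `id` for the mirrored twin region.
#'
#' @return An object of class `toy_atlas_spec` with the full (two-hemisphere)
#'   region table.
#' @export
toy_atlas_spec <- function(regions, grid_shape, voxel_size = 25,
                           mirror_axis = 3, twin_offset = 500L) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1), voxel_size > 0,
            mirror_axis %in% 1:3)
  regions <- tibble::as_tibble(regions)
  req <- c("id", "name", "shape", "cx", "cy", "cz", "rx", "ry", "rz")
  missing_cols <- setdiff(req, names(regions))
  if (length(missing_cols) > 0) {
    abort(paste0("regions is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(regions$id)) abort("region ids must be unique")
  if (any(regions$id <= 0)) abort("region ids must be positive")
  if (!all(regions$shape %in% c("box", "ellipsoid"))) {
    abort("shape must be 'box' or 'ellipsoid'")
  }
  ctr <- as.matrix(regions[, c("cx", "cy", "cz")])
  ext <- as.matrix(regions[, c("rx", "ry", "rz")])
  for (ax in 1:3) {
    if (any(ctr[, ax] - ext[, ax] < 0 | ctr[, ax] + ext[, ax] > grid_shape[ax])) {
      abort("a region primitive extends outside the grid")
    }
  }
  base <- dplyr::mutate(regions, hemisphere = "left")
  twin <- base
  twin$id <- twin$id + twin_offset
  twin$hemisphere <- "right"
  ax_col <- c("cx", "cy", "cz")[mirror_axis]
  # mirror of continuous coordinate c (voxel units) about the grid midplane
  twin[[ax_col]] <- grid_shape[mirror_axis] - twin[[ax_col]]
  if (any(twin$id %in% base$id)) abort("twin_offset collides with base ids")
  full <- dplyr::bind_rows(base, twin)
  structure(
    list(grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
         mirror_axis = as.integer(mirror_axis), regions = full,
         twin_offset = as.integer(twin_offset)),
    class = "toy_atlas_spec"
  )
}

#' Paint a toy annotation volume from its specification
#'
#' Rasterizes each region primitive onto the integer label grid, in region
#' table order; where primitives of the same hemisphere overlap, the later
#' primitive wins and a warning is raised. The result is mirror-symmetric by
#' construction: the label of a voxel and of its mirrored voxel are twin
#' regions.
#'
#' @param spec A [toy_atlas_spec()].
#' @param seed Unused (painting is deterministic); kept for interface symmetry
#'   with the other generators.
#' @return An `annotation_volume`: list with `labels` (3-D integer array),
#'   `voxel_size` (um), `origin` (um, length 3), `mirror_axis`, and `regions`
#'   (tibble `id`, `name`, `hemisphere`).
#' @export
build_toy_atlas <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "toy_atlas_spec"))
  gs <- spec$grid_shape
  labels <- array(0L, dim = gs)
  # voxel center coordinates in voxel units
  cx <- (seq_len(gs[1]) - 0.5)
  cy <- (seq_len(gs[2]) - 0.5)
  cz <- (seq_len(gs[3]) - 0.5)
  overlap_warned <- FALSE
  for (i in seq_len(nrow(spec$regions))) {
    r <- spec$regions[i, ]
    inx <- abs(cx - r$cx) <= r$rx
    iny <- abs(cy - r$cy) <= r$ry
    inz <- abs(cz - r$cz) <= r$rz
    if (r$shape == "box") {
      sel <- outer(outer(inx, iny, "&"), inz, "&")
    } else {
      dx2 <- ((cx - r$cx) / r$rx)^2
      dy2 <- ((cy - r$cy) / r$ry)^2
      dz2 <- ((cz - r$cz) / r$rz)^2
      sel <- outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
    }
    prev <- labels[sel]
    if (!overlap_warned && any(prev != 0L)) {
      same_side <- spec$regions$hemisphere[match(prev[prev != 0L],
                                                 spec$regions$id)] ==
        r$hemisphere
      if (any(same_side)) {
        warn(paste0("region ", r$id, " overlaps an earlier region of the ",
                    "same hemisphere; later primitive wins"))
        overlap_warned <- TRUE
      }
    }
    labels[sel] <- as.integer(r$id)
  }
  structure(
    list(labels = labels, voxel_size = spec$voxel_size,
         origin = c(0, 0, 0), mirror_axis = spec$mirror_axis,
         regions = spec$regions[, c("id", "name", "hemisphere")]),
    class = "annotation_volume"
  )
}

#' Construct an annotation volume from components
#'
#' @param labels 3-D integer array of region labels (0 = unlabeled).
#' @param voxel_size Isotropic voxel edge, um.
#' @param origin Coordinate (um) of the grid corner of voxel (0,0,0).
#' @param mirror_axis Axis (1-3) carrying the mid-sagittal mirror plane.
#' @param regions Tibble with `id`, `name`, `hemisphere`.
#' @return An `annotation_volume`.
#' @export
annotation_volume <- function(labels, voxel_size, origin = c(0, 0, 0),
                              mirror_axis = 3, regions) {
  stopifnot(length(dim(labels)) == 3, voxel_size > 0, length(origin) == 3)
  structure(
    list(labels = labels, voxel_size = voxel_size, origin = as.numeric(origin),
         mirror_axis = as.integer(mirror_axis),
         regions = tibble::as_tibble(regions)),
    class = "annotation_volume"
  )
}

#' @export
print.annotation_volume <- function(x, ...) {
  cat("<annotation_volume> ", paste(dim(x$labels), collapse = " x "),
      " voxels @ ", x$voxel_size, " um, mirror axis ", x$mirror_axis, "\n",
      nrow(x$regions), " regions, ", sum(x$labels != 0L),
      " labeled voxels\n", sep = "")
  invisible(x)
}

#' Map micrometre coordinates to 0-based voxel indices
#'
#' Voxels are half-open: a point belongs to voxel `floor((p - origin) /
#' voxel_size)`.
#'
#' @param points Numeric matrix or data frame with 3 columns (um).
#' @param atlas An `annotation_volume`.
#' @param strict Error on out-of-bounds points (default TRUE). With
#'   `strict = FALSE` out-of-bounds rows are returned as NA.
#' @return Integer matrix of 0-based voxel indices.
#' @export
to_voxel <- function(points, atlas, strict = TRUE) {
  p <- as.matrix(points)
  stopifnot(ncol(p) == 3)
  idx <- floor(sweep(p, 2, atlas$origin) / atlas$voxel_size)
  oob <- idx < 0 | sweep(idx, 2, dim(atlas$labels), ">=")
  bad <- rowSums(oob) > 0
  if (any(bad)) {
    if (strict) abort(paste0(sum(bad), " point(s) outside the volume bounds"))
    idx[bad, ] <- NA_integer_
  }
  mode(idx) <- "integer"
  idx
}

#' Voxel center coordinates (um) for 0-based voxel indices
#' @param idx Integer matrix of 0-based voxel indices (n x 3).
#' @param atlas An `annotation_volume`.
#' @return Numeric matrix of centers in um.
#' @export
voxel_center <- function(idx, atlas) {
  sweep((as.matrix(idx) + 0.5) * atlas$voxel_size, 2, atlas$origin, "+")
}

#' Region label at each point
#'
#' @param points n x 3 matrix of um coordinates.
#' @param atlas An `annotation_volume`.
#' @return Integer vector of region ids; 0 for unlabeled, 0 also for points
#'   outside the volume (with `strict = FALSE` semantics).
#' @export
region_of <- function(points, atlas) {
  idx <- to_voxel(points, atlas, strict = FALSE)
  out <- integer(nrow(idx))
  ok <- !is.na(idx[, 1])
  if (any(ok)) {
    out[ok] <- atlas$labels[idx[ok, , drop = FALSE] + 1L]
  }
  out
}

#' Mirror points across the atlas midplane
#'
#' Reflects only the mirror-axis coordinate about the grid midplane; an
#' involution that maps voxel centers to voxel centers.
#'
#' @param points n x 3 matrix (um).
#' @param atlas An `annotation_volume`.
#' @return Mirrored matrix, same shape.
#' @export
mirror_point <- function(points, atlas) {
  p <- as.matrix(points)
  ax <- atlas$mirror_axis
  span <- dim(atlas$labels)[ax] * atlas$voxel_size
  p[, ax] <- 2 * atlas$origin[ax] + span - p[, ax]
  p
}

#' Hemisphere of each point
#'
#' "left" is the lower-index side of the mirror axis.
#' @inheritParams mirror_point
#' @return Character vector "left"/"right".
#' @export
hemisphere_of <- function(points, atlas) {
  p <- as.matrix(points)
  ax <- atlas$mirror_axis
  mid <- atlas$origin[ax] + dim(atlas$labels)[ax] * atlas$voxel_size / 2
  ifelse(p[, ax] < mid, "left", "right")
}

#' Mirror points into a canonical hemisphere
#'
#' Points already on the canonical side are returned unchanged; the rest are
#' reflected across the midplane. Used to pool somas ipsilaterally before
#' anatomy-based distance computation.
#'
#' @inheritParams mirror_point
#' @param side Canonical hemisphere, "left" (default) or "right".
#' @export
mirror_to_hemisphere <- function(points, atlas, side = c("left", "right")) {
  side <- match.arg(side)
  p <- as.matrix(points)
  wrong <- hemisphere_of(p, atlas) != side
  if (any(wrong)) p[wrong, ] <- mirror_point(p[wrong, , drop = FALSE], atlas)
  p
}

#' Mirror a set of 0-based voxel indices across the midplane
#' @param idx n x 3 integer matrix of 0-based voxel indices.
#' @param atlas An `annotation_volume`.
#' @export
mirror_voxel <- function(idx, atlas) {
  m <- as.matrix(idx)
  ax <- atlas$mirror_axis
  m[, ax] <- dim(atlas$labels)[ax] - 1L - m[, ax]
  mode(m) <- "integer"
  m
}

#' 0-based voxel indices of one region
#' @param region_id Region label.
#' @param atlas An `annotation_volume`.
#' @return n x 3 integer matrix of 0-based indices.
#' @export
region_voxels <- function(region_id, atlas) {
  w <- which(atlas$labels == region_id, arr.ind = TRUE)
  m <- w - 1L
  colnames(m) <- c("i", "j", "k")
  mode(m) <- "integer"
  m
}

# linear 0-based voxel index from 0-based (i,j,k)
voxel_linear <- function(idx, dims) {
  as.integer(idx[, 1] + dims[1] * (idx[, 2] + dims[2] * idx[, 3]))
}

# inverse of voxel_linear
voxel_unlinear <- function(lin, dims) {
  i <- lin %% dims[1]
  j <- (lin %/% dims[1]) %% dims[2]
  k <- lin %/% (dims[1] * dims[2])
  cbind(i = as.integer(i), j = as.integer(j), k = as.integer(k))
}
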