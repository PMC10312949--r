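#' 3-D alpha-shape of a point cloud
#'
#' Computes the Delaunay tetrahedralization of the points and keeps the
#' tetrahedra whose circumradius is at most `alpha`; the alpha-shape is the
#' union of the kept tetrahedra. As `alpha` tends to infinity the shape
#' equals the convex hull. Fewer than 5 points, or a (near-)coplanar cloud,
#' triggers a fallback: the union of balls of radius `fallback_radius`
#' around the input points (logged via a message).
#'
#' @param points n x 3 numeric matrix, in any consistent coordinate units;
#'   `alpha` is in the same units.
#' @param alpha Circumradius threshold (use `Inf` for the convex hull).
#' @param fallback_radius Dilation radius for the degenerate-input fallback;
#'   defaults to `alpha` if finite, else 1.
#' @return An `alpha_shape3` object: kept tetrahedra, circumradii, the
#'   triangulated (jittered) coordinates, bounding box, and fallback state.
#' @export
alpha_shape <- function(points, alpha = 0.4, fallback_radius = NULL) {
  stopifnot(alpha > 0)
  p <- unique(as.matrix(points))
  storage.mode(p) <- "double"
  if (is.null(fallback_radius)) {
    fallback_radius <- if (is.finite(alpha)) alpha else 1
  }
  degenerate <- nrow(p) < 5 ||
    {
      ctr <- sweep(p, 2, colMeans(p))
      sv <- svd(ctr, nu = 0, nv = 0)$d
      sv[3] < 1e-9 * max(sv[1], 1e-300)
    }
  if (degenerate) {
    inform(paste0("alpha_shape: degenerate input (", nrow(p),
                  " points); falling back to point dilation of radius ",
                  format(fallback_radius)))
    return(structure(
      list(points = p, alpha = alpha, tets = NULL, circumradius = NULL,
           fallback = TRUE, fallback_radius = fallback_radius,
           bbox = rbind(lo = apply(p, 2, min) - fallback_radius,
                        hi = apply(p, 2, max) + fallback_radius)),
      class = "alpha_shape3"))
  }
  d <- .delaunay3d_cpp(p)
  keep <- d$circumradius <= alpha
  tets <- d$tets[keep, , drop = FALSE]
  if (nrow(tets) == 0) {
    inform("alpha_shape: no tetrahedron passes the circumradius threshold; falling back to point dilation")
    return(alpha_shape_fallback(p, alpha, fallback_radius))
  }
  # membership and rasterization use the original coordinates; the internal
  # jitter only disambiguates the triangulation topology
  structure(
    list(points = p, alpha = alpha, tets = tets,
         circumradius = d$circumradius[keep], fallback = FALSE,
         fallback_radius = fallback_radius,
         bbox = rbind(lo = apply(p, 2, min), hi = apply(p, 2, max))),
    class = "alpha_shape3")
}

alpha_shape_fallback <- function(p, alpha, fallback_radius) {
  structure(
    list(points = p, alpha = alpha, tets = NULL, circumradius = NULL,
         fallback = TRUE, fallback_radius = fallback_radius,
         bbox = rbind(lo = apply(p, 2, min) - fallback_radius,
                      hi = apply(p, 2, max) + fallback_radius)),
    class = "alpha_shape3")
}

#' @export
print.alpha_shape3 <- function(x, ...) {
  cat("<alpha_shape3> ", nrow(x$points), " points, alpha = ", x$alpha,
      if (x$fallback) " [dilated-point fallback]" else
        paste0(", ", nrow(x$tets), " tetrahedra"), "\n", sep = "")
  invisible(x)
}

#' Point membership in an alpha-shape
#'
#' @param shape An [alpha_shape()].
#' @param query m x 3 matrix of points (same units as the shape).
#' @return Logical vector.
#' @export
in_shape <- function(shape, query) {
  q <- as.matrix(query)
  storage.mode(q) <- "double"
  if (shape$fallback) {
    r2 <- shape$fallback_radius^2
    apply(q, 1, function(p) {
      d2 <- (shape$points[, 1] - p[1])^2 + (shape$points[, 2] - p[2])^2 +
        (shape$points[, 3] - p[3])^2
      any(d2 <= r2)
    })
  } else {
    .points_in_tets_cpp(q, shape$points, shape$tets)
  }
}

#' Voxelize an alpha-shape onto an atlas grid
#'
#' A voxel belongs to the mask iff its center lies inside the shape. The
#' shape must be expressed in voxel units of the atlas (coordinates divided
#' by `voxel_size`, origin at 0), which is the convention used by the
#' domain-detection pipeline.
#'
#' @param shape An [alpha_shape()] in voxel units, or any object with an
#'   `in_shape()`-compatible membership function via `inside_fn`.
#' @param atlas An `annotation_volume` providing grid geometry.
#' @param inside_fn Optional membership function `f(points_matrix) ->
#'   logical`, overriding the shape (used for analytically defined shapes).
#' @return A `voxel_mask`: list with `lin` (sorted 0-based linear voxel
#'   indices), `dims`, `voxel_size`.
#' @export
voxelize <- function(shape, atlas, inside_fn = NULL) {
  dims <- dim(atlas$labels)
  if (is.null(inside_fn) && !shape$fallback) {
    lin <- .rasterize_tets_cpp(shape$points, shape$tets,
                               as.integer(dims), 1.0, c(0, 0, 0))
    return(voxel_mask(sort(lin), dims, atlas$voxel_size))
  }
  # generic path: probe voxel centers within the shape's bounding box
  if (is.null(inside_fn)) {
    bb <- shape$bbox
    f <- function(pts) in_shape(shape, pts)
  } else {
    bb <- rbind(lo = c(0, 0, 0), hi = dims)
    f <- inside_fn
  }
  rng <- lapply(1:3, function(j) {
    lo <- max(0L, floor(bb["lo", j] - 1))
    hi <- min(dims[j] - 1L, ceiling(bb["hi", j] + 1))
    if (lo > hi) integer(0) else seq.int(lo, hi)
  })
  if (any(lengths(rng) == 0)) return(voxel_mask(integer(0), dims,
                                                atlas$voxel_size))
  grid <- as.matrix(expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]]))
  centers <- grid + 0.5
  inside <- f(centers)
  lin <- voxel_linear(grid[inside, , drop = FALSE], dims)
  voxel_mask(sort(lin), dims, atlas$voxel_size)
}

#' Construct a voxel mask
#' @param lin Sorted 0-based linear voxel indices.
#' @param dims Grid dimensions.
#' @param voxel_size Voxel edge, um.
#' @export
voxel_mask <- function(lin, dims, voxel_size) {
  structure(list(lin = as.integer(lin), dims = as.integer(dims),
                 voxel_size = voxel_size),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat("<voxel_mask> ", length(x$lin), " voxels on ",
      paste(x$dims, collapse = " x "), " grid (",
      format(mask_volume_mm3(x), digits = 4), " mm^3)\n", sep = "")
  invisible(x)
}

#' Volume of a voxel mask in cubic millimetres
#' @param mask A [voxel_mask()].
#' @export
mask_volume_mm3 <- function(mask) {
  length(mask$lin) * (mask$voxel_size * 1e-3)^3
}

#' Mirror a voxel mask across the atlas midplane
#' @param mask A [voxel_mask()].
#' @param atlas The `annotation_volume` the mask lives on.
#' @export
mirror_mask <- function(mask, atlas) {
  idx <- voxel_unlinear(mask$lin, mask$dims)
  voxel_mask(sort(voxel_linear(mirror_voxel(idx, atlas), mask$dims)),
             mask$dims, mask$voxel_size)
}
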