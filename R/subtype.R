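#' Build the spatially tuned affinity bundle
#'
#' Combines connectivity and soma-location information into one affinity:
#' `MC` is the cosine similarity of barcode rows, `MD` the anatomy-based
#' soma distance map; both are linearly normalized to `[0, 1]` over their
#' off-diagonal entries. The Gaussian distance affinity is
#' `MDA = exp(-MD * MD)` (elementwise), so coincident somas get affinity 1
#' and maximally distant somas `exp(-1)`. The combined affinity is the
#' Hadamard product `A = MC * MDA`, with the diagonal forced to `max(A)`.
#' All-zero barcode rows are excluded (with a message) before
#' normalization.
#'
#' @param barcodes Neurons x domains numeric matrix (or
#'   [connectivity_matrix()] tibble).
#' @param dmap [soma_distance_map()] over the same neurons, same order.
#' @return An `affinity_bundle`: matrices `MC`, `MD`, `MDA`, `A`, plus the
#'   ids kept.
#' @export
build_affinity <- function(barcodes, dmap) {
  if (is.data.frame(barcodes)) barcodes <- barcode_matrix(barcodes)
  b <- as.matrix(barcodes)
  stopifnot(nrow(b) >= 3, nrow(dmap) == nrow(b))
  zero <- rowSums(b != 0) == 0
  if (any(zero)) {
    inform(paste0("build_affinity: excluding ", sum(zero),
                  " all-zero barcode row(s)"))
    b <- b[!zero, , drop = FALSE]
    dmap <- unclass(dmap)[!zero, !zero, drop = FALSE]
    if (nrow(b) < 3) abort("fewer than 3 neurons left after exclusions")
  }
  mc <- minmax_offdiag(cosine_similarity(b), diag_value = 1)
  md <- minmax_offdiag(unclass(dmap), diag_value = 0)
  mda <- exp(-md * md)
  a <- mc * mda
  diag(a) <- max(a)
  ids <- rownames(b) %||% as.character(seq_len(nrow(b)))
  dimnames(a) <- dimnames(mc) <- dimnames(md) <- dimnames(mda) <-
    list(ids, ids)
  structure(list(MC = mc, MD = md, MDA = mda, A = a, ids = ids),
            class = "affinity_bundle")
}

# linear min-max normalization computed on off-diagonal entries only
minmax_offdiag <- function(m, diag_value) {
  off <- m[row(m) != col(m)]
  lo <- min(off)
  hi <- max(off)
  out <- if (hi > lo) (m - lo) / (hi - lo) else m * 0
  diag(out) <- diag_value
  out
}

#' @export
print.affinity_bundle <- function(x, ...) {
  cat("<affinity_bundle> ", length(x$ids), " neurons; A in [",
      format(min(x$A), digits = 3), ", ", format(max(x$A), digits = 3),
      "]\n", sep = "")
  invisible(x)
}

#' Calinski-Harabasz index
#'
#' Between-cluster over within-cluster dispersion ratio,
#' `(B / (k - 1)) / (W / (n - k))`, of a labeled sample set.
#'
#' @param x Samples x features matrix.
#' @param labels Integer cluster labels.
#' @return Scalar score (NaN for k = 1 or k = n).
#' @export
calinski_harabasz <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x)
  k <- length(unique(labels))
  if (k < 2 || k >= n) return(NaN)
  mu <- colMeans(x)
  b <- 0
  w <- 0
  for (g in unique(labels)) {
    xg <- x[labels == g, , drop = FALSE]
    mg <- colMeans(xg)
    b <- b + nrow(xg) * sum((mg - mu)^2)
    w <- w + sum(sweep(xg, 2, mg)^2)
  }
  (b / (k - 1)) / (w / (n - k))
}

#' Spatially tuned connectivity subtyping
#'
#' Hierarchically clusters the combined affinity (Ward linkage on the
#' dissimilarity `D = 1 - A`), cuts the tree at each candidate cluster
#' count, scores each cut by the Calinski-Harabasz index with the rows of
#' `A` as feature vectors, and returns the labels at the best cut.
#'
#' @param bundle An [build_affinity()] result.
#' @param k_range Candidate cluster counts; default `2:min(10, n - 1)`.
#' @param linkage "ward.D2" (default) or "average".
#' @return A `subtype_result`: `labels` (named), `k`, `ch` tibble (score per
#'   candidate k), the `hclust` tree and the bundle. Has [tidy()] /
#'   [glance()] / [autoplot()] methods.
#' @export
subtype_clusters <- function(bundle, k_range = NULL,
                             linkage = c("ward.D2", "average")) {
  stopifnot(inherits(bundle, "affinity_bundle"))
  linkage <- match.arg(linkage)
  n <- length(bundle$ids)
  if (is.null(k_range)) k_range <- 2:min(10, n - 1)
  if (max(k_range) > n - 1) {
    warn("k_range truncated to n - 1")
    k_range <- k_range[k_range <= n - 1]
  }
  d <- as.dist(1 - bundle$A)
  tree <- hclust(d, method = linkage)
  ch <- vapply(k_range, function(k) {
    calinski_harabasz(bundle$A, cutree(tree, k = k))
  }, numeric(1))
  best <- k_range[which.max(ch)]
  labels <- cutree(tree, k = best)
  names(labels) <- bundle$ids
  structure(
    list(labels = labels, k = best,
         ch = tibble::tibble(k = k_range, ch = ch),
         tree = tree, bundle = bundle),
    class = "subtype_result")
}

#' @export
print.subtype_result <- function(x, ...) {
  cat("<subtype_result> k = ", x$k, " over ", length(x$labels),
      " neurons; sizes: ",
      paste(tabulate(x$labels, nbins = x$k), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.subtype_result <- function(x, ...) {
  tibble::tibble(neuron_id = names(x$labels),
                 subtype = as.integer(x$labels))
}

#' @export
glance.subtype_result <- function(x, ...) {
  tibble::tibble(k = x$k, n = length(x$labels),
                 ch_max = max(x$ch$ch, na.rm = TRUE),
                 ch_median = stats::median(x$ch$ch, na.rm = TRUE))
}

#' Per-cluster summaries of a subtyping result
#'
#' @param result A [subtype_clusters()] result.
#' @param barcodes Barcode matrix/tibble over the same neurons (panel
#'   order columns).
#' @param somas Optional n x 3 soma matrix (um), rownames = neuron ids.
#' @param projections Optional [projection_matrix()] tibble for regional
#'   projection-length profiles.
#' @param top_n How many top target domains to report. Default 5.
#' @return Tibble: per cluster its size, soma centroid, top target domains
#'   (list-column, by mean barcode), mean barcode and mean projection
#'   profile (list-columns).
#' @export
subtype_report <- function(result, barcodes, somas = NULL,
                           projections = NULL, top_n = 5) {
  if (is.data.frame(barcodes)) barcodes <- barcode_matrix(barcodes)
  b <- as.matrix(barcodes)[names(result$labels), , drop = FALSE]
  rows <- lapply(sort(unique(result$labels)), function(g) {
    ids <- names(result$labels)[result$labels == g]
    mb <- colMeans(b[ids, , drop = FALSE])
    top <- names(sort(mb, decreasing = TRUE))[seq_len(min(top_n, length(mb)))]
    ctr <- if (!is.null(somas)) {
      colMeans(as.matrix(somas)[ids, , drop = FALSE])
    } else c(NA_real_, NA_real_, NA_real_)
    proj <- if (!is.null(projections)) {
      pm <- projections[match(ids, projections$neuron_id), , drop = FALSE]
      list(colMeans(as.matrix(pm[, setdiff(names(pm), "neuron_id")])))
    } else list(NULL)
    tibble::tibble(subtype = g, size = length(ids),
                   soma_x = ctr[1], soma_y = ctr[2], soma_z = ctr[3],
                   top_targets = list(top), mean_barcode = list(mb),
                   mean_projection = proj)
  })
  dplyr::bind_rows(rows)
}
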