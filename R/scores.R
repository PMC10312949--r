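#' Exponential cluster-pair similarity (m-score / c-score)
#'
#' Quantifies how similar two clusters of feature vectors are, combining
#' inter-class separation and intra-class spread:
#' `score = exp(-2 * D_inter / (0.5 * (D_intra1 + D_intra2)))`,
#' where `D_inter` is the Manhattan distance between the cluster centers
#' (per-feature means) and `D_intra(x)` is the average over samples of the
#' mean Manhattan distance to all other samples of the same cluster (0 for
#' singletons). Identical clusters score 1; well-separated tight clusters
#' score near 0. Degenerate rule: if both intra distances are 0, the score
#' is 1 when the centers coincide and 0 otherwise.
#'
#' Applied to morphometric features the result is the m-score; applied to
#' connectivity barcodes, the c-score.
#'
#' @param features_a,features_b Numeric matrices (samples x features), same
#'   feature dimension.
#' @param standardize Z-score each feature over the pooled samples of both
#'   clusters before distances (default TRUE; the feature panels span
#'   several orders of magnitude in units).
#' @return One-row tibble: `dist_inter`, `dist_intra_1`, `dist_intra_2`,
#'   `score`.
#' @export
mc_score <- function(features_a, features_b, standardize = TRUE) {
  a <- as.matrix(features_a)
  b <- as.matrix(features_b)
  if (ncol(a) != ncol(b)) abort("feature dimensions differ between clusters")
  if (standardize) {
    pooled <- rbind(a, b)
    mu <- colMeans(pooled)
    sdv <- apply(pooled, 2, sd)
    sdv[sdv == 0 | !is.finite(sdv)] <- 1
    a <- sweep(sweep(a, 2, mu), 2, sdv, "/")
    b <- sweep(sweep(b, 2, mu), 2, sdv, "/")
  }
  manhattan_intra <- function(m) {
    if (nrow(m) < 2) return(0)
    d <- as.matrix(dist(m, method = "manhattan"))
    mean(rowSums(d) / (nrow(m) - 1))
  }
  dist_inter <- sum(abs(colMeans(a) - colMeans(b)))
  i1 <- manhattan_intra(a)
  i2 <- manhattan_intra(b)
  denom <- 0.5 * (i1 + i2)
  score <- if (denom > 0) exp(-2 * dist_inter / denom) else
    if (dist_inter == 0) 1 else 0
  tibble::tibble(dist_inter = dist_inter, dist_intra_1 = i1,
                 dist_intra_2 = i2, score = score)
}

#' Pairwise m-score / c-score similarity matrix over groups
#'
#' @param groups Named list of feature matrices (samples x features), one
#'   per group; all with the same feature dimension.
#' @param standardize "global" (default; z-score each feature over all
#'   groups pooled) or "pairwise" (standardize within each pair inside
#'   [mc_score()]).
#' @return A symmetric `similarity_matrix` (plain matrix with group
#'   dimnames and attribute `metric = "mc_score"`); diagonal = 1.
#' @export
score_matrix <- function(groups, standardize = c("global", "pairwise")) {
  standardize <- match.arg(standardize)
  stopifnot(length(groups) >= 2)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  if (standardize == "global") {
    pooled <- do.call(rbind, lapply(groups, as.matrix))
    mu <- colMeans(pooled)
    sdv <- apply(pooled, 2, sd)
    sdv[sdv == 0 | !is.finite(sdv)] <- 1
    groups <- lapply(groups, function(g)
      sweep(sweep(as.matrix(g), 2, mu), 2, sdv, "/"))
  }
  k <- length(groups)
  m <- diag(1, k)
  dimnames(m) <- list(names(groups), names(groups))
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      m[i, j] <- m[j, i] <- mc_score(groups[[i]], groups[[j]],
                                     standardize = FALSE)$score
    }
  }
  attr(m, "metric") <- "mc_score"
  m
}

#' Elementwise ratio of c-scores over m-scores
#'
#' Entries where the m-score is exactly 0 are undefined (NA) and excluded
#' from summaries. Ratios below 1 mean connectivity features separate the
#' two groups more sharply than morphology features do.
#'
#' @param c_scores,m_scores Same-shaped [score_matrix()] results over the
#'   same group order.
#' @return List with `ratio` (matrix, NA where undefined),
#'   `frac_lt_1` (fraction of defined off-diagonal entries below 1) and
#'   `leaf_order` (display order: Ward/Euclidean dendrogram leaves of the
#'   m-score matrix).
#' @export
ratio_matrix <- function(c_scores, m_scores) {
  stopifnot(identical(dim(c_scores), dim(m_scores)))
  ratio <- unclass(c_scores) / unclass(m_scores)
  ratio[unclass(m_scores) == 0] <- NA_real_
  off <- ratio[row(ratio) != col(ratio)]
  frac <- mean(off[!is.na(off)] < 1)
  hc <- hclust(dist(unclass(m_scores), method = "euclidean"),
               method = "ward.D2")
  list(ratio = ratio, frac_lt_1 = frac, leaf_order = hc$order)
}

#' Anatomy-covariance (Mahalanobis) soma distance map of one s-type
#'
#' All somas are first mirrored to the canonical hemisphere; the metric's
#' covariance is the covariance of the region's ipsilateral voxel-center
#' coordinates (um). The entry for somas i, j is the squared form
#' `(si - sj)' Cov^-1 (si - sj)` as used throughout the package (set
#' `sqrt = TRUE` for the rooted variant). A singular covariance is
#' ridge-regularized (1e-6 x mean diagonal trace) with a message.
#'
#' @param somas n x 3 matrix of soma positions (um), rownames = neuron ids.
#' @param region_id Region whose ipsilateral voxel cloud defines the
#'   covariance.
#' @param atlas An `annotation_volume`.
#' @param side Canonical hemisphere. Default "left".
#' @param sqrt Return the square-rooted distance instead of the printed
#'   squared form. Default FALSE.
#' @return A `soma_distance_map`: symmetric matrix with zero diagonal,
#'   attributes `covariance` and `mirrored = TRUE`.
#' @export
soma_distance_map <- function(somas, region_id, atlas, side = "left",
                              sqrt = FALSE) {
  s <- as.matrix(somas)
  stopifnot(nrow(s) >= 2, ncol(s) == 3)
  s <- mirror_to_hemisphere(s, atlas, side = side)
  rid <- atlas$regions
  ipsi_ids <- rid$id[rid$name %in%
                       rid$name[rid$id == region_id] &
                       rid$hemisphere == side]
  if (length(ipsi_ids) == 0) ipsi_ids <- region_id
  rv <- do.call(rbind, lapply(ipsi_ids, region_voxels, atlas = atlas))
  if (is.null(rv) || nrow(rv) < 4) {
    abort("region has too few voxels to define an anatomy covariance")
  }
  centers <- voxel_center(rv, atlas)
  cv <- cov(centers)
  if (!is.finite(rcond_sym(cv)) || rcond_sym(cv) < 1e-12) {
    eps <- 1e-6 * mean(diag(cv))
    inform("soma_distance_map: singular anatomy covariance; applying ridge regularization")
    cv <- cv + diag(eps, 3)
  }
  d <- anatomy_distance(s, cv, sqrt = sqrt)
  attr(d, "covariance") <- cv
  attr(d, "mirrored") <- TRUE
  class(d) <- c("soma_distance_map", class(d))
  d
}

#' Pairwise Mahalanobis-form distances under a given covariance
#'
#' The quadratic form `(si - sj)' Cov^-1 (si - sj)` for every soma pair
#' (squared form; no root unless `sqrt = TRUE`). Under an identity
#' covariance this is the squared Euclidean distance.
#'
#' @param somas n x 3 position matrix (um).
#' @param covariance 3 x 3 covariance matrix.
#' @param sqrt Take the square root of the form. Default FALSE.
#' @return Symmetric n x n matrix with zero diagonal.
#' @export
anatomy_distance <- function(somas, covariance, sqrt = FALSE) {
  s <- as.matrix(somas)
  ci <- solve(covariance)
  n <- nrow(s)
  d <- matrix(0, n, n, dimnames = list(rownames(s), rownames(s)))
  for (i in seq_len(n - 1)) {
    dif <- sweep(s[(i + 1):n, , drop = FALSE], 2, s[i, ])
    q <- rowSums((dif %*% ci) * dif)
    d[i, (i + 1):n] <- q
    d[(i + 1):n, i] <- q
  }
  if (sqrt) d <- base::sqrt(pmax(d, 0))
  d
}

rcond_sym <- function(m) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (max(abs(ev)) == 0) return(0)
  min(abs(ev)) / max(abs(ev))
}

#' Pearson correlation between a distance map and a similarity matrix
#'
#' Computed over strictly-upper-triangle entries, both matrices in the same
#' neuron order. Returns NA with a warning if either vector is constant.
#'
#' @param dmap Square distance matrix.
#' @param sim Square similarity matrix, same order.
#' @return Scalar correlation.
#' @export
dmap_similarity_correlation <- function(dmap, sim) {
  stopifnot(identical(dim(dmap), dim(sim)))
  ut <- upper.tri(dmap)
  x <- dmap[ut]
  y <- sim[ut]
  if (sd(x) == 0 || sd(y) == 0) {
    warn("constant vector; correlation undefined")
    return(NA_real_)
  }
  cor(x, y)
}

#' Cosine similarity matrix over barcode rows
#'
#' Zero rows get similarity 0 to everything, 1 on the diagonal.
#'
#' @param x Numeric matrix (rows = neurons).
#' @return Symmetric matrix with unit diagonal.
#' @export
cosine_similarity <- function(x) {
  x <- as.matrix(x)
  nrm <- base::sqrt(rowSums(x^2))
  xn <- x / ifelse(nrm > 0, nrm, 1)
  s <- tcrossprod(xn)
  s[nrm == 0, ] <- 0
  s[, nrm == 0] <- 0
  diag(s) <- 1
  if (!is.null(rownames(x))) dimnames(s) <- list(rownames(x), rownames(x))
  s
}

#' Pairwise class overlap measured by a linear SVM
#'
#' Fits a linear soft-margin classifier (cost 1000 by default) on the two
#' classes and reports the resubstitution misclassification percentage: 0
#' for cleanly separable classes, about 50 for indistinguishable ones.
#' Duplicated identical rows across the classes are reported, not fatal.
#'
#' @param class_a,class_b Numeric feature matrices (samples x features).
#' @param cost SVM cost parameter. Default 1000.
#' @return Overlap percentage (scalar in `[0, 100]`).
#' @export
svm_overlap <- function(class_a, class_b, cost = 1000) {
  a <- as.matrix(class_a)
  b <- as.matrix(class_b)
  stopifnot(nrow(a) >= 5, nrow(b) >= 5, ncol(a) == ncol(b))
  dup <- sum(apply(b, 1, function(r) any(colSums(abs(t(a) - r)) == 0)))
  x <- rbind(a, b)
  y <- factor(rep(c("a", "b"), c(nrow(a), nrow(b))))
  const <- apply(x, 2, sd) == 0
  if (all(const)) return(50)
  fit <- e1071::svm(x[, !const, drop = FALSE], y, kernel = "linear",
                    cost = cost, scale = TRUE)
  pred <- stats::predict(fit, x[, !const, drop = FALSE])
  pct <- mean(pred != y) * 100
  if (dup > 0) {
    inform(paste0("svm_overlap: ", dup,
                  " identical rows appear in both classes"))
  }
  pct
}

#' Append principal components of the connectivity matrix to m-features
#'
#' Column-centers the connectivity matrix, takes its first `n_components`
#' principal-component scores and appends them to the morphology feature
#' rows (same sample order). This is the dimension-increment step that makes
#' morphologically entangled s-types separable.
#'
#' @param m_features Samples x morphology-features matrix.
#' @param connectivity Samples x domains barcode matrix, same row order.
#' @param n_components Number of PCs to append. Default 3.
#' @return Matrix with `ncol(m_features) + n_components` columns.
#' @export
pca_augment <- function(m_features, connectivity, n_components = 3) {
  m <- as.matrix(m_features)
  cmat <- as.matrix(connectivity)
  stopifnot(nrow(m) == nrow(cmat))
  n_components <- min(n_components, ncol(cmat), nrow(cmat) - 1)
  pc <- prcomp(cmat, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  colnames(scores) <- paste0("conn_pc", seq_len(n_components))
  cbind(m, scores)
}
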