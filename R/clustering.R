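#' Manhattan distance matrix between community compositions
#'
#' d(i, j) = sum_k |x_ik - x_jk|, robust to the outlier samples common in
#' compositional pigment data.
#'
#' @param table Samples x classes matrix or data frame of relative
#'   contributions (percent of total chl a).
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
manhattan_distance_matrix <- function(table) {
  m <- as.matrix(table)
  if (nrow(m) < 2) stop("need at least two samples")
  if (any(!is.finite(m))) stop("compositions must be complete")
  as.matrix(stats::dist(m, method = "manhattan"))
}

#' Hierarchical clustering of communities cut at k groups
#'
#' Agglomerative clustering on a precomputed distance matrix (average
#' linkage by default; Ward is excluded because the distance is
#' non-Euclidean), cut into `k` clusters.
#'
#' @param d Distance matrix (as from [manhattan_distance_matrix()]) or a
#'   `dist` object.
#' @param k Number of clusters (>= 1, <= number of samples).
#' @param linkage `"average"`, `"complete"` or `"single"`.
#' @return List with `labels` (integer cluster per sample), `tree` (the
#'   `hclust` object: merge order and heights) and `k`.
#' @export
hca_cut <- function(d, k = 4, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  if (k < 1) stop("k must be >= 1")
  dd <- if (inherits(d, "dist")) d else stats::as.dist(d)
  n <- attr(dd, "Size")
  if (k > n) stop("k exceeds the number of samples")
  tree <- stats::hclust(dd, method = linkage)
  labels <- stats::cutree(tree, k = k)
  list(labels = labels, tree = tree, k = k)
}

#' Principal-component check of a clustering
#'
#' Centered (unscaled: percent units are commensurate) principal component
#' analysis of the composition table, with a summary of how well the
#' cluster labels separate in the PC1-PC2 plane: for every label pair, the
#' distance between centroids divided by the mean within-cluster spread
#' (mean distance of members to their own centroid). Ratios well above 1
#' indicate the clusters are not an artefact of the tree cut.
#'
#' @param table Samples x classes composition table.
#' @param labels Cluster labels (one per sample).
#' @param scale. Scale columns to unit variance before the decomposition.
#' @return List with `scores`, `loadings`, `variance_fraction` and
#'   `separation` (data frame: pair, centroid distance, mean spread,
#'   ratio).
#' @export
pca_validation <- function(table, labels, scale. = FALSE) {
  m <- as.matrix(table)
  if (nrow(m) < 3) stop("need at least three samples")
  if (all(apply(m, 2, stats::var) == 0)) stop("constant table")
  keep <- apply(m, 2, stats::var) > 0 | !scale.
  p <- stats::prcomp(m[, keep, drop = FALSE], center = TRUE, scale. = scale.)
  vf <- p$sdev^2 / sum(p$sdev^2)
  sc <- p$x[, seq_len(min(2, ncol(p$x))), drop = FALSE]
  labs <- as.character(labels)
  cent <- do.call(rbind, lapply(split(seq_len(nrow(sc)), labs), function(i)
    colMeans(sc[i, , drop = FALSE])))
  spread <- vapply(split(seq_len(nrow(sc)), labs), function(i) {
    ctr <- colMeans(sc[i, , drop = FALSE])
    mean(sqrt(rowSums((sc[i, , drop = FALSE] -
                         rep(ctr, each = length(i)))^2)))
  }, numeric(1))
  ug <- rownames(cent)
  if (length(ug) >= 2) {
    pairs <- utils::combn(ug, 2)
    sep <- data.frame(
      a = pairs[1, ], b = pairs[2, ],
      centroid_distance = apply(pairs, 2, function(pr)
        sqrt(sum((cent[pr[1], ] - cent[pr[2], ])^2))),
      mean_spread = apply(pairs, 2, function(pr)
        mean(spread[pr])),
      stringsAsFactors = FALSE)
    sep$ratio <- ifelse(sep$mean_spread > 0,
                        sep$centroid_distance / sep$mean_spread, Inf)
  } else {
    sep <- data.frame(a = character(0), b = character(0),
                      centroid_distance = numeric(0),
                      mean_spread = numeric(0), ratio = numeric(0))
  }
  list(scores = p$x, loadings = p$rotation, variance_fraction = vf,
       separation = sep)
}

#' Mean size class of the pigmented community
#'
#' Diagnostic-pigment size fractions following the Bricaud/Uitz
#' convention: micro ~ 1.41 Fuco + 1.41 Perid; nano ~ 1.27 Hex Fuco +
#' 0.35 But Fuco + 0.60 Allo; pico ~ 1.01 Chl b + 0.86 Zea. Fractions are
#' normalized to 1 and the size index is their weighted mean with tags
#' micro = 3, nano = 2, pico = 1.
#'
#' @param pigments Samples x pigments matrix or data frame holding the
#'   seven diagnostic pigments (ug/L), named as in [pigment_names()].
#' @return Data frame with `micro`, `nano`, `pico` fractions and
#'   `size_index`; all NA for samples where the seven pigments are zero.
#' @export
mean_size_index <- function(pigments) {
  m <- as.matrix(as.data.frame(pigments, check.names = FALSE))
  need <- c("Fuco", "Perid", "Hex Fuco", "But Fuco", "Allo", "Chl b", "Zea")
  if (!all(need %in% colnames(m)))
    stop("missing diagnostic pigments: ",
         paste(setdiff(need, colnames(m)), collapse = ", "))
  micro <- 1.41 * m[, "Fuco"] + 1.41 * m[, "Perid"]
  nano <- 1.27 * m[, "Hex Fuco"] + 0.35 * m[, "But Fuco"] + 0.60 * m[, "Allo"]
  pico <- 1.01 * m[, "Chl b"] + 0.86 * m[, "Zea"]
  tot <- micro + nano + pico
  out <- data.frame(micro = micro / tot, nano = nano / tot,
                    pico = pico / tot)
  out$size_index <- 3 * out$micro + 2 * out$nano + 1 * out$pico
  out[tot == 0, ] <- NA_real_
  rownames(out) <- rownames(m)
  out
}
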