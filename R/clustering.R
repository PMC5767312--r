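#' Euclidean distances between samples
#'
#' `d(i, j) = sqrt(sum over probes of (x_pi - x_pj)^2)` on the columns of
#' the expression matrix.
#'
#' @param mat log2 expression matrix (probes x samples), no missing values.
#' @return symmetric distance matrix with zero diagonal, sample ids as
#'   dimnames.
#' @export
distance_matrix <- function(mat) {
  if (ncol(mat) < 2L) stop("need >= 2 samples")
  if (anyNA(mat) || any(!is.finite(mat)))
    stop("missing or non-finite values in the expression matrix")
  as.matrix(dist(t(mat), method = "euclidean"))
}

#' Ward hierarchical clustering of samples
#'
#' Agglomerative clustering with Ward's minimum-variance criterion in its
#' squared-Euclidean dialect (`hclust` method `ward.D2`): distances are
#' squared inside the Lance-Williams update and merge heights are reported
#' on the original distance scale. Merge heights are non-decreasing.
#'
#' @param distances symmetric distance matrix (e.g. [distance_matrix()]).
#' @return an `hclust` tree with sample labels.
#' @export
ward_linkage <- function(distances) {
  distances <- as.matrix(distances)
  if (nrow(distances) != ncol(distances) ||
      !isTRUE(all.equal(distances, t(distances), tolerance = 1e-8)) ||
      any(diag(distances) != 0))
    stop("non-metric input: distance matrix must be symmetric with zero diagonal")
  hclust(as.dist(distances), method = "ward.D2")
}

#' Cut a linkage tree into k clusters
#'
#' Labels induced by removing the `k - 1` highest merges.
#'
#' @param tree an `hclust` tree.
#' @param k number of clusters, `1 <= k <= n`.
#' @return named integer vector of cluster labels per sample.
#' @export
cut_tree <- function(tree, k) {
  n <- length(tree$labels %||% tree$order)
  if (k < 1 || k > n) stop("k out of range [1, ", n, "]")
  cutree(tree, k = k)
}

#' Export a dendrogram as Newick
#'
#' @param tree an `hclust` tree.
#' @param path output file; when NULL the Newick string is returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(tree)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Does a cut split the samples exactly along a factor?
#'
#' Utility for structure checks: TRUE iff the clustering at `k` groups
#' samples identically to the grouping induced by `factor_values`.
#'
#' @param labels cluster labels from [cut_tree()].
#' @param factor_values vector of factor values in the same sample order.
#' @return logical.
#' @export
cut_matches_factor <- function(labels, factor_values) {
  tab <- table(labels, factor_values)
  all(rowSums(tab > 0) == 1L) && all(colSums(tab > 0) == 1L)
}
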