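# Average-linkage agglomerative clustering of the voxel rows of Z and the
# Calinski-Harabasz cut-height search. The distance matrix and merge tree come
# from stats::dist / stats::hclust (UPGMA); the CH index, its variation
# decomposition and the iterative 1 percent height-shrink search are
# implemented here.

.asZ <- function(Z) {
  if (is(Z, "GroupMatrix")) Z@Z
  else if (is(Z, "SubjectSeries")) Z@data
  else as.matrix(Z)
}

#' Pairwise Euclidean distances between voxel rows
#'
#' @param Z a [GroupMatrix-class], [SubjectSeries-class] or plain matrix with
#'   at least two rows.
#' @return a `stats::dist` object (condensed lower triangle).
#' @export
pairwiseEuclidean <- function(Z) {
  m <- .asZ(Z)
  if (nrow(m) < 2L) stop("need at least two voxels")
  if (any(!is.finite(m)))
    hippStop("invalidDataError", "non-finite rows in the clustering substrate")
  stats::dist(m, method = "euclidean")
}

#' Build the average-linkage dendrogram
#'
#' Agglomerative UPGMA: the distance between two clusters is the arithmetic
#' mean of all inter-cluster pairwise distances, so merge heights are
#' non-decreasing (no inversions).
#'
#' @param D a `stats::dist` object from [pairwiseEuclidean()].
#' @return an object of class `hclust`.
#' @export
buildDendrogram <- function(D) {
  stats::hclust(D, method = "average")
}

#' Cut the dendrogram at a height
#'
#' Applies exactly the merges with height less than or equal to `h`
#' (inclusive, so tied heights merge together) and labels the resulting
#' clusters 1..K in order of each cluster's first member in canonical voxel
#' order.
#'
#' @param tree an `hclust` object.
#' @param h nonnegative cut height.
#' @return integer label vector of length N.
#' @export
cutAtHeight <- function(tree, h) {
  stopifnot(h >= 0)
  n <- length(tree$height) + 1L
  k <- n - sum(tree$height <= h)
  labs <- stats::cutree(tree, k = k)
  as.integer(match(labs, unique(labs)))
}

# Cluster means and the two variation terms, via rowsum (no N x p copies).
# Returns the unweighted between term B (as printed), the size-weighted
# between term Bw, and W computed from the total sum of squares identity
# TSS = W + Bw.
.decompose <- function(m, labels) {
  K <- max(labels)
  sizes <- tabulate(labels, nbins = K)
  if (any(sizes == 0L))
    hippStop("invalidLabelsError", "labels must use every value 1..K")
  centers <- rowsum(m, labels) / sizes
  grand <- colMeans(m)
  dev <- sweep(centers, 2, grand)
  devSq <- rowSums(dev^2)
  B <- sum(devSq)
  Bw <- sum(sizes * devSq)
  tss <- sum(sweep(m, 2, grand)^2)
  W <- max(0, tss - Bw)
  list(B = B, Bw = Bw, W = W, K = K, sizes = sizes)
}

#' Between- and within-cluster variation
#'
#' `B` is the unweighted sum of squared distances of cluster centers from the
#' grand center (one term per cluster, no size weight); `W` is the sum of
#' squared distances of each row from its cluster center.
#'
#' @param Z clustering substrate (see [pairwiseEuclidean()]).
#' @param labels integer labels 1..K, one per row.
#' @return list with elements `B` and `W`.
#' @examples
#' variationDecomposition(matrix(c(0, 1, 4, 5)), c(1, 1, 2, 2))  # B = 8, W = 1
#' @export
variationDecomposition <- function(Z, labels) {
  m <- .asZ(Z)
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(m))
  d <- .decompose(m, labels)
  list(B = d$B, W = d$W)
}

#' Calinski-Harabasz index
#'
#' `CH(K) = (B / (K - 1)) / (W / (N - K))`. The default "weighted" variant is
#' the classical index with the size-weighted between-cluster term
#' `B = sum_k n_k ||C_k - C||^2`; "printed" drops the size weight (one squared
#' center deviation per cluster). The unweighted form is biased toward finer
#' partitions -- for noisy data its `B` grows like `sum_k 1/n_k` as clusters
#' shrink, so a cut search maximizing it over-fragments -- and is provided for
#' comparability only. Perfect separation (W = 0 with K < N) returns `Inf`.
#'
#' @param Z clustering substrate.
#' @param labels integer labels 1..K; requires 2 <= K <= N - 1.
#' @param variant "weighted" (default) or "printed".
#' @return the CH value.
#' @export
calinskiHarabasz <- function(Z, labels, variant = c("weighted", "printed")) {
  variant <- match.arg(variant)
  m <- .asZ(Z)
  labels <- as.integer(labels)
  n <- nrow(m)
  d <- .decompose(m, labels)
  if (d$K < 2L || d$K > n - 1L)
    hippStop("undefinedIndexError",
             sprintf("CH undefined for K = %d with N = %d", d$K, n))
  B <- if (variant == "printed") d$B else d$Bw
  if (d$W == 0) return(Inf)
  (B / (d$K - 1)) / (d$W / (n - d$K))
}

#' Optimize the dendrogram cut height by the CH index
#'
#' Starting from the root merge height, the cut height is repeatedly reduced
#' by the shrink fraction (multiplicatively, `h <- (1 - shrink) * h`); at each
#' visited height yielding 2 <= K <= N - 1 clusters the CH index is recorded.
#' The search stops once the height falls below the baseline (by default the
#' mean merge height of the dendrogram) and returns the visited cut with the
#' largest CH, breaking ties toward the larger height (fewer clusters).
#'
#' @param tree an `hclust` object over the rows of `Z`.
#' @param Z the clustering substrate the tree was built from.
#' @param shrink per-iteration height reduction fraction (default 0.01).
#' @param baseline "mean" (mean merge height) or a nonnegative number.
#' @param chVariant passed to [calinskiHarabasz()].
#' @return a [ClusterSolution-class] with the full search trace.
#' @export
optimizeCut <- function(tree, Z, shrink = 0.01, baseline = "mean",
                        chVariant = c("weighted", "printed")) {
  chVariant <- match.arg(chVariant)
  m <- .asZ(Z)
  n <- nrow(m)
  stopifnot(n >= 3L, shrink > 0, shrink < 1)
  heights <- tree$height
  h0 <- max(heights)
  base <- if (identical(baseline, "mean")) mean(heights) else as.numeric(baseline)
  if (h0 <= 0)
    hippStop("unstableSolutionError",
             "all merge heights are zero; no stable cluster solution")
  # a zero/negative baseline would never stop the multiplicative shrink, but
  # partitions stop changing below the smallest positive merge height, so
  # that height becomes the effective floor
  effBase <- if (base > 0) base else min(heights[heights > 0])

  hs <- numeric(0); ks <- integer(0); chs <- numeric(0)
  chCache <- new.env(parent = emptyenv())
  h <- h0
  while (h >= effBase) {
    nApplied <- sum(heights <= h)
    K <- n - nApplied
    if (K >= 2L && K <= n - 1L) {
      key <- as.character(nApplied)
      ch <- chCache[[key]]
      if (is.null(ch)) {
        labs <- cutAtHeight(tree, h)
        ch <- calinskiHarabasz(m, labs, variant = chVariant)
        chCache[[key]] <- ch
      }
      hs <- c(hs, h); ks <- c(ks, K); chs <- c(chs, ch)
    }
    h <- (1 - shrink) * h
  }
  trace <- data.frame(height = hs, K = ks, CH = chs)
  if (nrow(trace) == 0L)
    hippStop("unstableSolutionError",
             "no visited cut height yielded 2 <= K <= N - 1 clusters")
  best <- which.max(trace$CH)  # trace is in decreasing height order, so the
                               # first maximum is the largest-height tie
  labs <- cutAtHeight(tree, trace$height[best])
  vl <- if (is(Z, "GroupMatrix") || is(Z, "SubjectSeries"))
    voxelList(Z) else matrix(integer(0), 0, 3)
  new("ClusterSolution", labels = labs, K = trace$K[best],
      cutHeight = trace$height[best],
      chValue = calinskiHarabasz(m, labs, variant = chVariant),
      trace = trace, voxelList = vl)
}
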