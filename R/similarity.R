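# Torres-style similarity between two clusterings of the same voxel set: an
# m x n matrix of blockwise Jaccard coefficients summed and divided by
# max(m, n). Equals 1 for identical partitions (each block matches exactly one
# block with Jaccard 1 and overlaps no other); used as the group-vs-individual
# stability index.

#' Jaccard similarity coefficient
#'
#' Intersection size over union size of two voxel-index sets.
#'
#' @param a,b integer vectors (treated as sets); not both empty.
#' @return fraction in \[0, 1\].
#' @export
jaccardIndex <- function(a, b) {
  if (length(a) == 0L && length(b) == 0L)
    hippStop("undefinedIndexError", "Jaccard undefined for two empty sets")
  length(intersect(a, b)) / length(union(a, b))
}

#' Convert a label vector to a Partition
#'
#' Blocks are ordered by label value; with labels from [cutAtHeight()] this is
#' the order of each cluster's first member in canonical voxel order.
#'
#' @param labels integer label vector over the universe `1..length(labels)`.
#' @return a [Partition-class].
#' @export
asPartition <- function(labels) {
  labels <- as.integer(labels)
  blocks <- unname(split(seq_along(labels), labels))
  new("Partition", blocks = blocks, universeSize = length(labels))
}

.checkSameUniverse <- function(C, D) {
  if (C@universeSize != D@universeSize)
    hippStop("alignmentError", "partitions cover different voxel universes")
}

#' Blockwise Jaccard similarity matrix
#'
#' Entry (i, j) is the Jaccard coefficient of block i of `C` with block j of
#' `D`. Computed via the contingency table of the two label vectors.
#'
#' @param C,D [Partition-class] objects over the same universe.
#' @return m x n numeric matrix with entries in \[0, 1\].
#' @export
similarityMatrix <- function(C, D) {
  .checkSameUniverse(C, D)
  u <- C@universeSize
  lc <- integer(u); ld <- integer(u)
  for (i in seq_along(C@blocks)) lc[C@blocks[[i]]] <- i
  for (j in seq_along(D@blocks)) ld[D@blocks[[j]]] <- j
  inter <- unclass(table(factor(lc, seq_along(C@blocks)),
                         factor(ld, seq_along(D@blocks))))
  sizeC <- vapply(C@blocks, length, 1L)
  sizeD <- vapply(D@blocks, length, 1L)
  un <- outer(sizeC, sizeD, "+") - inter
  S <- inter / un
  dimnames(S) <- NULL
  S
}

#' Similarity index between two clusterings
#'
#' The sum of all entries of the blockwise Jaccard matrix divided by
#' `max(m, n)`. Lies in \[0, 1\], is symmetric, is invariant to block order and
#' label renumbering, and equals 1 exactly for identical partitions. The sum
#' runs over all m x n pairs (not a matching), so unrelated partitions
#' generally score above 0.
#'
#' @param C,D [Partition-class] objects over the same universe.
#' @return fraction in \[0, 1\].
#' @examples
#' C <- asPartition(c(1, 1, 2, 2))
#' D <- asPartition(c(1, 1, 1, 1))
#' similarityIndex(C, D)  # (0.5 + 0.5) / 2 = 0.5
#' @export
similarityIndex <- function(C, D) {
  S <- similarityMatrix(C, D)
  sum(S) / max(length(C@blocks), length(D@blocks))
}

#' Individual-vs-group cluster stability
#'
#' Runs the full clustering stack (standardize, Euclidean distances,
#' average-linkage dendrogram, CH cut optimization) on a single subject's
#' series and returns the similarity index between the subject's partition and
#' the group partition. An unstable individual solution propagates as an
#' `unstableSolutionError`; callers record such subjects as excluded.
#'
#' @param subject a [SubjectSeries-class] whose voxel list matches the group
#'   solution's universe.
#' @param groupSolution a [ClusterSolution-class] from the group run.
#' @param standardize,shrink,baseline,chVariant clustering parameters, as in
#'   [standardizeSeries()] and [optimizeCut()]; use the same values as the
#'   group run.
#' @return the similarity index, a fraction in \[0, 1\].
#' @export
individualVsGroup <- function(subject, groupSolution,
                              standardize = "zscore", shrink = 0.01,
                              baseline = "mean", chVariant = "weighted") {
  if (!identical(subject@voxelList, groupSolution@voxelList))
    hippStop("alignmentError",
             "subject voxel list does not match the group solution universe")
  s <- standardizeSeries(subject, method = standardize)
  tree <- buildDendrogram(pairwiseEuclidean(s))
  sol <- optimizeCut(tree, s, shrink = shrink, baseline = baseline,
                     chVariant = chVariant)
  similarityIndex(asPartition(sol@labels), asPartition(groupSolution@labels))
}
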