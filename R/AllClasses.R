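#' @import methods
NULL

#' Volume geometry
#'
#' Spatial frame of a 3D/4D volume: grid dimensions, voxel size in mm and the
#' 4x4 voxel-to-world affine. All volumes in one analysis are assumed
#' co-registered, so geometries are compared for equality rather than resampled.
#'
#' @slot dims integer(3), grid dimensions (nx, ny, nz).
#' @slot voxelSize numeric(3), voxel edge lengths in mm.
#' @slot affine 4x4 numeric voxel-to-world transform.
#' @export
setClass("VolumeGeometry",
  representation(dims = "integer", voxelSize = "numeric", affine = "matrix"),
  validity = function(object) {
    if (length(object@dims) != 3L || any(object@dims < 1L))
      return("dims must be three positive integers")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
      return("voxelSize must be three positive reals")
    if (!all(dim(object@affine) == c(4L, 4L)))
      return("affine must be 4x4")
    if (abs(det(object@affine)) < .Machine$double.eps)
      return("affine must be invertible")
    TRUE
  }
)

#' @rdname VolumeGeometry-class
#' @param dims integer(3) grid dimensions.
#' @param voxelSize numeric(3) voxel size in mm.
#' @param affine optional 4x4 affine; defaults to a scaling by `voxelSize`.
#' @export
VolumeGeometry <- function(dims, voxelSize = c(1, 1, 1), affine = NULL) {
  if (is.null(affine)) affine <- diag(c(voxelSize, 1))
  new("VolumeGeometry", dims = as.integer(dims),
      voxelSize = as.numeric(voxelSize), affine = affine)
}

#' Ground-truth parcellation for synthetic cohorts
#'
#' A binary ROI mask together with an integer label volume assigning every
#' in-mask voxel to one of `KTrue` compartments arranged as contiguous slabs
#' along a chosen anatomical axis.
#'
#' @slot mask 3D logical array.
#' @slot labels 3D integer array, 0 outside the mask, 1..KTrue inside.
#' @slot axis one of "longitudinal", "dorsoventral", "mediolateral".
#' @slot KTrue number of ground-truth compartments.
#' @slot geometry a [VolumeGeometry-class].
#' @export
setClass("GroundTruthParcellation",
  representation(mask = "array", labels = "array", axis = "character",
                 KTrue = "integer", geometry = "VolumeGeometry"),
  validity = function(object) {
    if (!is.logical(object@mask)) return("mask must be logical")
    if (!identical(dim(object@mask), dim(object@labels)))
      return("mask and labels dims differ")
    inmask <- object@labels[object@mask]
    if (any(object@labels[!object@mask] != 0L))
      return("labels outside mask must be 0")
    if (any(inmask < 1L) || any(inmask > object@KTrue))
      return("in-mask labels must lie in 1..KTrue")
    if (!all(seq_len(object@KTrue) %in% inmask))
      return("every label 1..KTrue must occupy at least one voxel")
    if (!object@axis %in% c("longitudinal", "dorsoventral", "mediolateral"))
      return("unknown axis")
    TRUE
  }
)

#' Region-of-interest mask
#'
#' A boolean mask plus the canonical ordered voxel list. The canonical order is
#' ascending slice (k), then row (j), then column (i) -- i.e. R's column-major
#' order -- and every row-indexed object downstream (time-series matrices,
#' label vectors, partitions) indexes against it.
#'
#' @slot mask 3D logical array.
#' @slot voxelList N x 3 integer matrix of (i, j, k) voxel indices (1-based).
#' @slot geometry a [VolumeGeometry-class].
#' @export
setClass("RoiMask",
  representation(mask = "array", voxelList = "matrix",
                 geometry = "VolumeGeometry"),
  validity = function(object) {
    if (nrow(object@voxelList) == 0L) return("empty ROI")
    expect <- which(object@mask, arr.ind = TRUE)
    dimnames(expect) <- NULL
    if (!identical(expect, object@voxelList))
      return("voxelList must enumerate mask voxels in canonical (k,j,i) order")
    TRUE
  }
)

#' Per-subject voxel time series
#'
#' The N voxels x T timepoints matrix extracted for one subject under one
#' condition. Row r corresponds to `voxelList[r, ]`.
#'
#' @slot data numeric matrix, N voxels x T timepoints.
#' @slot subjectId character scalar.
#' @slot condition character scalar.
#' @slot voxelList N x 3 integer matrix, as in [RoiMask-class].
#' @export
setClass("SubjectSeries",
  representation(data = "matrix", subjectId = "character",
                 condition = "character", voxelList = "matrix"),
  validity = function(object) {
    if (nrow(object@data) != nrow(object@voxelList))
      return("data rows must match voxelList")
    if (ncol(object@data) < 2L) return("need at least 2 timepoints")
    if (!all(is.finite(object@data))) return("data must be finite")
    TRUE
  }
)

#' Group clustering substrate
#'
#' The matrix Z of N ROI voxels by p concatenated timepoints across the M
#' included subjects; the object hierarchical clustering operates on.
#'
#' @slot Z numeric matrix, N x p.
#' @slot subjectBoundaries integer vector of cumulative column offsets; subject
#'   s occupies columns (boundaries\[s\], boundaries\[s+1\]\].
#' @slot voxelList N x 3 integer matrix.
#' @slot includedSubjects character vector of subject identifiers.
#' @export
setClass("GroupMatrix",
  representation(Z = "matrix", subjectBoundaries = "integer",
                 voxelList = "matrix", includedSubjects = "character"),
  validity = function(object) {
    if (nrow(object@Z) != nrow(object@voxelList))
      return("Z rows must match voxelList")
    nb <- length(object@subjectBoundaries)
    if (nb != length(object@includedSubjects) + 1L)
      return("boundaries must have one more entry than subjects")
    if (object@subjectBoundaries[1L] != 0L ||
        object@subjectBoundaries[nb] != ncol(object@Z))
      return("boundaries must start at 0 and end at ncol(Z)")
    if (is.unsorted(object@subjectBoundaries, strictly = TRUE))
      return("boundaries must be strictly increasing")
    if (!all(is.finite(object@Z))) return("Z must be finite")
    TRUE
  }
)

#' Optimized cluster solution
#'
#' Result of the Calinski-Harabasz cut-height search: voxel labels, cluster
#' count, the chosen cut height, the CH value there, and the full search trace.
#'
#' @slot labels integer vector of length N with values 1..K, numbered by each
#'   cluster's first member in canonical voxel order.
#' @slot K integer, number of clusters (>= 2).
#' @slot cutHeight the selected dendrogram cut height.
#' @slot chValue Calinski-Harabasz index at the selected cut (may be `Inf` for
#'   perfect separation).
#' @slot trace data.frame of every visited (height, K, CH).
#' @slot voxelList the voxel universe the labels index against.
#' @export
setClass("ClusterSolution",
  representation(labels = "integer", K = "integer", cutHeight = "numeric",
                 chValue = "numeric", trace = "data.frame",
                 voxelList = "matrix"),
  validity = function(object) {
    tab <- tabulate(object@labels, nbins = object@K)
    if (any(tab == 0L)) return("every label 1..K must occur")
    if (length(unique(object@labels)) != object@K)
      return("K must equal the number of distinct labels")
    if (object@cutHeight < 0) return("cutHeight must be nonnegative")
    TRUE
  }
)

#' Partition of the ROI voxel set
#'
#' Disjoint nonempty blocks of voxel indices covering 1..universeSize; the
#' input to the Jaccard similarity matrix and similarity index.
#'
#' @slot blocks list of integer vectors.
#' @slot universeSize size of the voxel universe.
#' @export
setClass("Partition",
  representation(blocks = "list", universeSize = "integer"),
  validity = function(object) {
    if (length(object@blocks) < 1L) return("need at least one block")
    if (any(vapply(object@blocks, length, 1L) == 0L))
      return("blocks must be nonempty")
    all_idx <- sort(unlist(object@blocks, use.names = FALSE))
    if (!identical(all_idx, seq_len(object@universeSize)))
      return("blocks must be disjoint and cover 1..universeSize")
    TRUE
  }
)

#' Repeated-measures ANOVA result
#'
#' One within-subject effect with Greenhouse-Geisser correction and partial
#' eta squared.
#'
#' @slot effect factor name ("hemisphere" or "condition").
#' @slot F F statistic.
#' @slot df1,df2 uncorrected degrees of freedom.
#' @slot epsilon Greenhouse-Geisser epsilon, in \[1/(k-1), 1\].
#' @slot pUncorrected,pGG p values before and after the correction.
#' @slot partialEtaSq effect size SS_effect / (SS_effect + SS_error).
#' @slot nComplete number of listwise-complete subjects used.
#' @export
setClass("AnovaResult",
  representation(effect = "character", F = "numeric", df1 = "numeric",
                 df2 = "numeric", epsilon = "numeric",
                 pUncorrected = "numeric", pGG = "numeric",
                 partialEtaSq = "numeric", nComplete = "integer"),
  validity = function(object) {
    k <- object@df1 + 1
    if (object@epsilon > 1 + 1e-9 || object@epsilon < 1 / (k - 1) - 1e-9)
      return("epsilon out of [1/(k-1), 1]")
    eta <- (object@F * object@df1) / (object@F * object@df1 + object@df2)
    if (is.finite(eta) && abs(eta - object@partialEtaSq) > 1e-9)
      return("partialEtaSq violates the F-based identity")
    TRUE
  }
)
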