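#' @name accessors
#' @title Accessors for hippcluster classes
#' @description Slot accessors; user code should use these rather than `@`.
#' @param x an object of the documented class.
NULL

#' @rdname accessors
#' @export
setGeneric("voxelList", function(x) standardGeneric("voxelList"))
#' @rdname accessors
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))
#' @rdname accessors
#' @export
setGeneric("nVoxels", function(x) standardGeneric("nVoxels"))
#' @rdname accessors
#' @export
setGeneric("seriesMatrix", function(x) standardGeneric("seriesMatrix"))
#' @rdname accessors
#' @export
setGeneric("groupMatrix", function(x) standardGeneric("groupMatrix"))
#' @rdname accessors
#' @export
setGeneric("subjectBoundaries", function(x) standardGeneric("subjectBoundaries"))
#' @rdname accessors
#' @export
setGeneric("includedSubjects", function(x) standardGeneric("includedSubjects"))
#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setGeneric("clusterCount", function(x) standardGeneric("clusterCount"))
#' @rdname accessors
#' @export
setGeneric("cutHeight", function(x) standardGeneric("cutHeight"))
#' @rdname accessors
#' @export
setGeneric("chValue", function(x) standardGeneric("chValue"))
#' @rdname accessors
#' @export
setGeneric("searchTrace", function(x) standardGeneric("searchTrace"))
#' @rdname accessors
#' @export
setGeneric("partitionBlocks", function(x) standardGeneric("partitionBlocks"))
#' @rdname accessors
#' @export
setGeneric("truthLabels", function(x) standardGeneric("truthLabels"))

#' @rdname accessors
#' @export
setMethod("voxelList", "RoiMask", function(x) x@voxelList)
#' @rdname accessors
#' @export
setMethod("voxelList", "SubjectSeries", function(x) x@voxelList)
#' @rdname accessors
#' @export
setMethod("voxelList", "GroupMatrix", function(x) x@voxelList)
#' @rdname accessors
#' @export
setMethod("voxelList", "ClusterSolution", function(x) x@voxelList)

#' @rdname accessors
#' @export
setMethod("geometry", "RoiMask", function(x) x@geometry)
#' @rdname accessors
#' @export
setMethod("geometry", "GroundTruthParcellation", function(x) x@geometry)

#' @rdname accessors
#' @export
setMethod("nVoxels", "RoiMask", function(x) nrow(x@voxelList))
#' @rdname accessors
#' @export
setMethod("nVoxels", "SubjectSeries", function(x) nrow(x@data))
#' @rdname accessors
#' @export
setMethod("nVoxels", "GroupMatrix", function(x) nrow(x@Z))

#' @rdname accessors
#' @export
setMethod("seriesMatrix", "SubjectSeries", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("groupMatrix", "GroupMatrix", function(x) x@Z)
#' @rdname accessors
#' @export
setMethod("subjectBoundaries", "GroupMatrix", function(x) x@subjectBoundaries)
#' @rdname accessors
#' @export
setMethod("includedSubjects", "GroupMatrix", function(x) x@includedSubjects)

#' @rdname accessors
#' @export
setMethod("clusterLabels", "ClusterSolution", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("clusterCount", "ClusterSolution", function(x) x@K)
#' @rdname accessors
#' @export
setMethod("cutHeight", "ClusterSolution", function(x) x@cutHeight)
#' @rdname accessors
#' @export
setMethod("chValue", "ClusterSolution", function(x) x@chValue)
#' @rdname accessors
#' @export
setMethod("searchTrace", "ClusterSolution", function(x) x@trace)

#' @rdname accessors
#' @export
setMethod("partitionBlocks", "Partition", function(x) x@blocks)

#' @rdname accessors
#' @export
setMethod("truthLabels", "GroundTruthParcellation", function(x) x@labels)

setMethod("show", "VolumeGeometry", function(object) {
  cat(sprintf("VolumeGeometry: %d x %d x %d grid, voxels %.2f x %.2f x %.2f mm\n",
              object@dims[1], object@dims[2], object@dims[3],
              object@voxelSize[1], object@voxelSize[2], object@voxelSize[3]))
})

setMethod("show", "GroundTruthParcellation", function(object) {
  cat(sprintf("GroundTruthParcellation: %d voxels, K = %d slabs along %s axis\n",
              sum(object@mask), object@KTrue, object@axis))
})

setMethod("show", "RoiMask", function(object) {
  cat(sprintf("RoiMask: %d voxels in a %s grid\n", nrow(object@voxelList),
              paste(object@geometry@dims, collapse = " x ")))
})

setMethod("show", "SubjectSeries", function(object) {
  cat(sprintf("SubjectSeries '%s' (%s): %d voxels x %d timepoints\n",
              object@subjectId, object@condition,
              nrow(object@data), ncol(object@data)))
})

setMethod("show", "GroupMatrix", function(object) {
  cat(sprintf("GroupMatrix: %d voxels x %d concatenated timepoints (%d subjects)\n",
              nrow(object@Z), ncol(object@Z), length(object@includedSubjects)))
})

setMethod("show", "ClusterSolution", function(object) {
  cat(sprintf(
    "ClusterSolution: K = %d clusters at cut height %.4g (CH = %.4g; %d heights visited)\n",
    object@K, object@cutHeight, object@chValue, nrow(object@trace)))
})

setMethod("show", "Partition", function(object) {
  cat(sprintf("Partition: %d blocks over %d voxels (sizes: %s)\n",
              length(object@blocks), object@universeSize,
              paste(vapply(object@blocks, length, 1L), collapse = ", ")))
})

setMethod("show", "AnovaResult", function(object) {
  cat(sprintf(
    "Within-subject ANOVA [%s]: F(%.3f, %.3f) = %.3f, p_GG = %.4g (eps = %.3f), partial eta^2 = %.3f, n = %d\n",
    object@effect, object@epsilon * object@df1, object@epsilon * object@df2,
    object@F, object@pGG, object@epsilon, object@partialEtaSq,
    object@nComplete))
})
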