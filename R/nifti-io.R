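# NIfTI-1 I/O, delegated to RNifti. Geometry travels as a VolumeGeometry and
# is written into the sform (code 2, aligned/standard space); voxel size is
# recovered from the affine's column norms so pixdim and sform cannot drift
# apart.

geometryFromImage <- function(img) {
  d <- dim(img)[1:3]
  aff <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE))
  attributes(aff) <- list(dim = c(4L, 4L))
  vs <- sqrt(colSums(aff[1:3, 1:3]^2))
  VolumeGeometry(dims = d, voxelSize = vs, affine = aff)
}

applyGeometry <- function(img, geom) {
  RNifti::`sform<-`(img, structure(geom@affine, code = 2L))
}

#' Read a NIfTI volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return list with elements `data` (the array) and `geometry`
#'   (a [VolumeGeometry-class]).
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = img[drop = FALSE], geometry = geometryFromImage(img))
}

#' Write a NIfTI volume
#'
#' @param data 3D or 4D numeric array.
#' @param geom a [VolumeGeometry-class]; its dims must match `dim(data)[1:3]`.
#' @param path output path; `.nii` writes uncompressed.
#' @param datatype passed to [RNifti::writeNifti()] (e.g. "float", "int16").
#' @return `path`, invisibly.
#' @export
writeVolume <- function(data, geom, path, datatype = "float") {
  if (!identical(as.integer(dim(data)[1:3]), geom@dims))
    hippStop("geometryError", "volume dims do not match geometry dims")
  img <- RNifti::asNifti(data)
  img <- applyGeometry(img, geom)  # pixdim is implied by the sform scale
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Write a cluster label volume
#'
#' Maps a label vector back to image space: voxel `voxelList[r, ]` receives
#' `labels[r]`, all other voxels 0. The output is an integer NIfTI with the
#' geometry (affine) supplied, suitable for overlay on the co-registered
#' anatomy.
#'
#' @param labels integer vector of cluster labels.
#' @param voxelList N x 3 integer matrix of voxel indices, same length.
#' @param geom a [VolumeGeometry-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @examples
#' geom <- VolumeGeometry(c(4, 4, 4))
#' vl <- cbind(1:3, 1L, 1L)
#' f <- tempfile(fileext = ".nii")
#' writeLabelVolume(c(1L, 1L, 2L), vl, geom, f)
#' @export
writeLabelVolume <- function(labels, voxelList, geom, path) {
  if (length(labels) != nrow(voxelList))
    hippStop("alignmentError", "labels length must equal voxelList rows")
  arr <- array(0L, dim = geom@dims)
  arr[voxelList] <- as.integer(labels)
  writeVolume(arr, geom, path, datatype = "int16")
}
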