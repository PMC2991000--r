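#' Load an MRI volume from NIfTI or a DICOM series directory
#'
#' Reads a 3D scalar volume together with its geometry. NIfTI files
#' (\code{.nii}/\code{.nii.gz}) are the primary on-disk format; a directory is
#' interpreted as a single-frame DICOM series whose slices are ordered by
#' their world position along the slice normal regardless of file names.
#' World coordinates follow the RAS convention (+x right, +y anterior,
#' +z superior); DICOM's LPS patient axes are converted on load. Voxel indices
#' are 0-based in the index-to-world affine.
#'
#' @param path a NIfTI file or a DICOM series directory.
#' @param sequence sequence tag to attach ("T1", "T2" or "OTHER").
#' @return An \linkS4class{ImageVolume}. Integer intensities are preserved
#'   bit-exactly.
#' @export
loadVolume <- function(path, sequence = "OTHER") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (dir.exists(path)) return(readDicomSeries(path, sequence = sequence))
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  data <- as.array(img)
  d <- dim(data)
  if (length(d) == 4L && d[4] == 1L) d <- d[1:3]
  data <- array(as.double(data), d)
  sp <- RNifti::pixdim(img)[1:3]
  if (anyNA(data) || any(!is.finite(data))) stop("volume contains non-finite values")
  ImageVolume(data, spacing = sp, affine = aff, sequence = sequence)
}

#' Write a volume as NIfTI-1
#'
#' @param vol an \linkS4class{ImageVolume}.
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @param datatype NIfTI storage type; "auto" keeps double precision.
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(vol, path, datatype = "auto") {
  img <- RNifti::asNifti(vol@data,
                         reference = list(pixdim = c(-1, vol@spacing, 1, 1, 1, 1)))
  aff <- structure(vol@affine, code = 2L)
  RNifti::sform(img) <- aff
  RNifti::qform(img) <- aff
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Write a segmentation mask as uint8 NIfTI with its reference geometry
#'
#' @param mask a \linkS4class{SegmentationMask}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeMask <- function(mask, path) {
  vol <- new("ImageVolume", data = array(as.double(mask@data), dim(mask@data)),
             spacing = mask@spacing, affine = mask@affine, sequence = "OTHER")
  writeVolume(vol, path, datatype = "uint8")
}

#' Transport a mask between two image grids
#'
#' Resamples a binary mask from the grid of \code{source} onto the grid of
#' \code{target} through world space, using the index-to-world affines stored
#' with each acquisition. Each target voxel becomes foreground iff its world
#' center maps (nearest-neighbour) onto a foreground source voxel, so binary
#' masks stay binary. When source and target geometry are identical the mask
#' is returned unchanged, making the operation idempotent.
#'
#' @param mask a \linkS4class{SegmentationMask} aligned to \code{source}.
#' @param source,target \linkS4class{ImageVolume} objects (or masks) carrying
#'   the two geometries.
#' @return The mask on the target grid. If a non-empty mask transports to an
#'   empty result (non-overlapping fields of view) a warning is raised.
#' @export
transportMask <- function(mask, source, target) {
  stopifnot(all(dim(mask@data) == dim(source@data)))
  if (sameGeometry(source, target))
    return(SegmentationMask(mask@data, target, label = mask@label))
  d <- dim(target@data)
  n <- prod(d)
  idx <- arrayInd(seq_len(n), d) - 1L
  src <- worldToVoxel(source@affine, voxelToWorld(target@affine, idx))
  si <- round(src) + 1
  ds <- dim(source@data)
  ok <- si[, 1] >= 1 & si[, 1] <= ds[1] &
        si[, 2] >= 1 & si[, 2] <= ds[2] &
        si[, 3] >= 1 & si[, 3] <= ds[3]
  out <- logical(n)
  out[ok] <- mask@data[cbind(si[ok, 1], si[ok, 2], si[ok, 3])]
  if (!any(out) && any(mask@data))
    warning("mask transported to an empty result: fields of view may not overlap")
  SegmentationMask(array(out, d), target, label = mask@label)
}
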