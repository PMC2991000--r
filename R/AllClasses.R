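#' @useDynLib kneefusion, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods new validObject is slot slotNames
#' @importFrom stats rnorm runif sd setNames
#' @importFrom utils write.csv
NULL

.SEQUENCES <- c("T1", "T2", "OTHER")
.MASK_LABELS <- c("FEMUR", "TIBIA", "PATELLA_FAT", "NONINTEREST",
                  "FLUID_CANDIDATE", "EFFUSION", "BODY", "CANDIDATE", "OTHER")

#' 3D scalar MRI volume with grid geometry
#'
#' The unit of all processing: a 3D intensity grid together with its per-axis
#' voxel size in millimetres, the 4x4 affine mapping 0-based voxel indices to
#' world coordinates in mm (RAS convention: +x right, +y anterior,
#' +z superior), and the acquisition sequence tag.
#'
#' @slot data 3D numeric array of intensities (arbitrary MR units).
#' @slot spacing numeric(3), voxel size in mm, all positive.
#' @slot affine 4x4 invertible voxel-index-to-world matrix (mm).
#' @slot sequence one of "T1", "T2", "OTHER".
#' @export
setClass("ImageVolume",
  representation(data = "array", spacing = "numeric",
                 affine = "matrix", sequence = "character"),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 3L) return("data must be a 3D array")
    if (any(d < 2L)) return("grid must have at least 2 voxels per axis")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0)) return("spacing must be 3 positive values")
    if (!all(dim(object@affine) == c(4L, 4L))) return("affine must be 4x4")
    if (abs(det(object@affine)) < 1e-12) return("affine must be invertible")
    if (anyNA(object@data) || any(!is.finite(object@data)))
      return("data contains non-finite values")
    if (!object@sequence %in% .SEQUENCES)
      return(sprintf("sequence must be one of %s", paste(.SEQUENCES, collapse = ", ")))
    TRUE
  })

#' Construct an ImageVolume
#'
#' @param data 3D numeric array.
#' @param spacing voxel size in mm (numeric of length 3).
#' @param affine optional 4x4 index-to-world matrix; defaults to a diagonal
#'   affine with the world origin at the grid center.
#' @param sequence sequence tag ("T1", "T2" or "OTHER").
#' @return An \linkS4class{ImageVolume}.
#' @export
ImageVolume <- function(data, spacing, affine = NULL, sequence = "OTHER") {
  storage.mode(data) <- "double"
  if (is.null(affine)) affine <- centeredAffine(spacing, dim(data))
  new("ImageVolume", data = data, spacing = as.numeric(spacing),
      affine = affine, sequence = sequence)
}

#' Binary segmentation mask aligned to an image grid
#'
#' @slot data 3D logical array, same grid as the reference volume.
#' @slot spacing,affine geometry copied from the reference grid.
#' @slot label semantic label of the mask.
#' @export
setClass("SegmentationMask",
  representation(data = "array", spacing = "numeric",
                 affine = "matrix", label = "character"),
  validity = function(object) {
    if (length(dim(object@data)) != 3L) return("mask must be a 3D array")
    if (!is.logical(object@data)) return("mask values must be strictly binary (logical)")
    if (anyNA(object@data)) return("mask contains NA")
    if (!object@label %in% .MASK_LABELS)
      return(sprintf("label must be one of %s", paste(.MASK_LABELS, collapse = ", ")))
    TRUE
  })

#' Construct a SegmentationMask on the grid of a reference volume or mask
#'
#' @param data 3D logical array.
#' @param geometry an \linkS4class{ImageVolume} or \linkS4class{SegmentationMask}
#'   supplying spacing and affine; its grid shape must match \code{data}.
#' @param label semantic mask label.
#' @return A \linkS4class{SegmentationMask}.
#' @export
SegmentationMask <- function(data, geometry, label = "OTHER") {
  stopifnot(all(dim(data) == dim(geometry@data)))
  new("SegmentationMask", data = (data & TRUE), spacing = geometry@spacing,
      affine = geometry@affine, label = label)
}

#' Intensity histogram of a voxel region
#'
#' @slot binEdges monotonically increasing bin edges (length counts + 1).
#' @slot counts non-negative integer counts per bin.
#' @slot sourceRegion free-text description of the histogrammed voxel set.
#' @export
setClass("IntensityHistogram",
  representation(binEdges = "numeric", counts = "integer", sourceRegion = "character"),
  validity = function(object) {
    if (length(object@binEdges) != length(object@counts) + 1L)
      return("need length(binEdges) == length(counts) + 1")
    if (is.unsorted(object@binEdges, strictly = FALSE)) return("binEdges must be increasing")
    if (any(object@counts < 0L)) return("counts must be non-negative")
    TRUE
  })

#' Lower/upper intensity threshold pair
#'
#' @slot tLower,tUpper intensity thresholds with tLower < tUpper.
#' @export
setClass("ThresholdPair",
  representation(tLower = "numeric", tUpper = "numeric"),
  validity = function(object) {
    if (!(object@tLower < object@tUpper)) return("need tLower < tUpper")
    TRUE
  })

#' Femoral seed region for the bone-intensity histogram
#'
#' An axis-aligned voxel box of physical extent 18 x 36 x 18 mm (longest side
#' along the anterior-posterior axis) centered on the image grid.
#'
#' @slot center grid-center voxel index (1-based).
#' @slot extentMm physical box extent in mm.
#' @slot lo,hi inclusive 1-based voxel index bounds of the box.
#' @export
setClass("FemoralSeedRegion",
  representation(center = "numeric", extentMm = "numeric",
                 lo = "integer", hi = "integer"))

#' Solid femur and tibia objects
#'
#' @slot femur,tibia segmentation masks; disjoint, each a single 26-connected
#'   solid component.
#' @slot frame coordinate frame, "T1" or "T2".
#' @export
setClass("BoneObjects",
  representation(femur = "SegmentationMask", tibia = "SegmentationMask",
                 frame = "character"),
  validity = function(object) {
    f <- object@femur@data; t <- object@tibia@data
    if (!all(dim(f) == dim(t))) return("femur and tibia must share one grid")
    if (any(f & t)) return("femur and tibia must be disjoint")
    if (!object@frame %in% c("T1", "T2")) return("frame must be T1 or T2")
    for (nm in c("femur", "tibia")) {
      m <- slot(object, nm)@data
      if (!any(m)) return(sprintf("%s mask is empty", nm))
      lab <- .ccLabel3d(as.logical(m), dim(m), 26L)
      if (attr(lab, "n") != 1L) return(sprintf("%s is not a single 26-connected component", nm))
      if (any(fillHoles3d(m) & !m)) return(sprintf("%s is not solid (has internal cavities)", nm))
    }
    TRUE
  })

#' T2 volume with non-interest mask and analysis domain
#'
#' The "masked images set": the T2 volume restricted (by domain, not by
#' overwriting intensities) to the voxels where joint fluid is searched for.
#'
#' @slot t2 the T2 \linkS4class{ImageVolume}.
#' @slot noninterest union mask of bones, patella and fat.
#' @slot analysisDomain complement of noninterest within the body region.
#' @export
setClass("MaskedImageSet",
  representation(t2 = "ImageVolume", noninterest = "SegmentationMask",
                 analysisDomain = "SegmentationMask"),
  validity = function(object) {
    if (!all(dim(object@t2@data) == dim(object@noninterest@data)) ||
        !all(dim(object@t2@data) == dim(object@analysisDomain@data)))
      return("masks must share the T2 grid")
    if (any(object@noninterest@data & object@analysisDomain@data))
      return("noninterest and analysis domain must be disjoint")
    TRUE
  })

#' A candidate fluid object (one 26-connected component)
#'
#' @slot mask component mask.
#' @slot centroidMm world-space centroid.
#' @slot bboxMm 2x3 world-space bounding box (min row, max row).
#' @slot voxelCount foreground voxel count.
#' @export
setClass("CandidateObject",
  representation(mask = "SegmentationMask", centroidMm = "numeric",
                 bboxMm = "matrix", voxelCount = "integer"))

#' Peri-articular pouch region derived from the bones
#'
#' Axial bands in world mm within which retained fluid must lie: the femoral
#' band extends proximally from the femur's distal (joint) end over one third
#' of its in-image extent (anterior half-space); the tibial band extends
#' distally from the tibia's proximal end over one fourth of its extent
#' (posterior half-space).
#'
#' @slot femoralBand,tibialBand numeric(2) world-z intervals (mm).
#' @slot femoralAnteriorCut,tibialPosteriorCut world-y half-space cuts (mm).
#' @slot dilationMm outward margin from the bone surfaces (mm).
#' @export
setClass("PouchRegion",
  representation(femoralBand = "numeric", tibialBand = "numeric",
                 femoralAnteriorCut = "numeric", tibialPosteriorCut = "numeric",
                 dilationMm = "numeric"))

#' Closed triangular surface mesh in world mm
#'
#' @slot vertices N x 3 matrix of world coordinates (mm).
#' @slot faces M x 3 integer matrix of vertex indices (1-based), consistently
#'   outward oriented.
#' @slot componentId id of the mask component the mesh encloses.
#' @export
setClass("SurfaceMesh",
  representation(vertices = "matrix", faces = "matrix", componentId = "integer"),
  validity = function(object) {
    if (ncol(object@vertices) != 3L) return("vertices must be N x 3")
    if (ncol(object@faces) != 3L) return("faces must be M x 3")
    if (nrow(object@faces) < 4L) return("too few faces for a closed surface")
    TRUE
  })

#' Subvoxel volume measurement
#'
#' @slot totalMl total volume in millilitres.
#' @slot perComponentMl per-component volumes (ml).
#' @slot interiorVoxelMl volume contributed by fully interior voxels.
#' @slot partialVoxelMl volume contributed by mesh-intersected voxels.
#' @slot method "SUBVOXEL_MESH" or "VOXEL_COUNT_FALLBACK".
#' @slot methodPerComponent per-component method flags.
#' @export
setClass("VolumeResult",
  representation(totalMl = "numeric", perComponentMl = "numeric",
                 interiorVoxelMl = "numeric", partialVoxelMl = "numeric",
                 method = "character", methodPerComponent = "character"))

#' Analytic phantom specification
#'
#' Geometry and acquisition parameters of a calibrated digital phantom:
#' either two disjoint perpendicular fluid-filled cylinders in a water bath
#' ("CYLINDER_PAIR") or a dark solid sphere surrounded by a fluid shell
#' ("SPHERE_SHELL"). The ground-truth fluid volume is always recomputed from
#' the closed-form geometry, never stored.
#'
#' @slot kind "CYLINDER_PAIR" or "SPHERE_SHELL".
#' @slot geometry named list of analytic parameters in mm.
#' @slot spacingMm acquisition voxel size (mm).
#' @slot gridDim acquisition grid size (voxels).
#' @slot intensities named list of tissue intensities (fluid defines the unit).
#' @slot noiseSigma additive Gaussian noise SD relative to the fluid intensity.
#' @slot orientationJitterDeg per-scan random rotation range (+/- degrees).
#' @slot offsetJitterMm per-scan random translation range (+/- mm per axis).
#' @slot seed RNG seed making the rendering a pure function of the spec.
#' @export
setClass("PhantomSpec",
  representation(kind = "character", geometry = "list", spacingMm = "numeric",
                 gridDim = "integer", intensities = "list", noiseSigma = "numeric",
                 orientationJitterDeg = "numeric", offsetJitterMm = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (!object@kind %in% c("CYLINDER_PAIR", "SPHERE_SHELL"))
      return("kind must be CYLINDER_PAIR or SPHERE_SHELL")
    if (any(object@spacingMm <= 0)) return("spacing components must be positive")
    TRUE
  })

#' Synthetic knee acquisition specification
#'
#' Defines a paired T1/T2 acquisition of a knee-like object: femur and tibia
#' as capsules with dark cortical shells and bright marrow, hyaline-cartilage
#' shells apposed to the joint surfaces, a C-shaped synovial fluid pouch, an
#' anterior patella/fat complex, a posterior vessel decoy, a smooth
#' multiplicative intensity-inhomogeneity field and additive noise.
#'
#' @slot t1Dim,t1Spacing,t2Dim,t2Spacing grids of the two sequences.
#' @slot geometry named list of analytic structure parameters (mm).
#' @slot t1Intensities,t2Intensities per-sequence tissue intensity tables.
#' @slot biasAmplitude amplitude of the multiplicative bias field.
#' @slot noiseSigma additive Gaussian noise SD relative to the brightest tissue.
#' @slot seed RNG seed.
#' @export
setClass("KneeSpec",
  representation(t1Dim = "integer", t1Spacing = "numeric",
                 t2Dim = "integer", t2Spacing = "numeric",
                 geometry = "list", t1Intensities = "list", t2Intensities = "list",
                 biasAmplitude = "numeric", noiseSigma = "numeric", seed = "integer"))

#' Pipeline configuration
#'
#' All tunables of the four-stage pipeline with their defaults.
#'
#' @slot nBins histogram bins (256).
#' @slot connectivity 3D connectivity for component labelling (26).
#' @slot minObjectVoxels minimum candidate-object size (5).
#' @slot repairAreaFraction slice-area drop triggering inter-slice repair (0.5).
#' @slot contrastSearchDepth boundary search depth of the 2D contrast
#'   correction, in pixels (3).
#' @slot contrastSigma Gaussian smoothing (px) before gradients (1).
#' @slot pouchMarginMm bone-surface margin of the anatomic filter (15).
#' @slot shellFraction,shellDistanceVoxels cartilage-shell exclusion rule:
#'   discard candidates with >= shellFraction of voxels within
#'   shellDistanceVoxels in-plane voxels of a bone surface (0.8 / 2).
#' @slot subsampling per-axis subvoxel sampling of partial voxels (5).
#' @slot thresholdMethod "triangle" (default) or "otsu".
#' @slot anteriorMarginMm tolerance of the anterior patella/fat rule (4).
#' @slot vertexPlacement mesh vertex placement, "interpolated" or "centers".
#' @slot seed RNG seed recorded with every run.
#' @export
setClass("PipelineConfig",
  representation(nBins = "integer", connectivity = "integer",
                 minObjectVoxels = "integer", repairAreaFraction = "numeric",
                 contrastSearchDepth = "integer", contrastSigma = "numeric",
                 pouchMarginMm = "numeric", shellFraction = "numeric",
                 shellDistanceVoxels = "integer", subsampling = "integer",
                 thresholdMethod = "character", anteriorMarginMm = "numeric",
                 vertexPlacement = "character", seed = "integer"),
  validity = function(object) {
    if (!object@thresholdMethod %in% c("triangle", "otsu"))
      return("thresholdMethod must be 'triangle' or 'otsu'")
    if (!object@vertexPlacement %in% c("interpolated", "centers"))
      return("vertexPlacement must be 'interpolated' or 'centers'")
    if (!object@connectivity %in% c(6L, 26L)) return("connectivity must be 6 or 26")
    if (object@nBins < 8L) return("nBins must be >= 8")
    TRUE
  })

## ---- accessors ----

#' @export
setGeneric("imgData", function(x) standardGeneric("imgData"))
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @export
setGeneric("affineMatrix", function(x) standardGeneric("affineMatrix"))
#' @export
setGeneric("seqType", function(x) standardGeneric("seqType"))
#' @export
setGeneric("maskLabel", function(x) standardGeneric("maskLabel"))
#' @export
setGeneric("totalMl", function(x) standardGeneric("totalMl"))

#' @describeIn ImageVolume intensity array accessor
#' @param x object
#' @export
setMethod("imgData", "ImageVolume", function(x) x@data)
#' @describeIn SegmentationMask logical array accessor
#' @param x object
#' @export
setMethod("imgData", "SegmentationMask", function(x) x@data)
#' @describeIn ImageVolume voxel spacing in mm
#' @export
setMethod("voxelSpacing", "ImageVolume", function(x) x@spacing)
#' @describeIn SegmentationMask voxel spacing in mm
#' @export
setMethod("voxelSpacing", "SegmentationMask", function(x) x@spacing)
#' @describeIn ImageVolume index-to-world affine
#' @export
setMethod("affineMatrix", "ImageVolume", function(x) x@affine)
#' @describeIn SegmentationMask index-to-world affine
#' @export
setMethod("affineMatrix", "SegmentationMask", function(x) x@affine)
#' @describeIn ImageVolume sequence tag
#' @export
setMethod("seqType", "ImageVolume", function(x) x@sequence)
#' @describeIn SegmentationMask semantic label
#' @export
setMethod("maskLabel", "SegmentationMask", function(x) x@label)
#' @describeIn VolumeResult total volume in ml
#' @export
setMethod("totalMl", "VolumeResult", function(x) x@totalMl)

#' @export
setMethod("dim", "ImageVolume", function(x) dim(x@data))
#' @export
setMethod("dim", "SegmentationMask", function(x) dim(x@data))

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageVolume [%s] %d x %d x %d, spacing %s mm\n",
              object@sequence, d[1], d[2], d[3],
              paste(format(object@spacing, digits = 4), collapse = " x ")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "SegmentationMask", function(object) {
  d <- dim(object@data)
  cat(sprintf("SegmentationMask [%s] %d x %d x %d, %d foreground voxels (%.2f ml)\n",
              object@label, d[1], d[2], d[3], sum(object@data),
              sum(object@data) * prod(object@spacing) / 1000))
})

setMethod("show", "ThresholdPair", function(object) {
  cat(sprintf("ThresholdPair [%.6g, %.6g]\n", object@tLower, object@tUpper))
})

setMethod("show", "VolumeResult", function(object) {
  cat(sprintf("VolumeResult: %.3f ml (%s; interior %.3f + partial %.3f)\n",
              object@totalMl, object@method,
              object@interiorVoxelMl, object@partialVoxelMl))
  if (length(object@perComponentMl) > 1)
    cat("  components (ml):", paste(format(object@perComponentMl, digits = 4),
                                    collapse = ", "), "\n")
})

setMethod("show", "BoneObjects", function(object) {
  cat(sprintf("BoneObjects [frame %s]: femur %d voxels, tibia %d voxels\n",
              object@frame, sum(object@femur@data), sum(object@tibia@data)))
})
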