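# Stage 2: mask the objects of non-interest (bones, patella, fat) in T2.

# Body (leg) region of a T2 volume: everything above the optimal point over
# the dominant (air) mode, hole-filled in 3D. Restricting analysis to the
# body keeps the stage-3 histogram free of the air mode.
bodyRegion <- function(t2, config = effusionConfig()) {
  hist <- buildHistogram(t2, NULL, config@nBins, "whole T2 volume")
  thr <- tryCatch(optimalPointThreshold(hist, "above", config@thresholdMethod),
                  error = function(e) min(t2@data) - 1)
  m <- fillHoles3d(t2@data >= thr)
  SegmentationMask(m, t2, label = "BODY")
}

#' Stage 2a: segment the patella/fat complex in T2
#'
#' Patella and fat are bright on T2, lie in close proximity anterior to the
#' femur, and are masked together. Per slice, an optimal-point threshold of
#' the body-region histogram (bone voxels excluded) selects bright
#' candidates; 26-connected 3D components that reach anterior of the femur's
#' per-slice anterior extent (by more than a small tolerance) are labelled
#' patella/fat. Components below the minimum object size are ignored.
#'
#' @param t2 the T2 \linkS4class{ImageVolume}.
#' @param bones \linkS4class{BoneObjects} in the T2 frame.
#' @param config a \linkS4class{PipelineConfig}.
#' @return A \linkS4class{SegmentationMask} (label PATELLA_FAT), never
#'   overlapping the bones. May be empty.
#' @export
segmentPatellaFat <- function(t2, bones, config = effusionConfig()) {
  stopifnot(bones@frame == "T2")
  body <- bodyRegion(t2, config)@data
  boneM <- bones@femur@data | bones@tibia@data
  d <- dim(t2@data)
  bright <- array(FALSE, d)
  for (k in seq_len(d[3])) {
    sel <- body[, , k] & !boneM[, , k]
    if (sum(sel) < 64) next
    h <- histogramFromValues(t2@data[, , k][sel], config@nBins, "T2 slice (body, no bone)")
    thr <- tryCatch(optimalPointThreshold(h, "above", config@thresholdMethod),
                    error = function(e) Inf)
    bright[, , k] <- sel & t2@data[, , k] >= thr
  }
  if (!any(bright))
    return(SegmentationMask(bright, t2, label = "PATELLA_FAT"))
  # world-anterior (+y) extent of the femur per slice; near the bone ends the
  # per-slice cross-section shrinks and its extent is unrepresentative, so the
  # reference never drops more than 2 mm below the femur's global extent
  femIdx <- whichIdx(bones@femur@data)
  yWorld <- voxelToWorld(t2@affine, femIdx - 1)[, 2]
  femYmax <- rep(Inf, d[3])       # no femur on a slice -> nothing qualifies
  agg <- tapply(yWorld, femIdx[, 3], max)
  femYmax[as.integer(names(agg))] <- pmax(agg, max(yWorld) - 2)
  bIdx <- whichIdx(bright)
  bY <- voxelToWorld(t2@affine, bIdx - 1)[, 2]
  anterior <- bY > femYmax[bIdx[, 3]] + config@anteriorMarginMm
  lab <- ccLabel(bright, config@connectivity)
  n <- attr(lab, "n")
  labAt <- lab[bright]                     # label per bright voxel, same order as bIdx
  sizes <- tabulate(labAt, nbins = n)
  antLabs <- unique(labAt[anterior])
  keep <- antLabs[sizes[antLabs] >= config@minObjectVoxels]
  out <- array(lab %in% keep, d) & !boneM
  SegmentationMask(out, t2, label = "PATELLA_FAT")
}

#' Stage 2b: build the masked images set
#'
#' Combines the transported bones with the patella/fat mask into the
#' non-interest mask and exposes the remaining body voxels as the analysis
#' domain for the fluid segmentation. Masking is by domain restriction only:
#' T2 intensities are never overwritten, so downstream histograms are not
#' contaminated by artificial zero peaks.
#'
#' @param t2 the T2 \linkS4class{ImageVolume}.
#' @param bones \linkS4class{BoneObjects} in the T2 frame.
#' @param config a \linkS4class{PipelineConfig}.
#' @return A \linkS4class{MaskedImageSet}. An empty analysis domain is
#'   signalled with a warning.
#' @export
buildMaskedSet <- function(t2, bones, config = effusionConfig()) {
  pf <- segmentPatellaFat(t2, bones, config)
  body <- bodyRegion(t2, config)
  non <- bones@femur@data | bones@tibia@data | pf@data
  domain <- body@data & !non
  if (!any(domain)) warning("empty analysis domain: non-interest mask covers the body")
  new("MaskedImageSet", t2 = t2,
      noninterest = SegmentationMask(non, t2, label = "NONINTEREST"),
      analysisDomain = SegmentationMask(domain, t2, label = "BODY"))
}

#' Trivial masked set over the whole grid
#'
#' The phantom pathway enters the pipeline at stage 3 (no bones or other
#' structures are present), so the whole grid is the analysis domain and the
#' non-interest mask is empty.
#'
#' @param t2 an \linkS4class{ImageVolume}.
#' @return A \linkS4class{MaskedImageSet}.
#' @export
fullDomainMaskedSet <- function(t2) {
  d <- dim(t2@data)
  new("MaskedImageSet", t2 = t2,
      noninterest = SegmentationMask(array(FALSE, d), t2, label = "NONINTEREST"),
      analysisDomain = SegmentationMask(array(TRUE, d), t2, label = "BODY"))
}
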