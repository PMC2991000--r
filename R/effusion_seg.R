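# Stage 3: joint-fluid segmentation in the masked set, anatomic filtering,
# and boundary repair.

#' Stage 3a: candidate fluid objects from the masked set
#'
#' Applies the recursive two-pass threshold to the histogram of
#' analysis-domain intensities, selects domain voxels at or above the
#' threshold, labels 26-connected components, and discards components below
#' the minimum size.
#'
#' @param mset a \linkS4class{MaskedImageSet}.
#' @param config a \linkS4class{PipelineConfig}.
#' @return List of \linkS4class{CandidateObject}s, sorted by voxel count
#'   (descending). The threshold is attached as attribute \code{threshold}.
#' @export
segmentFluidCandidates <- function(mset, config = effusionConfig()) {
  domain <- mset@analysisDomain@data
  if (!any(domain)) stop("empty analysis domain")
  t2 <- mset@t2
  hist <- histogramFromValues(t2@data[domain], config@nBins, "analysis domain (T2)")
  thr <- tryCatch(recursiveThreshold(hist, method = config@thresholdMethod),
                  error = function(e) NULL)
  if (is.null(thr)) {
    # degenerate (near-constant) domain: no bright content to segment
    out <- list()
    attr(out, "threshold") <- NA_real_
    return(out)
  }
  fg <- domain & t2@data >= as.numeric(thr)
  cands <- list()
  if (any(fg)) {
    lab <- ccLabel(fg, config@connectivity)
    n <- attr(lab, "n")
    sizes <- tabulate(lab[lab > 0L], nbins = n)
    keep <- which(sizes >= config@minObjectVoxels)
    keep <- keep[order(sizes[keep], decreasing = TRUE)]
    for (l in keep) {
      m <- SegmentationMask(array(lab == l, dim(fg)), t2, label = "FLUID_CANDIDATE")
      cands[[length(cands) + 1L]] <-
        new("CandidateObject", mask = m, centroidMm = maskCentroidMm(m),
            bboxMm = maskBboxMm(m), voxelCount = sizes[l])
    }
  }
  attr(cands, "threshold") <- thr
  cands
}

#' Peri-articular pouch region from the bones
#'
#' The synovial pouch extends anteroproximally along one third of the femur
#' and posterodistally along one fourth of the tibia from the knee joint.
#' The bands are axial world-z intervals measured from each bone's joint-side
#' end, combined with the anterior (femur) / posterior (tibia) half-space of
#' the bone's centroid.
#'
#' @param bones \linkS4class{BoneObjects} in the T2 frame.
#' @param dilationMm outward bone-surface margin (default 15 mm).
#' @return A \linkS4class{PouchRegion}.
#' @export
pouchRegion <- function(bones, dilationMm = 15) {
  femW <- voxelToWorld(bones@femur@affine, whichIdx(bones@femur@data) - 1)
  tibW <- voxelToWorld(bones@tibia@affine, whichIdx(bones@tibia@data) - 1)
  fz <- range(femW[, 3]); tz <- range(tibW[, 3])
  femBand <- c(fz[1], fz[1] + diff(fz) / 3)        # distal end, upward
  tibBand <- c(tz[2] - diff(tz) / 4, tz[2])        # proximal end, downward
  new("PouchRegion", femoralBand = femBand, tibialBand = tibBand,
      femoralAnteriorCut = mean(femW[, 2]), tibialPosteriorCut = mean(tibW[, 2]),
      dilationMm = dilationMm)
}

#' Stage 3b: anatomic filtering of candidate objects
#'
#' A candidate is retained iff (a) its centroid lies within the configured
#' margin of a bone surface, (b) its bounding box intersects the femoral or
#' the tibial pouch band, and (c) it is not a thin shell apposed to
#' subchondral bone (candidates with >= \code{shellFraction} of their voxels
#' within \code{shellDistanceVoxels} in-plane voxels of a bone surface are
#' discarded as hyaline cartilage). Candidates are only included or excluded
#' whole; their masks are never modified.
#'
#' @param candidates list of \linkS4class{CandidateObject}s.
#' @param bones \linkS4class{BoneObjects} in the T2 frame.
#' @param pouch optional \linkS4class{PouchRegion}; computed from the bones
#'   when missing.
#' @param config a \linkS4class{PipelineConfig}.
#' @return The retained sub-list, with a per-candidate audit table (attribute
#'   \code{audit}: centroid, size, retained flag and firing rule).
#' @export
anatomicFilter <- function(candidates, bones, pouch = NULL,
                           config = effusionConfig()) {
  if (length(candidates) == 0L) {
    out <- list()
    attr(out, "audit") <- data.frame()
    return(out)
  }
  if (is.null(pouch)) pouch <- pouchRegion(bones, config@pouchMarginMm)
  boneM <- bones@femur@data | bones@tibia@data
  surf <- bgNeighbor6(boneM) & boneM
  surfW <- voxelToWorld(bones@femur@affine, whichIdx(surf) - 1)
  # in-plane dilation of the bone by the shell distance (cartilage test)
  r <- config@shellDistanceVoxels
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  shellZone <- boneM
  for (k in seq_len(dim(boneM)[3]))
    shellZone[, , k] <- as.matrix(EBImage::dilate(boneM[, , k] * 1, brush)) > 0
  shellZone <- shellZone & !boneM
  rows <- vector("list", length(candidates))
  retained <- logical(length(candidates))
  for (i in seq_along(candidates)) {
    cd <- candidates[[i]]
    dist <- sqrt(min(colSums((t(surfW) - cd@centroidMm)^2)))
    nearBone <- dist <= pouch@dilationMm
    bb <- cd@bboxMm
    inFem <- bb[2, 3] >= pouch@femoralBand[1] && bb[1, 3] <= pouch@femoralBand[2] &&
      bb[2, 2] >= pouch@femoralAnteriorCut
    inTib <- bb[2, 3] >= pouch@tibialBand[1] && bb[1, 3] <= pouch@tibialBand[2] &&
      bb[1, 2] <= pouch@tibialPosteriorCut
    shellFrac <- sum(cd@mask@data & shellZone) / cd@voxelCount
    isShell <- shellFrac >= config@shellFraction
    keep <- nearBone && (inFem || inTib) && !isShell
    rule <- if (keep) "retained"
      else if (!nearBone) "far from bone surface"
      else if (!(inFem || inTib)) "outside pouch bands"
      else "cartilage shell"
    retained[i] <- keep
    rows[[i]] <- data.frame(candidate = i, voxels = cd@voxelCount,
                            x = cd@centroidMm[1], y = cd@centroidMm[2],
                            z = cd@centroidMm[3], boneDistMm = dist,
                            shellFraction = shellFrac, retained = keep,
                            rule = rule)
  }
  out <- candidates[retained]
  attr(out, "audit") <- do.call(rbind, rows)
  out
}

#' Stage 3c: final effusion mask
#'
#' Union of the retained candidates, passed through the inter-slice repair
#' operator to sharpen boundaries degraded by intensity inhomogeneity, and
#' clipped against the non-interest mask. The result may consist of several
#' components (the effusion object's topology varies between patients).
#'
#' @param retained list of retained \linkS4class{CandidateObject}s.
#' @param mset the \linkS4class{MaskedImageSet}.
#' @param config a \linkS4class{PipelineConfig}.
#' @return A \linkS4class{SegmentationMask} with label EFFUSION.
#' @export
finalizeEffusion <- function(retained, mset, config = effusionConfig()) {
  d <- dim(mset@t2@data)
  acc <- array(FALSE, d)
  for (cd in retained) acc <- acc | cd@mask@data
  m <- SegmentationMask(acc, mset@t2, label = "EFFUSION")
  m <- repairSlices(m, config@repairAreaFraction)
  m@data <- m@data & !mset@noninterest@data
  m
}
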