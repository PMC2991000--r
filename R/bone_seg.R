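#' Femoral seed region at the image center
#'
#' The femur lies at the center of axial knee acquisitions, so a fixed
#' 18 x 36 x 18 mm box (the 36 mm side along the anterior-posterior axis)
#' centered on the grid defines a pure bone-marrow sample for the histogram
#' analysis.
#'
#' @param volume the T1 \linkS4class{ImageVolume}.
#' @param extentMm physical box extent (mm) per axis; default c(18, 36, 18).
#' @return A \linkS4class{FemoralSeedRegion}.
#' @export
seedRegion <- function(volume, extentMm = c(18, 36, 18)) {
  d <- dim(volume@data)
  nvox <- pmax(1L, as.integer(round(extentMm / volume@spacing)))
  if (any(nvox > d))
    stop("field of view smaller than the seed box (needs ",
         paste(nvox, collapse = "x"), " voxels)")
  lo <- as.integer(floor((d - nvox) / 2) + 1L)
  hi <- as.integer(lo + nvox - 1L)
  new("FemoralSeedRegion", center = (d + 1) / 2, extentMm = as.numeric(extentMm),
      lo = lo, hi = hi)
}

#' Select bone voxels by an intensity interval
#'
#' @param volume an \linkS4class{ImageVolume}.
#' @param pair a \linkS4class{ThresholdPair} (typically from
#'   \code{\link{dualThresholds}} of the seed-region histogram).
#' @return A \linkS4class{SegmentationMask} of voxels with
#'   tLower <= intensity <= tUpper.
#' @export
thresholdBone <- function(volume, pair) {
  m <- volume@data >= pair@tLower & volume@data <= pair@tUpper
  SegmentationMask(m, volume, label = "CANDIDATE")
}

#' 2D contrast correction of a slice mask boundary
#'
#' Refines a 2D object boundary against the image signal: each boundary point
#' may move up to \code{depth} pixels along the local inward/outward normal to
#' the position of maximum intensity-gradient magnitude (gradients from
#' central differences after Gaussian smoothing). The moved boundary is
#' re-imposed through the mask's signed distance transform, holes are filled
#' and stray new components are dropped, so the output remains one filled
#' region per input region.
#'
#' @param sliceMask 2D logical matrix.
#' @param sliceImage 2D numeric matrix of the same shape.
#' @param depth maximum boundary displacement in pixels (default 3).
#' @param sigma Gaussian smoothing (px) before gradient computation.
#' @return The corrected 2D logical mask.
#' @export
contrastCorrectSlice <- function(sliceMask, sliceImage, depth = 3L, sigma = 1) {
  stopifnot(all(dim(sliceMask) == dim(sliceImage)))
  if (!any(sliceMask)) return(sliceMask)
  if (all(sliceMask)) return(sliceMask)
  d <- signedDistance2d(sliceMask)
  g <- gradientMagnitude2d(sliceImage, sigma)
  n1 <- nrow(d); n2 <- ncol(d)
  # inward normal from the signed distance gradient
  dx <- matrix(0, n1, n2); dy <- matrix(0, n1, n2)
  dx[2:(n1 - 1), ] <- (d[3:n1, ] - d[1:(n1 - 2), ]) / 2
  dy[, 2:(n2 - 1)] <- (d[, 3:n2] - d[, 1:(n2 - 2)]) / 2
  nrm <- sqrt(dx^2 + dy^2); nrm[nrm == 0] <- 1
  bnd <- which(sliceMask & d <= 1, arr.ind = TRUE)
  if (nrow(bnd) == 0L) return(sliceMask)
  nx <- dx[bnd] / nrm[bnd]; ny <- dy[bnd] / nrm[bnd]
  offs <- (-depth):depth
  score <- matrix(-Inf, nrow(bnd), length(offs))
  for (j in seq_along(offs)) {
    px <- round(bnd[, 1] + offs[j] * nx)
    py <- round(bnd[, 2] + offs[j] * ny)
    ok <- px >= 1 & px <= n1 & py >= 1 & py <= n2
    score[ok, j] <- g[cbind(px[ok], py[ok])]
  }
  # preferred displacement per boundary pixel: max gradient; a tiny distance
  # penalty keeps near-tied scores (e.g. symmetric edges) at the smallest move
  mx <- max(score[is.finite(score)], 0)
  score <- score - matrix(abs(offs), nrow(bnd), length(offs), byrow = TRUE) *
    (mx * 1e-6 + 1e-12)
  pref <- order(abs(offs))
  best <- apply(score[, pref, drop = FALSE], 1, which.max)
  shift <- offs[pref][best]                 # >0 means move inward (shrink)
  # interpolate the sparse per-boundary-pixel shifts over the search band
  w <- matrix(0, n1, n2); sw <- matrix(0, n1, n2)
  w[bnd] <- 1; sw[bnd] <- shift
  ws <- smooth2d(w, 2); sws <- smooth2d(sw, 2)
  shiftField <- ifelse(ws > 1e-8, sws / ws, 0)
  shiftField <- pmin(pmax(shiftField, -depth), depth)
  band <- abs(d) <= depth + 1
  out <- sliceMask
  out[band] <- d[band] >= shiftField[band]
  out <- as.matrix(EBImage::fillHull(out * 1)) > 0
  # no new components: keep those overlapping the input mask
  lab <- as.matrix(EBImage::bwlabel(out * 1))
  keep <- unique(lab[sliceMask & lab > 0])
  out & matrix(lab %in% keep, n1, n2)
}

#' Inter-slice repair of a 3D mask
#'
#' A slice whose object cross-section is empty or smaller than a fraction of
#' its two neighbours' mean area, while both neighbours are non-empty, is
#' taken to carry missing or partial object information and is replaced by
#' the morphological interpolation of its neighbours (the zero level of the
#' mean of their signed distance transforms). All other slices pass through
#' unchanged; neighbour slices are always read from the input, so the
#' operation is a deterministic single pass.
#'
#' @param mask a \linkS4class{SegmentationMask} spanning >= 3 slices.
#' @param areaFraction area-drop trigger (default 0.5).
#' @return The repaired \linkS4class{SegmentationMask}.
#' @export
repairSlices <- function(mask, areaFraction = 0.5) {
  m <- mask@data
  nz <- dim(m)[3]
  if (nz < 3L || !any(m)) return(mask)
  areas <- sliceAreas(m)
  out <- m
  for (k in 2:(nz - 1)) {
    if (areas[k - 1] == 0 || areas[k + 1] == 0) next
    neigh <- (areas[k - 1] + areas[k + 1]) / 2
    if (areas[k] < areaFraction * neigh) {
      sd1 <- signedDistance2d(m[, , k - 1])
      sd2 <- signedDistance2d(m[, , k + 1])
      out[, , k] <- (sd1 + sd2) / 2 >= 0
    }
  }
  SegmentationMask(out, mask, label = mask@label)
}

#' Stage 1: segment femur and tibia from the T1 volume
#'
#' Pipeline: seed-region histogram, dual optimal-point thresholds, 3D
#' threshold selection, per-slice contrast correction, inter-slice repair,
#' 26-connected component labelling. The femur is the component containing
#' the seed region (the seed box itself is included by definition); the tibia
#' is the largest remaining component centered distal (inferior) to the
#' femur. Both are hole-filled into solid objects and transported into the T2
#' frame through the stored affines.
#'
#' @param t1,t2 the paired \linkS4class{ImageVolume}s.
#' @param config a \linkS4class{PipelineConfig}.
#' @return A \linkS4class{BoneObjects} in the T2 frame. The stage thresholds
#'   are attached as attribute \code{thresholds}.
#' @export
segmentBones <- function(t1, t2, config = effusionConfig()) {
  if (t1@sequence != "T1") stop("bone segmentation expects the T1 sequence")
  seed <- seedRegion(t1)
  hist <- buildHistogram(t1, seed, config@nBins, "femoral seed region (T1)")
  pair <- dualThresholds(hist, method = config@thresholdMethod)
  raw <- thresholdBone(t1, pair)
  m <- raw@data
  for (k in seq_len(dim(m)[3]))
    m[, , k] <- contrastCorrectSlice(m[, , k], t1@data[, , k],
                                     depth = config@contrastSearchDepth,
                                     sigma = config@contrastSigma)
  rep <- repairSlices(SegmentationMask(m, t1, "CANDIDATE"),
                      config@repairAreaFraction)
  m <- rep@data
  lab <- ccLabel(m, config@connectivity)
  n <- attr(lab, "n")
  if (n == 0L) stop("femur not found: no bone-intensity component")
  seedBox <- array(FALSE, dim(m))
  seedBox[seed@lo[1]:seed@hi[1], seed@lo[2]:seed@hi[2], seed@lo[3]:seed@hi[3]] <- TRUE
  overlap <- tabulate(lab[seedBox & lab > 0L], nbins = n)
  if (length(overlap) == 0L || max(overlap) == 0L)
    stop("femur not found: no component contains the seed region")
  femLab <- which.max(overlap)
  femur <- fillHoles3d(array(lab == femLab, dim(m)) | seedBox)
  # femur centroid along the slice axis (world z = superior)
  zWorld <- function(idx) voxelToWorld(t1@affine, idx - 1)[, 3]
  femZ <- mean(zWorld(whichIdx(femur)))
  sizes <- tabulate(lab[lab > 0L], nbins = n)
  tibLab <- 0L; tibSize <- 0L
  for (l in seq_len(n)) {
    if (l == femLab || sizes[l] <= tibSize) next
    comp <- array(lab == l, dim(m))
    if (mean(zWorld(whichIdx(comp))) < femZ) { tibLab <- l; tibSize <- sizes[l] }
  }
  if (tibLab == 0L) stop("tibia not found: no component distal to the femur")
  tibia <- fillHoles3d(array(lab == tibLab, dim(m)) & !femur)
  femurT2 <- transportMask(SegmentationMask(femur, t1, "FEMUR"), t1, t2)
  tibiaT2 <- transportMask(SegmentationMask(tibia, t1, "TIBIA"), t1, t2)
  # transport keeps solidity in practice; enforce the object invariants
  femurT2@data <- fillHoles3d(largestComponent(femurT2@data, config@connectivity))
  tibiaT2@data <- fillHoles3d(largestComponent(tibiaT2@data, config@connectivity)) &
    !femurT2@data
  bones <- new("BoneObjects", femur = femurT2, tibia = tibiaT2, frame = "T2")
  attr(bones, "thresholds") <- c(tLower = pair@tLower, tUpper = pair@tUpper)
  bones
}
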