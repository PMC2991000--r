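#' Build an intensity histogram of a voxel region
#'
#' Equal-width bins spanning exactly the observed intensity range of the
#' region. Every voxel of the region is counted exactly once.
#'
#' @param volume an \linkS4class{ImageVolume}.
#' @param region the voxel set to histogram: \code{NULL} (whole grid), a
#'   \linkS4class{SegmentationMask}, a logical array, or a
#'   \linkS4class{FemoralSeedRegion} box.
#' @param nBins number of bins (>= 8, default 256).
#' @param description free-text label of the source region.
#' @return An \linkS4class{IntensityHistogram}.
#' @export
buildHistogram <- function(volume, region = NULL, nBins = 256L,
                           description = "region") {
  nBins <- as.integer(nBins)
  if (nBins < 8L) stop("nBins must be >= 8")
  vals <- regionValues(volume, region)
  if (length(vals) == 0L) stop("empty histogram region")
  histogramFromValues(vals, nBins, description)
}

regionValues <- function(volume, region) {
  if (is.null(region)) return(as.vector(volume@data))
  if (is(region, "FemoralSeedRegion")) {
    lo <- region@lo; hi <- region@hi
    return(as.vector(volume@data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]))
  }
  if (is(region, "SegmentationMask")) region <- region@data
  if (is.logical(region)) {
    stopifnot(all(dim(region) == dim(volume@data)))
    return(volume@data[region])
  }
  stop("unsupported region type")
}

histogramFromValues <- function(vals, nBins, description = "region") {
  r <- range(vals)
  if (r[1] == r[2]) {
    # degenerate constant region: a single occupied bin
    edges <- r[1] + seq(-0.5, nBins - 0.5, length.out = nBins + 1L)
    counts <- integer(nBins)
    counts[1L] <- length(vals)
  } else {
    edges <- seq(r[1], r[2], length.out = nBins + 1L)
    bin <- pmin(pmax(findInterval(vals, edges, rightmost.closed = TRUE), 1L), nBins)
    counts <- tabulate(bin, nbins = nBins)
  }
  new("IntensityHistogram", binEdges = edges, counts = as.integer(counts),
      sourceRegion = description)
}

binCenters <- function(hist) {
  e <- hist@binEdges
  (e[-1] + e[-length(e)]) / 2
}

dominantModeBin <- function(counts) {
  # ties broken toward the higher intensity
  mx <- max(counts)
  max(which(counts == mx))
}

#' Optimal-point threshold of a histogram curve
#'
#' The default method is the triangle (maximum chord-deviation) technique: a
#' chord is drawn from the dominant mode's peak to the last ("above") or first
#' ("below") non-empty bin, and the returned threshold is the bin-center
#' intensity maximizing the perpendicular distance from the (axis-normalized)
#' histogram curve to that chord. Deterministic for a fixed histogram; ties
#' are broken toward the higher intensity. An Otsu (maximum between-class
#' variance) alternative is available.
#'
#' @param hist an \linkS4class{IntensityHistogram} with at least 2 non-empty
#'   bins.
#' @param side "above" or "below": which side of the dominant mode to search.
#' @param method "triangle" (default) or "otsu".
#' @return Threshold intensity (a bin center).
#' @export
optimalPointThreshold <- function(hist, side = c("above", "below"),
                                  method = c("triangle", "otsu")) {
  side <- match.arg(side)
  method <- match.arg(method)
  counts <- as.numeric(hist@counts)
  occupied <- which(counts > 0)
  if (length(occupied) < 2L)
    stop("histogram needs >= 2 non-empty bins for an optimal point")
  centers <- binCenters(hist)
  if (method == "otsu") return(.otsuThreshold(counts, centers, side))
  mode <- dominantModeBin(counts)
  end <- if (side == "above") max(occupied) else min(occupied)
  if (end == mode)
    stop("no separable optimal point ", side, " the dominant mode")
  d <- .triangleDeviation(counts, centers, mode, end)
  lo <- min(mode, end); hi <- max(mode, end)
  cand <- setdiff(lo:hi, c(mode, end))   # strictly between peak and endpoint
  if (length(cand) == 0L) cand <- lo:hi
  dev <- d[cand]
  best <- cand[max(which(dev == max(dev)))]  # tie toward higher intensity
  centers[best]
}

# perpendicular distance of every bin to the chord from the mode peak to the
# end bin, on axes normalized to [0, 1] (bin position, peak count)
.triangleDeviation <- function(counts, centers, mode, end) {
  n <- length(counts)
  x <- (seq_len(n) - mode) / (end - mode)       # 0 at peak, 1 at endpoint
  y <- counts / counts[mode]
  x0 <- 0; y0 <- 1
  x1 <- 1; y1 <- counts[end] / counts[mode]
  num <- abs((y1 - y0) * x - (x1 - x0) * y + x1 * y0 - y1 * x0)
  num / sqrt((y1 - y0)^2 + (x1 - x0)^2)
}

.otsuThreshold <- function(counts, centers, side) {
  total <- sum(counts)
  w <- cumsum(counts)
  mu <- cumsum(counts * centers)
  muT <- mu[length(mu)]
  wb <- w[-length(w)]; wf <- total - wb
  valid <- wb > 0 & wf > 0
  sigma <- rep(-Inf, length(wb))
  sigma[valid] <- (muT * wb[valid] - mu[-length(mu)][valid])^2 /
    (wb[valid] * wf[valid])
  k <- max(which(sigma == max(sigma)))
  (centers[k] + centers[k + 1]) / 2
}

#' Lower and upper thresholds bracketing the dominant intensity mode
#'
#' Computes the optimal point below and above the dominant mode of the
#' histogram, defining the intensity interval of the mode's tissue class
#' (used for the bone-marrow interval of the femoral seed-region histogram).
#'
#' @inheritParams optimalPointThreshold
#' @return A \linkS4class{ThresholdPair}.
#' @export
dualThresholds <- function(hist, method = c("triangle", "otsu")) {
  method <- match.arg(method)
  lo <- optimalPointThreshold(hist, side = "below", method = method)
  hi <- optimalPointThreshold(hist, side = "above", method = method)
  new("ThresholdPair", tLower = lo, tUpper = hi)
}

#' Recursive two-pass fluid threshold
#'
#' Stage-3 threshold of the joint-fluid segmentation. Pass 1 computes the
#' optimal point above the histogram's dominant (background/soft-tissue) mode,
#' delimiting the bright intensity range. Pass 2 restricts the curve to
#' intensities >= the pass-1 value, locates the dominant bright mode there,
#' and returns the separating threshold midway between the two mode
#' intensities (never below the pass-1 value). This places the selection cut
#' at the midpoint of the partial-volume ramp between background and fluid,
#' which is what makes the downstream subvoxel volumetry unbiased; a slightly
#' higher but stable threshold is preferred on ties.
#'
#' When the restricted curve degenerates (fewer than 2 non-empty bins, or no
#' bright mode separable from the range limit) the pass-1 value is returned
#' and flagged.
#'
#' @inheritParams optimalPointThreshold
#' @return The threshold intensity, with attributes \code{t1} (pass-1 value),
#'   \code{fallback} (logical), \code{mode1} and \code{mode2} (the two mode
#'   intensities; \code{mode2} is \code{NA} on fallback).
#' @export
recursiveThreshold <- function(hist, method = c("triangle", "otsu")) {
  method <- match.arg(method)
  counts <- as.numeric(hist@counts)
  centers <- binCenters(hist)
  m1 <- centers[dominantModeBin(counts)]
  t1 <- tryCatch(optimalPointThreshold(hist, side = "above", method = method),
                 error = function(e) NULL)
  if (is.null(t1)) stop("histogram needs >= 2 non-empty bins for an optimal point")
  fallback <- function() structure(t1, t1 = t1, fallback = TRUE,
                                   mode1 = m1, mode2 = NA_real_)
  keep <- which(centers >= t1)
  restricted <- counts[keep]
  if (sum(restricted > 0) < 2L) return(fallback())
  # bright mode of the restricted curve: the decaying tail of the dominant
  # dark mode can reach past t1, so the maximum is searched beyond the initial
  # non-increasing run of the (lightly smoothed) curve; the run itself is not
  # a mode of the bright content
  sm <- stats::filter(restricted, rep(1 / 5, 5), sides = 2)
  sm[is.na(sm)] <- restricted[is.na(sm)]
  sm <- as.numeric(sm)
  m2i <- max(which(sm == max(sm)))
  run <- 1L
  while (run < length(sm) && sm[run + 1] <= sm[run]) run <- run + 1L
  if (m2i <= run) {
    if (run >= length(sm)) return(fallback())
    rest <- sm[(run + 1):length(sm)]
    if (max(rest) <= 0) return(fallback())
    m2i <- run + max(which(rest == max(rest)))
  }
  m2 <- centers[keep[m2i]]
  if (m2 <= m1) return(fallback())
  thr <- max(t1, (m1 + m2) / 2)
  structure(thr, t1 = t1, fallback = FALSE, mode1 = m1, mode2 = m2)
}
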