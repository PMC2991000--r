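# Shared fixtures, generated once per test run and cached.

.fix <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fix)) assign(key, force(expr), envir = .fix)
  get(key, envir = .fix)
}

# default synthetic knee and its full pipeline run
getKnee <- function() cached("knee", renderKnee(kneeSpec(seed = 7L)))
getKneeRun <- function() {
  k <- getKnee()
  cached("kneeRun", runSegment(k$t1, k$t2))
}

# knee variant with the vessel decoy bright enough to be segmented
getBrightVesselKnee <- function()
  cached("kneeBV", renderKnee(kneeSpec(vesselIntensityT2 = 0.9, seed = 11L)))
getBrightVesselRun <- function() {
  k <- getBrightVesselKnee()
  cached("kneeBVRun", runSegment(k$t1, k$t2))
}

# one rendered cylinder-phantom scan (default acquisition conditions)
getCylScan <- function() cached("cylScan", renderPhantom(cylinderPhantomSpec(seed = 1L)))

# small, fast sphere phantom for unit tests (not the acceptance conditions)
smallSphereSpec <- function(seed = 0L)
  spherePhantomSpec(fluidVolumeMl = 80, solidRadiusMm = 15,
                    gridDim = c(128L, 128L, 24L), seed = seed)

# digitized ball mask: voxel centers within r voxels of the grid center
ballMask <- function(r, spacing = c(1, 1, 1), margin = 3L) {
  d <- rep(2L * (as.integer(ceiling(r)) + margin) + 1L, 3L)
  ctr <- (d + 1) / 2
  idx <- arrayInd(seq_len(prod(d)), d)
  m <- array(sqrt(rowSums(sweep(idx, 2, ctr)^2)) <= r, d)
  SegmentationMask(m, ImageVolume(array(0, d), spacing))
}

cuboidMask <- function(a, b, c, spacing = c(1, 1, 1), pad = 3L) {
  d <- c(a, b, c) + 2L * pad
  m <- array(FALSE, d)
  m[pad + seq_len(a), pad + seq_len(b), pad + seq_len(c)] <- TRUE
  SegmentationMask(m, ImageVolume(array(0, d), spacing))
}

# independent exhaustive oracle for the triangle optimal point: scan every bin
# strictly between the dominant mode and the end bin, computing the
# perpendicular point-to-chord distance on normalized axes directly
triangleOracle <- function(counts, centers, side) {
  mode <- max(which(counts == max(counts)))
  occ <- which(counts > 0)
  end <- if (side == "above") max(occ) else min(occ)
  lo <- min(mode, end); hi <- max(mode, end)
  cand <- setdiff(lo:hi, c(mode, end))
  if (length(cand) == 0L) cand <- lo:hi
  dperp <- vapply(cand, function(i) {
    x <- (i - mode) / (end - mode)
    y <- counts[i] / counts[mode]
    x1 <- 1; y1 <- counts[end] / counts[mode]
    abs((y1 - 1) * x - (x1 - 0) * y + x1 * 1 - y1 * 0) / sqrt((y1 - 1)^2 + x1^2)
  }, numeric(1))
  centers[cand[max(which(dperp == max(dperp)))]]  # ties toward higher intensity
}

# 26-neighbourhood erosion (helper for boundary-band checks)
erode26 <- function(m) {
  d <- dim(m)
  acc <- array(TRUE, d)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    sh <- array(FALSE, d)
    if (max(1, 1 + dx) > min(d[1], d[1] + dx) ||
        max(1, 1 + dy) > min(d[2], d[2] + dy) ||
        max(1, 1 + dz) > min(d[3], d[3] + dz)) next
    sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
    sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
    sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
    tx <- max(1, 1 - dx):min(d[1], d[1] - dx)
    ty <- max(1, 1 - dy):min(d[2], d[2] - dy)
    tz <- max(1, 1 - dz):min(d[3], d[3] - dz)
    sh[tx, ty, tz] <- m[sx, sy, sz]
    acc <- acc & sh
  }
  acc
}
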