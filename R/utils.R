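# Internal geometry / array helpers shared across the pipeline stages.

# diagonal RAS affine with the world origin at the grid center
centeredAffine <- function(spacing, dim) {
  a <- diag(c(spacing, 1))
  a[1:3, 4] <- -spacing * (dim - 1) / 2
  a
}

# 0-based voxel indices (N x 3) -> world mm
voxelToWorld <- function(affine, idx) {
  idx <- matrix(idx, ncol = 3)
  t(affine %*% rbind(t(idx), 1))[, 1:3, drop = FALSE]
}

# world mm (N x 3) -> 0-based continuous voxel indices
worldToVoxel <- function(affine, xyz) {
  xyz <- matrix(xyz, ncol = 3)
  t(solve(affine) %*% rbind(t(xyz), 1))[, 1:3, drop = FALSE]
}

sameGeometry <- function(a, b, tol = 1e-6) {
  all(dim(a@data) == dim(b@data)) &&
    max(abs(a@affine - b@affine)) < tol &&
    max(abs(a@spacing - b@spacing)) < tol
}

# matrix of 1-based voxel indices of TRUE entries
whichIdx <- function(mask) which(mask, arr.ind = TRUE)

# 26- (or 6-) connected labelling; returns integer array with attr "n"
ccLabel <- function(mask, connectivity = 26L) {
  .ccLabel3d(as.logical(mask), dim(mask), as.integer(connectivity))
}

# logical array: does voxel have >= 1 background 6-neighbour (grid border
# counts as background)?
bgNeighbor6 <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  bg <- !mask
  # x
  out[1, , ] <- TRUE; out[d[1], , ] <- TRUE
  out[-1, , ] <- out[-1, , ] | bg[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | bg[-1, , ]
  # y
  out[, 1, ] <- TRUE; out[, d[2], ] <- TRUE
  out[, -1, ] <- out[, -1, ] | bg[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | bg[, -1, ]
  # z
  out[, , 1] <- TRUE; out[, , d[3]] <- TRUE
  out[, , -1] <- out[, , -1] | bg[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] | bg[, , -1]
  out
}

# 26-neighbourhood binary dilation (3x3x3 box)
dilate26 <- function(mask) {
  d <- dim(mask)
  acc <- array(FALSE, d)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (max(1, 1 + dx) > min(d[1], d[1] + dx) ||
        max(1, 1 + dy) > min(d[2], d[2] + dy) ||
        max(1, 1 + dz) > min(d[3], d[3] + dz)) next
    sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
    sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
    sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
    tx <- max(1, 1 - dx):min(d[1], d[1] - dx)
    ty <- max(1, 1 - dy):min(d[2], d[2] - dy)
    tz <- max(1, 1 - dz):min(d[3], d[3] - dz)
    acc[tx, ty, tz] <- acc[tx, ty, tz] | mask[sx, sy, sz]
  }
  acc
}

# all 26 neighbours foreground (voxels at the grid border never qualify)
allNeighborsFg26 <- function(mask) {
  d <- dim(mask)
  acc <- array(TRUE, d)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    shifted <- array(FALSE, d)
    if (max(1, 1 + dx) > min(d[1], d[1] + dx) ||
        max(1, 1 + dy) > min(d[2], d[2] + dy) ||
        max(1, 1 + dz) > min(d[3], d[3] + dz)) next
    sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
    sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
    sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
    tx <- max(1, 1 - dx):min(d[1], d[1] - dx)
    ty <- max(1, 1 - dy):min(d[2], d[2] - dy)
    tz <- max(1, 1 - dz):min(d[3], d[3] - dz)
    shifted[tx, ty, tz] <- mask[sx, sy, sz]
    acc <- acc & shifted
  }
  acc & mask
}

# fill fully enclosed background cavities (background components not
# 6-connected to the grid border)
fillHoles3d <- function(mask) {
  bg <- !mask
  lab <- ccLabel(bg, 6L)
  d <- dim(mask)
  border <- unique(c(lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ],
                     lab[, , 1], lab[, , d[3]]))
  border <- border[border > 0L]
  hole <- bg & !(array(lab %in% border, d))
  mask | hole
}

largestComponent <- function(mask, connectivity = 26L) {
  lab <- ccLabel(mask, connectivity)
  n <- attr(lab, "n")
  if (n == 0L) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0L], nbins = n)
  array(lab == which.max(sizes), dim(mask))
}

#' Dice overlap of two binary masks
#'
#' @param a,b logical arrays or \linkS4class{SegmentationMask} objects of the
#'   same shape.
#' @return 2|A n B| / (|A| + |B|); 1 when both are empty.
#' @export
dice <- function(a, b) {
  if (is(a, "SegmentationMask")) a <- a@data
  if (is(b, "SegmentationMask")) b <- b@data
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}

# per-slice foreground areas (voxel counts), slices along the 3rd axis
sliceAreas <- function(mask) apply(mask, 3, sum)

# evaluate expr with a fixed RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# EBImage wrappers on plain matrices
dist2d <- function(m) as.matrix(EBImage::distmap(m * 1))

signedDistance2d <- function(m) {
  if (!any(m)) return(matrix(-Inf, nrow(m), ncol(m)))
  if (all(m)) return(matrix(Inf, nrow(m), ncol(m)))
  dist2d(m) - dist2d(!m)
}

smooth2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  as.matrix(EBImage::gblur(m, sigma = sigma))
}

gradientMagnitude2d <- function(img, sigma = 1) {
  s <- smooth2d(img, sigma)
  n1 <- nrow(s); n2 <- ncol(s)
  gx <- matrix(0, n1, n2); gy <- matrix(0, n1, n2)
  gx[2:(n1 - 1), ] <- (s[3:n1, ] - s[1:(n1 - 2), ]) / 2
  gy[, 2:(n2 - 1)] <- (s[, 3:n2] - s[, 1:(n2 - 2)]) / 2
  sqrt(gx^2 + gy^2)
}

# world-space centroid and bbox of a mask (helpers for candidate objects)
maskCentroidMm <- function(mask) {
  idx <- whichIdx(mask@data)
  colMeans(voxelToWorld(mask@affine, idx - 1))
}

maskBboxMm <- function(mask) {
  idx <- whichIdx(mask@data)
  w <- voxelToWorld(mask@affine, idx - 1)
  rbind(apply(w, 2, min), apply(w, 2, max))
}
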