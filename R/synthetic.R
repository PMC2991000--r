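# Synthetic acquisitions: shared scene renderer and calibrated phantoms.
#
# A scene is an ordered list of structures (first match wins), each with a
# vectorized world-space indicator and a tissue intensity. Voxels whose
# 6-neighbourhood is label-homogeneous take the pure tissue intensity; voxels
# on a label boundary are rendered with partial-volume mixing by sub-voxel
# sampling, which also yields per-structure occupancy fractions used as
# ground truth.

sceneRender <- function(structures, dims, spacing, affine, nsub = 5L,
                        truthNames = character(0)) {
  # per-axis sub-sampling: scale the base rate by the spacing ratio so the
  # physical sampling pitch is comparable across anisotropic voxels (slices
  # are typically 6x thicker than the in-plane pitch); odd counts keep
  # occupancy fractions away from exact .5 ties
  if (length(nsub) == 1L)
    nsub <- pmin(49L, as.integer(round(nsub * spacing / min(spacing))))
  nsub <- as.integer(nsub) + as.integer(nsub %% 2L == 0L)
  dims <- as.integer(dims)
  n <- prod(dims)
  idx <- arrayInd(seq_len(n), dims) - 1L
  pts <- voxelToWorld(affine, idx)
  nS <- length(structures)
  intens <- vapply(structures, function(s) s$intensity, numeric(1))
  classify <- function(p) {
    lab <- integer(nrow(p))
    for (si in seq_len(nS)) {
      un <- lab == 0L
      if (!any(un)) break
      hit <- structures[[si]]$inside(p[un, , drop = FALSE])
      lab[un][hit] <- si
    }
    if (any(lab == 0L)) stop("scene does not cover the grid (missing background)")
    lab
  }
  lab <- array(classify(pts), dims)
  # voxels whose label differs from a 6-neighbour get sub-voxel treatment
  boundary <- array(FALSE, dims)
  d <- dims
  boundary[-1, , ] <- boundary[-1, , ] | (lab[-1, , ] != lab[-d[1], , ])
  boundary[-d[1], , ] <- boundary[-d[1], , ] | (lab[-d[1], , ] != lab[-1, , ])
  boundary[, -1, ] <- boundary[, -1, ] | (lab[, -1, ] != lab[, -d[2], ])
  boundary[, -d[2], ] <- boundary[, -d[2], ] | (lab[, -d[2], ] != lab[, -1, ])
  boundary[, , -1] <- boundary[, , -1] | (lab[, , -1] != lab[, , -d[3]])
  boundary[, , -d[3]] <- boundary[, , -d[3]] | (lab[, , -d[3]] != lab[, , -1])
  img <- array(intens[lab], dims)
  names(structures) <- vapply(structures, function(s) s$name, character(1))
  fracs <- list()
  for (nm in truthNames) fracs[[nm]] <- array(as.double(lab == which(names(structures) == nm)), dims)
  bIdx <- which(boundary)
  if (length(bIdx)) {
    bPts0 <- pts[bIdx, , drop = FALSE]
    offAx <- lapply(nsub, function(k) (seq_len(k) - 0.5) / k - 0.5)
    nTot <- prod(nsub)
    acc <- numeric(length(bIdx))
    cnt <- matrix(0, length(bIdx), length(truthNames))
    colnames(cnt) <- truthNames
    A3 <- affine[1:3, 1:3]
    for (oz in offAx[[3]]) for (oy in offAx[[2]]) for (ox in offAx[[1]]) {
      p <- bPts0 + matrix(rep(A3 %*% c(ox, oy, oz), each = length(bIdx)),
                          ncol = 3)
      sl <- classify(p)
      acc <- acc + intens[sl]
      for (nm in truthNames)
        cnt[, nm] <- cnt[, nm] + (sl == which(names(structures) == nm))
    }
    img[bIdx] <- acc / nTot
    for (nm in truthNames) fracs[[nm]][bIdx] <- cnt[, nm] / nTot
  }
  list(intensity = img, fractions = fracs, labels = lab)
}

# small-angle rotation matrix from Euler angles (degrees), R = Rz Ry Rx
.eulerRotation <- function(deg) {
  r <- deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

# wrap an indicator so the object is rotated by R about the world origin and
# translated by t: p belongs to the moved object iff R^-1 (p - t) is inside
.jitterWrap <- function(inside, R, t) {
  force(inside); force(R); force(t)
  function(p) inside(sweep(p, 2, t) %*% R)
}

# distance from points to a vertical capsule axis segment
.capsuleDist <- function(p, cx, cy, z0, z1) {
  zm <- (z0 + z1) / 2; h <- (z1 - z0) / 2
  dz <- pmax(0, abs(p[, 3] - zm) - h)
  sqrt((p[, 1] - cx)^2 + (p[, 2] - cy)^2 + dz^2)
}

#' Calibrated two-cylinder phantom specification
#'
#' Two disjoint perpendicular cylinders (one along the acquisition direction,
#' one in-plane) filled with a bright solution and embedded in a water bath,
#' calibrated to a total fluid volume of 14.1 ml. Geometry beyond the total
#' volume is config-visible; the analytic truth is always recomputed as
#' 2 pi r^2 L from the stored geometry.
#'
#' @param totalVolumeMl calibrated total fluid volume (default 14.1).
#' @param radiusMm cylinder radius (default 7.5).
#' @param spacingMm acquisition voxel size, default c(0.5, 0.5, 3).
#' @param gridDim acquisition grid, default c(128, 128, 22).
#' @param noiseSigma additive noise SD relative to the fluid intensity.
#' @param orientationJitterDeg,offsetJitterMm per-scan pose jitter ranges.
#' @param seed RNG seed.
#' @return A \linkS4class{PhantomSpec} of kind CYLINDER_PAIR.
#' @export
cylinderPhantomSpec <- function(totalVolumeMl = 14.1, radiusMm = 7.5,
                                spacingMm = c(0.5, 0.5, 3),
                                gridDim = c(128L, 128L, 22L),
                                noiseSigma = 0.04, orientationJitterDeg = 5,
                                offsetJitterMm = spacingMm / 2, seed = 0L) {
  halfLen <- totalVolumeMl * 1000 / (2 * pi * radiusMm^2) / 2
  # one cylinder along the acquisition direction, one in-plane: the paper
  # notes partial volume is smallest when the axes are parallel or
  # perpendicular to the acquisition direction, so this is the nominal pose
  geom <- list(radius = radiusMm, halfLen = halfLen,
               centerA = c(-14, -12, 0), axisA = "z",
               centerB = c(10, 14, 0), axisB = "x")
  new("PhantomSpec", kind = "CYLINDER_PAIR", geometry = geom,
      spacingMm = as.numeric(spacingMm), gridDim = as.integer(gridDim),
      intensities = list(fluid = 1, background = 0.15),
      noiseSigma = noiseSigma, orientationJitterDeg = orientationJitterDeg,
      offsetJitterMm = as.numeric(offsetJitterMm), seed = as.integer(seed))
}

#' Calibrated sphere phantom specification
#'
#' A dark calibrated solid sphere surrounded by the bright solution inside a
#' spherical container; the fluid shell is calibrated to 247 ml. The
#' container radius is derived from the solid radius and the fluid volume.
#'
#' @param fluidVolumeMl calibrated fluid volume (default 247).
#' @param solidRadiusMm radius of the dark solid sphere (default 20).
#' @param spacingMm voxel size, default c(0.5, 0.5, 3).
#' @param gridDim acquisition grid, default c(192, 192, 32).
#' @param noiseSigma,orientationJitterDeg,offsetJitterMm,seed as for
#'   \code{\link{cylinderPhantomSpec}}.
#' @return A \linkS4class{PhantomSpec} of kind SPHERE_SHELL.
#' @export
spherePhantomSpec <- function(fluidVolumeMl = 247, solidRadiusMm = 20,
                              spacingMm = c(0.5, 0.5, 3),
                              gridDim = c(192L, 192L, 32L),
                              noiseSigma = 0.04, orientationJitterDeg = 5,
                              offsetJitterMm = spacingMm / 2, seed = 0L) {
  rc <- (solidRadiusMm^3 + 3 * fluidVolumeMl * 1000 / (4 * pi))^(1 / 3)
  geom <- list(solidRadius = solidRadiusMm, containerRadius = rc)
  new("PhantomSpec", kind = "SPHERE_SHELL", geometry = geom,
      spacingMm = as.numeric(spacingMm), gridDim = as.integer(gridDim),
      intensities = list(fluid = 1, solid = 0.12, background = 0.05),
      noiseSigma = noiseSigma, orientationJitterDeg = orientationJitterDeg,
      offsetJitterMm = as.numeric(offsetJitterMm), seed = as.integer(seed))
}

#' Analytic ground-truth fluid volume of a phantom spec
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return Closed-form fluid volume in ml, recomputed from the geometry.
#' @export
phantomTruthMl <- function(spec) {
  g <- spec@geometry
  if (spec@kind == "CYLINDER_PAIR") {
    2 * pi * g$radius^2 * (2 * g$halfLen) / 1000
  } else {
    4 / 3 * pi * (g$containerRadius^3 - g$solidRadius^3) / 1000
  }
}

#' Render a phantom acquisition
#'
#' Renders the T2-like scan of a calibrated phantom: each voxel's noiseless
#' intensity mixes the tissue intensities by the voxel's occupancy fractions
#' (5^3 sub-voxel sampling at label boundaries), a random rotation and
#' sub-voxel translation drawn from the spec's jitter ranges is applied to
#' the phantom pose, and zero-mean Gaussian noise is added (clamped at zero,
#' as MR magnitude data are non-negative). Rendering is a pure function of
#' the spec (including its seed).
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param nsub per-axis sub-voxel sampling (default 5).
#' @return List with \code{t2} (the \linkS4class{ImageVolume}),
#'   \code{truthVolumeMl} (analytic), \code{truthMask} (voxels with fluid
#'   occupancy >= 0.5) and \code{fluidFraction} (per-voxel occupancy array).
#' @export
renderPhantom <- function(spec, nsub = 5L) {
  g <- spec@geometry
  dims <- spec@gridDim
  affine <- centeredAffine(spec@spacingMm, dims)
  # geometry must fit the field of view (with jitter headroom)
  fov <- spec@spacingMm * dims / 2
  reach <- if (spec@kind == "CYLINDER_PAIR")
    max(abs(unlist(g[c("centerA", "centerB")]))) + g$halfLen + g$radius
  else g$containerRadius
  if (reach > sqrt(sum(fov^2)))
    stop("phantom geometry exceeds the field of view")
  withSeed(spec@seed, {
    rot <- .eulerRotation(runif(3, -spec@orientationJitterDeg,
                                spec@orientationJitterDeg))
    off <- runif(3, -spec@offsetJitterMm, spec@offsetJitterMm)
    ints <- spec@intensities
    if (spec@kind == "CYLINDER_PAIR") {
      cylInside <- function(p) {
        inA <- .cylInside(p, g$centerA, g$axisA, g$radius, g$halfLen)
        inB <- .cylInside(p, g$centerB, g$axisB, g$radius, g$halfLen)
        inA | inB
      }
      structures <- list(
        list(name = "fluid", inside = .jitterWrap(cylInside, rot, off),
             intensity = ints$background + ints$fluid),
        list(name = "background", inside = function(p) rep(TRUE, nrow(p)),
             intensity = ints$background))
    } else {
      rs <- g$solidRadius; rc <- g$containerRadius
      structures <- list(
        list(name = "solid",
             inside = .jitterWrap(function(p) rowSums(p^2) <= rs^2, rot, off),
             intensity = ints$solid),
        list(name = "fluid",
             inside = .jitterWrap(function(p) rowSums(p^2) <= rc^2, rot, off),
             intensity = ints$fluid),
        list(name = "background", inside = function(p) rep(TRUE, nrow(p)),
             intensity = ints$background))
    }
    sc <- sceneRender(structures, dims, spec@spacingMm, affine, nsub,
                      truthNames = "fluid")
    img <- sc$intensity + rnorm(length(sc$intensity), 0, spec@noiseSigma)
    img <- pmax(img, 0)
    vol <- ImageVolume(array(img, dims), spec@spacingMm, affine, sequence = "T2")
    frac <- sc$fractions$fluid
    list(t2 = vol, truthVolumeMl = phantomTruthMl(spec),
         truthMask = SegmentationMask(frac >= 0.5, vol, label = "FLUID_CANDIDATE"),
         fluidFraction = frac)
  })
}

.cylInside <- function(p, center, axis, radius, halfLen) {
  q <- sweep(p, 2, center)
  if (axis == "z") {
    q[, 1]^2 + q[, 2]^2 <= radius^2 & abs(q[, 3]) <= halfLen
  } else if (axis == "x") {
    q[, 2]^2 + q[, 3]^2 <= radius^2 & abs(q[, 1]) <= halfLen
  } else {
    q[, 1]^2 + q[, 3]^2 <= radius^2 & abs(q[, 2]) <= halfLen
  }
}

#' Phantom reproducibility study
#'
#' Renders \code{nScans} independent phantom acquisitions (seed =
#' \code{baseSeed + i - 1}), runs the stage-3/stage-4 pipeline on each (the
#' phantom pathway enters at stage 3: candidate segmentation over the full
#' grid, boundary repair, subvoxel mesh volumetry) and summarizes the
#' recovered volumes.
#'
#' @param spec a \linkS4class{PhantomSpec} (its own seed is ignored).
#' @param nScans number of simulated acquisitions (>= 2).
#' @param baseSeed first scan seed.
#' @param config a \linkS4class{PipelineConfig}.
#' @param seeds optional explicit per-scan seeds overriding
#'   \code{baseSeed + 0:(nScans-1)} (e.g. forcing identical replicates).
#' @return List with \code{volumesMl} (per-scan), \code{seeds}, \code{meanMl},
#'   \code{sdMl}, \code{covPercent} (SD/mean x 100) and \code{truthMl}.
#' @export
phantomStudy <- function(spec, nScans, baseSeed = 0L, config = effusionConfig(),
                         seeds = NULL) {
  if (nScans < 2L) stop("nScans must be >= 2")
  if (is.null(seeds)) seeds <- as.integer(baseSeed) + seq_len(nScans) - 1L
  stopifnot(length(seeds) == nScans)
  vols <- numeric(nScans)
  for (i in seq_len(nScans)) {
    s <- spec
    s@seed <- seeds[i]
    vols[i] <- measurePhantomScan(s, config)
  }
  list(volumesMl = vols, seeds = seeds, meanMl = mean(vols), sdMl = sd(vols),
       covPercent = 100 * sd(vols) / mean(vols), truthMl = phantomTruthMl(spec))
}

# stage 3 + 4 on a single rendered phantom
measurePhantomScan <- function(spec, config = effusionConfig()) {
  ph <- renderPhantom(spec, nsub = config@subsampling)
  mset <- fullDomainMaskedSet(ph$t2)
  cands <- segmentFluidCandidates(mset, config)
  eff <- finalizeEffusion(cands, mset, config)
  res <- meshAndVolume(eff, config)
  res@totalMl
}
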