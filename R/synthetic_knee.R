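# Synthetic knee-like paired T1/T2 acquisitions with ground-truth labels.

#' Synthetic knee acquisition specification
#'
#' Default geometry (world mm, RAS, origin at the grid center): a femoral
#' capsule entering from the superior edge and a tibial capsule leaving
#' through the inferior edge, each with bright marrow and a thin dark
#' cortical shell; hyaline-cartilage shells on the joint-facing surfaces; a
#' C-shaped synovial fluid pouch wrapping the distal femur (anterior portion
#' clipped so it stays behind the femur's anterior extent, where the
#' suprapatellar capsule lies) plus a small posterodistal tibial recess; an
#' anterior patella/fat complex; a posterior popliteal vessel decoy far from
#' the joint; an elliptical soft-tissue (muscle) leg cross-section in air.
#'
#' Grids are scaled-down analogues of the paired axial acquisitions (T2
#' 160 x 160 x 30 at 1 x 1 x 3 mm; T1 240 x 240 x 30 at 0.6 x 0.6 x 3 mm,
#' same world frame). Tissue intensities are relative units: on T1 marrow and
#' fat are bright and fluid dark; on T2 fluid is bright and every other
#' tissue below half its intensity.
#'
#' @param fluidScale radial scale of the pouch (1 = default ~moderate
#'   effusion).
#' @param vesselIntensityT2 T2 intensity of the vessel decoy (default 0.47;
#'   raise above the fluid threshold to exercise the anatomic filter).
#' @param biasAmplitude multiplicative bias-field amplitude (default 0.05).
#' @param noiseSigma additive noise SD relative to the brightest tissue
#'   (default 0.04).
#' @param seed RNG seed.
#' @return A \linkS4class{KneeSpec}.
#' @export
kneeSpec <- function(fluidScale = 1, vesselIntensityT2 = 0.47,
                     biasAmplitude = 0.05, noiseSigma = 0.04, seed = 0L) {
  geom <- list(
    femur = list(cx = 0, cy = 0, z0 = -1, z1 = 39, r = 21),
    tibia = list(cx = 0, cy = -3, z0 = -70, z1 = -43.5, r = 17),
    cortexMm = 0.8, cartilageMm = 1.5,
    cartFemZmax = -11, cartTibZmin = -35,
    pouch = list(rIn = 1.5, rOut = 1.5 + 7.5 * fluidScale,
                 femZ = c(-22, -0.5), yClip = 20,
                 tibROut = 1.5 + 5.5 * fluidScale, tibZ = c(-31, -26.5),
                 tibYMax = -3),
    patella = list(c = c(0, 33, -11), semi = c(10, 5, 11)),
    fat = list(c = c(0, 42, -3), semi = c(16, 8, 20)),
    vessel = list(x = 8, y = -48, r = 3.5),
    leg = list(cx = 0, cy = -2, a = 60, b = 52))
  t1i <- list(marrow = 1.0, cortex = 0.1, cartilage = 0.35, fluid = 0.15,
              patella = 0.85, fat = 0.85, vessel = 0.25, muscle = 0.3,
              air = 0.03)
  t2i <- list(marrow = 0.44, cortex = 0.1, cartilage = 0.42, fluid = 1.0,
              patella = 0.45, fat = 0.47, vessel = vesselIntensityT2,
              muscle = 0.2, air = 0.045)
  new("KneeSpec",
      t1Dim = c(240L, 240L, 30L), t1Spacing = c(0.6, 0.6, 3),
      t2Dim = c(160L, 160L, 30L), t2Spacing = c(1, 1, 3),
      geometry = geom, t1Intensities = t1i, t2Intensities = t2i,
      biasAmplitude = biasAmplitude, noiseSigma = noiseSigma,
      seed = as.integer(seed))
}

# structure list of the knee scene for one intensity table (priority order:
# first match wins, so shells are listed after the tissue they enclose)
.kneeStructures <- function(geom, ints) {
  fem <- geom$femur; tib <- geom$tibia
  ctx <- geom$cortexMm; car <- geom$cartilageMm
  pou <- geom$pouch; pat <- geom$patella; fat <- geom$fat
  ves <- geom$vessel; leg <- geom$leg
  dF <- function(p) .capsuleDist(p, fem$cx, fem$cy, fem$z0, fem$z1)
  dT <- function(p) .capsuleDist(p, tib$cx, tib$cy, tib$z0, tib$z1)
  ell <- function(p, c, s)
    ((p[, 1] - c[1]) / s[1])^2 + ((p[, 2] - c[2]) / s[2])^2 +
      ((p[, 3] - c[3]) / s[3])^2 <= 1
  list(
    list(name = "marrowFem", intensity = ints$marrow,
         inside = function(p) dF(p) <= fem$r - ctx),
    list(name = "cortexFem", intensity = ints$cortex,
         inside = function(p) dF(p) <= fem$r),
    list(name = "marrowTib", intensity = ints$marrow,
         inside = function(p) dT(p) <= tib$r - ctx),
    list(name = "cortexTib", intensity = ints$cortex,
         inside = function(p) dT(p) <= tib$r),
    list(name = "cartFem", intensity = ints$cartilage,
         inside = function(p) dF(p) <= fem$r + car & p[, 3] <= geom$cartFemZmax),
    list(name = "cartTib", intensity = ints$cartilage,
         inside = function(p) dT(p) <= tib$r + car & p[, 3] >= geom$cartTibZmin),
    list(name = "fluid", intensity = ints$fluid,
         inside = function(p) {
           f <- dF(p)
           t <- dT(p)
           (f > fem$r + pou$rIn & f <= fem$r + pou$rOut &
              p[, 3] >= pou$femZ[1] & p[, 3] <= pou$femZ[2] &
              p[, 2] <= pou$yClip) |
             (t > tib$r + pou$rIn & t <= tib$r + pou$tibROut &
                p[, 3] >= pou$tibZ[1] & p[, 3] <= pou$tibZ[2] &
                p[, 2] <= pou$tibYMax)
         }),
    list(name = "patella", intensity = ints$patella,
         inside = function(p) ell(p, pat$c, pat$semi)),
    list(name = "fat", intensity = ints$fat,
         inside = function(p) ell(p, fat$c, fat$semi)),
    list(name = "vessel", intensity = ints$vessel,
         inside = function(p) (p[, 1] - ves$x)^2 + (p[, 2] - ves$y)^2 <= ves$r^2),
    list(name = "muscle", intensity = ints$muscle,
         inside = function(p)
           ((p[, 1] - leg$cx) / leg$a)^2 + ((p[, 2] - leg$cy) / leg$b)^2 <= 1),
    list(name = "air", intensity = ints$air,
         inside = function(p) rep(TRUE, nrow(p))))
}

.kneeTruthNames <- c("marrowFem", "cortexFem", "marrowTib", "cortexTib",
                     "cartFem", "cartTib", "fluid", "patella", "fat", "vessel")

# smooth multiplicative bias field over world points
.biasField <- function(p, amplitude, phases) {
  1 + amplitude *
    cos(pi * (p[, 1] - phases[1]) / 160) *
    cos(pi * (p[, 2] - phases[2]) / 160) *
    cos(pi * (p[, 3] - phases[3]) / 90)
}

#' Render a paired synthetic knee acquisition
#'
#' Renders the T1 and T2 volumes of a \code{\link{kneeSpec}} scene on their
#' respective grids (shared world frame, different voxel sizes), applies the
#' same smooth multiplicative intensity-inhomogeneity field to both, adds
#' independent Gaussian noise per sequence, and returns ground-truth label
#' masks (voxel occupancy >= 0.5) on both grids. Rendering is a pure function
#' of the spec.
#'
#' @param spec a \linkS4class{KneeSpec}.
#' @param nsub per-axis sub-voxel sampling at label boundaries (default 3).
#' @return List with \code{t1}, \code{t2} (\linkS4class{ImageVolume}s),
#'   \code{labels} (per-grid lists of \linkS4class{SegmentationMask}s:
#'   femur, tibia, cartilage, fluid, patella, fat, vessel, marrowFem),
#'   and \code{truth} (list with \code{fluidVolumeMl} from fine-grid
#'   quadrature of the analytic pouch geometry).
#' @export
renderKnee <- function(spec, nsub = 3L) {
  geom <- spec@geometry
  withSeed(spec@seed, {
    phases <- runif(3, -20, 20)
    out <- list()
    for (seqName in c("t1", "t2")) {
      ints <- if (seqName == "t1") spec@t1Intensities else spec@t2Intensities
      dims <- if (seqName == "t1") spec@t1Dim else spec@t2Dim
      sp <- if (seqName == "t1") spec@t1Spacing else spec@t2Spacing
      affine <- centeredAffine(sp, dims)
      sc <- sceneRender(.kneeStructures(geom, ints), dims, sp, affine, nsub,
                        truthNames = .kneeTruthNames)
      idx <- arrayInd(seq_len(prod(dims)), dims) - 1L
      bias <- array(.biasField(voxelToWorld(affine, idx), spec@biasAmplitude,
                               phases), dims)
      img <- sc$intensity * bias +
        rnorm(length(sc$intensity), 0, spec@noiseSigma)
      vol <- ImageVolume(pmax(img, 0), sp, affine,
                         sequence = toupper(seqName))
      fr <- sc$fractions
      # the bone object is delimited at the marrow-to-subchondral interface
      # (what the thresholds select and the contrast correction sharpens), so
      # the bone truth labels are the marrow compartments
      lb <- list(
        femur = SegmentationMask(fr$marrowFem >= 0.5, vol, "FEMUR"),
        tibia = SegmentationMask(fr$marrowTib >= 0.5, vol, "TIBIA"),
        cartilage = SegmentationMask(fr$cartFem + fr$cartTib >= 0.5, vol, "OTHER"),
        fluid = SegmentationMask(fr$fluid >= 0.5, vol, "EFFUSION"),
        patella = SegmentationMask(fr$patella >= 0.5, vol, "PATELLA_FAT"),
        fat = SegmentationMask(fr$fat >= 0.5, vol, "PATELLA_FAT"),
        marrowFem = SegmentationMask(fr$marrowFem >= 0.5, vol, "OTHER"),
        vessel = SegmentationMask(fr$vessel >= 0.5, vol, "OTHER"))
      out[[seqName]] <- list(vol = vol, labels = lb)
    }
    list(t1 = out$t1$vol, t2 = out$t2$vol,
         labels = list(t1 = out$t1$labels, t2 = out$t2$labels),
         truth = list(fluidVolumeMl = kneeFluidTruthMl(spec)))
  })
}

#' Ground-truth fluid volume of a knee spec
#'
#' Fine fixed-resolution quadrature (1 mm grid, 4^3 sub-voxel samples) of the
#' analytic pouch geometry, independent of the acquisition grids.
#'
#' @param spec a \linkS4class{KneeSpec}.
#' @return Fluid volume in ml.
#' @export
kneeFluidTruthMl <- function(spec) {
  geom <- spec@geometry
  pou <- geom$pouch
  fem <- geom$femur; tib <- geom$tibia
  lo <- c(-(fem$r + pou$rOut) - 2, -(tib$r + pou$tibROut) - 2, pou$tibZ[1] - 2)
  hi <- c(fem$r + pou$rOut + 2, pou$yClip + 2, pou$femZ[2] + 2)
  step <- 1
  nsub <- 4L
  offs <- (seq_len(nsub) - 0.5) / nsub - 0.5
  gx <- seq(lo[1] + step / 2, hi[1], by = step)
  gy <- seq(lo[2] + step / 2, hi[2], by = step)
  gz <- seq(lo[3] + step / 2, hi[3], by = step)
  structs <- .kneeStructures(geom, spec@t2Intensities)
  nm <- vapply(structs, function(s) s$name, character(1))
  fluidInside <- structs[[which(nm == "fluid")]]$inside
  total <- 0
  base <- as.matrix(expand.grid(x = gx, y = gy))
  for (z in gz) {
    acc <- numeric(nrow(base))
    for (oz in offs) for (oy in offs) for (ox in offs) {
      p <- cbind(base[, 1] + ox * step, base[, 2] + oy * step, z + oz * step)
      acc <- acc + fluidInside(p)
    }
    total <- total + sum(acc) / nsub^3 * step^3
  }
  total / 1000
}
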