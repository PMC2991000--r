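test_that("fluid candidates cover the generated fluid; dark domains are empty", {
  k <- getKnee()
  run <- getKneeRun()
  mset <- buildMaskedSet(k$t2, run$bones)
  cands <- segmentFluidCandidates(mset)
  expect_gt(length(cands), 0L)
  union <- Reduce(`|`, lapply(cands, function(cd) imgData(cd@mask)))
  fluid <- imgData(k$labels$t2$fluid)
  expect_gte(sum(union & fluid) / sum(fluid), 0.95)
  # sorted by size, decreasing
  sizes <- vapply(cands, function(cd) cd@voxelCount, integer(1))
  expect_true(all(diff(sizes) <= 0))

  # all-dark (constant) domain: no candidate objects
  d <- c(24L, 24L, 8L)
  dark <- ImageVolume(array(0.1, d), c(1, 1, 3), sequence = "T2")
  expect_identical(length(segmentFluidCandidates(fullDomainMaskedSet(dark))), 0L)

  empty <- fullDomainMaskedSet(dark)
  empty@analysisDomain@data[] <- FALSE
  expect_error(segmentFluidCandidates(empty), "empty analysis domain")
})

test_that("the phantom pathway returns exactly the phantom's bright objects", {
  ph <- getCylScan()
  cands <- segmentFluidCandidates(fullDomainMaskedSet(ph$t2))
  expect_identical(length(cands), 2L)          # two disjoint cylinders
  sp <- smallSphereSpec(seed = 2L)
  cands2 <- segmentFluidCandidates(fullDomainMaskedSet(renderPhantom(sp)$t2))
  expect_identical(length(cands2), 1L)         # one fluid shell
})

test_that("anatomic filtering keeps fluid and rejects by position and shape", {
  d <- c(40L, 96L, 12L)
  geom <- ImageVolume(array(0, d), c(1, 1, 3))
  idx <- arrayInd(seq_len(prod(d)), d)
  w <- kneefusion:::voxelToWorld(affineMatrix(geom), idx - 1)
  femur <- array(abs(w[, 1]) <= 8 & abs(w[, 2]) <= 8 & w[, 3] >= 3, d)
  tibia <- array(abs(w[, 1]) <= 7 & abs(w[, 2]) <= 7 & w[, 3] <= -9, d)
  bones <- new("BoneObjects", femur = SegmentationMask(femur, geom, "FEMUR"),
               tibia = SegmentationMask(tibia, geom, "TIBIA"), frame = "T2")
  mk <- function(sel) {
    m <- SegmentationMask(array(sel, d), geom, "FLUID_CANDIDATE")
    new("CandidateObject", mask = m, centroidMm = kneefusion:::maskCentroidMm(m),
        bboxMm = kneefusion:::maskBboxMm(m), voxelCount = sum(sel))
  }
  # near-bone blob in the femoral band, anterior
  good <- mk(w[, 1] >= 10 & w[, 1] <= 13 & abs(w[, 2] - 6) <= 4 &
               w[, 3] >= 3 & w[, 3] <= 9)
  # same shape but 30 mm posterior, far outside the margin
  far <- mk(abs(w[, 1]) <= 3 & w[, 2] <= -35 & w[, 3] >= 3 & w[, 3] <= 9)
  # one-voxel-thick sheet hugging the femur face (cartilage-like shell)
  shell <- mk(w[, 1] == 9.5 & abs(w[, 2]) <= 7 & w[, 3] >= 3 & w[, 3] <= 9)
  res <- anatomicFilter(list(good, far, shell), bones)
  audit <- attr(res, "audit")
  expect_identical(length(res), 1L)
  expect_identical(audit$rule, c("retained", "far from bone surface",
                                 "cartilage shell"))
  # filtering includes/excludes whole objects without altering masks
  expect_identical(imgData(res[[1]]@mask), imgData(good@mask))
  emptyRes <- anatomicFilter(list(), bones)
  expect_identical(length(emptyRes), 0L)
})

test_that("a bright vessel decoy is segmented but discarded by position", {
  k <- getBrightVesselKnee()
  run <- getBrightVesselRun()
  audit <- run$candidates
  vesselRows <- audit[audit$boneDistMm > 15, ]
  expect_gt(nrow(vesselRows), 0L)             # the decoy became a candidate
  expect_false(any(vesselRows$retained))
  expect_identical(sum(imgData(run$effusion) & imgData(k$labels$t2$vessel)), 0L)
  # fluid is still recovered
  expect_lt(abs(run$volume@totalMl / k$truth$fluidVolumeMl - 1), 0.10)
})

test_that("finalization unions, repairs and respects the non-interest mask", {
  k <- getKnee()
  run <- getKneeRun()
  mset <- buildMaskedSet(k$t2, run$bones)
  cands <- segmentFluidCandidates(mset)
  keep <- anatomicFilter(cands, run$bones)
  eff <- finalizeEffusion(keep, mset)
  expect_identical(maskLabel(eff), "EFFUSION")
  expect_false(any(imgData(eff) & imgData(mset@noninterest)))

  # single complete object: repair is a no-op and output equals its mask
  one <- keep[1]
  effOne <- finalizeEffusion(one, mset)
  expect_identical(imgData(effOne), imgData(one[[1]]@mask))

  # corrupted slice inside the object is repaired
  m <- imgData(one[[1]]@mask)
  zs <- which(apply(m, 3, sum) > 0)
  mid <- zs[ceiling(length(zs) / 2)]
  corrupted <- m; corrupted[, , mid] <- FALSE
  cd <- one[[1]]
  cd@mask <- SegmentationMask(corrupted, mset@t2, "FLUID_CANDIDATE")
  effRep <- finalizeEffusion(list(cd), mset)
  expect_gte(dice(imgData(effRep)[, , mid], m[, , mid]), 0.8)
})

test_that("unselected fluid voxels lie on the partial-volume boundary", {
  k <- getKnee()
  run <- getKneeRun()
  fluid <- imgData(k$labels$t2$fluid)
  missed <- fluid & !imgData(run$effusion)
  interior <- erode26(fluid)
  expect_identical(sum(missed & interior), 0L)
})

test_that("the stage-3 pipeline is deterministic", {
  k <- getKnee()
  run <- getKneeRun()
  again <- runSegment(k$t1, k$t2)
  expect_identical(imgData(again$effusion), imgData(run$effusion))
  expect_identical(again$volume@totalMl, run$volume@totalMl)
})
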