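test_that("seed region converts mm extents to voxel boxes at the grid center", {
  # paper-resolution T1 grid
  v1 <- ImageVolume(array(0, c(640L, 512L, 35L)), c(0.28125, 0.28125, 3))
  s1 <- seedRegion(v1)
  expect_identical(s1@hi - s1@lo + 1L, c(64L, 128L, 6L))
  v2 <- ImageVolume(array(0, c(64L, 64L, 20L)), c(1, 1, 3))
  s2 <- seedRegion(v2)
  expect_identical(s2@hi - s2@lo + 1L, c(18L, 36L, 6L))
  # box centered on the grid center index (within rounding)
  expect_true(all(abs((s2@lo + s2@hi) / 2 - (dim(v2) + 1) / 2) <= 0.5))
  expect_error(seedRegion(ImageVolume(array(0, c(10L, 10L, 4L)), c(1, 1, 3))),
               "field of view")
})

test_that("bone thresholding is a monotone intensity interval selection", {
  set.seed(5)
  d <- c(12L, 12L, 6L)
  vol <- ImageVolume(array(runif(prod(d), 0, 100), d), c(1, 1, 3))
  all <- thresholdBone(vol, new("ThresholdPair", tLower = -1, tUpper = 101))
  expect_true(all(imgData(all)))          # full-range pair saturates
  narrow <- thresholdBone(vol, new("ThresholdPair", tLower = 40, tUpper = 60))
  wide <- thresholdBone(vol, new("ThresholdPair", tLower = 40, tUpper = 80))
  expect_true(all(imgData(wide)[imgData(narrow)]))  # widening never removes
})

test_that("contrast correction recovers a blurred analytic boundary", {
  n <- 64L
  xy <- expand.grid(x = seq_len(n), y = seq_len(n))
  r <- matrix(sqrt((xy$x - 32.5)^2 + (xy$y - 32.5)^2), n, n)
  img <- matrix(pmin(1, pmax(0, (20 - r) / 4 + 0.5)), n, n)  # rim blurred 4 px
  eroded <- r <= 18                              # initial mask 2 px short
  fixed <- contrastCorrectSlice(eroded, img, depth = 3L)
  per <- fixed & !(erode26(array(fixed, c(n, n, 1)))[, , 1])
  radii <- r[per]
  expect_lt(sqrt(mean((radii - 20)^2)), 1)       # within 1 px RMS of truth
  # correction never moves the boundary beyond the configured depth
  expect_true(all(abs(r[fixed != eroded] - 18) <= 3 + 1.5))
})

test_that("contrast correction fixes points on exact step edges, passes empties", {
  n <- 48L
  img <- matrix(0, n, n); img[, 1:20] <- 1
  mask <- matrix(FALSE, n, n); mask[, 1:20] <- TRUE
  expect_identical(contrastCorrectSlice(mask, img), mask)
  empty <- matrix(FALSE, n, n)
  expect_identical(contrastCorrectSlice(empty, img), empty)
})

test_that("inter-slice repair restores a held-out slice and is otherwise a no-op", {
  d <- c(32L, 32L, 9L)
  geom <- ImageVolume(array(0, d), c(1, 1, 3))
  xy <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]))
  disc <- matrix(sqrt((xy$x - 16.5)^2 + (xy$y - 16.5)^2) <= 10, d[1], d[2])
  cyl <- array(rep(disc, d[3]), d)
  intact <- SegmentationMask(cyl, geom)
  expect_identical(imgData(repairSlices(intact)), imgData(intact))

  holed <- cyl; holed[, , 5] <- FALSE
  repaired <- repairSlices(SegmentationMask(holed, geom))
  expect_gte(dice(imgData(repaired)[, , 5], cyl[, , 5]), 0.95)

  partial <- cyl
  partial[, , 5] <- disc & matrix(xy$x <= 12, d[1], d[2])   # heavy area drop
  rep2 <- repairSlices(SegmentationMask(partial, geom))
  expect_gte(dice(imgData(rep2)[, , 5], cyl[, , 5]), 0.95)

  empty <- SegmentationMask(array(FALSE, d), geom)
  expect_identical(imgData(repairSlices(empty)), imgData(empty))

  # natural taper at object ends (empty neighbour) is left alone
  taper <- cyl; taper[, , 9] <- FALSE
  taper[, , 8] <- disc & matrix(sqrt((xy$x - 16.5)^2 + (xy$y - 16.5)^2) <= 4,
                                d[1], d[2])
  expect_identical(imgData(repairSlices(SegmentationMask(taper, geom))), taper)
})

test_that("stage 1 recovers solid disjoint bones in the T2 frame", {
  k <- getKnee()
  run <- getKneeRun()
  bones <- run$bones
  expect_identical(bones@frame, "T2")
  expect_identical(dim(bones@femur), dim(k$t2))
  expect_gte(dice(bones@femur, k$labels$t2$femur), 0.90)
  expect_gte(dice(bones@tibia, k$labels$t2$tibia), 0.90)
  expect_false(any(imgData(bones@femur) & imgData(bones@tibia)))
  for (m in list(bones@femur, bones@tibia)) {
    lab <- kneefusion:::ccLabel(imgData(m), 26L)
    expect_identical(attr(lab, "n"), 1L)                       # one component
    expect_identical(kneefusion:::fillHoles3d(imgData(m)), imgData(m))  # solid
  }
  # the tibia lies distal (inferior) to the femur
  fz <- kneefusion:::maskCentroidMm(bones@femur)[3]
  tz <- kneefusion:::maskCentroidMm(bones@tibia)[3]
  expect_lt(tz, fz)
})

test_that("the femur component contains the seed box; thresholds select marrow", {
  k <- getKnee()
  seed <- seedRegion(k$t1)
  h <- buildHistogram(k$t1, seed, 256L)
  pair <- dualThresholds(h)
  raw <- thresholdBone(k$t1, pair)
  marrow <- imgData(k$labels$t1$marrowFem)
  expect_gte(sum(imgData(raw) & marrow) / sum(marrow), 0.90)

  bonesT1 <- kneefusion:::transportMask(getKneeRun()$bones@femur, k$t2, k$t1)
  box <- array(FALSE, dim(k$t1))
  box[seed@lo[1]:seed@hi[1], seed@lo[2]:seed@hi[2], seed@lo[3]:seed@hi[3]] <- TRUE
  expect_gte(sum(imgData(bonesT1) & box) / sum(box), 0.99)
})

test_that("stage 1 is deterministic", {
  k <- getKnee()
  b1 <- segmentBones(k$t1, k$t2)
  b2 <- segmentBones(k$t1, k$t2)
  expect_identical(imgData(b1@femur), imgData(b2@femur))
  expect_identical(imgData(b1@tibia), imgData(b2@tibia))
})
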