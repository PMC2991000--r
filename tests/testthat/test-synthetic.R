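test_that("phantom truths are closed forms recomputed from geometry", {
  cyl <- cylinderPhantomSpec()
  expect_equal(phantomTruthMl(cyl), 14.1, tolerance = 1e-12)
  g <- cyl@geometry
  expect_equal(2 * pi * g$radius^2 * 2 * g$halfLen / 1000, 14.1,
               tolerance = 1e-12)
  sph <- spherePhantomSpec()
  expect_equal(phantomTruthMl(sph), 247, tolerance = 1e-12)
  # truth scales with the requested calibration, not a stored constant
  expect_equal(phantomTruthMl(cylinderPhantomSpec(totalVolumeMl = 20)), 20,
               tolerance = 1e-12)
})

test_that("partial-volume bookkeeping reproduces the analytic volume", {
  spec <- cylinderPhantomSpec(noiseSigma = 0, orientationJitterDeg = 0,
                              offsetJitterMm = c(0, 0, 0), seed = 0L)
  # axis-aligned flat end caps are the worst case for sub-voxel quadrature;
  # a denser sampling base shows the bookkeeping converges on the truth
  ph <- renderPhantom(spec, nsub = 8L)
  pvVol <- sum(ph$fluidFraction) * prod(spec@spacingMm) / 1000
  expect_lt(abs(pvVol / ph$truthVolumeMl - 1), 0.001)
  # noiseless rendering takes exactly the tabulated intensities off-boundary
  img <- imgData(ph$t2)
  expect_equal(max(img), spec@intensities$background + spec@intensities$fluid,
               tolerance = 1e-12)
  expect_equal(min(img), spec@intensities$background, tolerance = 1e-12)
})

test_that("rendering is a pure function of the spec", {
  a <- renderPhantom(cylinderPhantomSpec(seed = 5L))
  b <- renderPhantom(cylinderPhantomSpec(seed = 5L))
  expect_identical(imgData(a$t2), imgData(b$t2))
  c <- renderPhantom(cylinderPhantomSpec(seed = 6L))
  expect_false(identical(imgData(a$t2), imgData(c$t2)))
})

test_that("phantom geometry must fit the field of view", {
  expect_error(renderPhantom(spherePhantomSpec(gridDim = c(64L, 64L, 10L))),
               "field of view")
})

test_that("the knee scene has fluid-dominant T2 contrast and disjoint labels", {
  k <- getKnee()
  t2 <- imgData(k$t2)
  fluid <- imgData(k$labels$t2$fluid)
  interiorOf <- function(m) erode26(m)
  fluidMean <- mean(t2[interiorOf(fluid)])
  others <- c("femur", "tibia", "cartilage", "patella", "fat", "vessel")
  for (nm in others) {
    m <- interiorOf(imgData(k$labels$t2[[nm]]))
    if (!any(m)) m <- imgData(k$labels$t2[[nm]])
    expect_gt(fluidMean, 2 * mean(t2[m]))
  }
  # muscle and air, via complement of all labels within/outside the leg
  labs <- Reduce(`|`, lapply(k$labels$t2, imgData))
  expect_gt(fluidMean, 2 * mean(t2[!labs]))
  # labels are mutually disjoint (patella/fat overlap is by design: they are
  # one masked complex; all other pairs must not intersect)
  nms <- setdiff(names(k$labels$t2), c("marrowFem"))
  for (i in seq_along(nms)) for (j in seq_along(nms)) {
    if (i >= j) next
    if (all(c(nms[i], nms[j]) %in% c("patella", "fat"))) next
    expect_identical(sum(imgData(k$labels$t2[[nms[i]]]) &
                           imgData(k$labels$t2[[nms[j]]])), 0L,
                     info = paste(nms[i], nms[j]))
  }
})

test_that("noiseless, bias-free knee rendering matches the intensity table", {
  spec <- kneeSpec(biasAmplitude = 0, noiseSigma = 0, seed = 1L)
  k <- renderKnee(spec)
  t2 <- imgData(k$t2)
  fluid <- erode26(imgData(k$labels$t2$fluid))
  expect_equal(unique(round(t2[fluid], 10)), spec@t2Intensities$fluid)
  vessel <- erode26(imgData(k$labels$t2$vessel))
  expect_equal(unique(round(t2[vessel], 10)), spec@t2Intensities$vessel)
})

test_that("knee rendering is deterministic per seed", {
  a <- renderKnee(kneeSpec(seed = 21L))
  b <- renderKnee(kneeSpec(seed = 21L))
  expect_identical(imgData(a$t2), imgData(b$t2))
  expect_identical(imgData(a$t1), imgData(b$t1))
})

test_that("phantom studies summarize per-scan volumes correctly", {
  spec <- smallSphereSpec()
  st <- phantomStudy(spec, 3L, baseSeed = 4L)
  expect_identical(st$seeds, 4:6)
  expect_equal(st$meanMl, mean(st$volumesMl), tolerance = 1e-12)
  expect_equal(st$covPercent, 100 * sd(st$volumesMl) / mean(st$volumesMl),
               tolerance = 1e-12)
  # degenerate replication: identical seeds give identical volumes, CoV 0
  st2 <- phantomStudy(spec, 2L, seeds = c(4L, 4L))
  expect_identical(st2$volumesMl[1], st2$volumesMl[2])
  expect_identical(st2$covPercent, 0)
  expect_error(phantomStudy(spec, 1L), ">= 2")
})

test_that("knee fluid truth quadrature is stable and plausible", {
  spec <- kneeSpec()
  truth <- kneeFluidTruthMl(spec)
  expect_gt(truth, 5); expect_lt(truth, 60)
  # voxel-grid occupancy agrees with the independent fine-grid quadrature
  k <- getKnee()
  gridVol <- sum(imgData(k$labels$t2$fluid)) * prod(voxelSpacing(k$t2)) / 1000
  expect_lt(abs(gridVol / truth - 1), 0.05)
})
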