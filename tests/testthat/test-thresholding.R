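test_that("histograms conserve counts and span the region's range", {
  set.seed(42)
  d <- c(10L, 10L, 10L)
  vol <- ImageVolume(array(runif(prod(d), 50, 150), d), c(1, 1, 1))
  h <- buildHistogram(vol, NULL, 64L)
  expect_identical(sum(h@counts), 1000L)
  expect_equal(range(h@binEdges), range(imgData(vol)))
  expect_length(h@binEdges, length(h@counts) + 1L)

  # constant-intensity region: everything in one bin
  cvol <- ImageVolume(array(7, d), c(1, 1, 1))
  hc <- buildHistogram(cvol)
  expect_identical(sum(hc@counts > 0L), 1L)
  expect_identical(max(hc@counts), 1000L)

  # two-level region, 8 bins: counts concentrate in the first and last bin
  tw <- array(100, d); tw[1:6, , ] <- 100; tw[7:10, , ] <- 200
  tvol <- ImageVolume(tw, c(1, 1, 1))
  ht <- buildHistogram(tvol, NULL, 8L)
  expect_identical(ht@counts[1L], 600L)
  expect_identical(ht@counts[8L], 400L)
  expect_identical(sum(ht@counts), 1000L)

  expect_error(buildHistogram(vol, array(FALSE, d)), "empty")
  expect_error(buildHistogram(vol, NULL, 4L), ">= 8")
})

test_that("triangle threshold equals the exhaustive maximum-distance oracle", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(16:128, 1)
    counts <- as.integer(round(runif(n, 0, 50)))
    peak <- sample(seq_len(n), 1)
    counts[peak] <- counts[peak] + sample(100:500, 1)
    h <- new("IntensityHistogram", binEdges = as.numeric(0:n), counts = counts,
             sourceRegion = "random")
    centers <- (0:(n - 1)) + 0.5
    mode <- max(which(counts == max(counts)))
    occ <- which(counts > 0)
    if (max(occ) > mode) {
      expect_identical(optimalPointThreshold(h, "above"),
                       triangleOracle(as.numeric(counts), centers, "above"))
    }
    if (min(occ) < mode) {
      expect_identical(optimalPointThreshold(h, "below"),
                       triangleOracle(as.numeric(counts), centers, "below"))
    }
  }
})

test_that("a mirrored histogram mirrors the threshold side", {
  # tie-free bimodal curve
  counts <- as.integer(c(2, 5, 30, 200, 40, 12, 6, 3, 2, 1, 8, 60, 25, 4, 1))
  n <- length(counts)
  h <- new("IntensityHistogram", binEdges = as.numeric(0:n), counts = counts,
           sourceRegion = "bimodal")
  hm <- new("IntensityHistogram", binEdges = as.numeric(0:n), counts = rev(counts),
            sourceRegion = "mirrored")
  above <- optimalPointThreshold(h, "above")
  below <- optimalPointThreshold(hm, "below")
  expect_equal(below, n - above)
  expect_error(optimalPointThreshold(
    new("IntensityHistogram", binEdges = c(0, 1, 2), counts = c(5L, 0L),
        sourceRegion = "single"), "above"), "non-empty bins")
})

test_that("thresholds are invariant to uniform intensity scaling", {
  set.seed(7)
  vals <- c(rnorm(4000, 100, 6), rnorm(800, 180, 8))
  for (k in c(0.25, 3, 40)) {
    h1 <- kneefusion:::histogramFromValues(vals, 128L)
    h2 <- kneefusion:::histogramFromValues(k * vals, 128L)
    expect_equal(optimalPointThreshold(h2, "above"),
                 k * optimalPointThreshold(h1, "above"), tolerance = 1e-12)
    expect_equal(as.numeric(recursiveThreshold(h2)),
                 k * as.numeric(recursiveThreshold(h1)), tolerance = 1e-12)
  }
})

test_that("raising a threshold never increases the selected voxel count", {
  set.seed(12)
  x <- runif(5000)
  counts <- vapply(seq(0.1, 0.9, by = 0.1), function(t) sum(x >= t), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("dual thresholds bracket the dominant mid-intensity mode", {
  set.seed(31)
  # trimodal: dark background, dominant bone mode, bright fat mode
  vals <- c(rnorm(2000, 30, 5), rnorm(6000, 100, 7), rnorm(1500, 190, 8))
  h <- kneefusion:::histogramFromValues(vals, 256L)
  pair <- dualThresholds(h)
  expect_lt(pair@tLower, pair@tUpper)
  expect_gt(pair@tLower, 30); expect_lt(pair@tLower, 100)
  expect_gt(pair@tUpper, 100); expect_lt(pair@tUpper, 190)
  centers <- kneefusion:::binCenters(h)
  counts <- as.numeric(h@counts)
  expect_identical(pair@tLower, triangleOracle(counts, centers, "below"))
  expect_identical(pair@tUpper, triangleOracle(counts, centers, "above"))

  # symmetric unimodal: pair symmetric about the mode within one bin
  sym <- c(rnorm(20000, 100, 10))
  hs <- kneefusion:::histogramFromValues(c(sym, 200 - sym), 128L)
  ps <- dualThresholds(hs)
  binw <- diff(hs@binEdges[1:2])
  expect_lt(abs((ps@tLower + ps@tUpper) / 2 - 100), binw + 1e-9)
})

test_that("seed-region dual thresholds bracket the marrow intensities", {
  k <- getKnee()
  seed <- seedRegion(k$t1)
  h <- buildHistogram(k$t1, seed, 256L)
  pair <- dualThresholds(h)
  marrow <- imgData(getKnee()$labels$t1$marrowFem)
  box <- array(FALSE, dim(marrow))
  box[seed@lo[1]:seed@hi[1], seed@lo[2]:seed@hi[2], seed@lo[3]:seed@hi[3]] <- TRUE
  vals <- imgData(k$t1)[box & marrow]
  expect_gte(mean(vals >= pair@tLower & vals <= pair@tUpper), 0.95)
})

test_that("recursive threshold separates a bright fluid mode from background", {
  set.seed(9)
  vals <- c(rnorm(50000, 100, 5), rnorm(5000, 200, 5))
  h <- kneefusion:::histogramFromValues(vals, 256L)
  thr <- recursiveThreshold(h)
  expect_false(attr(thr, "fallback"))
  expect_lt(as.numeric(thr), 195)                       # below the fluid mode
  fluid <- vals[vals > 170]
  expect_gte(mean(fluid >= as.numeric(thr)), 0.99)      # retains the mode mass

  # pass-2 collapse: everything above t1 falls into a single occupied bin
  vals2 <- c(runif(3000, 90, 110), rep(250, 30))
  h2 <- kneefusion:::histogramFromValues(vals2, 256L)
  thr2 <- recursiveThreshold(h2)
  expect_true(attr(thr2, "fallback"))
  expect_identical(as.numeric(thr2), attr(thr2, "t1"))
})

test_that("the two-pass threshold is never below the one-pass value", {
  set.seed(77)
  for (i in 1:100) {
    vals <- c(rnorm(5000, 100, runif(1, 3, 10)),
              runif(sample(200:2000, 1), 110, 250))   # unimodal + bright tail
    h <- kneefusion:::histogramFromValues(vals, 128L)
    thr <- recursiveThreshold(h)
    expect_gte(as.numeric(thr), attr(thr, "t1"))
  }
})
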