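test_that("peripheral voxels are the foreground with background face-neighbours", {
  cube <- cuboidMask(5L, 5L, 5L)
  expect_identical(nrow(peripheralVoxels(cube)), 125L - 27L)   # 5^3 - 3^3
  single <- cuboidMask(1L, 1L, 1L)
  expect_identical(nrow(peripheralVoxels(single)), 1L)
  sheet <- cuboidMask(6L, 6L, 1L)
  expect_identical(nrow(peripheralVoxels(sheet)), 36L)         # no interior
  emptyM <- SegmentationMask(array(FALSE, c(4L, 4L, 4L)),
                             ImageVolume(array(0, c(4L, 4L, 4L)), c(1, 1, 1)))
  expect_identical(nrow(peripheralVoxels(emptyM)), 0L)
})

test_that("meshes are closed, outward, and the cuboid volumes are analytic", {
  cub <- cuboidMask(10L, 12L, 14L)
  mi <- buildMesh(cub, "interpolated")[[1]]
  mc <- buildMesh(cub, "centers")[[1]]
  for (m in list(mi, mc)) {
    ig <- meshIntegrity(m)
    expect_true(ig$closed)
    expect_true(ig$outward)
    expect_identical(ig$eulerCharacteristic, 2L)
    expect_gt(ig$minFaceArea, 0)
  }
  # center-linking surface: the box through the outer voxel centers
  expect_equal(meshSignedVolume(mc), 9 * 11 * 13, tolerance = 1e-6)
  # midway surface never exceeds the voxel hull
  expect_lte(meshSignedVolume(mi), 10 * 12 * 14 + 1e-9)
})

test_that("a digitized ball meshes into one sphere-topology surface per ball", {
  ball <- ballMask(20)
  meshes <- buildMesh(ball)
  expect_identical(length(meshes), 1L)
  ig <- meshIntegrity(meshes[[1]])
  expect_true(ig$closed)
  expect_identical(ig$eulerCharacteristic, 2L)

  two <- imgData(ballMask(6, margin = 10L))
  d <- dim(two)
  shifted <- array(FALSE, d)
  shifted[1:(d[1] - 20), , ] <- two[21:d[1], , ]
  pair <- SegmentationMask(two | shifted, ImageVolume(array(0, d), c(1, 1, 1)))
  expect_identical(length(buildMesh(pair)), 2L)
})

test_that("subvoxel volume matches the analytic ball and its own invariants", {
  ball <- ballMask(20, spacing = c(0.5, 0.5, 0.5))
  meshes <- buildMesh(ball)
  res <- subvoxelVolume(ball, meshes)
  analytic <- 4 / 3 * pi * 10^3 / 1000             # r = 20 voxels = 10 mm
  expect_lt(abs(res@totalMl / analytic - 1), 0.015)
  expect_identical(res@method, "SUBVOXEL_MESH")
  # the two estimators measure the same model volume
  expect_lt(abs(meshSignedVolume(meshes[[1]]) / 1000 - res@totalMl) /
              res@totalMl, 0.005)
  # bookkeeping: total = interior + partial; total <= voxel-count volume
  expect_equal(res@totalMl, res@interiorVoxelMl + res@partialVoxelMl,
               tolerance = 1e-9)
  voxCount <- sum(imgData(ball)) * prod(voxelSpacing(ball)) / 1000
  expect_lte(res@totalMl, voxCount + 1e-9)

  emptyM <- SegmentationMask(array(FALSE, c(4L, 4L, 4L)),
                             ImageVolume(array(0, c(4L, 4L, 4L)), c(1, 1, 1)))
  expect_identical(subvoxelVolume(emptyM)@totalMl, 0)
})

test_that("thin components fall back to voxel-count volume", {
  d <- c(12L, 12L, 8L)
  geom <- ImageVolume(array(0, d), c(1, 1, 1))
  m <- array(FALSE, d)
  m[3:8, 3:8, 3:6] <- TRUE     # meshable block
  m[11, 11, 2] <- TRUE         # isolated voxel
  msk <- SegmentationMask(m, geom)
  res <- subvoxelVolume(msk)
  expect_setequal(res@methodPerComponent,
                  c("SUBVOXEL_MESH", "VOXEL_COUNT_FALLBACK"))
  expect_identical(res@method, "SUBVOXEL_MESH")
  fallback <- which(res@methodPerComponent == "VOXEL_COUNT_FALLBACK")
  expect_equal(res@perComponentMl[fallback], 1 / 1000)
})

test_that("volume is invariant under translation and axis permutation", {
  base <- ballMask(7)
  d <- dim(imgData(base))
  ref <- subvoxelVolume(base)@totalMl
  shifted <- array(FALSE, d)
  shifted[2:d[1], , ] <- imgData(base)[1:(d[1] - 1), , ]
  vs <- subvoxelVolume(SegmentationMask(shifted,
                                        ImageVolume(array(0, d), c(1, 1, 1))))
  expect_equal(vs@totalMl, ref, tolerance = 1e-12)
  perm <- aperm(imgData(base), c(3, 1, 2))
  vp <- subvoxelVolume(SegmentationMask(perm,
                                        ImageVolume(array(0, d), c(1, 1, 1))))
  expect_equal(vp@totalMl, ref, tolerance = 1e-12)
})

test_that("digitized-ball volume error shrinks with radius", {
  errs <- vapply(c(5, 10, 20), function(r) {
    res <- subvoxelVolume(ballMask(r))
    abs(res@totalMl * 1000 / (4 / 3 * pi * r^3) - 1)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("open meshes are rejected by the volume integrator", {
  cub <- cuboidMask(6L, 6L, 6L)
  m <- buildMesh(cub)[[1]]
  m@faces <- m@faces[-1, , drop = FALSE]
  expect_error(subvoxelVolume(cub, list(m)), "open mesh")
})

test_that("meshes export as readable ASCII STL", {
  path <- withr::local_tempfile(fileext = ".stl")
  writeMeshStl(buildMesh(cuboidMask(4L, 4L, 4L))[[1]], path)
  txt <- readLines(path)
  expect_match(txt[1], "^solid")
  expect_identical(sum(grepl("facet normal", txt)),
                   nrow(buildMesh(cuboidMask(4L, 4L, 4L))[[1]]@faces))
})
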