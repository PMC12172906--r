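test_that("invalid configurations fail naming the offending field", {
  expect_error(phantomConfig(gridShape = c(6, 64, 16)), "gridShape")
  expect_error(phantomConfig(nVisits = 1), "nVisits")
  expect_error(phantomConfig(oddEvenFactor = 0), "oddEvenFactor")
  expect_error(phantomConfig(voxelSpacing = c(1, 0, 3)), "voxelSpacing")
  expect_error(phantomConfig(noiseSigma = -1), "noiseSigma")
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- phantomConfig(seed = 21L)
  a <- generateStudy(cfg)
  b <- generateStudy(cfg)
  expect_identical(a@visits[[1]]$pd@data, b@visits[[1]]$pd@data)
  expect_identical(a@visits[[2]]$t2@data, b@visits[[2]]$t2@data)
  expect_identical(a@truth$intervals, b@truth$intervals)
  # a different seed gives different noise
  c2 <- generateStudy(phantomConfig(seed = 22L))
  expect_false(identical(a@visits[[1]]$pd@data, c2@visits[[1]]$pd@data))
})

test_that("truth bookkeeping: TLVC is the signed sum of category volumes
           and matches the painted lesion masks", {
  st <- smallStudy(seed = 31L)
  voxMl <- prod(st@config@voxelSpacing) / 1000
  tr <- st@truth$intervals[["1-2"]]
  expect_equal(tr$tlvc,
               (tr$volNew + tr$volEnlarging) -
                 (tr$volDisappearing + tr$volShrinking),
               tolerance = 1e-12)
  # lesion-mask voxel counts agree with the truth inventory
  counts <- vapply(st@truth$lesionInventory,
                   function(l) l$voxelCounts, numeric(2))
  expect_equal(sum(st@visits[[1]]$lesionMask@data), sum(counts[1, ]))
  expect_equal(sum(st@visits[[2]]$lesionMask@data), sum(counts[2, ]))
  # per-lesion category volumes recomputed independently from the counts
  vols <- c(new = 0, enlarging = 0, shrinking = 0, disappearing = 0)
  for (l in st@truth$lesionInventory) {
    cv <- l$voxelCounts[1] * voxMl; cw <- l$voxelCounts[2] * voxMl
    if (cv == 0 && cw > 0) vols["new"] <- vols["new"] + cw
    else if (cv > 0 && cw == 0)
      vols["disappearing"] <- vols["disappearing"] + cv
    else if (cw > cv) vols["enlarging"] <- vols["enlarging"] + (cw - cv)
    else if (cv > cw) vols["shrinking"] <- vols["shrinking"] + (cv - cw)
  }
  expect_equal(unname(vols["new"]), tr$volNew, tolerance = 1e-12)
  expect_equal(unname(vols["enlarging"]), tr$volEnlarging, tolerance = 1e-12)
})

test_that("a no-change configuration has zero true TLVC and a single new
           lesion contributes its voxel volume", {
  les <- list(list(center = c(0, -10, 0), schedule = c(4, 4)))
  cfg <- phantomConfig(seed = 5L, lesionSpec = les, noiseSigma = 0,
                       motionSpec = list(rep(0, 6), rep(0, 6)))
  st <- generateStudy(cfg)
  expect_equal(st@truth$intervals[["1-2"]]$tlvc, 0)
  # new lesion: truth volume = voxel count x 3 mm^3, TLVC positive
  les2 <- list(list(center = c(0, -10, 0), schedule = c(0, 4)))
  st2 <- generateStudy(phantomConfig(seed = 5L, lesionSpec = les2,
                                     noiseSigma = 0))
  n <- sum(st2@visits[[2]]$lesionMask@data)
  expect_gt(n, 0)
  expect_equal(st2@truth$intervals[["1-2"]]$volNew, n * 0.003,
               tolerance = 1e-12)
  expect_equal(st2@truth$intervals[["1-2"]]$tlvc, n * 0.003,
               tolerance = 1e-12)
})

test_that("per-visit geometry is shared and lesions lie inside the brain", {
  st <- smallStudy(seed = 41L)
  for (v in st@visits) {
    expect_equal(dim(v$pd@data), dim(v$t2@data))
    expect_equal(v$pd@affine, v$t1@affine)
    # lesion mask is a subset of the brain mask
    expect_true(all(v$brainMask@data[v$lesionMask@data > 0] == 1))
  }
})

test_that("acquisition artifacts behave as configured", {
  base <- mkVol(array(100, c(16, 16, 8)), spacing = c(1, 1, 3))
  neutral <- phantomConfig(gridShape = c(16L, 16L, 8L), nVisits = 2L,
                           lesionSpec = list(), noiseSigma = 0,
                           oddEvenFactor = 1, biasFieldAmplitude = 0)
  out <- applyAcquisitionArtifacts(base, neutral)
  expect_equal(out@data, base@data, tolerance = 1e-12)

  oe <- phantomConfig(gridShape = c(16L, 16L, 8L), nVisits = 2L,
                      lesionSpec = list(), noiseSigma = 0,
                      oddEvenFactor = 1.2, biasFieldAmplitude = 0)
  out <- applyAcquisitionArtifacts(base, oe)
  odd0 <- c(2, 4, 6, 8)                  # 0-based odd slices
  expect_equal(mean(out@data[, , odd0]) / mean(out@data[, , -odd0]), 1.2,
               tolerance = 1e-12)

  bf <- phantomConfig(gridShape = c(16L, 16L, 8L), nVisits = 2L,
                      lesionSpec = list(), noiseSigma = 0,
                      oddEvenFactor = 1, biasFieldAmplitude = 0.1)
  out <- applyAcquisitionArtifacts(base, bf)
  expect_true(all(is.finite(out@data)))
  expect_gt(sd(out@data) / mean(out@data), 0)   # nonzero CoV
  expect_true(all(out@data > 0))

  # non-finite input is a data error (validity bypassed to reach the check)
  bad <- base
  slot(bad, "data", check = FALSE) <- {
    x <- base@data; x[1] <- NA; x
  }
  expect_error(applyAcquisitionArtifacts(bad, neutral), "finite")
})

test_that("study export writes NIfTI volumes and a readable truth manifest", {
  st <- smallStudy(seed = 51L)
  d <- tempfile()
  writeStudy(st, d)
  v1 <- loadVisit(file.path(d, "visit1"))
  expect_equal(v1$pd@data, st@visits[[1]]$pd@data, tolerance = 1e-6)
  expect_equal(v1$lesionMask@data, st@visits[[1]]$lesionMask@data)
  manifest <- jsonlite::read_json(file.path(d, "truth.json"),
                                  simplifyVector = TRUE)
  expect_equal(manifest$voxelVolume_mm3, 3)
  expect_equal(manifest$intervals[["1-2"]]$tlvc,
               st@truth$intervals[["1-2"]]$tlvc, tolerance = 1e-9)
  unlink(d, recursive = TRUE)
})
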