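test_that("subtraction is voxelwise, sign-correct and antisymmetric", {
  set.seed(13)
  d <- c(8, 8, 4)
  a <- mkVol(array(runif(prod(d)), d))
  b <- mkVol(a@data)
  expect_true(all(subtractImages(b, a)@data == 0))
  # a regional increase over time appears positive
  b2 <- a@data; b2[2:4, 2:4, 2] <- b2[2:4, 2:4, 2] + 0.2
  sub <- subtractImages(mkVol(b2), a)
  expect_equal(sub@data[3, 3, 2], 0.2, tolerance = 1e-12)
  expect_equal(sum(sub@data != 0), 9)
  # antisymmetry
  expect_equal(subtractImages(mkVol(b2), a)@data,
               -subtractImages(a, mkVol(b2))@data, tolerance = 1e-12)
  expect_error(subtractImages(a, mkVol(array(0, c(4, 4, 4)))), "grid")
})

test_that("Z-scoring standardizes against tissue excluding lesions with the
           sample SD", {
  d <- c(6, 6, 2)
  sub <- array(0, d)
  # reference region of two voxels at -1 and +1: sample SD = sqrt(2)
  ref <- array(0, d); ref[1, 1, 1] <- 1; ref[2, 1, 1] <- 1
  sub[1, 1, 1] <- -1; sub[2, 1, 1] <- 1
  sub[3, 3, 2] <- 2
  z <- toZScores(mkVol(sub, modality = "SUBTRACTION"), mkMask(ref),
                 mkMask(array(0, d)))
  expect_equal(z@refMean, 0)
  expect_equal(z@refSD, sqrt(2))
  expect_equal(z@data[3, 3, 2], 2 / sqrt(2), tolerance = 1e-12)
  # within the reference mask the Z map has mean 0 and SD 1 by construction
  expect_equal(mean(z@data[ref > 0]), 0, tolerance = 1e-12)
  expect_equal(sd(z@data[ref > 0]), 1, tolerance = 1e-12)
  # lesion voxels are excluded from the reference statistics
  les <- array(0, d); les[2, 1, 1] <- 1
  expect_error(toZScores(mkVol(sub, modality = "SUBTRACTION"), mkMask(ref),
                         mkMask(les)), "fewer than 2")
  # constant reference region has no variance to standardize by
  flat <- array(1, d)
  expect_error(toZScores(mkVol(flat, modality = "SUBTRACTION"),
                         mkMask(array(1, d)), mkMask(array(0, d))),
               "variance")
})

test_that("lesion-mask conditioning thresholds at 0.25 and removes in-slice
           singletons", {
  d <- c(12, 12, 4)
  arr <- array(0, d)
  arr[4:7, 4:7, 2] <- 1
  mask <- mkMask(arr, spacing = c(1, 1, 1))
  grid <- imageGrid(mask)
  # identity: no fractional voxels, no singletons -> unchanged
  out <- conditionLesionMask(mask, identityTransform(), grid)
  expect_identical(out@data, arr)
  # half-voxel shift of a 1-voxel line: 0.5 fractions are kept (>= 0.25)
  line <- array(0, d); line[4:8, 6, 2] <- 1
  hm <- computeHalfway(paramsToTransform(translations = c(0, 1, 0)),
                       paramsToTransform(translations = c(0, -1, 0)))
  out <- conditionLesionMask(mkMask(line, c(1, 1, 1)), hm@H1, grid)
  # the line lands half-way between two voxel rows; both rows reach 0.5
  expect_equal(sum(out@data), 2 * 5)
  # an isolated single voxel in a slice is removed
  single <- arr; single[10, 10, 3] <- 1
  out <- conditionLesionMask(mkMask(single, c(1, 1, 1)),
                             identityTransform(), grid)
  expect_equal(out@data[10, 10, 3], 0)
  expect_equal(sum(out@data), sum(arr))
  # conditioning an off-grid mask to emptiness warns and flags
  tiny <- array(0, d); tiny[6, 6, 2] <- 1
  expect_warning(
    gone <- conditionLesionMask(mkMask(tiny, c(1, 1, 1)),
                                paramsToTransform(translations = c(50, 0, 0)),
                                grid),
    "emptied")
  expect_true(attr(gone, "emptied"))
  # removal rule agrees with the brute-force singleton oracle
  set.seed(14)
  rnd <- array(rbinom(prod(d), 1, 0.15), d)
  out <- conditionLesionMask(mkMask(rnd, c(1, 1, 1)), identityTransform(),
                             grid)
  expect_identical(out@data, oracleRemoveSingletons(rnd))
})

test_that("lesion components pair into the three situations with
           transitive-overlap grouping", {
  d <- c(12, 12, 3)
  m1 <- array(0, d); m2 <- array(0, d)
  # situation 1: blob only at visit 2
  m2[2:3, 2:3, 1] <- 1
  # situation 2: blob only at visit 1 (kept clear of the chain below,
  # which 26-connectivity would otherwise absorb across slices)
  m1[9:10, 2:3, 3] <- 1
  # situation 3 chain: A1 overlaps B2, B2 overlaps C1 -> one group
  m1[2:4, 7:9, 2] <- 1          # A1
  m1[8:10, 7:9, 2] <- 1         # C1
  m2[4:8, 7:9, 2] <- 1          # B2 bridges both
  corr <- pairLesionComponents(mkMask(m1), mkMask(m2))
  expect_length(corr$situation1, 1)
  expect_length(corr$situation2, 1)
  expect_length(corr$situation3, 1)
  grp <- corr$situation3[[1]]
  expect_setequal(grp$region,
                  which(array((m1 + m2) > 0, d) &
                          array(rep(seq_len(d[3]), each = prod(d[1:2])) == 2,
                                d)))
  expect_length(grp$members1, 2)
  expect_length(grp$members2, 1)
  # empty masks give empty tables
  none <- pairLesionComponents(mkMask(array(0, d)), mkMask(array(0, d)))
  expect_length(none$situation1, 0)
  expect_length(none$situation3, 0)
})

test_that("classification matches the hand-coded rule interpreter on toy
           grids, including boundary Z values and the erosion restriction", {
  d <- c(8, 8, 3)
  set.seed(15)
  for (rep in 1:25) {
    m1 <- array(rbinom(prod(d), 1, 0.25), d)
    m2 <- array(rbinom(prod(d), 1, 0.25), d)
    z <- array(sample(c(-3, -1.5, -1, 0, 1, 1.5, 3), prod(d), TRUE), d)
    zmap <- new("ZScoreMap", data = z, affine = mkVol(z)@affine,
                modality = "ZSCORE", refMean = 0, refSD = 1,
                maskProvenance = "test")
    corr <- pairLesionComponents(mkMask(m1), mkMask(m2))
    got <- classifyActivity(zmap, corr, mkMask(m1), mkMask(m2), 1.5)
    expect_identical(got@labels, oracleClassify(z, m1, m2, 1.5))
  }
})

test_that("explicit classification cases follow the stated rules", {
  d <- c(6, 6, 1)
  z <- array(0, d)
  aff <- mkVol(z)@affine
  # situation 1 region with 10 voxels above and 5 below threshold
  m2 <- array(0, d); m2[1:3, 1:5, 1] <- 1
  m2[4, 1:5, 1] <- 0
  m1 <- array(0, d)
  z[1:2, 1:5, 1] <- 2                      # 10 voxels above
  z[3, 1:5, 1] <- 1                        # 5 below
  zmap <- new("ZScoreMap", data = z, affine = aff, modality = "ZSCORE",
              refMean = 0, refSD = 1, maskProvenance = "t")
  corr <- pairLesionComponents(mkMask(m1), mkMask(m2))
  lab <- classifyActivity(zmap, corr, mkMask(m1), mkMask(m2), 1.5)
  expect_equal(sum(lab@labels == activityCodes[["new"]]), 10)
  # voxels exactly at +/- 1.5 stay none (strict inequalities)
  z2 <- array(1.5, d)
  zmap2 <- new("ZScoreMap", data = z2, affine = aff, modality = "ZSCORE",
               refMean = 0, refSD = 1, maskProvenance = "t")
  lab2 <- classifyActivity(zmap2, corr, mkMask(m1), mkMask(m2), 1.5)
  expect_true(all(lab2@labels == 0))
  # situation 3: high Z inside the eroded visit-1 mask stays none
  d3 <- c(7, 7, 1)
  M1 <- array(0, d3); M1[2:6, 2:6, 1] <- 1
  M2 <- array(0, d3); M2[2:6, 2:6, 1] <- 1
  Z3 <- array(0, d3); Z3[4, 4, 1] <- 2     # center: inside eroded mask
  Z3[2, 4, 1] <- 2                         # border: outside eroded mask
  zmap3 <- new("ZScoreMap", data = Z3, affine = mkVol(Z3)@affine,
               modality = "ZSCORE", refMean = 0, refSD = 1,
               maskProvenance = "t")
  corr3 <- pairLesionComponents(mkMask(M1), mkMask(M2))
  lab3 <- classifyActivity(zmap3, corr3, mkMask(M1), mkMask(M2), 1.5)
  expect_equal(lab3@labels[4, 4, 1], 0)
  expect_equal(lab3@labels[2, 4, 1], activityCodes[["enlarging"]])
  expect_error(classifyActivity(zmap3, corr3, mkMask(M1), mkMask(M2), 0),
               "configuration")
})

test_that("TLVC arithmetic follows the count-times-voxel-volume rule", {
  lab <- array(0L, c(10, 10, 3))
  lab[1:10, 1:5, 1] <- activityCodes[["new"]]          # 50 voxels
  lab[1:10, 1:3, 2] <- activityCodes[["enlarging"]]    # 30
  lab[1:10, 1:2, 3] <- activityCodes[["shrinking"]]    # 20
  lab[1:10, 6:9, 1] <- activityCodes[["disappearing"]] # 40
  res <- computeTLVC(new("ActivityLabelMap", labels = lab, voxelVolume = 3))
  # independent count-and-multiply oracle
  counts <- table(factor(lab[lab > 0], levels = 1:4))
  expect_equal(tlvc(res),
               unname((counts[1] + counts[2]) - (counts[4] + counts[3])) *
                 0.003, tolerance = 1e-12)
  expect_equal(tlvc(res), (80 - 60) * 0.003, tolerance = 1e-12)
  v <- activityVolumes(res)
  expect_equal(unname(v["positive"]), 0.24, tolerance = 1e-12)
  expect_equal(unname(v["negative"]), 0.18, tolerance = 1e-12)
  # all none -> zero
  expect_equal(tlvc(computeTLVC(new("ActivityLabelMap",
                                    labels = array(0L, c(4, 4, 2)),
                                    voxelVolume = 3))), 0)
})

test_that("raising the Z threshold never increases any category volume", {
  d <- c(8, 8, 3)
  set.seed(16)
  m1 <- array(rbinom(prod(d), 1, 0.3), d)
  m2 <- array(rbinom(prod(d), 1, 0.3), d)
  z <- array(rnorm(prod(d), sd = 2), d)
  zmap <- new("ZScoreMap", data = z, affine = mkVol(z)@affine,
              modality = "ZSCORE", refMean = 0, refSD = 1,
              maskProvenance = "t")
  corr <- pairLesionComponents(mkMask(m1), mkMask(m2))
  prev <- NULL
  for (thr in c(0.5, 1, 1.5, 2, 3)) {
    res <- activityVolumes(computeTLVC(
      classifyActivity(zmap, corr, mkMask(m1), mkMask(m2), thr)))
    if (!is.null(prev))
      expect_true(all(res[c("new", "enlarging", "shrinking",
                            "disappearing")] <=
                        prev[c("new", "enlarging", "shrinking",
                               "disappearing")] + 1e-12))
    prev <- res
  }
})

test_that("the field-of-view flag matches an exhaustive voxel check", {
  d <- c(6, 6, 4)
  full <- mkMask(array(1, d))
  les1 <- array(0, d); les1[3, 3, 2] <- 1
  les2 <- array(0, d); les2[4, 4, 4] <- 1   # top slice
  fov2partial <- array(1, d); fov2partial[, , 4] <- 0
  expect_false(checkFovCoverage(mkMask(les1), mkMask(les2), full, full))
  # visit-2 lesion in a slice visit 1 did not acquire -> flag
  expect_true(checkFovCoverage(mkMask(les1), mkMask(les2),
                               mkMask(fov2partial), full))
  # brute-force equivalence on random masks
  set.seed(17)
  for (i in 1:10) {
    l1 <- array(rbinom(prod(d), 1, 0.1), d)
    l2 <- array(rbinom(prod(d), 1, 0.1), d)
    f1 <- array(rbinom(prod(d), 1, 0.9), d)
    f2 <- array(rbinom(prod(d), 1, 0.9), d)
    expected <- FALSE
    for (v in seq_len(prod(d))) {
      if (l1[v] > 0 && f2[v] == 0) expected <- TRUE
      if (l2[v] > 0 && f1[v] == 0) expected <- TRUE
    }
    expect_identical(checkFovCoverage(mkMask(l1), mkMask(l2), mkMask(f1),
                                      mkMask(f2)), expected)
  }
})
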