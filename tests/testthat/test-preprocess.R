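test_that("odd/even correction equalizes parity means, preserves the
           within-mask mean, and is idempotent", {
  set.seed(4)
  d <- c(12, 12, 8)
  arr <- array(100 + rnorm(prod(d), sd = 3), d)
  odd0 <- c(2, 4, 6, 8)                  # 0-based odd slices
  arr[, , odd0] <- arr[, , odd0] * 1.2
  pd <- mkVol(arr)
  mask <- mkMask(array(1, d))
  out <- correctOddEvenSlices(pd, mask)
  mOdd <- mean(out@data[, , odd0]); mEven <- mean(out@data[, , -odd0])
  expect_equal(mOdd / mEven, 1, tolerance = 1e-6)
  expect_equal(mean(out@data), mean(arr), tolerance = 1e-9)
  # idempotence
  twice <- correctOddEvenSlices(out, mask)
  expect_equal(twice@data, out@data, tolerance = 1e-6)
  # an already balanced image passes through unchanged
  bal <- mkVol(array(100, d))
  expect_equal(correctOddEvenSlices(bal, mask)@data, bal@data,
               tolerance = 1e-12)
})

test_that("odd/even correction fails on slice-parity starvation", {
  d <- c(8, 8, 6)
  pd <- mkVol(array(100, d))
  m <- array(0, d); m[, , c(1, 3, 5)] <- 1   # even 0-based slices only
  expect_error(correctOddEvenSlices(pd, mkMask(m)), "parity")
})

test_that("bias-field correction removes a known low-order field", {
  d <- c(24, 24, 10)
  nx <- seq(-1, 1, length.out = d[1])
  ny <- seq(-1, 1, length.out = d[2])
  nz <- seq(-1, 1, length.out = d[3])
  field <- exp(0.2 * (outer(outer(nx, ny, function(a, b) a + 0.5 * a * b),
                            nz, function(ab, c) ab + 0.3 * c^2)))
  pd <- mkVol(array(100, d) * field)
  m <- array(0, d); m[5:20, 5:20, 3:8] <- 1
  mask <- mkMask(m)
  out <- correctBiasField(pd, mask)
  cov0 <- sd(pd@data[m > 0]) / mean(pd@data[m > 0])
  cov1 <- sd(out@data[m > 0]) / mean(out@data[m > 0])
  expect_lt(cov1, 0.2 * cov0)            # >= 80% reduction
  # within-mask mean preserved; estimated field strictly positive
  expect_equal(mean(out@data[m > 0]), mean(pd@data[m > 0]),
               tolerance = 1e-6)
  expect_true(all(attr(out, "field") > 0))
  # an unbiased constant image is essentially untouched inside the mask
  flat <- mkVol(array(50, d))
  outF <- correctBiasField(flat, mask)
  expect_equal(outF@data[m > 0] / 50, rep(1, sum(m)), tolerance = 0.01)
})

test_that("bias-field correction rejects degenerate input", {
  d <- c(10, 10, 6)
  expect_error(correctBiasField(mkVol(array(0, d)), mkMask(array(1, d))),
               "degenerate")
  expect_error(correctBiasField(mkVol(array(1, d)), mkMask(array(0, d))),
               "empty")
})

test_that("brain-mask propagation is binary, exact under identity, and
           tracks a known shift", {
  d <- c(20, 20, 8)
  m <- array(0, d); m[8:13, 8:13, 3:6] <- 1
  mask <- mkMask(m, spacing = c(1, 1, 3))
  target <- mkVol(array(0, d), spacing = c(1, 1, 3))
  same <- propagateBrainMask(mask, identityTransform(), target)
  expect_identical(same@data, mask@data)
  # whole-grid mask saturates under any within-FOV rigid transform
  full <- mkMask(array(1, d), spacing = c(1, 1, 3))
  tr <- paramsToTransform(translations = c(1, -1, 0))
  out <- propagateBrainMask(full, tr, target)
  expect_true(all(out@data %in% c(0, 1)))
  expect_gt(mean(out@data), 0.85)        # saturated up to border clipping
  # a 3 mm shift moves the centroid by 3 mm within a voxel
  tr3 <- paramsToTransform(translations = c(3, 0, 0))
  shifted <- propagateBrainMask(mask, tr3, target)
  centroid <- function(x) {
    idx <- arrayInd(which(x@data > 0), dim(x@data))
    (x@affine %*% c(colMeans(idx) - 1, 1))[1:3]
  }
  expect_equal(centroid(shifted) - centroid(mask), c(-3, 0, 0),
               tolerance = 1)
  # count change stays within the rigid-transform bound
  expect_lt(abs(sum(shifted@data) - sum(mask@data)) / sum(mask@data), 0.1)
})

test_that("T1-to-T2 registration recovers identity and known translations", {
  st <- smallStudy(seed = 61L, noiseSigma = 1)
  v <- st@visits[[1]]
  tr <- registerT1ToT2(v$t1, v$t2)
  # same-session, same-grid phantom: identity within 0.1 mm / 0.1 deg
  expect_lt(max(abs(tr@matrix[1:3, 4])), 0.1)
  expect_lt(max(abs(tr@matrix[1:3, 1:3] - diag(3))), 0.1 * pi / 180 + 5e-3)
  # T2 content translated by +(3, 0, 0) mm: the fixed->moving transform
  # maps each T2 point back to the T1 location, i.e. translation -3
  g <- imageGrid(v$t1)
  pullback <- paramsToTransform(translations = c(-3, 0, 0))
  t2shift <- resampleVolume(v$t2, pullback, g, "trilinear")
  t2shift@modality <- "T2"
  tr2 <- registerT1ToT2(v$t1, t2shift)
  expect_equal(tr2@matrix[1:3, 4], c(-3, 0, 0), tolerance = 0.5)
})

test_that("registration of unrelated noise images fails the metric floor", {
  set.seed(8)
  a <- mkVol(array(rnorm(16 * 16 * 8), c(16, 16, 8)), modality = "T1")
  b <- mkVol(array(rnorm(16 * 16 * 8), c(16, 16, 8)), modality = "T2")
  expect_error(registerT1ToT2(a, b, metricFloor = 1.05), "metric")
})
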