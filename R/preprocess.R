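# Per-visit preparation of the PD-weighted image: odd/even slice intensity
# equalization, bias-field correction, and propagation of the T1-space
# brain mask to the dual-echo grid.

#' Propagate a brain mask through a transform
#'
#' Pulls a T1-space mask onto the target (T2/PD) grid with
#' nearest-neighbour interpolation; the output stays strictly binary.
#'
#' @param maskT1 a [BinaryMask-class] in T1 space.
#' @param transform the [AffineTransform-class] from [registerT1ToT2()]
#'   (target-space world points to T1-space world points).
#' @param target an [ImageVolume-class] defining the output grid.
#' @return a [BinaryMask-class] on the target grid.
#' @export
propagateBrainMask <- function(maskT1, transform, target) {
  if (!is(maskT1, "BinaryMask")) stop("data error: maskT1 must be a BinaryMask")
  resampleVolume(maskT1, transform, imageGrid(target), "nearest")
}

#' Equalize odd and even slice intensities
#'
#' Interleaved 2D acquisition can leave a systematic intensity difference
#' between odd and even slices.  Within the brain mask, the mean signal of
#' the odd slices (0-based along the axial axis) and of the even slices are
#' matched: odd slices are scaled by `g = sqrt(mEven / mOdd)` and even
#' slices by `1/g`, and a final global factor restores the original
#' within-mask mean.  The correction is symmetric in slice parity,
#' mean-preserving, and idempotent.
#'
#' @param pd an [ImageVolume-class] (PD-weighted).
#' @param brainMask a [BinaryMask-class] on the same grid, intersecting
#'   both slice parities.
#' @return corrected [ImageVolume-class].
#' @export
correctOddEvenSlices <- function(pd, brainMask) {
  if (!all(dim(pd@data) == dim(brainMask@data)))
    stop("data error: mask geometry does not match image")
  d <- dim(pd@data)
  parity <- (seq_len(d[3]) - 1) %% 2      # 0-based slice index parity
  m <- brainMask@data > 0
  oddSel <- m & rep(parity == 1, each = d[1] * d[2])
  evenSel <- m & rep(parity == 0, each = d[1] * d[2])
  if (!any(oddSel) || !any(evenSel))
    stop("correction error: brain mask empty on odd or even slices ",
         "(slice-parity starvation)")
  mOdd <- mean(pd@data[oddSel])
  mEven <- mean(pd@data[evenSel])
  if (mOdd <= 0 || mEven <= 0)
    stop("data error: non-positive within-mask mean")
  g <- sqrt(mEven / mOdd)
  arr <- pd@data
  arr[, , parity == 1] <- arr[, , parity == 1] * g
  arr[, , parity == 0] <- arr[, , parity == 0] / g
  meanBefore <- mean(pd@data[m])
  arr <- arr * (meanBefore / mean(arr[m]))
  new("ImageVolume", data = arr, affine = pd@affine, modality = pd@modality)
}

#' Correct the smooth multiplicative bias field
#'
#' Estimates a smooth positive multiplicative field by fitting a
#' third-degree polynomial to the log-intensities within the brain mask
#' and divides it out over the whole volume.  The field is normalized to a
#' within-mask mean of 1, so the within-mask mean intensity is preserved.
#'
#' @param pd an [ImageVolume-class].
#' @param brainMask a nonempty [BinaryMask-class] on the same grid.
#' @param degree polynomial degree of the log-domain field model (<= 3).
#' @return corrected [ImageVolume-class], with the estimated field attached
#'   as attribute `field`.
#' @export
correctBiasField <- function(pd, brainMask, degree = 3L) {
  if (!all(dim(pd@data) == dim(brainMask@data)))
    stop("data error: mask geometry does not match image")
  m <- brainMask@data > 0
  if (!any(m)) stop("data error: empty brain mask")
  pos <- m & pd@data > 0
  if (sum(pos) < 20)
    stop("data error: degenerate image (too few positive voxels in mask)")
  d <- dim(pd@data)
  nx <- seq(-1, 1, length.out = d[1])
  ny <- seq(-1, 1, length.out = d[2])
  nz <- seq(-1, 1, length.out = d[3])
  coords <- arrayInd(which(pos), d)
  X <- nx[coords[, 1]]; Y <- ny[coords[, 2]]; Z <- nz[coords[, 3]]
  basis <- function(X, Y, Z) {
    b <- cbind(1, X, Y, Z)
    if (degree >= 2)
      b <- cbind(b, X * Y, X * Z, Y * Z, X^2, Y^2, Z^2)
    if (degree >= 3)
      b <- cbind(b, X^3, Y^3, Z^3, X^2 * Y, X^2 * Z, Y^2 * X, Y^2 * Z,
                 Z^2 * X, Z^2 * Y, X * Y * Z)
    b
  }
  B <- basis(X, Y, Z)
  beta <- qr.coef(qr(B), log(pd@data[pos]))
  beta[is.na(beta)] <- 0
  coordsAll <- arrayInd(seq_len(prod(d)), d)
  Ball <- basis(nx[coordsAll[, 1]], ny[coordsAll[, 2]], nz[coordsAll[, 3]])
  # drop the constant term: the field carries shape only, not overall level
  beta[1] <- 0
  field <- array(exp(Ball %*% beta), d)
  corrected <- pd@data / field
  # exact mean preservation within the mask
  scale <- mean(pd@data[m]) / mean(corrected[m])
  corrected <- corrected * scale
  field <- field / scale
  out <- new("ImageVolume", data = corrected, affine = pd@affine,
             modality = pd@modality)
  attr(out, "field") <- field
  out
}
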