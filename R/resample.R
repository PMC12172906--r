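.methodCode <- function(method) {
  switch(method,
         nearest = 0L, trilinear = 1L, sinc = 2L,
         stop("unknown interpolation method '", method,
              "' (use 'sinc', 'trilinear' or 'nearest')"))
}

# Core resampler: pull `source` onto `targetGrid` through `transform`,
# which maps target-space world points to source-space world points
# (resampling convention).  Returns list(values, inbounds).
.resampleRaw <- function(source, transform, targetGrid, method) {
  vmat <- solve(source@affine) %*% transform@matrix %*% targetGrid$affine
  .c_resample(as.double(source@data), dim(source@data), vmat,
              as.integer(targetGrid$dim), .methodCode(method))
}

#' Resample a volume or mask onto a target grid
#'
#' `transform` maps target-space world points to source-space world points
#' (the resampling convention); voxels sampled outside the source field of
#' view are set to 0.  `sinc` uses a Hann-windowed sinc kernel of radius
#' 4 with per-sample weight renormalization; `trilinear` on a binary mask
#' yields a fractional mask in \[0, 1\]; `nearest` preserves binary values.
#'
#' @param source an [ImageVolume-class] or [BinaryMask-class].
#' @param transform an [AffineTransform-class] (target -> source world map).
#' @param targetGrid list with `dim` (3 integers) and `affine` (4x4
#'   voxel-to-world), e.g. `imageGrid(x)`.
#' @param method `"sinc"`, `"trilinear"` or `"nearest"`.
#' @return an [ImageVolume-class] (or [BinaryMask-class] for `nearest` on a
#'   mask) on the target grid.
#' @export
resampleVolume <- function(source, transform, targetGrid,
                           method = c("trilinear", "sinc", "nearest")) {
  method <- match.arg(method)
  r <- .resampleRaw(source, transform, targetGrid, method)
  if (method == "nearest" && is(source, "BinaryMask"))
    new("BinaryMask", data = r$values, affine = targetGrid$affine,
        modality = "MASK")
  else
    new("ImageVolume", data = r$values, affine = targetGrid$affine,
        modality = source@modality)
}

#' @describeIn resampleVolume binary mask of target voxels whose sampling
#'   location falls inside the source field of view.
#' @export
fovMask <- function(source, transform, targetGrid) {
  r <- .resampleRaw(source, transform, targetGrid, "nearest")
  new("BinaryMask", data = r$inbounds + 0, affine = targetGrid$affine,
      modality = "MASK")
}

#' Sampling lattice of a volume
#'
#' @param x an [ImageVolume-class].
#' @return list with `dim`, `spacing` and `affine`, usable as a target grid
#'   for [resampleVolume()].
#' @export
imageGrid <- function(x)
  list(dim = dim(x@data), spacing = voxelSpacing(x), affine = x@affine)

#' Resample an image or mask into halfway space
#'
#' Applies the inverse of the visit-to-halfway map `H` in the resampling
#' convention: each halfway grid point is pulled back to the visit's native
#' space and interpolated there.  Per the pipeline's conventions, PD/T2
#' images use `sinc`, brain masks `nearest`, and lesion masks `trilinear`
#' (producing a fractional mask to be thresholded downstream).
#'
#' @param x an [ImageVolume-class] or [BinaryMask-class] in visit space.
#' @param H the visit-to-halfway [AffineTransform-class] (`H1` or `H2` of a
#'   [HalfwaySpace-class]).
#' @param grid the halfway sampling lattice (list with `dim`, `affine`).
#' @param method `"sinc"`, `"trilinear"` or `"nearest"`.
#' @return volume or mask on the halfway grid.
#' @export
resampleToHalfway <- function(x, H, grid,
                              method = c("sinc", "trilinear", "nearest")) {
  method <- match.arg(method)
  resampleVolume(x, invertTransform(H), grid, method)
}

# Block-average downsampling by integer factors (registration pyramid).
# Affine is updated so voxel centers of the coarse grid sit at the mean
# position of the averaged fine voxels.
.downsampleVolume <- function(x, factors) {
  d <- dim(x@data)
  f <- pmin(as.integer(factors), d)
  nd <- d %/% f
  stopifnot(all(nd >= 1))
  arr <- x@data[seq_len(nd[1] * f[1]), seq_len(nd[2] * f[2]),
                seq_len(nd[3] * f[3]), drop = FALSE]
  dim(arr) <- c(f[1], nd[1], f[2], nd[2], f[3], nd[3])
  coarse <- apply(arr, c(2, 4, 6), mean)
  aff <- x@affine
  scale <- diag(c(f, 1))
  shift <- (f - 1) / 2
  scale[1:3, 4] <- shift
  new("ImageVolume", data = coarse, affine = aff %*% scale,
      modality = x@modality)
}
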