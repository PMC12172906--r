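#' Read and write volumes as NIfTI-1
#'
#' Volumes are stored with the voxel-to-world affine in the sform/qform
#' (code 2); on reading, the affine is taken from the NIfTI xform.
#'
#' @param x an [ImageVolume-class] or [BinaryMask-class].
#' @param path file path (`.nii` or `.nii.gz`).
#' @param modality modality tag to attach on read.
#' @param mask logical: read as a [BinaryMask-class] (values are binarized
#'   at 0.5).
#' @return [readImageVolume()] returns an [ImageVolume-class] (or
#'   [BinaryMask-class] when `mask = TRUE`); [writeImageVolume()] returns
#'   `path` invisibly.
#' @export
writeImageVolume <- function(x, path) {
  im <- RNifti::asNifti(x@data)
  RNifti::qform(im) <- structure(x@affine, code = 2L)
  RNifti::sform(im) <- structure(x@affine, code = 2L)
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' @rdname writeImageVolume
#' @export
readImageVolume <- function(path, modality = "OTHER", mask = FALSE) {
  im <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(im))
  attributes(aff) <- list(dim = c(4L, 4L))
  arr <- array(as.double(im), dim(im)[1:3])
  if (mask)
    new("BinaryMask", data = (arr > 0.5) + 0, affine = aff,
        modality = "MASK")
  else
    new("ImageVolume", data = arr, affine = aff, modality = modality)
}
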