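#' @rdname ImageVolume-class
#' @param object,x an object.
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname ImageVolume-class
#' @export
setGeneric("voxelAffine", function(x) standardGeneric("voxelAffine"))

#' @rdname ImageVolume-class
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname ImageVolume-class
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))

#' @rdname ImageVolume-class
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' @rdname LesionChangeResult-class
#' @export
setGeneric("tlvc", function(x) standardGeneric("tlvc"))

#' @rdname LesionChangeResult-class
#' @export
setGeneric("activityVolumes", function(x) standardGeneric("activityVolumes"))

setMethod("voxelData", "ImageVolume", function(x) x@data)
setMethod("voxelAffine", "ImageVolume", function(x) x@affine)
setMethod("voxelSpacing", "ImageVolume", function(x)
  sqrt(colSums(x@affine[1:3, 1:3]^2)))
setMethod("voxelVolume", "ImageVolume", function(x)
  abs(det(x@affine[1:3, 1:3])))
setMethod("modality", "ImageVolume", function(x) x@modality)

setMethod("dim", "ImageVolume", function(x) dim(x@data))

#' @rdname LesionChangeResult-class
#' @export
setMethod("tlvc", "LesionChangeResult", function(x) x@tlvc)

#' @describeIn LesionChangeResult-class named vector of the four category
#'   volumes plus positive/negative activity and TLVC, in mL.
#' @export
setMethod("activityVolumes", "LesionChangeResult", function(x)
  c(new = x@volNew, enlarging = x@volEnlarging, shrinking = x@volShrinking,
    disappearing = x@volDisappearing, positive = x@positiveActivity,
    negative = x@negativeActivity, tlvc = x@tlvc))

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@data)
  sp <- voxelSpacing(object)
  cat(sprintf("%s volume (%s): %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              class(object), object@modality, d[1], d[2], d[3],
              sp[1], sp[2], sp[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "AffineTransform", function(object) {
  cat("AffineTransform (fixed -> moving world map):\n")
  print(round(object@matrix, 6))
})

setMethod("show", "HalfwaySpace", function(object) {
  cat("HalfwaySpace:\n  grid:", paste(object@grid$dim, collapse = " x "),
      "voxels\n  H1 (visit 1 -> halfway):\n")
  print(round(object@H1@matrix, 4))
  cat("  H2 (visit 2 -> halfway):\n")
  print(round(object@H2@matrix, 4))
})

setMethod("show", "LesionChangeResult", function(object) {
  v <- activityVolumes(object)
  cat("Lesion change result (volumes in mL):\n")
  cat(sprintf("  new          %8.3f\n  enlarging    %8.3f\n", v["new"],
              v["enlarging"]))
  cat(sprintf("  shrinking    %8.3f\n  disappearing %8.3f\n", v["shrinking"],
              v["disappearing"]))
  cat(sprintf("  positive %8.3f   negative %8.3f\n", v["positive"],
              v["negative"]))
  cat(sprintf("  TLVC %8.3f mL%s\n", v["tlvc"],
              if (object@excluded) "   [FLAGGED: incomplete FOV coverage]"
              else ""))
})

setMethod("show", "SyntheticStudy", function(object) {
  cat(sprintf("SyntheticStudy: %d visits, grid %s, %d lesions\n",
              length(object@visits),
              paste(dim(object@visits[[1]]$pd@data), collapse = "x"),
              length(object@config@lesionSpec)))
  tt <- object@truth$intervals
  for (nm in names(tt))
    cat(sprintf("  interval %s: true TLVC %+.3f mL\n", nm, tt[[nm]]$tlvc))
})

setMethod("show", "PhantomConfig", function(object) {
  cat(sprintf(paste0("PhantomConfig: grid %s, spacing %s mm, %d visits, ",
                     "%d lesions\n  noiseSigma %.3g, oddEvenFactor %.3g, ",
                     "biasFieldAmplitude %.3g, seed %d\n"),
              paste(object@gridShape, collapse = "x"),
              paste(object@voxelSpacing, collapse = "x"),
              object@nVisits, length(object@lesionSpec),
              object@noiseSigma, object@oddEvenFactor,
              object@biasFieldAmplitude, object@seed))
})
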