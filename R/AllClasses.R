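#' ImageVolume: a 3D scalar intensity grid with world geometry
#'
#' The basic image container of the package: a 3D array of intensities, the
#' voxel spacing in mm, and a 4x4 voxel-to-world affine (0-based voxel
#' indices, NIfTI convention).  All MRI volumes handled by the pipeline
#' (PD-, T2-, T1-weighted, subtraction and Z-score maps) are stored in this
#' form.
#'
#' @slot data 3D numeric array of intensities (all finite).
#' @slot affine 4x4 voxel-to-world matrix; bottom row (0,0,0,1); invertible.
#' @slot modality character tag: one of "PD", "T2", "T1", "SUBTRACTION",
#'   "ZSCORE", "MASK", "OTHER".
#'
#' @exportClass ImageVolume
setClass("ImageVolume",
         representation(data = "array", affine = "matrix",
                        modality = "character"),
         prototype(modality = "OTHER"))

.validImageVolume <- function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array")
  if (!all(is.finite(object@data)))
    msg <- c(msg, "all intensities must be finite")
  a <- object@affine
  if (!all(dim(a) == c(4L, 4L)))
    msg <- c(msg, "affine must be 4x4")
  else {
    if (max(abs(a[4, ] - c(0, 0, 0, 1))) > 1e-8)
      msg <- c(msg, "affine bottom row must be (0,0,0,1)")
    if (abs(det(a[1:3, 1:3])) < 1e-12)
      msg <- c(msg, "affine must be invertible")
  }
  if (!object@modality %in% c("PD", "T2", "T1", "SUBTRACTION", "ZSCORE",
                              "MASK", "OTHER"))
    msg <- c(msg, "unknown modality tag")
  if (length(msg)) msg else TRUE
}
setValidity("ImageVolume", .validImageVolume)

#' BinaryMask: a 0/1 grid on an ImageVolume geometry
#'
#' Used for brain masks, manual lesion masks, tissue-class masks and
#' field-of-view masks.  Extends [ImageVolume-class]; the data array may
#' contain only 0 and 1.
#'
#' @exportClass BinaryMask
setClass("BinaryMask", contains = "ImageVolume")

setValidity("BinaryMask", function(object) {
  if (!all(object@data %in% c(0, 1)))
    return("mask values must be 0 or 1")
  TRUE
})

#' AffineTransform: a 4x4 homogeneous world-space transform
#'
#' Transforms follow the resampling convention used throughout the package:
#' a transform attached to a registration of moving image M onto fixed
#' image F maps *fixed-space world points to moving-space world points*, so
#' it can be used directly to pull M onto F's grid.
#'
#' @slot matrix 4x4 homogeneous matrix, bottom row (0,0,0,1), invertible.
#' @exportClass AffineTransform
setClass("AffineTransform", representation(matrix = "matrix"))

setValidity("AffineTransform", function(object) {
  m <- object@matrix
  if (!all(dim(m) == c(4L, 4L))) return("matrix must be 4x4")
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > 1e-8)
    return("bottom row must be (0,0,0,1)")
  if (abs(det(m[1:3, 1:3])) < 1e-12) return("matrix must be invertible")
  TRUE
})

#' HalfwaySpace: the symmetric common frame of two visits
#'
#' Both visits are moved "half way" toward each other so that they suffer
#' equal interpolation, following the SIENA construction.  `H1` maps
#' visit-1 world coordinates to halfway world coordinates and `H2` does the
#' same for visit 2; the composition `inverse(H2) o H1` recovers the
#' visit-1-to-visit-2 registration.  `grid` carries the halfway sampling
#' lattice (dims, spacing, voxel-to-world affine): the visit-1 lattice
#' carried into halfway space.
#'
#' @slot H1,H2 [AffineTransform-class] visit-to-halfway maps.
#' @slot grid list with elements `dim`, `spacing`, `affine`.
#' @exportClass HalfwaySpace
setClass("HalfwaySpace",
         representation(H1 = "AffineTransform", H2 = "AffineTransform",
                        grid = "list"))

#' ZScoreMap: a standardized subtraction image
#'
#' The subtraction image expressed in units of the standard deviation of
#' intensity change within normal-appearing brain tissue (the brain-tissue
#' mask excluding lesions), so that the activity threshold is comparable
#' across scanners and sites.
#'
#' @slot refMean,refSD mean and (sample) SD of the subtraction image within
#'   the reference mask, used for the conversion.
#' @slot maskProvenance character label identifying the reference mask.
#' @exportClass ZScoreMap
setClass("ZScoreMap", contains = "ImageVolume",
         representation(refMean = "numeric", refSD = "numeric",
                        maskProvenance = "character"),
         prototype(modality = "ZSCORE", maskProvenance = ""))

#' ActivityLabelMap: per-voxel lesion-change categories
#'
#' Integer-coded categorical grid: 0 none, 1 new, 2 enlarging, 3 shrinking,
#' 4 disappearing.
#'
#' @slot labels 3D integer array of category codes.
#' @slot voxelVolume voxel volume in mm^3.
#' @exportClass ActivityLabelMap
setClass("ActivityLabelMap",
         representation(labels = "array", voxelVolume = "numeric"))

setValidity("ActivityLabelMap", function(object) {
  if (!all(object@labels %in% 0:4))
    return("labels must be integer codes in 0..4")
  if (length(object@voxelVolume) != 1L || object@voxelVolume <= 0)
    return("voxelVolume must be a positive scalar")
  TRUE
})

#' Activity label codes
#'
#' Named integer vector mapping category names to the codes used in
#' [ActivityLabelMap-class] arrays and in exported NIfTI label maps.
#' @export
activityCodes <- c(none = 0L, new = 1L, enlarging = 2L, shrinking = 3L,
                   disappearing = 4L)

#' LesionChangeResult: per-category lesion volumes and TLVC
#'
#' Volumes are in mL.  Positive activity is new + enlarging, negative
#' activity is disappearing + shrinking, and the total lesion volume change
#' (TLVC) is positive minus negative activity.
#'
#' @slot volNew,volEnlarging,volShrinking,volDisappearing category volumes (mL).
#' @slot positiveActivity,negativeActivity,tlvc derived volumes (mL).
#' @slot excluded logical: TRUE when the field-of-view check flagged a
#'   lesion covered in only one visit (the interval should be excluded).
#' @exportClass LesionChangeResult
setClass("LesionChangeResult",
         representation(volNew = "numeric", volEnlarging = "numeric",
                        volShrinking = "numeric", volDisappearing = "numeric",
                        positiveActivity = "numeric",
                        negativeActivity = "numeric",
                        tlvc = "numeric", excluded = "logical"),
         prototype(excluded = FALSE))

setValidity("LesionChangeResult", function(object) {
  tol <- 1e-9
  pos <- object@volNew + object@volEnlarging
  neg <- object@volDisappearing + object@volShrinking
  if (abs(object@positiveActivity - pos) > tol)
    return("positiveActivity must equal new + enlarging")
  if (abs(object@negativeActivity - neg) > tol)
    return("negativeActivity must equal disappearing + shrinking")
  if (abs(object@tlvc - (pos - neg)) > tol)
    return("tlvc must equal positive minus negative activity")
  TRUE
})

#' PhantomConfig: parameters of a synthetic longitudinal study
#'
#' Describes the geometry, anatomy, artifact levels, per-visit motion and
#' atrophy, and the lesion schedule of one synthetic subject.  See
#' [phantomConfig()] for field semantics and defaults.
#'
#' @exportClass PhantomConfig
setClass("PhantomConfig",
         representation(gridShape = "integer", voxelSpacing = "numeric",
                        nVisits = "integer", lesionSpec = "list",
                        intensityMeans = "list", noiseSigma = "numeric",
                        oddEvenFactor = "numeric",
                        biasFieldAmplitude = "numeric",
                        motionSpec = "list", atrophySpec = "numeric",
                        seed = "integer"))

setValidity("PhantomConfig", function(object) {
  msg <- character()
  if (length(object@gridShape) != 3L || any(object@gridShape < 8L))
    msg <- c(msg, "gridShape: all dimensions must be >= 8")
  if (length(object@voxelSpacing) != 3L || any(object@voxelSpacing <= 0))
    msg <- c(msg, "voxelSpacing: all spacings must be > 0")
  if (object@nVisits < 2L)
    msg <- c(msg, "nVisits: at least 2 visits required")
  if (object@oddEvenFactor <= 0)
    msg <- c(msg, "oddEvenFactor: must be > 0")
  if (object@noiseSigma < 0)
    msg <- c(msg, "noiseSigma: must be >= 0")
  if (object@biasFieldAmplitude < 0)
    msg <- c(msg, "biasFieldAmplitude: must be >= 0")
  if (length(object@motionSpec) != object@nVisits)
    msg <- c(msg, "motionSpec: one 6-parameter set per visit required")
  if (length(object@atrophySpec) != object@nVisits)
    msg <- c(msg, "atrophySpec: one scale factor per visit required")
  if (any(object@atrophySpec <= 0))
    msg <- c(msg, "atrophySpec: scale factors must be > 0")
  if (length(msg)) msg else TRUE
})

#' SyntheticStudy: a generated longitudinal subject with ground truth
#'
#' @slot visits list (one element per visit) of lists with components
#'   `pd`, `t2`, `t1` ([ImageVolume-class]) and `brainMask`, `lesionMask`
#'   ([BinaryMask-class]).
#' @slot truth list with the true per-visit world transforms, per-interval
#'   category volumes and TLVC (mL), and the lesion inventory.
#' @slot config the generating [PhantomConfig-class].
#' @exportClass SyntheticStudy
setClass("SyntheticStudy",
         representation(visits = "list", truth = "list",
                        config = "PhantomConfig"))
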