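# The method's core: subtraction, Z-scoring, lesion-mask conditioning,
# three-situation activity classification, TLVC, and the field-of-view
# coverage check.

#' Voxelwise subtraction of the two halfway PD images
#'
#' Computes visit 2 minus visit 1, so an intensity increase over time
#' (e.g. a newly appearing hyperintense lesion) is positive.
#'
#' @param pd2Matched histogram-matched halfway PD of visit 2.
#' @param pd1 reference halfway PD of visit 1.
#' @return a SUBTRACTION [ImageVolume-class].
#' @export
subtractImages <- function(pd2Matched, pd1) {
  if (!all(dim(pd2Matched@data) == dim(pd1@data)))
    stop("data error: images are not on a common grid")
  new("ImageVolume", data = pd2Matched@data - pd1@data,
      affine = pd1@affine, modality = "SUBTRACTION")
}

#' Convert a subtraction image to Z-scores
#'
#' Standardizes by the mean and sample SD of the subtraction intensities
#' within the brain-tissue mask *excluding* the lesions, making the
#' activity threshold comparable across scanners and sites.  The Z
#' transform is applied to the whole image.
#'
#' @param subtraction the SUBTRACTION [ImageVolume-class].
#' @param brainTissueMask halfway brain-tissue [BinaryMask-class].
#' @param lesionMaskUnion union of both visits' conditioned lesion masks
#'   ([BinaryMask-class]); excluded from the reference region.
#' @return a [ZScoreMap-class].
#' @export
toZScores <- function(subtraction, brainTissueMask, lesionMaskUnion) {
  ref <- brainTissueMask@data > 0 & lesionMaskUnion@data == 0
  n <- sum(ref)
  if (n < 2)
    stop("statistics error: reference mask (tissue minus lesions) has ",
         "fewer than 2 voxels")
  v <- subtraction@data[ref]
  mu <- mean(v)
  sdv <- sd(v)                           # sample SD (n - 1)
  if (!is.finite(sdv) || sdv <= 0)
    stop("statistics error: zero variance in the reference region")
  new("ZScoreMap", data = (subtraction@data - mu) / sdv,
      affine = subtraction@affine, modality = "ZSCORE",
      refMean = mu, refSD = sdv,
      maskProvenance = "brain tissue excluding lesions")
}

#' Condition a manual lesion mask into halfway space
#'
#' The native-space manual mask is resampled with trilinear interpolation
#' (yielding a fractional mask), thresholded at >= 0.25 -- a deliberately
#' low cut that keeps lesion boundaries -- and isolated single voxels
#' within an image slice are removed (2D 8-connectivity).
#'
#' @param manualMask native-space binary lesion mask.
#' @param H the visit-to-halfway [AffineTransform-class].
#' @param grid the halfway sampling lattice.
#' @param threshold fractional-mask threshold (default 0.25).
#' @return a conditioned [BinaryMask-class] on the halfway grid, with
#'   attribute `emptied` set to TRUE if a nonempty input conditioned to an
#'   empty mask (a warning is also raised).
#' @export
conditionLesionMask <- function(manualMask, H, grid, threshold = 0.25) {
  frac <- resampleToHalfway(manualMask, H, grid, "trilinear")
  arr <- (frac@data >= threshold) + 0
  arr <- .removeInSliceSingletons(arr)
  emptied <- sum(manualMask@data) > 0 && sum(arr) == 0
  if (emptied)
    warning("conditioning emptied a nonempty lesion mask")
  out <- new("BinaryMask", data = arr, affine = grid$affine,
             modality = "MASK")
  attr(out, "emptied") <- emptied
  out
}

#' Pair lesion components across the two visits
#'
#' Lesions are identified as 3D 26-connected components of each visit's
#' conditioned halfway mask.  Each component falls into one of three
#' situations: a visit-2 component with no overlap against visit 1
#' (situation 1, candidate new lesion), a visit-1 component with no
#' overlap against visit 2 (situation 2, candidate disappearing lesion),
#' or a group of transitively overlapping components from both visits
#' (situation 3, changing lesion), whose combined region is the union of
#' all members.
#'
#' @param mask1Hw,mask2Hw conditioned halfway lesion masks.
#' @return list with `situation1`, `situation2` (lists of voxel-index
#'   vectors) and `situation3` (list of lists with `region`, `members1`,
#'   `members2`), plus the label arrays `labels1`, `labels2`.
#' @export
pairLesionComponents <- function(mask1Hw, mask2Hw) {
  lab1 <- .labelComponents(mask1Hw@data)
  lab2 <- .labelComponents(mask2Hw@data)
  n1 <- max(lab1); n2 <- max(lab2)
  # overlap graph between visit-1 and visit-2 components
  both <- lab1 > 0 & lab2 > 0
  pairs <- unique(cbind(lab1[both], lab2[both]))
  paired1 <- unique(pairs[, 1]); paired2 <- unique(pairs[, 2])
  situation1 <- lapply(setdiff(seq_len(n2), paired2),
                       function(cc) which(lab2 == cc))
  situation2 <- lapply(setdiff(seq_len(n1), paired1),
                       function(cc) which(lab1 == cc))
  situation3 <- list()
  if (nrow(pairs)) {
    # transitive closure over the bipartite overlap graph
    g <- igraph::make_graph(t(cbind(pairs[, 1], n1 + pairs[, 2])),
                            n = n1 + n2, directed = FALSE)
    comp <- igraph::components(g)$membership
    groups <- unique(comp[c(pairs[, 1], n1 + pairs[, 2])])
    for (grp in groups) {
      m1 <- which(comp[seq_len(n1)] == grp)
      m2 <- which(comp[n1 + seq_len(n2)] == grp)
      region <- which(array(lab1 %in% m1 | lab2 %in% m2, dim(lab1)))
      situation3[[length(situation3) + 1L]] <-
        list(region = region, members1 = m1, members2 = m2)
    }
  }
  list(situation1 = situation1, situation2 = situation2,
       situation3 = situation3, labels1 = lab1, labels2 = lab2)
}

#' Classify per-voxel lesion activity
#'
#' Situation-1 regions: voxels with Z above the threshold are "new".
#' Situation-2 regions: voxels with Z below the negative threshold are
#' "disappearing".  Situation-3 combined regions: Z above threshold is
#' "enlarging" unless the voxel lies in the eroded visit-1 mask, Z below
#' the negative threshold is "shrinking" unless in the eroded visit-2 mask
#' (enlargement cannot occur where the lesion already was, and shrinkage
#' cannot occur where it still is).  Comparisons are strict, so voxels
#' exactly at +/- the threshold stay "none".  Erosion is one iteration of
#' 2D in-slice 4-neighbour erosion of the conditioned masks.
#'
#' @param z a [ZScoreMap-class].
#' @param correspondence output of [pairLesionComponents()].
#' @param mask1Hw,mask2Hw conditioned halfway lesion masks.
#' @param zThreshold positive activity threshold (default 1.5).
#' @return an [ActivityLabelMap-class].
#' @export
classifyActivity <- function(z, correspondence, mask1Hw, mask2Hw,
                             zThreshold = 1.5) {
  if (zThreshold <= 0)
    stop("configuration error: zThreshold must be > 0")
  lab <- array(0L, dim(z@data))
  zv <- z@data
  for (vox in correspondence$situation1)
    lab[vox[zv[vox] > zThreshold]] <- activityCodes[["new"]]
  for (vox in correspondence$situation2)
    lab[vox[zv[vox] < -zThreshold]] <- activityCodes[["disappearing"]]
  if (length(correspondence$situation3)) {
    er1 <- .erodeInSlice(mask1Hw@data)
    er2 <- .erodeInSlice(mask2Hw@data)
    for (grp in correspondence$situation3) {
      vox <- grp$region
      up <- vox[zv[vox] > zThreshold & er1[vox] == 0]
      dn <- vox[zv[vox] < -zThreshold & er2[vox] == 0]
      lab[up] <- activityCodes[["enlarging"]]
      lab[dn] <- activityCodes[["shrinking"]]
    }
  }
  new("ActivityLabelMap", labels = lab,
      voxelVolume = abs(det(z@affine[1:3, 1:3])))
}

#' Total lesion volume change from an activity label map
#'
#' Category volumes are voxel counts times the voxel volume, reported in
#' mL; TLVC is (new + enlarging) minus (disappearing + shrinking).
#'
#' @param labels an [ActivityLabelMap-class].
#' @param excluded logical FOV-exclusion flag to carry through.
#' @return a [LesionChangeResult-class].
#' @export
computeTLVC <- function(labels, excluded = FALSE) {
  mL <- labels@voxelVolume / 1000
  counts <- tabulate(labels@labels[labels@labels > 0], nbins = 4L)
  volNew <- counts[activityCodes[["new"]]] * mL
  volEnl <- counts[activityCodes[["enlarging"]]] * mL
  volShr <- counts[activityCodes[["shrinking"]]] * mL
  volDis <- counts[activityCodes[["disappearing"]]] * mL
  new("LesionChangeResult", volNew = volNew, volEnlarging = volEnl,
      volShrinking = volShr, volDisappearing = volDis,
      positiveActivity = volNew + volEnl,
      negativeActivity = volDis + volShr,
      tlvc = (volNew + volEnl) - (volDis + volShr),
      excluded = excluded)
}

#' Field-of-view coverage check
#'
#' An interval must be excluded when, due to incomplete brain coverage,
#' a lesion is inside the field of view in one visit but not in the other.
#' The flag is raised when any conditioned lesion voxel of one visit lies
#' outside the other visit's field-of-view mask in halfway space.
#'
#' @param mask1Hw,mask2Hw conditioned halfway lesion masks.
#' @param fov1,fov2 halfway-space FOV masks (acquired-voxel masks of each
#'   visit, e.g. from [fovMask()]).
#' @return logical flag (TRUE = exclude the interval).
#' @export
checkFovCoverage <- function(mask1Hw, mask2Hw, fov1, fov2) {
  any(mask1Hw@data > 0 & fov2@data == 0) ||
    any(mask2Hw@data > 0 & fov1@data == 0)
}
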