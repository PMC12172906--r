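# Intensity comparability of the two halfway PD images: 0-1 range
# normalization, two-class brain/CSF segmentation of the halfway T2,
# tissue+lesion mask construction, and masked histogram matching.

#' Linearly normalize intensities to the 0-1 interval
#'
#' The image minimum maps to 0 and the maximum to 1.
#'
#' @param x an [ImageVolume-class] with a non-degenerate intensity range.
#' @param robust if `TRUE`, use the 1st/99th percentiles instead of the
#'   absolute extremes (then clamp to \[0, 1\]); default off.
#' @return normalized [ImageVolume-class].
#' @export
normalizeRange <- function(x, robust = FALSE) {
  v <- x@data
  r <- if (robust) quantile(v, c(0.01, 0.99), names = FALSE) else range(v)
  if (diff(r) <= 0)
    stop("normalization error: constant image (zero intensity range)")
  arr <- (v - r[1]) / (r[2] - r[1])
  if (robust) arr <- pmin(pmax(arr, 0), 1)
  new("ImageVolume", data = array(arr, dim(v)), affine = x@affine,
      modality = x@modality)
}

# Otsu threshold on a numeric vector (256-bin histogram)
.otsu <- function(v, nbins = 256L) {
  r <- range(v)
  if (diff(r) <= 0) return(NA_real_)
  h <- tabulate(.histBin(v, r[1], r[2], nbins), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  centers <- r[1] + (seq_len(nbins) - 0.5) / nbins * diff(r)
  mu <- cumsum(p * centers)
  muT <- mu[nbins]
  sigmaB <- (muT * omega - mu)^2 / (omega * (1 - omega))
  sigmaB[!is.finite(sigmaB)] <- 0
  centers[which.max(sigmaB)]
}

#' Segment the brain-masked T2 into brain tissue and CSF
#'
#' Two-class intensity segmentation (Otsu threshold on the within-mask
#' histogram); on T2-weighted images CSF is the brighter class, so the
#' class above the threshold is labeled CSF regardless of cluster order.
#' If the within-mask histogram is effectively unimodal (one class would
#' be nearly empty), a warning is issued and all voxels are assigned to
#' brain tissue with the `singleClass` attribute set.
#'
#' @param t2Halfway halfway-space T2 [ImageVolume-class].
#' @param brainMask halfway-space [BinaryMask-class].
#' @return list with `brainTissue` and `csf` ([BinaryMask-class], disjoint,
#'   union = brain mask).
#' @export
segmentBrainCsf <- function(t2Halfway, brainMask) {
  m <- brainMask@data > 0
  if (!any(m)) stop("segmentation error: empty brain mask")
  v <- t2Halfway@data[m]
  thr <- .otsu(v)
  singleClass <- FALSE
  if (is.na(thr) || min(mean(v > thr), mean(v <= thr)) < 0.01) {
    warning("segmentation warning: within-mask T2 histogram looks ",
            "unimodal; assigning a single brain-tissue class")
    thr <- Inf
    singleClass <- TRUE
  }
  csfArr <- array(0, dim(t2Halfway@data))
  csfArr[m & t2Halfway@data > thr] <- 1
  tissueArr <- (m & csfArr == 0) + 0
  out <- list(
    brainTissue = new("BinaryMask", data = array(tissueArr, dim(csfArr)),
                      affine = t2Halfway@affine, modality = "MASK"),
    csf = new("BinaryMask", data = csfArr, affine = t2Halfway@affine,
              modality = "MASK"))
  attr(out, "threshold") <- thr
  attr(out, "singleClass") <- singleClass
  out
}

#' Union of the brain-tissue class with both visits' lesion masks
#'
#' Lesions can be misassigned to the CSF class by the two-class
#' segmentation; adding the halfway-registered lesion masks of both visits
#' back to the brain-tissue class prevents their exclusion.
#'
#' @param tissue the output of [segmentBrainCsf()] (or any list with a
#'   `brainTissue` mask).
#' @param lesionHwV1,lesionHwV2 conditioned halfway lesion masks
#'   ([BinaryMask-class]).
#' @return a [BinaryMask-class]: brain tissue plus lesions.
#' @export
buildTissuePlusLesionMask <- function(tissue, lesionHwV1, lesionHwV2) {
  bt <- tissue$brainTissue
  if (!all(dim(bt@data) == dim(lesionHwV1@data)) ||
      !all(dim(bt@data) == dim(lesionHwV2@data)))
    stop("data error: masks are not on a common grid")
  arr <- (bt@data + lesionHwV1@data + lesionHwV2@data > 0) + 0
  new("BinaryMask", data = arr, affine = bt@affine, modality = "MASK")
}

#' Match the intensity histogram of one image to another
#'
#' A monotone piecewise-linear quantile mapping is estimated from the
#' within-mask voxels of the two images, mapping the second image's
#' quantiles onto the first's, and is then applied to the *entire* second
#' image (including voxels outside the mask).  Visit 1 is the reference
#' and is returned unchanged.
#'
#' Landmarks are placed at *interior* quantiles (default 1st to 90th
#' percentile); outside the landmark span the map continues linearly.
#' Pinning the extremes would force the images' hyperintense tails onto
#' each other, which destroys exactly the signal of interest when the
#' lesion load differs between visits; excluding the top tail from the
#' estimation matches the bulk (tissue/CSF) distribution while preserving
#' lesion contrast, the behavior of the histogram-matching filters used
#' in MS subtraction pipelines.
#'
#' @param pd1,pd2 0-1 normalized halfway PD volumes ([ImageVolume-class]).
#' @param mask the "brain tissue + lesions" [BinaryMask-class].
#' @param nLandmarks number of quantile landmarks (default 256).
#' @param probRange quantile range covered by the landmarks.
#' @return list with `pd1` (unchanged), `pd2` (remapped) and `transfer`,
#'   a two-column matrix (input level, mapped level) of the fitted
#'   transfer function.
#' @export
matchHistograms <- function(pd1, pd2, mask, nLandmarks = 256L,
                            probRange = c(0.01, 0.90)) {
  m <- mask@data > 0
  if (sum(m) < nLandmarks)
    stop("estimation error: mask smaller than the landmark count")
  probs <- seq(probRange[1], probRange[2], length.out = nLandmarks)
  q1 <- quantile(pd1@data[m], probs, names = FALSE, type = 7)
  q2 <- quantile(pd2@data[m], probs, names = FALSE, type = 7)
  q1 <- cummax(q1)                        # enforce a non-decreasing map
  # collapse duplicated source landmarks to keep approx() well defined
  keep <- !duplicated(q2)
  q2k <- q2[keep]; q1k <- q1[keep]
  if (length(q2k) < 2)
    stop("estimation error: degenerate within-mask intensity distribution")
  # overall span slope as the fallback linear extension beyond the
  # landmark range (piecewise-constant histograms can make the edge
  # segments flat)
  span <- (q1k[length(q1k)] - q1k[1]) / (q2k[length(q2k)] - q2k[1])
  if (!is.finite(span) || span <= 0) span <- 1
  x <- as.vector(pd2@data)
  mapped <- approx(q2k, q1k, xout = x, rule = 2)$y
  lo <- x < q2k[1]; hi <- x > q2k[length(q2k)]
  mapped[lo] <- q1k[1] + span * (x[lo] - q2k[1])
  mapped[hi] <- q1k[length(q1k)] + span * (x[hi] - q2k[length(q2k)])
  out2 <- new("ImageVolume", data = array(mapped, dim(pd2@data)),
              affine = pd2@affine, modality = pd2@modality)
  list(pd1 = pd1, pd2 = out2, transfer = cbind(input = q2k, mapped = q1k))
}
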