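# Intensity-based affine registration.
#
# Transforms are estimated in world coordinates (mm/degrees) by direct
# search (Nelder-Mead) over a two-level resolution pyramid, maximizing
# either normalized mutual information (different-contrast pairs, e.g.
# T1 to T2) or the masked correlation ratio (same-contrast inter-visit
# pairs, brain masks as weights).  All interpolation inside the metric is
# trilinear; the returned transform maps fixed-space world points to
# moving-space world points (resampling convention).

.histBin <- function(v, lo, hi, nbins) {
  b <- floor((v - lo) / (hi - lo) * nbins) + 1L
  pmin.int(pmax.int(b, 1L), nbins)
}

# normalized mutual information (Studholme), weights >= 0
.metricNMI <- function(f, m, w, frange, mrange, nbins = 32L) {
  bf <- .histBin(f, frange[1], frange[2], nbins)
  bm <- .histBin(m, mrange[1], mrange[2], nbins)
  joint <- rowsum(w, group = bf + nbins * (bm - 1L))
  p <- joint / sum(joint)
  pidx <- as.integer(rownames(joint))
  bfj <- ((pidx - 1L) %% nbins) + 1L
  bmj <- ((pidx - 1L) %/% nbins) + 1L
  pf <- rowsum(p, bfj); pm <- rowsum(p, bmj)
  hj <- -sum(p * log(p))
  hf <- -sum(pf * log(pf)); hm <- -sum(pm * log(pm))
  (hf + hm) / hj
}

# correlation ratio eta^2 of moving given binned fixed intensities
.metricCR <- function(f, m, w, frange, nbins = 64L) {
  bf <- .histBin(f, frange[1], frange[2], nbins)
  sw <- rowsum(w, bf)
  sm <- rowsum(w * m, bf)
  sm2 <- rowsum(w * m * m, bf)
  n <- sum(sw)
  mu <- sum(sm) / n
  vtot <- sum(sm2) / n - mu^2
  if (vtot <= 0) return(0)
  vwithin <- sum(sm2 - sm^2 / pmax(sw, 1e-12)) / n
  1 - vwithin / vtot
}

.metricValue <- function(metric, f, m, w, frange, mrange) {
  if (metric == "nmi") .metricNMI(f, m, w, frange, mrange)
  else .metricCR(f, m, w, frange)
}

# separable [1 2 1]/4 smoothing along all three axes (replicated borders);
# registration evaluates its metric on mildly smoothed images, which
# suppresses interpolation-alias bias of the metric optimum
.smooth3 <- function(a) {
  d <- dim(a)
  w <- c(0.25, 0.5, 0.25)
  for (ax in 1:3) {
    if (d[ax] < 3) next
    a2 <- a
    a <- a * w[2]
    i <- seq_len(d[ax] - 1)
    if (ax == 1) {
      a[i + 1, , ] <- a[i + 1, , ] + w[1] * a2[i, , ]
      a[i, , ] <- a[i, , ] + w[3] * a2[i + 1, , ]
      a[1, , ] <- a[1, , ] + w[1] * a2[1, , ]
      a[d[1], , ] <- a[d[1], , ] + w[3] * a2[d[1], , ]
    } else if (ax == 2) {
      a[, i + 1, ] <- a[, i + 1, ] + w[1] * a2[, i, ]
      a[, i, ] <- a[, i, ] + w[3] * a2[, i + 1, ]
      a[, 1, ] <- a[, 1, ] + w[1] * a2[, 1, ]
      a[, d[2], ] <- a[, d[2], ] + w[3] * a2[, d[2], ]
    } else {
      a[, , i + 1] <- a[, , i + 1] + w[1] * a2[, , i]
      a[, , i] <- a[, , i] + w[3] * a2[, , i + 1]
      a[, , 1] <- a[, , 1] + w[1] * a2[, , 1]
      a[, , d[3]] <- a[, , d[3]] + w[3] * a2[, , d[3]]
    }
  }
  a
}

.maskCentroid <- function(image, weights) {
  w <- as.vector(weights)
  d <- dim(image@data)
  idx <- arrayInd(which(w > 0), d) - 1
  ww <- w[w > 0]
  vox <- colSums(idx * ww) / sum(ww)
  (image@affine %*% c(vox, 1))[1:3]
}

# single-level metric evaluation factory; samples the moving image at the
# within-mask fixed voxels only, with histogram accumulation in C++
.levelCost <- function(fixed, moving, weights, metric, dof, center,
                       mrange, interp = 1L) {
  w0 <- as.vector(weights)
  sel <- which(w0 > 0)
  fvals <- as.vector(fixed@data)[sel]
  frange <- range(fvals)
  if (diff(frange) <= 0) stop("registration error: fixed image is ",
                              "constant within the weight mask")
  nbf <- if (metric == "nmi") 32L else 64L
  nbm <- 32L
  fbin <- .histBin(fvals, frange[1], frange[2], nbf)
  pts <- arrayInd(sel, dim(fixed@data)) - 1
  storage.mode(pts) <- "double"
  w <- w0[sel]
  fixAff <- fixed@affine
  movAffInv <- solve(moving@affine)
  metricCode <- if (metric == "nmi") 0L else 1L
  mdata <- as.double(moving@data)
  mdim <- dim(moving@data)
  function(p) {
    tr <- .vecToTransform(p, dof, center)
    vmat <- movAffInv %*% tr@matrix %*% fixAff
    r <- .c_metric(mdata, mdim, vmat, pts, fbin, w, nbf, nbm,
                   mrange[1], mrange[2], metricCode, interp)
    if (r$massFraction < 0.5 || is.na(r$value)) return(1e6)
    -r$value
  }
}

.registerImages <- function(fixed, moving, weights, dof = 6L,
                            metric = c("cr", "nmi"),
                            metricFloor = -Inf) {
  metric <- match.arg(metric)
  if (is(weights, "ImageVolume")) weights <- weights@data
  center <- .maskCentroid(fixed, weights)
  fixed <- new("ImageVolume", data = .smooth3(fixed@data),
               affine = fixed@affine, modality = fixed@modality)
  moving <- new("ImageVolume", data = .smooth3(moving@data),
                affine = moving@affine, modality = moving@modality)
  mrange <- range(moving@data)
  if (diff(mrange) <= 0) stop("registration error: moving image is constant")
  # initial translation from the intensity/mask centroids
  movCentroid <- .maskCentroid(moving, array(pmax(moving@data, 0),
                                             dim(moving@data)))
  fixCentroid <- .maskCentroid(fixed, weights * pmax(fixed@data, 0))
  p0 <- c(rep(0, 3), movCentroid - fixCentroid,
          if (dof == 12L) rep(0, 6) else NULL)

  # coarse level: 2x in-plane block averaging
  fC <- .downsampleVolume(fixed, c(2, 2, 1))
  mC <- .downsampleVolume(moving, c(2, 2, 1))
  wC <- .downsampleVolume(new("ImageVolume", data = weights,
                              affine = fixed@affine, modality = "MASK"),
                          c(2, 2, 1))@data
  parscaleC <- c(rep(2, 3), rep(2, 3),
                 if (dof == 12L) rep(0.02, 6) else NULL)
  costC <- .levelCost(fC, mC, wC, metric, dof, center, mrange)
  optC <- optim(p0, costC, method = "Nelder-Mead",
                control = list(maxit = 600, reltol = 1e-10,
                               parscale = parscaleC))
  # full resolution, two Nelder-Mead passes (restart refreshes the simplex)
  costF <- .levelCost(fixed, moving, weights, metric, dof, center, mrange)
  parscaleF <- c(rep(0.5, 3), rep(0.5, 3),
                 if (dof == 12L) rep(0.005, 6) else NULL)
  optF <- optim(optC$par, costF, method = "Nelder-Mead",
                control = list(maxit = 400, reltol = 1e-12,
                               parscale = parscaleF))
  # final pass with windowed-sinc interpolation inside the metric:
  # trilinear interpolation error biases the metric optimum by a few
  # hundredths of a voxel, which matters for subtraction imaging
  costS <- .levelCost(fixed, moving, weights, metric, dof, center,
                      mrange, interp = 2L)
  optF <- optim(optF$par, costS, method = "Nelder-Mead",
                control = list(maxit = 300, reltol = 1e-12,
                               parscale = parscaleF / 5))
  value <- -optF$value
  if (value < metricFloor)
    stop(sprintf("registration error: final %s metric %.4f below floor %.4f",
                 metric, value, metricFloor))
  out <- .vecToTransform(optF$par, dof, center)
  attr(out, "metric") <- value
  attr(out, "parameters") <- optF$par
  out
}

#' Register the T1-weighted image to the T2-weighted image
#'
#' Rigid-body (6 degrees of freedom) registration maximizing normalized
#' mutual information, suitable for the different tissue contrasts of the
#' two sequences.  The returned transform maps T2-space world points to
#' T1-space world points (resampling convention), so it can be applied
#' directly to pull the T1-space brain mask onto the T2 grid.
#'
#' @param t1,t2 [ImageVolume-class] volumes with overlapping fields of view.
#' @param weights optional weight/mask array on the T2 grid; default all 1.
#' @param metricFloor minimum acceptable final NMI (registration of
#'   structured brain images reaches well above this; unrelated or pure
#'   noise inputs do not).
#' @return an [AffineTransform-class] with attributes `metric` (final NMI)
#'   and `parameters`.
#' @export
registerT1ToT2 <- function(t1, t2, weights = NULL, metricFloor = 1.02) {
  if (is.null(weights)) weights <- array(1, dim(t2@data))
  .registerImages(fixed = t2, moving = t1, weights = weights, dof = 6L,
                  metric = "nmi", metricFloor = metricFloor)
}

#' Inter-visit affine registration in both directions
#'
#' 12-degrees-of-freedom affine registration of the two visits' T2-weighted
#' images maximizing the correlation ratio, with the brain masks as
#' weights, run independently in both directions as in the halfway-space
#' construction.
#'
#' @param t2v1,t2v2 preprocessed T2 volumes of visit 1 and 2.
#' @param mask1,mask2 [BinaryMask-class] brain masks on the respective
#'   grids.
#' @return list with `A12` (visit-1 -> visit-2 world map) and `A21`
#'   (visit-2 -> visit-1), each carrying `metric`/`parameters` attributes.
#' @export
registerVisits <- function(t2v1, t2v2, mask1, mask2) {
  if (sum(mask1@data) == 0 || sum(mask2@data) == 0)
    stop("registration error: empty brain mask")
  A12 <- .registerImages(fixed = t2v1, moving = t2v2, weights = mask1@data,
                         dof = 12L, metric = "cr", metricFloor = 0.2)
  A21 <- .registerImages(fixed = t2v2, moving = t2v1, weights = mask2@data,
                         dof = 12L, metric = "cr", metricFloor = 0.2)
  list(A12 = A12, A21 = A21)
}
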