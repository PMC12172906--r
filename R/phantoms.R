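# Synthetic longitudinal brain phantoms with known ground truth.
#
# The anatomy is a nested-ellipsoid head: a "skull" shell around a brain
# ellipsoid whose outer 2.5 mm is a CSF rim, two ventricular CSF
# ellipsoids, and spherical white-matter lesions whose radius follows a
# per-visit schedule (0 = absent).  Classes are piecewise-constant in
# intensity per modality; lesions are hyperintense on PD/T2.  Later visits
# apply a rigid repositioning and a global linear "atrophy" scale, both of
# which are analytic, so the true inter-visit affine is exactly known.

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

.defaultIntensityMeans <- function() {
  # arbitrary-unit class means chosen to mimic 1.5T spin-echo contrast:
  # CSF mildly hyperintense to tissue on PD, strongly on T2; lesions
  # hyperintense on PD/T2 and mildly hypointense on T1.  Order matches
  # the internal class codes: background, skull, csf, tissue, lesion.
  list(pd = c(background = 0, skull = 30, csf = 125, tissue = 100,
              lesion = 150),
       t2 = c(background = 0, skull = 25, csf = 200, tissue = 100,
              lesion = 160),
       t1 = c(background = 0, skull = 40, csf = 35, tissue = 100,
              lesion = 80))
}

#' Configure a synthetic longitudinal subject
#'
#' @param gridShape voxels per axis (default 64 x 64 x 16).
#' @param voxelSpacing voxel size in mm (default 1 x 1 x 3, axial slices).
#' @param nVisits number of visits (>= 2).
#' @param lesionSpec list of lesions, each a list with `center` (subject
#'   world mm), `schedule` (radius in mm per visit, 0 = absent).  Default
#'   `NULL` draws a random inventory with [randomLesionSpec()].
#' @param intensityMeans per-modality named class-mean vectors
#'   (`background`, `skull`, `tissue`, `csf`, `lesion`).
#' @param noiseSigma additive Gaussian noise SD (default 2, about 2% of
#'   tissue signal).
#' @param oddEvenFactor multiplicative intensity ratio applied to odd
#'   slices (0-based along the third, axial axis; default 1.05).
#' @param biasFieldAmplitude relative amplitude of the smooth multiplicative
#'   bias field (default 0.1).
#' @param motionSpec list of per-visit rigid parameters
#'   `c(rx, ry, rz, tx, ty, tz)` (deg, mm).  Default `NULL` draws visit-1
#'   identity and later visits uniformly within +/-1 deg about the in-plane
#'   axes, +/-3 deg about the slice axis, +/-3 mm in-plane and +/-1.5 mm
#'   through-plane (typical repositioning for a 2D axial protocol).
#' @param atrophySpec per-visit global linear scale factor (1 = no change).
#'   Default 1 for every visit.
#' @param seed integer RNG seed; identical config + seed gives bit-identical
#'   studies.
#' @return a validated [PhantomConfig-class].
#' @export
phantomConfig <- function(gridShape = c(64L, 64L, 16L),
                          voxelSpacing = c(1, 1, 3),
                          nVisits = 2L,
                          lesionSpec = NULL,
                          intensityMeans = .defaultIntensityMeans(),
                          noiseSigma = 2,
                          oddEvenFactor = 1.05,
                          biasFieldAmplitude = 0.1,
                          motionSpec = NULL,
                          atrophySpec = NULL,
                          seed = 1L) {
  gridShape <- as.integer(gridShape)
  nVisits <- as.integer(nVisits)
  # basic field checks up front, before defaults are generated from them
  if (length(gridShape) != 3L || any(gridShape < 8L))
    stop("configuration error: gridShape: all dimensions must be >= 8")
  if (length(voxelSpacing) != 3L || any(voxelSpacing <= 0))
    stop("configuration error: voxelSpacing: all spacings must be > 0")
  if (nVisits < 2L)
    stop("configuration error: nVisits: at least 2 visits required")
  if (oddEvenFactor <= 0)
    stop("configuration error: oddEvenFactor: must be > 0")
  if (noiseSigma < 0)
    stop("configuration error: noiseSigma: must be >= 0")
  if (biasFieldAmplitude < 0)
    stop("configuration error: biasFieldAmplitude: must be >= 0")
  if (is.null(motionSpec))
    motionSpec <- .withSeed(seed * 7 + 1, {
      c(list(rep(0, 6)),
        replicate(max(nVisits - 1L, 0L), c(runif(2, -1, 1), runif(1, -3, 3),
                                           runif(2, -3, 3), runif(1, -1.5, 1.5)),
                  simplify = FALSE))
    })
  if (is.null(atrophySpec)) atrophySpec <- rep(1, nVisits)
  if (is.null(lesionSpec))
    lesionSpec <- randomLesionSpec(nVisits = nVisits, seed = seed * 7 + 2,
                                   gridShape = gridShape,
                                   voxelSpacing = voxelSpacing)
  new("PhantomConfig", gridShape = gridShape,
      voxelSpacing = as.numeric(voxelSpacing), nVisits = nVisits,
      lesionSpec = lesionSpec, intensityMeans = intensityMeans,
      noiseSigma = noiseSigma, oddEvenFactor = oddEvenFactor,
      biasFieldAmplitude = biasFieldAmplitude, motionSpec = motionSpec,
      atrophySpec = atrophySpec, seed = as.integer(seed))
}

# geometric constants of the phantom head, relative to the field of view
.anatomyParams <- function(gridShape, voxelSpacing) {
  fov <- gridShape * voxelSpacing
  list(headSemi = 0.46 * fov,
       brainSemi = 0.40 * fov,
       rim = 2.5,                       # CSF rim thickness, mm
       ventSemi = c(5, 9, 5),           # per-ventricle semi-axes, mm
       ventCenters = list(c(-8, 4, 0), c(8, 4, 0)))
}

# default grid affine: spacing on the diagonal, world origin at the grid
# center (RAS-like axes)
.gridAffine <- function(gridShape, voxelSpacing) {
  a <- diag(c(voxelSpacing, 1))
  a[1:3, 4] <- -(gridShape - 1) / 2 * voxelSpacing
  a
}

#' Draw a random lesion inventory
#'
#' Places `nLesions` non-overlapping spherical lesions inside the tissue
#' region (away from the ventricles and the CSF rim) and assigns each a
#' behavior cycling through new, disappearing, enlarging, shrinking and
#' stable, so every classification branch has a ground-truth exemplar.
#' Each changing lesion transitions at one randomly chosen interval.
#'
#' @param nVisits number of visits.
#' @param nLesions number of lesions (default 5).
#' @param seed RNG seed.
#' @param gridShape,voxelSpacing phantom geometry (for placement bounds).
#' @param radiusRange baseline radius range in mm.
#' @param growth radial growth (mm) for enlarging/shrinking lesions.
#' @param behaviors character vector of per-lesion behaviors (recycled to
#'   `nLesions`), from `"new"`, `"disappearing"`, `"enlarging"`,
#'   `"shrinking"`, `"stable"`.  The default cycles through all of them;
#'   recovery experiments typically rotate positive- and
#'   negative-dominant sets so each subject has a nonzero net change.
#' @return a `lesionSpec` list for [phantomConfig()].
#' @export
randomLesionSpec <- function(nVisits, nLesions = 4L, seed = 1L,
                             gridShape = c(64L, 64L, 16L),
                             voxelSpacing = c(1, 1, 3),
                             radiusRange = c(3, 5), growth = 1.5,
                             behaviors = c("new", "disappearing",
                                           "enlarging", "shrinking",
                                           "stable")) {
  an <- .anatomyParams(gridShape, voxelSpacing)
  behaviors <- rep(behaviors, length.out = nLesions)
  .withSeed(seed, {
    # one angular sector per lesion (a crude stand-in for the scattered
    # periventricular distribution of MS lesions), jittered within the
    # sector, so disjoint placement succeeds for any seed
    centers <- list()
    radii <- numeric()
    reff <- numeric()                    # radius after any growth
    tissueSemi <- an$brainSemi - an$rim
    for (i in seq_len(nLesions)) {
      placed <- FALSE
      for (try in seq_len(500)) {
        r <- runif(1, radiusRange[1], radiusRange[2])
        re <- r + if (behaviors[i] %in% c("enlarging", "shrinking")) growth
                  else 0
        margin <- re + an$rim + 1
        theta <- 2 * pi * (i - 0.5 + runif(1, -0.35, 0.35)) / nLesions
        rho <- runif(1, 0.5, 0.92)
        p <- c(rho * (tissueSemi[1] - margin) * cos(theta),
               rho * (tissueSemi[2] - margin) * sin(theta),
               runif(1, -0.6, 0.6) * max(tissueSemi[3] - margin, 0.5))
        # keep the lesion *center* clear of the ventricles (partial
        # overlap is clipped to parenchyma when the mask is painted)
        nearVent <- any(vapply(an$ventCenters, function(vc)
          sqrt(sum(((p - vc) / (an$ventSemi + 2))^2)) < 1,
          logical(1)))
        if (nearVent) next
        tooClose <- any(vapply(seq_along(centers), function(j)
          sqrt(sum((p - centers[[j]])^2)) < (re + reff[j] + 2), logical(1)))
        if (tooClose) next
        centers[[i]] <- p
        radii <- c(radii, r)
        reff <- c(reff, re)
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place ", nLesions, " disjoint lesions; reduce ",
             "count or radii")
    }
    lapply(seq_len(length(centers)), function(i) {
      b <- behaviors[i]
      cut <- if (nVisits > 2L) sample(nVisits - 1L, 1L) else 1L
      r <- radii[i]
      schedule <- switch(b,
        stable = rep(r, nVisits),
        new = c(rep(0, cut), rep(r, nVisits - cut)),
        disappearing = c(rep(r, cut), rep(0, nVisits - cut)),
        enlarging = c(rep(r, cut), rep(r + growth, nVisits - cut)),
        shrinking = c(rep(r + growth, cut), rep(r, nVisits - cut)))
      list(center = centers[[i]], schedule = schedule, behavior = b)
    })
  })
}

# per-visit subject->visit world transform (motion o atrophy scale, both
# about the subject-space origin at the head center)
.visitTransform <- function(config, v) {
  m <- config@motionSpec[[v]]
  s <- config@atrophySpec[v]
  composeTransforms(
    paramsToTransform(rotations = m[1:3], translations = m[4:6]),
    paramsToTransform(scales = rep(s, 3)))@matrix
}

# evaluate class labels at subject-space points (n x 3), for visit v
# codes: 0 background, 1 skull, 2 csf, 3 tissue, 4 lesion
.classifyPoints <- function(p, config, v) {
  an <- .anatomyParams(config@gridShape, config@voxelSpacing)
  ell <- function(pts, semi, center = c(0, 0, 0))
    (sweep(pts, 2, center)[, 1] / semi[1])^2 +
    (sweep(pts, 2, center)[, 2] / semi[2])^2 +
    (sweep(pts, 2, center)[, 3] / semi[3])^2 <= 1
  cls <- integer(nrow(p))
  inHead <- ell(p, an$headSemi)
  inBrain <- ell(p, an$brainSemi)
  inTissueCore <- ell(p, an$brainSemi - an$rim)
  cls[inHead] <- 1L                       # skull shell
  cls[inBrain] <- 2L                      # CSF rim (brain minus core)
  cls[inTissueCore] <- 3L                 # parenchyma
  for (vc in an$ventCenters) {
    inVent <- ell(p, an$ventSemi, vc)
    cls[inTissueCore & inVent] <- 2L      # ventricular CSF
  }
  for (les in config@lesionSpec) {
    r <- les$schedule[v]
    if (r <= 0) next
    d2 <- (p[, 1] - les$center[1])^2 + (p[, 2] - les$center[2])^2 +
      (p[, 3] - les$center[3])^2
    cls[cls == 3L & d2 <= r^2] <- 4L      # lesions live in parenchyma
  }
  cls
}

# subject-space coordinates of every voxel of the visit grid (optionally
# offset by a subvoxel shift, in voxel units), given the visit's true
# world transform
.voxelSubjectCoords <- function(config, v, offset = c(0, 0, 0)) {
  gs <- config@gridShape
  aff <- .gridAffine(gs, config@voxelSpacing)
  idx <- as.matrix(expand.grid(i = seq_len(gs[1]) - 1 + offset[1],
                               j = seq_len(gs[2]) - 1 + offset[2],
                               k = seq_len(gs[3]) - 1 + offset[3]))
  world <- cbind(idx, 1) %*% t(aff)
  Tinv <- solve(.visitTransform(config, v))
  (world %*% t(Tinv))[, 1:3, drop = FALSE]
}

# separable smoothing with a custom 3-tap kernel along one axis
.convAxis <- function(a, w, ax) {
  d <- dim(a)
  if (d[ax] < 3) return(a)
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
  a
}

# per-modality clean intensities: partial-volume averaging (each voxel is
# the mean class intensity over a 3 x 3 x 3 subvoxel sample grid) followed
# by the acquisition point-spread function -- an in-plane PSF of about 1.2
# voxels FWHM emulating the k-space truncation of the acquisition matrix,
# and a mild through-plane slice-profile crosstalk.  Real MR images are
# (nearly) band-limited; without this the phantom's hard class edges alias
# under resampling in ways no acquired image would.
.cleanIntensities <- function(config, v) {
  gs <- config@gridShape
  means <- config@intensityMeans
  sub <- c(-1, 0, 1) / 3
  acc <- list(pd = 0, t2 = 0, t1 = 0)
  for (oz in sub) for (oy in sub) for (ox in sub) {
    p <- .voxelSubjectCoords(config, v, offset = c(ox, oy, oz))
    cls <- .classifyPoints(p, config, v)
    for (mod in names(acc))
      acc[[mod]] <- acc[[mod]] + means[[mod]][cls + 1L]
  }
  inplane <- c(0.12, 0.76, 0.12)
  through <- c(0.10, 0.80, 0.10)
  lapply(acc, function(a) {
    a <- array(a / 27, gs)
    a <- .convAxis(a, inplane, 1L)
    a <- .convAxis(a, inplane, 2L)
    .convAxis(a, through, 3L)
  })
}

#' Apply acquisition artifacts to a clean phantom image
#'
#' Scales the odd slices (0-based along the axial axis) by
#' `oddEvenFactor`, multiplies by a smooth low-frequency bias field of the
#' configured relative amplitude (a positive exponentiated second-order
#' polynomial, zero-mean over the grid), and adds Gaussian noise.  The
#' input volume is not modified.
#'
#' @param image an [ImageVolume-class] matching the config geometry.
#' @param config a [PhantomConfig-class]; its `seed` drives the bias-field
#'   coefficients and the noise.
#' @return a new [ImageVolume-class] with artifacts applied.
#' @export
applyAcquisitionArtifacts <- function(image, config) {
  if (!all(dim(image@data) == config@gridShape))
    stop("image geometry does not match config gridShape")
  if (!all(is.finite(image@data))) stop("non-finite input intensities")
  .withSeed(config@seed * 7 + 3,
            .applyArtifactsRNG(image, config))
}

# artifact application using the *current* RNG stream (so the generator can
# give each visit/modality an independent draw under one master seed)
.applyArtifactsRNG <- function(image, config) {
  arr <- image@data
  d <- dim(arr)
  # odd/even slice intensity imbalance (0-based slice index parity)
  odd0 <- which((seq_len(d[3]) - 1) %% 2 == 1)
  arr[, , odd0] <- arr[, , odd0] * config@oddEvenFactor
  # smooth multiplicative bias field
  if (config@biasFieldAmplitude > 0) {
    co <- rnorm(9)
    x <- seq(-1, 1, length.out = d[1])
    y <- seq(-1, 1, length.out = d[2])
    z <- seq(-1, 1, length.out = d[3])
    X <- array(rep(x, times = d[2] * d[3]), d)
    Y <- array(rep(rep(y, each = d[1]), times = d[3]), d)
    Z <- array(rep(z, each = d[1] * d[2]), d)
    poly <- co[1] * X + co[2] * Y + co[3] * Z + co[4] * X * Y +
      co[5] * X * Z + co[6] * Y * Z + co[7] * (X^2 - 1 / 3) +
      co[8] * (Y^2 - 1 / 3) + co[9] * (Z^2 - 1 / 3)
    poly <- poly / max(abs(poly), 1e-12)
    field <- exp(config@biasFieldAmplitude * (poly - mean(poly)))
    arr <- arr * field
  }
  if (config@noiseSigma > 0)
    arr <- arr + rnorm(length(arr), sd = config@noiseSigma)
  new("ImageVolume", data = arr, affine = image@affine,
      modality = image@modality)
}

#' Generate a synthetic longitudinal study
#'
#' Builds all visits of one synthetic subject: PD/T2/T1 volumes with
#' acquisition artifacts, the T1-space brain mask, the per-visit "manual"
#' lesion mask (the exact voxelization of the scheduled lesion spheres),
#' and a fully populated ground-truth block: true per-visit world
#' transforms, per-interval category volumes and TLVC (consecutive
#' intervals plus the direct first-to-last interval), and the lesion
#' inventory.
#'
#' @param config a [PhantomConfig-class].
#' @return a [SyntheticStudy-class].
#' @export
generateStudy <- function(config) {
  validObject(config)
  gs <- config@gridShape
  aff <- .gridAffine(gs, config@voxelSpacing)
  means <- config@intensityMeans
  .withSeed(config@seed, {
    visits <- vector("list", config@nVisits)
    lesionCounts <- matrix(0, nrow = length(config@lesionSpec),
                           ncol = config@nVisits)
    for (v in seq_len(config@nVisits)) {
      p <- .voxelSubjectCoords(config, v)
      cls <- .classifyPoints(p, config, v)   # voxel-center classes:
                                             # masks and truth volumes
      clean <- .cleanIntensities(config, v)  # partial-volume intensities
      pd <- new("ImageVolume", data = clean$pd, affine = aff,
                modality = "PD")
      t2 <- new("ImageVolume", data = clean$t2, affine = aff,
                modality = "T2")
      t1 <- new("ImageVolume", data = clean$t1, affine = aff,
                modality = "T1")
      pd <- .applyArtifactsRNG(pd, config)
      t2 <- .applyArtifactsRNG(t2, config)
      if (config@noiseSigma > 0)
        t1@data <- t1@data + rnorm(length(t1@data), sd = config@noiseSigma)
      an <- .anatomyParams(gs, config@voxelSpacing)
      # .voxelSubjectCoords already divides out motion and atrophy, so
      # brain membership uses the unscaled semi-axes
      inBrain <- (p[, 1] / an$brainSemi[1])^2 +
        (p[, 2] / an$brainSemi[2])^2 + (p[, 3] / an$brainSemi[3])^2 <= 1
      brainMask <- new("BinaryMask", data = array(inBrain + 0, gs),
                       affine = aff, modality = "MASK")
      lesArr <- array(0, gs)
      for (li in seq_along(config@lesionSpec)) {
        les <- config@lesionSpec[[li]]
        r <- les$schedule[v]
        if (r <= 0) next
        d2 <- (p[, 1] - les$center[1])^2 + (p[, 2] - les$center[2])^2 +
          (p[, 3] - les$center[3])^2
        vox <- d2 <= r^2 & cls == 4L
        lesionCounts[li, v] <- sum(vox)
        lesArr[array(vox, gs)] <- 1
      }
      lesionMask <- new("BinaryMask", data = lesArr, affine = aff,
                        modality = "MASK")
      visits[[v]] <- list(pd = pd, t2 = t2, t1 = t1, brainMask = brainMask,
                          lesionMask = lesionMask)
    }
    voxVol <- prod(config@voxelSpacing)
    intervals <- list()
    pairList <- lapply(seq_len(config@nVisits - 1L), function(v) c(v, v + 1L))
    if (config@nVisits > 2L)
      pairList <- c(pairList, list(c(1L, config@nVisits)))
    for (pr in pairList) {
      v <- pr[1]; w <- pr[2]
      volNew <- volEnl <- volShr <- volDis <- 0
      for (li in seq_len(nrow(lesionCounts))) {
        cv <- lesionCounts[li, v] * voxVol / 1000
        cw <- lesionCounts[li, w] * voxVol / 1000
        if (cv == 0 && cw > 0) volNew <- volNew + cw
        else if (cv > 0 && cw == 0) volDis <- volDis + cv
        else if (cw > cv) volEnl <- volEnl + (cw - cv)
        else if (cv > cw) volShr <- volShr + (cv - cw)
      }
      intervals[[paste0(v, "-", w)]] <-
        list(visits = c(v, w), volNew = volNew, volEnlarging = volEnl,
             volShrinking = volShr, volDisappearing = volDis,
             tlvc = (volNew + volEnl) - (volDis + volShr))
    }
    truth <- list(
      transforms = lapply(seq_len(config@nVisits), function(v)
        affineTransform(.visitTransform(config, v))),
      intervals = intervals,
      lesionInventory = lapply(seq_along(config@lesionSpec), function(li)
        c(config@lesionSpec[[li]],
          list(voxelCounts = lesionCounts[li, ]))),
      voxelVolume = voxVol)
    new("SyntheticStudy", visits = visits, truth = truth, config = config)
  })
}

#' True inter-visit registration of a phantom
#'
#' Returns the exact visit-`from` to visit-`to` world map (resampling
#' convention: fixed = `from`, moving = `to`) implied by the generating
#' motion and atrophy parameters.
#'
#' @param study a [SyntheticStudy-class].
#' @param from,to visit indices.
#' @return an [AffineTransform-class].
#' @export
trueRegistration <- function(study, from = 1L, to = 2L) {
  Tf <- study@truth$transforms[[from]]@matrix
  Tt <- study@truth$transforms[[to]]@matrix
  affineTransform(Tt %*% solve(Tf))
}

#' Write a study to NIfTI files plus a truth manifest
#'
#' Each visit goes into `visit<N>/` as `pd.nii.gz`, `t2.nii.gz`,
#' `t1.nii.gz`, `brain_mask.nii.gz`, `lesion_mask.nii.gz`; the ground
#' truth (4x4 row-major transforms, per-interval volumes in mL) is written
#' to `truth.json`.
#'
#' @param study a [SyntheticStudy-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (v in seq_along(study@visits)) {
    vd <- file.path(dir, paste0("visit", v))
    dir.create(vd, showWarnings = FALSE)
    b <- study@visits[[v]]
    writeImageVolume(b$pd, file.path(vd, "pd.nii.gz"))
    writeImageVolume(b$t2, file.path(vd, "t2.nii.gz"))
    writeImageVolume(b$t1, file.path(vd, "t1.nii.gz"))
    writeImageVolume(b$brainMask, file.path(vd, "brain_mask.nii.gz"))
    writeImageVolume(b$lesionMask, file.path(vd, "lesion_mask.nii.gz"))
  }
  tr <- study@truth
  manifest <- list(
    convention = "transforms map subject-space world points (mm) to visit-space world points; row-major",
    transforms = lapply(tr$transforms, function(t) t@matrix),
    intervals = tr$intervals,
    voxelVolume_mm3 = tr$voxelVolume)
  jsonlite::write_json(manifest, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(dir)
}

#' Build a cohort of phantom configurations
#'
#' Convenience wrapper producing `n` subject configs with per-subject seeds
#' derived from `seed`, sharing geometry and artifact settings.
#'
#' @param n number of subjects.
#' @param seed master seed; subject i uses `seed * 1000 + i`.
#' @param ... passed to [phantomConfig()].
#' @return list of [PhantomConfig-class].
#' @export
phantomCohort <- function(n, seed = 1L, ...) {
  lapply(seq_len(n), function(i)
    phantomConfig(seed = seed * 1000L + i, ...))
}

#' Noise- and artifact-free validation cohort configurations
#'
#' Study conditions for the ground-truth recovery and transitivity
#' experiments: 64 x 64 x 16 grids at 1 x 1 x 3 mm, no noise or
#' acquisition artifacts (artifact correction is validated separately),
#' typical repositioning motion, and per subject one large changing
#' lesion plus one stable lesion, alternating between positive activity
#' (new or enlarging) and negative activity (disappearing or shrinking)
#' across subjects, so every category is exemplified over the cohort
#' while each subject's true TLVC is well away from zero (a balanced
#' schedule would make relative recovery of the near-zero net change
#' ill-posed).  Changing-lesion radii are 5.5-7 mm: any boundary-counting
#' volumetry carries an uncertainty of a fraction of a voxel layer over
#' the lesion surface, so a 10%-relative recovery experiment needs
#' lesions whose surface-to-volume ratio keeps that shell below 10% --
#' with 1 x 1 x 3 mm voxels that means radii above roughly 5 mm.
#'
#' @param n number of subjects.
#' @param seed master seed.
#' @param nVisits visits per subject (2 for recovery, 3 for transitivity).
#' @return list of [PhantomConfig-class].
#' @export
validationCohort <- function(n, seed = 1L, nVisits = 2L) {
  sets <- list(c("new", "stable"), c("disappearing", "stable"),
               c("enlarging", "stable"), c("shrinking", "stable"))
  lapply(seq_len(n), function(i) {
    subseed <- seed * 1000L + i
    les <- randomLesionSpec(nVisits, nLesions = 2L, seed = subseed,
                            behaviors = sets[[(i %% 4) + 1L]],
                            radiusRange = c(5.5, 7), growth = 2)
    phantomConfig(nVisits = nVisits, lesionSpec = les, noiseSigma = 0,
                  oddEvenFactor = 1, biasFieldAmplitude = 0,
                  seed = subseed)
  })
}
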