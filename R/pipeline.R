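# End-to-end orchestration: preprocess -> inter-visit registration ->
# halfway resampling -> intensity matching -> subtraction -> Z-scores ->
# activity classification -> TLVC, for a visit pair and for a multi-visit
# study.

#' Pipeline configuration
#'
#' Defaults follow the method's published operating point: Z threshold
#' 1.5, lesion fractional-mask threshold 0.25.
#'
#' @param zThreshold activity threshold on the Z-score map (default 1.5).
#' @param maskThreshold threshold on the trilinearly resampled lesion
#'   masks (default 0.25).
#' @param histogramLandmarks quantile landmarks for histogram matching.
#' @param biasDegree polynomial degree of the bias-field model.
#' @param erosion erosion kernel for the enlarging/shrinking restriction;
#'   currently `"cross2d"` (one iteration of in-slice 4-neighbour erosion).
#' @param robustNormalize use percentile-based 0-1 normalization.
#' @param seed integer seed recorded in provenance (the pipeline itself is
#'   deterministic).
#' @return a named list of settings.
#' @export
pipelineConfig <- function(zThreshold = 1.5, maskThreshold = 0.25,
                           histogramLandmarks = 256L, biasDegree = 3L,
                           erosion = "cross2d", robustNormalize = FALSE,
                           seed = 1L) {
  if (zThreshold <= 0)
    stop("configuration error: zThreshold must be > 0")
  if (maskThreshold <= 0 || maskThreshold > 1)
    stop("configuration error: maskThreshold must be in (0, 1]")
  list(zThreshold = zThreshold, maskThreshold = maskThreshold,
       histogramLandmarks = as.integer(histogramLandmarks),
       biasDegree = as.integer(biasDegree), erosion = erosion,
       robustNormalize = robustNormalize, seed = as.integer(seed))
}

#' Load one visit from a directory of NIfTI files
#'
#' Expects `pd.nii.gz`, `t2.nii.gz`, `t1.nii.gz`, `brain_mask.nii.gz` and
#' `lesion_mask.nii.gz` (plain `.nii` also accepted).
#'
#' @param dir visit directory.
#' @return list with `pd`, `t2`, `t1`, `brainMask`, `lesionMask`.
#' @export
loadVisit <- function(dir) {
  pick <- function(stem) {
    for (f in file.path(dir, paste0(stem, c(".nii.gz", ".nii"))))
      if (file.exists(f)) return(f)
    stop("I/O error: missing input file ", file.path(dir, stem), "(.nii[.gz])")
  }
  list(pd = readImageVolume(pick("pd"), "PD"),
       t2 = readImageVolume(pick("t2"), "T2"),
       t1 = readImageVolume(pick("t1"), "T1"),
       brainMask = readImageVolume(pick("brain_mask"), mask = TRUE),
       lesionMask = readImageVolume(pick("lesion_mask"), mask = TRUE))
}

.checkVisit <- function(visit, label) {
  need <- c("pd", "t2", "t1", "brainMask", "lesionMask")
  missing <- setdiff(need, names(visit))
  if (length(missing))
    stop("I/O error: visit ", label, " is missing ",
         paste(missing, collapse = ", "))
  d <- dim(visit$pd@data)
  for (nm in need)
    if (!all(dim(visit[[nm]]@data) == d))
      stop("data error: visit ", label, " component ", nm,
           " has inconsistent geometry")
  invisible(TRUE)
}

# per-visit preprocessing: brain-mask propagation to the dual-echo grid,
# odd/even equalization and bias-field correction of the PD image
.preprocessVisit <- function(visit, config) {
  t1reg <- registerT1ToT2(visit$t1, visit$t2)
  brainMaskT2 <- propagateBrainMask(visit$brainMask, t1reg, visit$t2)
  pd <- correctOddEvenSlices(visit$pd, brainMaskT2)
  pd <- correctBiasField(pd, brainMaskT2, degree = config$biasDegree)
  list(pd = pd, t2 = visit$t2, brainMask = brainMaskT2,
       lesionMask = visit$lesionMask, t1Transform = t1reg)
}

#' Quantify lesion volume change between two visits
#'
#' Runs the full pipeline on a pair of visits: per-visit preprocessing,
#' 12-DOF inter-visit registration of the T2 images in both directions
#' (brain masks as weights), halfway-space computation and resampling
#' (sinc for images, nearest neighbour for brain masks, trilinear for
#' lesion masks), 0-1 normalization, brain/CSF segmentation, histogram
#' matching within the tissue+lesions mask, subtraction, Z-scoring against
#' normal-appearing tissue, lesion-mask conditioning, three-situation
#' activity classification and TLVC.
#'
#' @param visit1,visit2 visit bundles (see [loadVisit()]) or directories.
#' @param config a [pipelineConfig()] list.
#' @param outDir optional output directory for intermediates (NIfTI),
#'   transforms (JSON), the result (JSON) and a provenance record.
#' @param keepIntermediates write intermediate volumes when `outDir` is
#'   given (default TRUE).
#' @return list with `result` (a [LesionChangeResult-class]), `halfway`
#'   (the [HalfwaySpace-class]), `zmap`, `labels`, `registration`
#'   (`A12`/`A21`), the conditioned masks and the analysis masks.
#' @export
runPair <- function(visit1, visit2, config = pipelineConfig(),
                    outDir = NULL, keepIntermediates = TRUE) {
  if (is.character(visit1)) visit1 <- loadVisit(visit1)
  if (is.character(visit2)) visit2 <- loadVisit(visit2)
  .checkVisit(visit1, "1"); .checkVisit(visit2, "2")

  p1 <- .preprocessVisit(visit1, config)
  p2 <- .preprocessVisit(visit2, config)

  reg <- registerVisits(p1$t2, p2$t2, p1$brainMask, p2$brainMask)
  hw <- computeHalfway(reg$A12, reg$A21)
  # halfway sampling lattice: the visit-1 grid in its original world
  # position; each visit is pulled onto it through its half-transform, so
  # both images undergo genuine (and equal) interpolation -- aligning the
  # grid with the half-moved visit-1 axes would degenerate visit 1's
  # resampling into an exact voxel copy
  grid <- imageGrid(p1$pd)
  hw@grid <- grid

  pd1h <- resampleToHalfway(p1$pd, hw@H1, grid, "sinc")
  pd2h <- resampleToHalfway(p2$pd, hw@H2, grid, "sinc")
  t21h <- resampleToHalfway(p1$t2, hw@H1, grid, "sinc")
  bm1h <- resampleToHalfway(p1$brainMask, hw@H1, grid, "nearest")
  bm2h <- resampleToHalfway(p2$brainMask, hw@H2, grid, "nearest")
  les1h <- conditionLesionMask(p1$lesionMask, hw@H1, grid,
                               config$maskThreshold)
  les2h <- conditionLesionMask(p2$lesionMask, hw@H2, grid,
                               config$maskThreshold)

  # analysis brain mask: region covered by both propagated masks
  brainBoth <- new("BinaryMask",
                   data = (bm1h@data > 0 & bm2h@data > 0) + 0,
                   affine = grid$affine, modality = "MASK")
  seg <- segmentBrainCsf(t21h, brainBoth)
  tissueLesions <- buildTissuePlusLesionMask(seg, les1h, les2h)

  pd1n <- normalizeRange(pd1h, robust = config$robustNormalize)
  pd2n <- normalizeRange(pd2h, robust = config$robustNormalize)
  matched <- matchHistograms(pd1n, pd2n, tissueLesions,
                             config$histogramLandmarks)
  sub <- subtractImages(matched$pd2, matched$pd1)

  lesionUnion <- new("BinaryMask",
                     data = (les1h@data + les2h@data > 0) + 0,
                     affine = grid$affine, modality = "MASK")
  zmap <- toZScores(sub, seg$brainTissue, lesionUnion)

  fov1 <- fovMask(p1$pd, invertTransform(hw@H1), grid)
  fov2 <- fovMask(p2$pd, invertTransform(hw@H2), grid)
  excluded <- checkFovCoverage(les1h, les2h, fov1, fov2)

  corr <- pairLesionComponents(les1h, les2h)
  labels <- classifyActivity(zmap, corr, les1h, les2h, config$zThreshold)
  result <- computeTLVC(labels, excluded = excluded)

  out <- list(result = result, halfway = hw, registration = reg,
              zmap = zmap, labels = labels, subtraction = sub,
              pdHalfway = list(v1 = matched$pd1, v2 = matched$pd2),
              lesionMasksHw = list(v1 = les1h, v2 = les2h),
              segmentation = seg, tissuePlusLesions = tissueLesions,
              transfer = matched$transfer, config = config)
  if (!is.null(outDir))
    .writePairOutputs(out, outDir, keepIntermediates)
  out
}

.writePairOutputs <- function(out, outDir, keepIntermediates) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  v <- activityVolumes(out$result)
  jsonlite::write_json(
    list(volumes_mL = as.list(round(v, 3)),
         excluded = out$result@excluded),
    file.path(outDir, "result.json"), auto_unbox = TRUE, digits = NA)
  writeTransform(out$registration$A12, file.path(outDir, "A12.json"))
  writeTransform(out$registration$A21, file.path(outDir, "A21.json"))
  writeTransform(out$halfway@H1, file.path(outDir, "H1.json"))
  writeTransform(out$halfway@H2, file.path(outDir, "H2.json"))
  prov <- list(package = "PDsubtract",
               version = as.character(utils::packageVersion("PDsubtract")),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
               config = out$config)
  jsonlite::write_json(prov, file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  if (keepIntermediates) {
    writeImageVolume(out$zmap, file.path(outDir, "zmap.nii.gz"))
    writeImageVolume(out$subtraction,
                     file.path(outDir, "subtraction.nii.gz"))
    lab <- new("ImageVolume", data = out$labels@labels + 0,
               affine = out$zmap@affine, modality = "OTHER")
    writeImageVolume(lab, file.path(outDir, "activity_labels.nii.gz"))
    utils::write.csv(out$transfer,
                     file.path(outDir, "histogram_transfer.csv"),
                     row.names = FALSE)
  }
  invisible(outDir)
}

#' Run a multi-visit study: yearly and one-step TLVC
#'
#' For a subject with N >= 2 visits, computes the TLVC of every
#' consecutive visit pair plus the direct first-to-last one-step TLVC,
#' the multi-step TLVC (sum of the consecutive TLVCs), and the manual
#' lesion volume change (numerical difference of the first and last
#' manual lesion mask volumes).
#'
#' @param visits list of visit bundles (see [loadVisit()]).
#' @param config a [pipelineConfig()] list.
#' @param subject subject identifier carried into the output table.
#' @return list with `pairs` (per-consecutive-interval [runPair()]
#'   outputs), `oneStep` (first-to-last [runPair()] output) and
#'   `measurements`, a one-row data.frame with columns `subject`,
#'   `interval`, `tlvcOneStep`, `tlvcMultiStep`, `manualLvc`,
#'   `manualLesionVolumeAvg`, `excluded`, plus the per-interval yearly
#'   TLVCs as attribute `yearly`.
#' @export
runStudy <- function(visits, config = pipelineConfig(), subject = "s1") {
  n <- length(visits)
  if (n < 2) stop("at least 2 visits required")
  for (i in seq_len(n)) .checkVisit(visits[[i]], as.character(i))
  pairs <- lapply(seq_len(n - 1), function(v)
    runPair(visits[[v]], visits[[v + 1]], config))
  oneStep <- if (n > 2) runPair(visits[[1]], visits[[n]], config)
             else pairs[[1]]
  yearly <- vapply(pairs, function(p) tlvc(p$result), numeric(1))
  manualVol <- vapply(visits, function(v)
    sum(v$lesionMask@data) * voxelVolume(v$lesionMask) / 1000, numeric(1))
  meas <- data.frame(
    subject = subject,
    interval = paste0("1-", n),
    tlvcOneStep = tlvc(oneStep$result),
    tlvcMultiStep = multiStepTLVC(yearly),
    manualLvc = manualVol[n] - manualVol[1],
    manualLesionVolumeAvg = mean(manualVol[c(1, n)]),
    excluded = oneStep$result@excluded ||
      any(vapply(pairs, function(p) p$result@excluded, logical(1))),
    stringsAsFactors = FALSE)
  attr(meas, "yearly") <- yearly
  list(pairs = pairs, oneStep = oneStep, measurements = meas)
}
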