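# Small constructors for toy volumes and masks used across tests.

mkVol <- function(arr, spacing = c(1, 1, 3), modality = "PD") {
  d <- dim(arr)
  aff <- diag(c(spacing, 1))
  aff[1:3, 4] <- -(d - 1) / 2 * spacing
  new("ImageVolume", data = arr, affine = aff, modality = modality)
}

mkMask <- function(arr, spacing = c(1, 1, 3)) {
  d <- dim(arr)
  aff <- diag(c(spacing, 1))
  aff[1:3, 4] <- -(d - 1) / 2 * spacing
  new("BinaryMask", data = (arr > 0) + 0, affine = aff, modality = "MASK")
}

# a quick two-visit phantom for pipeline-level tests (small grid, cheap)
smallStudy <- function(seed = 11L, ...) {
  generateStudy(phantomConfig(seed = seed, ...))
}
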