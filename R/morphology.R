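# Small binary-morphology utilities on 3D voxel grids: connected-component
# labeling (3D 26-connectivity for lesion identification, 2D in-slice
# 8-connectivity for the singleton rule), in-slice erosion, and isolated
# voxel removal.  Component graphs are built over the mask voxels only and
# labeled with igraph.

.neighborOffsets3d26 <- local({
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ])
})

.neighborOffsets2d8 <- local({
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = 0)
  as.matrix(g[!(g$dx == 0 & g$dy == 0), ])
})

# label connected components of a logical/0-1 3D array; returns an integer
# array (0 = background, 1..n = component id)
.labelComponents <- function(mask, offsets = .neighborOffsets3d26) {
  d <- dim(mask)
  vox <- which(mask > 0)
  lab <- array(0L, d)
  if (length(vox) == 0) return(lab)
  coords <- arrayInd(vox, d)
  key <- function(co) co[, 1] + d[1] * ((co[, 2] - 1) + d[2] * (co[, 3] - 1))
  id <- seq_along(vox)
  k0 <- key(coords)
  edges <- integer(0)
  for (o in seq_len(nrow(offsets))) {
    nb <- coords
    nb[, 1] <- nb[, 1] + offsets[o, 1]
    nb[, 2] <- nb[, 2] + offsets[o, 2]
    nb[, 3] <- nb[, 3] + offsets[o, 3]
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    tgt <- match(key(nb[ok, , drop = FALSE]), k0)
    src <- id[ok]
    hit <- !is.na(tgt) & src < tgt   # each undirected edge once
    edges <- c(edges, rbind(src[hit], tgt[hit]))
  }
  if (length(edges)) {
    g <- igraph::make_graph(edges, n = length(vox), directed = FALSE)
    comp <- igraph::components(g)$membership
  } else comp <- seq_along(vox)
  lab[vox] <- as.integer(comp)
  lab
}

# remove connected components of exactly one voxel within each axial slice
# (2D 8-connectivity, per the in-slice singleton rule)
.removeInSliceSingletons <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (k in seq_len(d[3])) {
    sl <- array(mask[, , k], c(d[1], d[2], 1))
    lab <- .labelComponents(sl, .neighborOffsets2d8)
    if (max(lab) == 0) next
    sizes <- tabulate(lab[lab > 0])
    single <- which(sizes == 1L)
    if (length(single))
      out[, , k][lab[, , 1] %in% single] <- 0
  }
  out
}

# one iteration of 2D in-slice 4-neighbour (cross) erosion; voxels on the
# slice border erode away (outside counts as background)
.erodeInSlice <- function(mask) {
  d <- dim(mask)
  out <- array(0, d)
  if (d[1] < 3 || d[2] < 3) return(out)
  core <- 2:(d[1] - 1)
  corej <- 2:(d[2] - 1)
  for (k in seq_len(d[3])) {
    sl <- mask[, , k]
    keep <- sl[core, corej] > 0 &
      sl[core - 1, corej] > 0 & sl[core + 1, corej] > 0 &
      sl[core, corej - 1] > 0 & sl[core, corej + 1] > 0
    outk <- array(0, d[1:2])
    outk[core, corej][keep] <- 1
    out[, , k] <- outk
  }
  out
}
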