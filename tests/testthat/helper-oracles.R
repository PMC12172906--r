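# Independent brute-force oracles, written with plain loops and no package
# internals, for cross-checking connected components, erosion, and the
# activity-classification rules.

# flood-fill 3D connected-component labeling (26-connectivity)
oracleLabel3d <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nextLab <- 0L
  for (k0 in seq_len(d[3])) for (j0 in seq_len(d[2])) for (i0 in seq_len(d[1])) {
    if (mask[i0, j0, k0] > 0 && lab[i0, j0, k0] == 0L) {
      nextLab <- nextLab + 1L
      queue <- list(c(i0, j0, k0))
      lab[i0, j0, k0] <- nextLab
      while (length(queue)) {
        p <- queue[[length(queue)]]
        queue[[length(queue)]] <- NULL
        for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
          if (di == 0 && dj == 0 && dk == 0) next
          q <- p + c(di, dj, dk)
          if (any(q < 1) || q[1] > d[1] || q[2] > d[2] || q[3] > d[3]) next
          if (mask[q[1], q[2], q[3]] > 0 && lab[q[1], q[2], q[3]] == 0L) {
            lab[q[1], q[2], q[3]] <- nextLab
            queue[[length(queue) + 1L]] <- q
          }
        }
      }
    }
  }
  lab
}

# flood-fill 2D (8-connectivity) labeling of one slice
oracleLabel2d <- function(sl) {
  d <- dim(sl)
  lab <- matrix(0L, d[1], d[2])
  nextLab <- 0L
  for (j0 in seq_len(d[2])) for (i0 in seq_len(d[1])) {
    if (sl[i0, j0] > 0 && lab[i0, j0] == 0L) {
      nextLab <- nextLab + 1L
      queue <- list(c(i0, j0))
      lab[i0, j0] <- nextLab
      while (length(queue)) {
        p <- queue[[length(queue)]]
        queue[[length(queue)]] <- NULL
        for (di in -1:1) for (dj in -1:1) {
          if (di == 0 && dj == 0) next
          q <- p + c(di, dj)
          if (any(q < 1) || q[1] > d[1] || q[2] > d[2]) next
          if (sl[q[1], q[2]] > 0 && lab[q[1], q[2]] == 0L) {
            lab[q[1], q[2]] <- nextLab
            queue[[length(queue) + 1L]] <- q
          }
        }
      }
    }
  }
  lab
}

# in-slice 4-neighbour erosion, plain loops
oracleErode <- function(mask) {
  d <- dim(mask)
  out <- array(0, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (mask[i, j, k] > 0 && i > 1 && i < d[1] && j > 1 && j < d[2] &&
        mask[i - 1, j, k] > 0 && mask[i + 1, j, k] > 0 &&
        mask[i, j - 1, k] > 0 && mask[i, j + 1, k] > 0)
      out[i, j, k] <- 1
  }
  out
}

# in-slice singleton removal, plain loops
oracleRemoveSingletons <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (k in seq_len(d[3])) {
    lab <- oracleLabel2d(mask[, , k, drop = TRUE])
    if (max(lab) == 0) next
    for (cc in seq_len(max(lab)))
      if (sum(lab == cc) == 1L) out[, , k][lab == cc] <- 0
  }
  out
}

# full independent interpreter of the three-situation classification rules
# (codes: 0 none, 1 new, 2 enlarging, 3 shrinking, 4 disappearing)
oracleClassify <- function(z, mask1, mask2, thr = 1.5) {
  d <- dim(z)
  lab1 <- oracleLabel3d(mask1)
  lab2 <- oracleLabel3d(mask2)
  n1 <- max(lab1); n2 <- max(lab2)
  overlap <- matrix(FALSE, max(n1, 1), max(n2, 1))
  if (n1 > 0 && n2 > 0)
    for (v in which(lab1 > 0 & lab2 > 0))
      overlap[lab1[v], lab2[v]] <- TRUE
  # transitive closure of the overlap relation via repeated expansion
  grp1 <- seq_len(n1); grp2 <- rep(0L, n2)
  if (n1 > 0 && n2 > 0) {
    repeat {
      changed <- FALSE
      for (a in seq_len(n1)) for (b in seq_len(n2)) {
        if (!overlap[a, b]) next
        if (grp2[b] == 0L) { grp2[b] <- grp1[a]; changed <- TRUE }
        else if (grp2[b] != grp1[a]) {
          old <- max(grp1[a], grp2[b]); newg <- min(grp1[a], grp2[b])
          grp1[grp1 == old] <- newg; grp2[grp2 == old] <- newg
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  er1 <- oracleErode(mask1)
  er2 <- oracleErode(mask2)
  out <- array(0L, d)
  paired1 <- if (n1 > 0 && n2 > 0) which(apply(overlap, 1, any)) else integer(0)
  paired2 <- if (n1 > 0 && n2 > 0) which(apply(overlap, 2, any)) else integer(0)
  # situation 1: visit-2 components with no overlap
  for (b in setdiff(seq_len(n2), paired2))
    for (v in which(lab2 == b))
      if (z[v] > thr) out[v] <- 1L
  # situation 2: visit-1 components with no overlap
  for (a in setdiff(seq_len(n1), paired1))
    for (v in which(lab1 == a))
      if (z[v] < -thr) out[v] <- 4L
  # situation 3: transitively overlapping groups, combined region = union
  if (length(paired1)) {
    for (g in unique(grp1[paired1])) {
      m1 <- which(grp1 == g & seq_len(n1) %in% paired1)
      m2 <- which(grp2 == g)
      region <- which(array(lab1 %in% m1 | lab2 %in% m2, d))
      for (v in region) {
        if (z[v] > thr && er1[v] == 0) out[v] <- 2L
        else if (z[v] < -thr && er2[v] == 0) out[v] <- 3L
      }
    }
  }
  out
}

# ICC(A,1) oracle: ANOVA mean squares from aov(), then the
# two-way-random absolute-agreement single-measures formula
oracleICC <- function(x, y) {
  n <- length(x)
  df <- data.frame(val = c(x, y),
                   subj = factor(rep(seq_len(n), 2)),
                   rater = factor(rep(1:2, each = n)))
  ms <- summary(aov(val ~ subj + rater, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  k <- 2
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

# consistency ICC(C,1) on the same mean squares, for contrast with the
# absolute-agreement variant
oracleConsistencyICC <- function(x, y) {
  n <- length(x)
  df <- data.frame(val = c(x, y),
                   subj = factor(rep(seq_len(n), 2)),
                   rater = factor(rep(1:2, each = n)))
  ms <- summary(aov(val ~ subj + rater, data = df))[[1]][["Mean Sq"]]
  (ms[1] - ms[3]) / (ms[1] + ms[3])
}
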