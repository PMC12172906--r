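#' Construct an AffineTransform
#'
#' @param matrix a 4x4 homogeneous matrix with bottom row (0,0,0,1).
#' @return an [AffineTransform-class].
#' @export
affineTransform <- function(matrix = diag(4)) {
  new("AffineTransform", matrix = unname(as.matrix(matrix)))
}

#' @describeIn affineTransform identity transform.
#' @export
identityTransform <- function() affineTransform(diag(4))

#' Compose and invert affine transforms
#'
#' `composeTransforms(a, b)` returns the transform applying `b` first and
#' then `a` (matrix product `a %*% b`); `invertTransform(a)` returns the
#' inverse map.
#'
#' @param a,b [AffineTransform-class] objects.
#' @return an [AffineTransform-class].
#' @export
composeTransforms <- function(a, b)
  affineTransform(a@matrix %*% b@matrix)

#' @rdname composeTransforms
#' @export
invertTransform <- function(a) affineTransform(solve(a@matrix))

#' Apply a transform to world points
#'
#' @param transform an [AffineTransform-class].
#' @param points n x 3 matrix of world coordinates (mm).
#' @return n x 3 matrix of mapped coordinates.
#' @export
applyTransform <- function(transform, points) {
  p <- cbind(as.matrix(points), 1)
  out <- p %*% t(transform@matrix)
  out[, 1:3, drop = FALSE]
}

# Rotation matrix (degrees) about the world axes, applied as Rz Ry Rx.
.rotationMatrix <- function(rx, ry, rz) {
  cx <- cos(rx * pi / 180); sx <- sin(rx * pi / 180)
  cy <- cos(ry * pi / 180); sy <- sin(ry * pi / 180)
  cz <- cos(rz * pi / 180); sz <- sin(rz * pi / 180)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Build a rigid or affine world transform from parameters
#'
#' Parameters are interpreted about a center of rotation `center` (world
#' mm): rotations in degrees (applied as Rz Ry Rx), translations in mm,
#' `scales` as per-axis linear factors and `shears` as the (xy, xz, yz)
#' entries of a unit upper-triangular matrix.
#'
#' @param rotations,translations numeric length-3 (deg, mm).
#' @param scales,shears numeric length-3.
#' @param center world-space center of rotation/scaling (mm).
#' @return an [AffineTransform-class].
#' @export
paramsToTransform <- function(rotations = c(0, 0, 0),
                              translations = c(0, 0, 0),
                              scales = c(1, 1, 1),
                              shears = c(0, 0, 0),
                              center = c(0, 0, 0)) {
  R <- .rotationMatrix(rotations[1], rotations[2], rotations[3])
  S <- diag(scales)
  H <- diag(3); H[1, 2] <- shears[1]; H[1, 3] <- shears[2]; H[2, 3] <- shears[3]
  L <- R %*% S %*% H
  m <- diag(4)
  m[1:3, 1:3] <- L
  m[1:3, 4] <- center + translations - L %*% center
  affineTransform(m)
}

# internal: optimizer parameter vector -> transform
.vecToTransform <- function(p, dof, center) {
  if (dof == 6L)
    paramsToTransform(p[1:3], p[4:6], center = center)
  else
    paramsToTransform(p[1:3], p[4:6], scales = exp(p[7:9]),
                      shears = p[10:12], center = center)
}

#' Compute the halfway space of two inter-visit registrations
#'
#' Given the visit-1-to-visit-2 registration `A12` and the independently
#' estimated reverse registration `A21` (both in the resampling convention:
#' `A12` maps visit-1 world points to visit-2 world points), the two are
#' symmetrized in the matrix-logarithm sense,
#' `M = expm((logm(A12) + logm(inverse(A21))) / 2)`, and each visit is
#' assigned "half" of `M`: `H1 = sqrtm(M)` maps visit 1 to the halfway
#' frame and `H2 = inverse(sqrtm(M))` maps visit 2 there.  For pure
#' translations or rotations this reduces exactly to halving the
#' parameters.  Both visits then suffer equal interpolation, as in the
#' SIENA halfway construction.
#'
#' @param A12,A21 [AffineTransform-class] registrations in the two
#'   directions.
#' @param grid optional halfway sampling lattice, a list with `dim`,
#'   `spacing`, `affine`.  Default (`NULL`) leaves the grid empty; pipeline
#'   code fills it with the visit-1 lattice carried into halfway space.
#' @return a [HalfwaySpace-class].
#' @export
computeHalfway <- function(A12, A21, grid = NULL) {
  m12 <- A12@matrix
  m21 <- A21@matrix
  if (det(m12[1:3, 1:3]) <= 0 || det(m21[1:3, 1:3]) <= 0)
    stop("halfway computation requires orientation-preserving transforms ",
         "(positive determinant)")
  # geometric mean of the two direction estimates (equals log-domain
  # averaging to second order in their discrepancy, and equals A12 exactly
  # when A21 is its inverse)
  M <- m12 %*% .sqrtm4(solve(m12) %*% solve(m21))
  H1 <- .sqrtm4(M)
  H2 <- .clean4(H1 %*% solve(M))   # = M^{-1/2}
  new("HalfwaySpace", H1 = affineTransform(H1), H2 = affineTransform(H2),
      grid = if (is.null(grid)) list() else grid)
}

.clean4 <- function(m) { m[4, ] <- c(0, 0, 0, 1); m }

# principal matrix square root by the Denman-Beavers iteration; valid for
# transforms without nonpositive real eigenvalues (rotations < 180 deg,
# positive scales), which inter-visit registrations always satisfy
.sqrtm4 <- function(m, maxit = 60L, tol = 1e-14) {
  Y <- m; Z <- diag(4)
  for (i in seq_len(maxit)) {
    Y1 <- 0.5 * (Y + solve(Z))
    Z1 <- 0.5 * (Z + solve(Y))
    if (max(abs(Y1 - Y)) < tol) { Y <- Y1; break }
    Y <- Y1; Z <- Z1
  }
  .clean4(Y)
}

#' Serialize / read transforms as JSON
#'
#' Transforms are written as 4x4 row-major world matrices together with a
#' statement of the convention (fixed-space points to moving-space points).
#'
#' @param transform an [AffineTransform-class].
#' @param path file path.
#' @export
writeTransform <- function(transform, path) {
  jsonlite::write_json(
    list(convention = "maps fixed-space world points (mm) to moving-space world points; row-major",
         matrix = transform@matrix),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname writeTransform
#' @export
readTransform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- x$matrix
  if (!is.matrix(m)) m <- matrix(unlist(m), 4, 4, byrow = TRUE)
  affineTransform(m)
}
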