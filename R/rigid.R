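#' @include AllClasses.R
NULL

#' Construct a rigid transform
#'
#' @param rotation 3 x 3 proper rotation matrix.
#' @param translation numeric(3), nm.
#' @return A [RigidTransform-class].
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation, translation = as.numeric(translation))
}

#' Apply a rigid transform to points
#'
#' @param transform a [RigidTransform-class].
#' @param points m x 3 matrix (or a [ParticleCloud-class]).
#' @param rotateOnly logical; if `TRUE` apply the rotation only (for versors).
#' @return Transformed points of the same class as the input.
#' @export
applyTransform <- function(transform, points, rotateOnly = FALSE) {
  if (is(points, "ParticleCloud")) {
    out <- points
    out@positions <- applyTransform(transform, points@positions, rotateOnly)
    return(out)
  }
  p <- points %*% t(transform@rotation)
  if (!rotateOnly) p <- sweep(p, 2, transform@translation, "+")
  dimnames(p) <- dimnames(points)
  p
}

#' Invert a rigid transform
#' @param transform a [RigidTransform-class].
#' @return The inverse [RigidTransform-class].
#' @export
invertTransform <- function(transform) {
  Rt <- t(transform@rotation)
  rigidTransform(Rt, -as.vector(Rt %*% transform@translation))
}

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the (weighted) RMSD
#' between `mobile` and `reference`. Reflections are excluded by the standard
#' sign correction on the smallest singular vector.
#'
#' @param mobile m x 3 matrix of points to move (nm).
#' @param reference m x 3 matrix of target points (nm).
#' @param weights optional nonnegative weights, length m.
#' @return list with `transform` (a [RigidTransform-class]) and `rmsd` (nm),
#'   the attained minimum.
#' @examples
#' pts <- matrix(rnorm(30), 10, 3)
#' fit <- kabschSuperpose(pts, pts)
#' fit$rmsd  # 0
#' @export
kabschSuperpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)))
    stop("kabschSuperpose: point sets differ in shape")
  m <- nrow(mobile)
  if (m < 3) stop("kabschSuperpose: need at least 3 points")
  if (is.null(weights)) weights <- rep(1, m)
  if (length(weights) != m || any(weights < 0) || sum(weights) == 0)
    stop("kabschSuperpose: invalid weights")
  w <- weights / sum(weights)

  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  X <- sweep(mobile, 2, cm)
  Y <- sweep(reference, 2, cr)

  ## collinearity check on the reference: the two smallest singular values of
  ## the centred coordinates vanish for a degenerate (collinear) set
  sv <- svd(Y * sqrt(w), nu = 0, nv = 0)$d
  if (sv[2] < 1e-9)
    stop("kabschSuperpose: degenerate (collinear) reference point set")

  H <- crossprod(X * w, Y)            # cross-covariance sum_i w_i x_i y_i^T
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- as.numeric(cr - R %*% cm)
  resid2 <- rowSums((X %*% t(R) - Y)^2)
  list(transform = rigidTransform(R, tr), rmsd = sqrt(sum(w * resid2)))
}

#' Random proper rotation matrix (uniform over SO(3))
#'
#' Utility for equivariance tests and fixtures; draws via a normalized
#' quaternion.
#'
#' @return 3 x 3 rotation matrix.
#' @export
randomRotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  quaternionToRotation(q)
}

#' Convert a unit quaternion to a rotation matrix
#' @param q numeric(4), (w, x, y, z), need not be normalized.
#' @return 3 x 3 rotation matrix.
#' @export
quaternionToRotation <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}
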