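# Rigid-body geometry: transforms, Kabsch superposition, helix axis fitting.

#' Construct a rigid transform
#'
#' A proper rigid motion `y = R x + t` applied to row-vector coordinates.
#'
#' @param rotation 3x3 proper rotation matrix (orthogonal, det +1).
#' @param translation length-3 numeric vector (angstrom).
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3, 3)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      abs(det(rotation) - 1) > 1e-8)
    stop_gd("rotation must be a proper 3x3 rotation matrix",
            class = "groovedock_value_error")
  structure(list(R = rotation, t = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n  rotation:\n")
  print(round(x$R, 6))
  cat("  translation:", paste(round(x$t, 4), collapse = " "), "\n")
  invisible(x)
}

#' Apply a rigid transform to coordinates or a structure
#'
#' @param tr a [rigid_transform()].
#' @param x an n x 3 coordinate matrix or a [structure3d()].
#' @return transformed object of the same kind as `x`.
#' @export
apply_transform <- function(tr, x) {
  if (inherits(x, "structure3d")) {
    xyz <- coords(x) %*% t(tr$R)
    a <- x$atoms
    a$x <- xyz[, 1] + tr$t[1]; a$y <- xyz[, 2] + tr$t[2]; a$z <- xyz[, 3] + tr$t[3]
    out <- x; out$atoms <- a
    return(out)
  }
  sweep(as.matrix(x) %*% t(tr$R), 2, tr$t, `+`)
}

#' Compose two rigid transforms
#'
#' `compose_transform(b, a)` is "apply `a`, then `b`".
#'
#' @param b,a [rigid_transform()] objects.
#' @return the composite [rigid_transform()].
#' @export
compose_transform <- function(b, a) {
  rigid_transform(b$R %*% a$R, as.numeric(b$R %*% a$t) + b$t)
}

#' Invert a rigid transform
#' @param tr a [rigid_transform()].
#' @return the inverse [rigid_transform()].
#' @export
invert_transform <- function(tr) {
  rigid_transform(t(tr$R), as.numeric(-t(tr$R) %*% tr$t))
}

#' Rotation about an arbitrary axis
#'
#' Rodrigues rotation by `angle` degrees about the axis through `point` with
#' direction `direction`.
#'
#' @param angle degrees.
#' @param point a point on the axis.
#' @param direction axis direction (normalized internally).
#' @return a [rigid_transform()].
#' @export
axis_rotation <- function(angle, point = c(0, 0, 0), direction = c(0, 0, 1)) {
  u <- as.numeric(direction); u <- u / sqrt(sum(u^2))
  th <- angle * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  p <- as.numeric(point)
  rigid_transform(R, p - as.numeric(R %*% p))
}

#' Least-squares (Kabsch) superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' corresponding points of `mobile` and `target` (reflections excluded).
#'
#' @param mobile,target n x 3 matrices of corresponding coordinates, n >= 3,
#'   not all collinear.
#' @return list with `transform` (a [rigid_transform()] mapping mobile onto
#'   target) and `rmsd` (post-fit, angstrom).
#' @export
kabsch <- function(mobile, target) {
  P <- as.matrix(mobile); Q <- as.matrix(target)
  if (!all(dim(P) == dim(Q)))
    stop_gd("coordinate sets differ in size (%d vs %d points)", nrow(P), nrow(Q),
            class = "groovedock_value_error")
  if (nrow(P) < 3)
    stop_gd("need at least 3 points for superposition", class = "groovedock_value_error")
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  # collinearity check: rank of the centred coordinates must be >= 2
  if (min(svd(P0)$d[2], svd(Q0)$d[2]) < 1e-8 * max(1, svd(P0)$d[1]))
    stop_gd("degenerate (collinear) coordinates: superposition is not unique",
            class = "groovedock_value_error")
  H <- crossprod(P0, Q0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cq - as.numeric(R %*% cp)
  tr <- rigid_transform(R, t)
  fit <- apply_transform(tr, P)
  list(transform = tr, rmsd = sqrt(mean(rowSums((fit - Q)^2))))
}

#' Fit the axis of a helix from its C-alpha trace
#'
#' The axis direction is the principal (largest-variance) axis of the centred
#' coordinates, oriented from the N terminus towards the C terminus; the axis
#' point is the centroid.
#'
#' @param ca_coords n x 3 matrix of C-alpha positions in chain order, n >= 4.
#' @return list with `point` (centroid) and `direction` (unit vector).
#' @export
fit_helix_axis <- function(ca_coords) {
  X <- as.matrix(ca_coords)
  if (nrow(X) < 4)
    stop_gd("need at least 4 C-alpha positions to fit a helix axis",
            class = "groovedock_value_error")
  ctr <- colMeans(X)
  X0 <- sweep(X, 2, ctr)
  v <- svd(X0)$v[, 1]
  if (sum(v * (X[nrow(X), ] - X[1, ])) < 0) v <- -v
  list(point = ctr, direction = v / sqrt(sum(v^2)))
}
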