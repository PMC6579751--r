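# Small rigid-body / linear-algebra helpers shared across modules.
# All coordinates are in Angstrom, all angles in degrees unless noted.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Rotation matrix about an arbitrary axis
#'
#' @param axis numeric length-3 direction (need not be unit length).
#' @param theta rotation angle in degrees; positive is counterclockwise when
#'   viewed from the tip of `axis` looking toward the origin (right-hand rule).
#' @return 3x3 rotation matrix.
#' @keywords internal
rotation_matrix <- function(axis, theta) {
  u <- axis / sqrt(sum(axis^2))
  th <- deg2rad(theta)
  ct <- cos(th); st <- sin(th)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
               3, 3, byrow = TRUE)
  ct * diag(3) + st * ux + (1 - ct) * (u %o% u)
}

# Apply `R %*% x + t` to an n x 3 coordinate matrix.
transform_coords <- function(xyz, R = diag(3), t = c(0, 0, 0)) {
  sweep(xyz %*% t(R), 2, -t)
}

# Rotate coordinates about a line through `origin` with direction `axis`.
rotate_about_line <- function(xyz, origin, axis, theta) {
  R <- rotation_matrix(axis, theta)
  sweep(sweep(xyz, 2, origin) %*% t(R), 2, -origin)
}

# Cn symmetry axis of an oligomeric point cloud: the coordinate-covariance
# eigenvector belonging to the eigenvalue most separated from the other two
# (the in-plane pair is degenerate for a symmetric ring, whether the ring is
# tall or flat).
symmetry_axis <- function(xyz) {
  ctr <- colMeans(xyz)
  cc <- sweep(xyz, 2, ctr)
  ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)
  lam <- ev$values  # descending
  axis_idx <- if ((lam[1] - lam[2]) >= (lam[2] - lam[3])) 1 else 3
  list(origin = ctr, direction = ev$vectors[, axis_idx])
}

#' Principal axis of a point cloud
#'
#' Unit eigenvector of the coordinate covariance belonging to the largest
#' eigenvalue, i.e. the direction of maximal extent.
#' @keywords internal
principal_axis <- function(xyz) {
  ctr <- colMeans(xyz)
  cc <- sweep(xyz, 2, ctr)
  ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)
  list(origin = ctr, direction = ev$vectors[, 1])
}

# Signed angle (degrees) from u to v in the plane perpendicular to `about`,
# positive counterclockwise viewed from the +about side.
signed_angle <- function(u, v, about) {
  n <- about / sqrt(sum(about^2))
  up <- u - sum(u * n) * n
  vp <- v - sum(v * n) * n
  rad2deg(atan2(sum(n * pracma_cross(up, vp)), sum(up * vp)))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Minimal rotation taking unit vector a onto unit vector b.
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- pracma_cross(a, b)
  s <- sqrt(sum(v^2)); cth <- sum(a * b)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    # antiparallel: rotate 180 degrees about any perpendicular
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    perp <- pracma_cross(a, p)
    return(rotation_matrix(perp, 180))
  }
  rotation_matrix(v, rad2deg(atan2(s, cth)))
}

#' Kabsch superposition
#'
#' Optimal rotation + translation mapping `mobile` onto `target`
#' (least-squares, proper rotation enforced).
#' @return list with `R`, `t` (apply as `x %*% t(R) + t`) and `rmsd`.
#' @keywords internal
kabsch <- function(mobile, target) {
  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(mobile, 2, cm); B <- sweep(target, 2, ct)
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t <- ct - as.vector(R %*% cm)
  fitted <- sweep(A %*% t(R), 2, -ct)
  list(R = R, t = t, rmsd = sqrt(mean(rowSums((fitted - sweep(B, 2, -ct))^2))))
}

#' Deterministic quasi-uniform points on the unit sphere
#'
#' Golden-section (Fibonacci) spiral; used by the solvent-accessibility
#' routine so results are reproducible without random numbers.
#' @keywords internal
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Random rigid transform (for invariance property tests).
random_rigid_transform <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ax <- stats::rnorm(3)
  list(R = rotation_matrix(ax, stats::runif(1, 0, 360)),
       t = stats::runif(3, -20, 20))
}

apply_rigid_to_structure <- function(x, rt) {
  xyz <- as.matrix(x[, c("x", "y", "z")])
  xyz <- transform_coords(xyz, rt$R, rt$t)
  x$x <- xyz[, 1]; x$y <- xyz[, 2]; x$z <- xyz[, 3]
  x
}
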