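#' Rigid-body pose
#'
#' A pose is a rigid transform mapping the reference frame onto a particle
#' frame: a rotation given by three Euler angles (degrees, ZXZ intrinsic:
#' `R = Rz(rot) %*% Rx(tilt) %*% Rz(psi)`) followed by a translation in voxels.
#'
#' @param rot,tilt,psi Euler angles in degrees (ZXZ intrinsic).
#' @param shift numeric(3) translation in voxels.
#' @return a `pose` object.
#' @export
pose <- function(rot = 0, tilt = 0, psi = 0, shift = c(0, 0, 0)) {
  structure(list(euler = c(rot = rot, tilt = tilt, psi = psi),
                 shift = as.numeric(shift)),
            class = "pose")
}

#' @export
print.pose <- function(x, ...) {
  cat(sprintf("pose: rot=%.2f tilt=%.2f psi=%.2f deg, shift=(%.2f, %.2f, %.2f) vx\n",
              x$euler[1], x$euler[2], x$euler[3],
              x$shift[1], x$shift[2], x$shift[3]))
  invisible(x)
}

rot_z <- function(a) {
  a <- a * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

rot_x <- function(a) {
  a <- a * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

#' Euler angles to rotation matrix (ZXZ intrinsic)
#' @param euler numeric(3) angles in degrees (rot, tilt, psi).
#' @return 3x3 rotation matrix.
#' @export
euler_to_matrix <- function(euler) {
  rot_z(euler[1]) %*% rot_x(euler[2]) %*% rot_z(euler[3])
}

#' Rotation matrix to Euler angles (ZXZ intrinsic)
#' @param R 3x3 rotation matrix.
#' @return numeric(3) angles in degrees (rot, tilt, psi).
#' @export
matrix_to_euler <- function(R) {
  cb <- max(-1, min(1, R[3, 3]))
  tilt <- acos(cb)
  if (abs(sin(tilt)) < 1e-10) {
    # gimbal: rot and psi share an axis; put everything in rot
    rot <- atan2(R[2, 1], R[1, 1])
    psi <- 0
  } else {
    rot <- atan2(R[1, 3], -R[2, 3])
    psi <- atan2(R[3, 1], R[3, 2])
  }
  c(rot = rot, tilt = tilt, psi = psi) * 180 / pi
}

pose_matrix <- function(p) euler_to_matrix(p$euler)

#' Compose two poses
#'
#' `pose_compose(p, q)` is the pose whose action is "apply `q`, then `p`":
#' rotation `Rp %*% Rq`, shift `Rp %*% sq + sp`.
#' @param p,q `pose` objects.
#' @return a `pose`.
#' @export
pose_compose <- function(p, q) {
  R <- pose_matrix(p) %*% pose_matrix(q)
  s <- as.numeric(pose_matrix(p) %*% q$shift) + p$shift
  e <- matrix_to_euler(R)
  pose(e[1], e[2], e[3], s)
}

#' Invert a pose
#' @param p a `pose`.
#' @return the inverse `pose`.
#' @export
pose_invert <- function(p) {
  R <- t(pose_matrix(p))
  e <- matrix_to_euler(R)
  pose(e[1], e[2], e[3], as.numeric(-R %*% p$shift))
}

# Geodesic angle (degrees) between two rotations.
rotation_distance <- function(R1, R2) {
  tr <- sum(diag(t(R1) %*% R2))
  acos(max(-1, min(1, (tr - 1) / 2))) * 180 / pi
}

#' Rotation matrix about an arbitrary axis (Rodrigues)
#' @param axis numeric(3), need not be normalized.
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
axis_angle_matrix <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  a <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

# Euler angles of the rotation taking the z axis onto unit vector n with
# zero azimuth (psi = 0).
normal_to_euler <- function(n) {
  n <- n / sqrt(sum(n^2))
  tilt <- acos(max(-1, min(1, n[3]))) * 180 / pi
  rot <- if (abs(n[1]) + abs(n[2]) < 1e-12) 0 else atan2(n[1], -n[2]) * 180 / pi
  c(rot = rot, tilt = tilt, psi = 0)
}

#' Resample a map under a pose (reference frame -> particle frame)
#'
#' Produces the map as it would appear in the particle's frame: the density is
#' rotated by the pose rotation about the box center and shifted by the pose
#' shift (voxels).
#'
#' @param map a `density_map` (cubic).
#' @param p a `pose`.
#' @param order interpolation order: 1 (trilinear) or 3 (tricubic).
#' @return transformed `density_map`.
#' @export
apply_pose <- function(map, p, order = 1L) {
  d <- dim(map$data)
  ctr <- (d - 1) / 2
  R <- pose_matrix(p)
  A <- t(R)
  b <- ctr - as.numeric(A %*% (ctr + p$shift))
  out <- c_affine_sample(as.numeric(map$data), as.integer(d), A, b, order)
  as_map_like(map, array(out, d))
}

#' Resample a map under the inverse of a pose (particle frame -> reference)
#' @param map a `density_map`.
#' @param p the `pose` that maps reference to particle frame.
#' @return transformed `density_map`.
#' @export
apply_pose_inverse <- function(map, p, order = 1L) {
  d <- dim(map$data)
  ctr <- (d - 1) / 2
  R <- pose_matrix(p)
  b <- ctr + p$shift - as.numeric(R %*% ctr)
  out <- c_affine_sample(as.numeric(map$data), as.integer(d), R, b, order)
  as_map_like(map, array(out, d))
}

#' Rotate a map about its center
#' @param map a `density_map`.
#' @param R 3x3 rotation matrix.
#' @return rotated `density_map`.
#' @export
rotate_map <- function(map, R, order = 1L) {
  d <- dim(map$data)
  ctr <- (d - 1) / 2
  A <- t(R)
  b <- ctr - as.numeric(A %*% ctr)
  out <- c_affine_sample(as.numeric(map$data), as.integer(d), A, b, order)
  as_map_like(map, array(out, d))
}

#' Quasi-uniform points on the unit sphere (Fibonacci lattice)
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}
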