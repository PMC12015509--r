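#' Rotation matrix from ZYZ Euler angles
#'
#' RELION-convention intrinsic ZYZ composition
#' `R = Rz(rot) %*% Ry(tilt) %*% Rz(psi)`, in degrees. The matrix maps
#' centered voxel coordinates of the reference volume into the particle
#' frame; the projector samples its transpose.
#'
#' @param euler Numeric `(rot, tilt, psi)` in degrees.
#' @return 3x3 orthonormal matrix with determinant +1.
#' @export
rotation_matrix <- function(euler) {
  euler <- as.numeric(euler)
  if (length(euler) != 3L || !all(is.finite(euler)))
    stop("euler must be three finite angles (rot, tilt, psi)")
  a <- euler * pi / 180
  rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
  ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
  rz(a[1]) %*% ry(a[2]) %*% rz(a[3])
}

#' Particle pose
#'
#' @param euler Euler angles `(rot, tilt, psi)` in degrees.
#' @param shift In-plane shift `(sx, sy)` in pixels.
#' @return Object of class `pose`.
#' @export
pose <- function(euler = c(0, 0, 0), shift = c(0, 0)) {
  euler <- as.numeric(euler); shift <- as.numeric(shift)
  stopifnot(length(euler) == 3L, length(shift) == 2L)
  if (!all(is.finite(c(euler, shift)))) stop("non-finite pose")
  structure(list(euler = euler, shift = shift), class = "pose")
}

#' Pose refinement output
#'
#' Additive per-particle corrections predicted by the encoder's
#' refinement head: Euler-angle deltas in degrees and in-plane shift
#' deltas in pixels.
#'
#' @param d_euler `(d_rot, d_tilt, d_psi)` in degrees.
#' @param d_shift `(d_sx, d_sy)` in pixels.
#' @return Object of class `pose_refinement`.
#' @export
pose_refinement <- function(d_euler = c(0, 0, 0), d_shift = c(0, 0)) {
  d_euler <- as.numeric(d_euler); d_shift <- as.numeric(d_shift)
  stopifnot(length(d_euler) == 3L, length(d_shift) == 2L)
  if (!all(is.finite(c(d_euler, d_shift)))) stop("non-finite refinement")
  structure(list(d_euler = d_euler, d_shift = d_shift),
            class = "pose_refinement")
}

#' Apply a pose refinement to a particle's stored pose
#'
#' Corrections are added to the stored Euler angles and shifts after
#' clamping each component to the configured bounds.
#'
#' @param record A [particle_record()] (or [pose()]).
#' @param refinement A [pose_refinement()].
#' @param clamp_deg Per-angle clamp in degrees.
#' @param clamp_px Per-axis shift clamp in pixels.
#' @return A [pose()].
#' @export
refine_pose <- function(record, refinement, clamp_deg = 5, clamp_px = 2) {
  de <- pmin(pmax(refinement$d_euler, -clamp_deg), clamp_deg)
  ds <- pmin(pmax(refinement$d_shift, -clamp_px), clamp_px)
  pose(record$euler + de, record$shift + ds)
}
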