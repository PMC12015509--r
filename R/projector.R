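# Real-space forward projection: rotate the volume (trilinear gather on
# the rotated lattice), sum along z, then apply the in-plane shift as a
# subpixel-exact Fourier phase ramp.

#' Shift an image by a subpixel translation (Fourier phase ramp)
#'
#' Translates image content by `(sx, sy)` pixels with circular boundary;
#' exact for subpixel shifts and linear in the image.
#'
#' @param image Square numeric matrix.
#' @param shift `(sx, sy)` in pixels.
#' @return Shifted matrix.
#' @export
fourier_shift <- function(image, shift) {
  if (all(shift == 0)) return(image)
  n <- nrow(image)
  f <- (seq_len(n) - 1 - floor(n / 2)) / n  # cycles/pixel, centered
  fx <- matrix(f, n, n); fy <- matrix(f, n, n, byrow = TRUE)
  ramp <- exp(-2i * pi * (fx * shift[1] + fy * shift[2]))
  ft <- stats::fft(image) * ifftshift2(ramp)
  Re(stats::fft(ft, inverse = TRUE)) / length(image)
}

#' Project a volume along the microscope axis
#'
#' Implements the geometric part of the image-formation model: the volume
#' is rotated by the pose's Euler matrix (trilinear interpolation), summed
#' along z, and translated in-plane by the pose shift. The identity-pose,
#' zero-shift projection of a volume sums to the volume sum exactly.
#'
#' @param vol A [volume_grid()] (or 3D array).
#' @param pose A [pose()] (a [particle_record()] is accepted too).
#' @return `N x N` projection image.
#' @export
project <- function(vol, pose) {
  v <- as_volume_data(vol)
  n <- dim(v)[1]
  R <- rotation_matrix(pose$euler)
  img <- cpp_rotate_project(as.numeric(v), R, n)
  fourier_shift(img, pose$shift)
}

#' Adjoint of [project()]
#'
#' Scatters an image-space gradient back into volume space through the
#' exact transpose of the projection operator (shift by the negated
#' translation, then trilinear backprojection). Used by training to
#' backpropagate the data term into the decoded volume.
#'
#' @param image `N x N` gradient image.
#' @param pose The pose used in the forward projection.
#' @param box Volume side in voxels.
#' @return `N^3` array.
#' @export
backproject <- function(image, pose, box) {
  img <- fourier_shift(image, -pose$shift)
  R <- rotation_matrix(pose$euler)
  cpp_rotate_backproject(img, R, box)
}

#' Rotate a volume by a pose's Euler angles
#'
#' @param vol A [volume_grid()] or 3D array.
#' @param euler `(rot, tilt, psi)` degrees.
#' @return 3D array of the rotated volume.
#' @export
rotate_volume <- function(vol, euler) {
  v <- as_volume_data(vol)
  cpp_rotate_volume(as.numeric(v), rotation_matrix(euler), dim(v)[1])
}

#' Noise-free forward model for one particle
#'
#' Full image-formation pipeline without the noise term: projection under
#' the particle's pose followed by CTF corruption. Deterministic, and
#' bit-identical to calling [project()] and [apply_ctf()] in sequence.
#'
#' @param vol A [volume_grid()].
#' @param record A [particle_record()].
#' @param ctf Optional precomputed centered CTF grid.
#' @return `N x N` simulated image.
#' @export
forward_model <- function(vol, record, ctf = NULL) {
  v <- as_volume_data(vol)
  if (inherits(vol, "volume_grid") && vol$voxel_size != record$ctf$pixel_size)
    stop("volume voxel size and CTF pixel size disagree")
  img <- project(v, record)
  apply_ctf(img, record$ctf, ctf = ctf)
}
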