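# Contrast transfer function simulation. The frequency grid is centered
# (DC at index floor(N/2), 0-based) in cycles/Angstrom; apply_ctf
# multiplies in Fourier space, which equals circular convolution with the
# inverse-transformed PSF in real space.

#' Microscope / CTF parameters
#'
#' @param defocus_u,defocus_v Defocus along the astigmatism axes, Angstrom
#'   (positive = underfocus).
#' @param astig_angle Astigmatism azimuth, degrees.
#' @param voltage Acceleration voltage, kV.
#' @param cs Spherical aberration, mm.
#' @param amplitude_contrast Amplitude contrast fraction in `[0, 1]`.
#' @param pixel_size Pixel size, Angstrom.
#' @return Object of class `ctf_params`.
#' @export
ctf_params <- function(defocus_u = 15000, defocus_v = 15000,
                       astig_angle = 0, voltage = 300, cs = 2.7,
                       amplitude_contrast = 0.1, pixel_size = 1) {
  if (voltage <= 0) stop("voltage must be positive")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  if (amplitude_contrast < 0 || amplitude_contrast > 1)
    stop("amplitude_contrast must lie in [0, 1]")
  structure(list(defocus_u = defocus_u, defocus_v = defocus_v,
                 astig_angle = astig_angle, voltage = voltage, cs = cs,
                 amplitude_contrast = amplitude_contrast,
                 pixel_size = pixel_size),
            class = "ctf_params")
}

#' Relativistic electron wavelength
#'
#' @param voltage_kv Acceleration voltage in kV.
#' @return Wavelength in Angstrom.
#' @export
electron_wavelength <- function(voltage_kv) {
  v <- voltage_kv * 1e3
  12.2639 / sqrt(v + 0.97845e-6 * v^2)
}

#' Centered frequency axis in cycles/Angstrom
#' @noRd
freq_axis <- function(n, pixel_size) {
  (seq_len(n) - 1 - floor(n / 2)) / (n * pixel_size)
}

#' CTF phase function chi(f) at spatial frequency f (cycles/Angstrom)
#' @noRd
ctf_chi <- function(f2, defocus, lambda, cs_mm) {
  cs <- cs_mm * 1e7  # mm -> Angstrom
  pi * lambda * defocus * f2 - (pi / 2) * cs * lambda^3 * f2^2
}

#' Evaluate the CTF on the centered frequency grid
#'
#' `CTF(f) = -sqrt(1 - A^2) sin(chi) - A cos(chi)` with
#' `chi = pi lambda df(theta) |f|^2 - (pi/2) Cs lambda^3 |f|^4` and the
#' astigmatic defocus
#' `df(theta) = (du + dv)/2 + (du - dv)/2 cos(2 (theta - astig))`.
#' At zero frequency the value is `-A`; the grid is Friedel-symmetric.
#'
#' @param params A [ctf_params()].
#' @param box Image side in pixels (N >= 2).
#' @return `box x box` matrix of CTF values in `[-1, 1]`, DC-centered.
#' @export
ctf_evaluate <- function(params, box) {
  stopifnot(inherits(params, "ctf_params"))
  if (box < 2) stop("box must be at least 2")
  f <- freq_axis(box, params$pixel_size)
  fx <- matrix(f, box, box)
  fy <- matrix(f, box, box, byrow = TRUE)
  f2 <- fx^2 + fy^2
  theta <- atan2(fy, fx)
  du <- params$defocus_u; dv <- params$defocus_v
  defocus <- (du + dv) / 2 +
    (du - dv) / 2 * cos(2 * (theta - params$astig_angle * pi / 180))
  lambda <- electron_wavelength(params$voltage)
  chi <- ctf_chi(f2, defocus, lambda, params$cs)
  a <- params$amplitude_contrast
  -sqrt(1 - a^2) * sin(chi) - a * cos(chi)
}

fftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  s1 <- floor(n1 / 2); s2 <- floor(n2 / 2)
  m[c((s1 + 1):n1, seq_len(s1)), c((s2 + 1):n2, seq_len(s2)), drop = FALSE]
}

ifftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  s1 <- ceiling(n1 / 2); s2 <- ceiling(n2 / 2)
  m[c((s1 + 1):n1, seq_len(s1)), c((s2 + 1):n2, seq_len(s2)), drop = FALSE]
}

#' Corrupt an image with the CTF
#'
#' Multiplies the image's Fourier transform by the (signed, real) CTF and
#' transforms back; linear in the input. The same operation is its own
#' adjoint, which training uses to backpropagate through the optics.
#'
#' @param image Square numeric matrix.
#' @param params A [ctf_params()].
#' @param ctf Optional precomputed centered CTF grid (overrides `params`).
#' @return Matrix of the same size.
#' @export
apply_ctf <- function(image, params = NULL, ctf = NULL) {
  if (!is.matrix(image) || nrow(image) != ncol(image))
    stop("image must be a square matrix")
  if (is.null(ctf)) ctf <- ctf_evaluate(params, nrow(image))
  if (!all(dim(ctf) == dim(image))) stop("CTF grid / image shape mismatch")
  ft <- stats::fft(image) * ifftshift2(ctf)
  Re(stats::fft(ft, inverse = TRUE)) / length(image)
}
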