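#' Cubic real-space density volume
#'
#' A `volume_grid` holds a cubic (`N x N x N`) real-valued density map
#' together with its voxel size in Angstrom per voxel. All rotation and
#' projection operators in the package treat voxel index `floor(N/2)`
#' (0-based) as the center on every axis, matching the FFT-centered
#' convention used by the frequency grids.
#'
#' @param data Numeric 3D array, cubic.
#' @param voxel_size Voxel size in Angstrom (> 0).
#' @return An object of class `volume_grid` with fields `data`, `voxel_size`
#'   and `box` (the box side in voxels).
#' @export
volume_grid <- function(data, voxel_size = 1) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume data must be a 3D array")
  d <- dim(data)
  if (d[1] != d[2] || d[2] != d[3])
    stop("volume must be cubic, got box ", paste(d, collapse = "x"))
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("voxel_size must be a single positive number")
  if (!all(is.finite(data)))
    stop("volume contains non-finite values")
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 box = as.integer(d[1])),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid %d^3, %.4g A/voxel, range [%.4g, %.4g]>\n",
              x$box, x$voxel_size, min(x$data), max(x$data)))
  invisible(x)
}

as_volume_data <- function(x) {
  if (inherits(x, "volume_grid")) x$data
  else if (is.array(x) && length(dim(x)) == 3L) x
  else stop("expected a volume_grid or 3D array")
}

#' Binary focus mask
#'
#' A binary region-of-interest selecting the voxels the decoder is allowed
#' to modify during focused reconstruction. Values must be exactly 0 or 1.
#'
#' @param data Numeric or logical 3D array of 0/1 values.
#' @return An object of class `vol_mask` with fields `data` (0/1 numeric
#'   array) and `voxel_count` (number of ones).
#' @export
vol_mask <- function(data) {
  if (is.logical(data)) data <- array(as.numeric(data), dim(data))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("mask must be a 3D array")
  if (!all(data %in% c(0, 1)))
    stop("mask values must be 0 or 1")
  structure(list(data = data, voxel_count = as.integer(sum(data))),
            class = "vol_mask")
}

#' Image stack
#'
#' A stack of `n` square particle images stored as an `N x N x n` array
#' (image x/y on the first two axes), plus the pixel size in Angstrom.
#'
#' @param images Numeric 3D array `N x N x n` (a single `N x N` matrix is
#'   promoted to a stack of one).
#' @param pixel_size Pixel size in Angstrom.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(images, pixel_size = 1) {
  if (is.matrix(images)) images <- array(images, c(dim(images), 1L))
  if (!is.array(images) || length(dim(images)) != 3L)
    stop("images must be an N x N x n array")
  d <- dim(images)
  if (d[1] != d[2]) stop("images must be square")
  if (!all(is.finite(images))) stop("image stack contains non-finite values")
  structure(list(images = images, pixel_size = as.numeric(pixel_size),
                 box = as.integer(d[1]), n = as.integer(d[3])),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("<image_stack %d images, %dx%d px, %.4g A/px>\n",
              x$n, x$box, x$box, x$pixel_size))
  invisible(x)
}
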