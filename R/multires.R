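# Multiresolution data objective. The "full" level compares image pairs
# as-is; the "half" level first applies a Gaussian lowpass whose transfer
# function falls to 0.5 at half the Nyquist frequency, then decimates by
# a factor of 2. Both branches are linear, so the gradient is obtained
# from the exact adjoint (conjugate filter + zero-upsampling).

# Gaussian transfer grid on the centered frequency lattice (cycles/px):
# H(f) = exp(-ln 2 * (|f| / f_c)^2), H(f_c) = 1/2, f_c = 0.25 cycles/px.
lowpass_transfer <- function(n, cutoff = 0.25) {
  f <- (seq_len(n) - 1 - floor(n / 2)) / n
  fx <- matrix(f, n, n); fy <- matrix(f, n, n, byrow = TRUE)
  exp(-log(2) * (fx^2 + fy^2) / cutoff^2)
}

lowpass_filter <- function(image, transfer = NULL) {
  n <- nrow(image)
  if (is.null(transfer)) transfer <- lowpass_transfer(n)
  ft <- stats::fft(image) * ifftshift2(transfer)
  Re(stats::fft(ft, inverse = TRUE)) / length(image)
}

decimate2 <- function(image) {
  idx <- seq(1, nrow(image), by = 2)
  image[idx, idx, drop = FALSE]
}

upsample2 <- function(small, n) {
  out <- matrix(0, n, n)
  idx <- seq(1, n, by = 2)
  out[idx, idx] <- small
  out
}

#' Lowpass + downsample operator for one multiresolution level
#'
#' @param image Square matrix.
#' @param level `"full"` (identity) or `"half"` (Gaussian lowpass with
#'   half-amplitude point at half Nyquist, then 2x decimation).
#' @return Filtered (possibly smaller) matrix.
#' @export
multires_operator <- function(image, level = c("full", "half")) {
  level <- match.arg(level)
  if (level == "full") return(image)
  decimate2(lowpass_filter(image))
}

#' Multiresolution data term
#'
#' Sum over resolution levels of the summed MSE between
#' filtered-and-downsampled experimental/decoded image pairs. With
#' `cutoffs = "full"` only, this equals [data_mse()] exactly.
#'
#' @param experimental,decoded `N x N x B` arrays or single matrices.
#' @param cutoffs Character subset of `c("full", "half")`.
#' @return Scalar.
#' @export
multires_data_loss <- function(experimental, decoded,
                               cutoffs = c("full", "half")) {
  if (!all(cutoffs %in% c("full", "half")))
    stop("invalid multiresolution level; use 'full' and/or 'half'")
  e <- if (is.matrix(experimental)) array(experimental, c(dim(experimental), 1)) else experimental
  d <- if (is.matrix(decoded)) array(decoded, c(dim(decoded), 1)) else decoded
  if (!all(dim(e) == dim(d))) stop("shape mismatch")
  n <- dim(e)[1]
  transfer <- if ("half" %in% cutoffs) lowpass_transfer(n) else NULL
  tot <- 0
  for (b in seq_len(dim(e)[3])) {
    if ("full" %in% cutoffs) tot <- tot + sum((e[, , b] - d[, , b])^2)
    if ("half" %in% cutoffs) {
      r <- lowpass_filter(e[, , b] - d[, , b], transfer)
      tot <- tot + sum(decimate2(r)^2)
    }
  }
  tot
}

# Gradient of the multiresolution data term w.r.t. one decoded image.
multires_data_grad <- function(exp_img, dec_img, cutoffs, transfer = NULL) {
  multires_grad_loss(exp_img, dec_img, cutoffs, transfer)$grad
}

# Gradient and loss value in one pass (shared filterings).
multires_grad_loss <- function(exp_img, dec_img, cutoffs, transfer = NULL) {
  n <- nrow(exp_img)
  g <- matrix(0, n, n)
  loss <- 0
  r <- dec_img - exp_img
  if ("full" %in% cutoffs) {
    g <- g + 2 * r
    loss <- loss + sum(r^2)
  }
  if ("half" %in% cutoffs) {
    if (is.null(transfer)) transfer <- lowpass_transfer(n)
    f1 <- lowpass_filter(r, transfer)
    d1 <- decimate2(f1)
    loss <- loss + sum(d1^2)
    g <- g + 2 * lowpass_filter(upsample2(d1, n), transfer)
  }
  list(grad = g, loss = loss)
}
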