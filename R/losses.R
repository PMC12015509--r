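# Objective terms. Every term is a pure scalar function; gradients used
# by training are exposed as *_grad companions so they can be checked
# against finite differences independently of the training loop.
#
# Batch summation convention: image data terms and latent decoupling
# terms are summed (not averaged) over the batch, matching the summed-MSE
# definition of the data term.

#' Summed mean-square data term
#'
#' Sum over the batch of squared L2 differences between experimental and
#' decoded images. Shapes must match; any layout whose elements pair up
#' (matrix batch rows, `N x N x B` arrays) is accepted.
#'
#' @param experimental,decoded Numeric arrays of identical shape.
#' @return Scalar.
#' @export
data_mse <- function(experimental, decoded) {
  if (!identical(dim(experimental), dim(decoded)) ||
      length(experimental) != length(decoded))
    stop("shape mismatch between experimental and decoded images")
  sum((experimental - decoded)^2)
}

data_mse_grad <- function(experimental, decoded) 2 * (decoded - experimental)

#' Negative mean Pearson correlation data term
#'
#' Computes Pearson correlation per image pair and returns the negated
#' batch mean so that minimization maximizes correlation. Invariant to
#' positive affine rescaling of either image; errors on zero-variance
#' images.
#'
#' @param experimental,decoded `N x N x B` arrays (or single matrices).
#' @return Scalar in `[-1, 1]`.
#' @export
data_correlation <- function(experimental, decoded) {
  e <- if (is.matrix(experimental)) array(experimental, c(dim(experimental), 1)) else experimental
  d <- if (is.matrix(decoded)) array(decoded, c(dim(decoded), 1)) else decoded
  if (!all(dim(e) == dim(d))) stop("shape mismatch")
  b <- dim(e)[3]
  cors <- vapply(seq_len(b), function(i) {
    x <- as.numeric(e[, , i]); y <- as.numeric(d[, , i])
    if (stats::var(x) == 0 || stats::var(y) == 0)
      stop("zero-variance image in correlation loss")
    stats::cor(x, y)
  }, numeric(1))
  -mean(cors)
}

# Gradient of the negative-mean-Pearson data term w.r.t. one decoded
# image (batch size B divides the mean).
data_correlation_grad_pair <- function(exp_img, dec_img, B) {
  x <- as.numeric(exp_img); y <- as.numeric(dec_img)
  xc <- x - mean(x); yc <- y - mean(y)
  sx <- sqrt(sum(xc^2)); sy <- sqrt(sum(yc^2))
  if (sx == 0 || sy == 0) stop("zero-variance image in correlation loss")
  r <- sum(xc * yc) / (sx * sy)
  matrix(-(xc / (sx * sy) - r * yc / sy^2) / B, nrow(exp_img), ncol(exp_img))
}

#' L1 density regularizer
#'
#' Penalizes total absolute density of the composed volume, suppressing
#' the diffuse pedestal that image noise would otherwise imprint on the
#' decoded map.
#'
#' @param volume A [volume_grid()] or numeric array.
#' @param lambda1 Nonnegative weight.
#' @return `lambda1 * sum(abs(volume))`.
#' @export
l1_density <- function(volume, lambda1 = 1) {
  lambda1 * sum(abs(as_any_array(volume)))
}

l1_density_grad <- function(volume, lambda1 = 1) lambda1 * sign(volume)

as_any_array <- function(x) if (inherits(x, "volume_grid")) x$data else x

#' Negative-value penalty
#'
#' L1 penalty on the negative part of the volume, discouraging the
#' decoder from balancing signal with unphysical negative density.
#'
#' @param volume A [volume_grid()] or numeric array.
#' @param lambda2 Nonnegative weight.
#' @return `lambda2 * sum(abs(pmin(volume, 0)))`.
#' @export
negative_penalty <- function(volume, lambda2 = 1) {
  v <- as_any_array(volume)
  lambda2 * sum(abs(pmin(v, 0)))
}

negative_penalty_grad <- function(volume, lambda2 = 1) {
  -lambda2 * (volume < 0)
}

# Forward differences with replicate (Neumann) boundary along each axis:
# the difference at the last plane is zero, so constants cost nothing.
vol_forward_diffs <- function(v) {
  n <- dim(v)[1]
  dx <- v[c(2:n, n), , , drop = FALSE] - v
  dy <- v[, c(2:n, n), , drop = FALSE] - v
  dz <- v[, , c(2:n, n), drop = FALSE] - v
  list(dx = dx, dy = dy, dz = dz)
}

# Adjoint of the forward-difference operator (negative divergence).
diff_adjoint <- function(g, axis) {
  n <- dim(g)[1]
  # replicate boundary means the last plane's difference is identically 0;
  # zero its gradient before applying the adjoint
  if (axis == "x") g[n, , ] <- 0
  if (axis == "y") g[, n, ] <- 0
  if (axis == "z") g[, , n] <- 0
  shifted <- array(0, dim(g))
  if (axis == "x") shifted[2:n, , ] <- g[1:(n - 1), , ]
  if (axis == "y") shifted[, 2:n, ] <- g[, 1:(n - 1), ]
  if (axis == "z") shifted[, , 2:n] <- g[, , 1:(n - 1)]
  shifted - g
}

#' Total-variation regularizers
#'
#' Anisotropic TV on the composed volume: `lambda3` weights the L1 norm
#' of the forward-difference spatial gradient and `lambda4` the squared
#' L2 norm. Replicate boundary, so constant volumes cost zero.
#'
#' @param volume A [volume_grid()] or numeric array.
#' @param lambda3,lambda4 Nonnegative weights.
#' @return Scalar `lambda3 * |grad V|_1 + lambda4 * |grad V|_2^2`.
#' @export
tv_loss <- function(volume, lambda3 = 0.1, lambda4 = 0.1) {
  d <- vol_forward_diffs(as_any_array(volume))
  l1 <- sum(abs(d$dx)) + sum(abs(d$dy)) + sum(abs(d$dz))
  l2 <- sum(d$dx^2) + sum(d$dy^2) + sum(d$dz^2)
  lambda3 * l1 + lambda4 * l2
}

tv_components <- function(volume) {
  d <- vol_forward_diffs(as_any_array(volume))
  c(l1 = sum(abs(d$dx)) + sum(abs(d$dy)) + sum(abs(d$dz)),
    l2 = sum(d$dx^2) + sum(d$dy^2) + sum(d$dz^2))
}

tv_loss_grad <- function(volume, lambda3 = 0.1, lambda4 = 0.1) {
  tv_grad_components(volume, lambda3, lambda4)$grad
}

# Gradient and both TV norms in one pass over the forward differences.
tv_grad_components <- function(volume, lambda3, lambda4) {
  v <- as_any_array(volume)
  d <- vol_forward_diffs(v)
  g <- diff_adjoint(lambda3 * sign(d$dx) + 2 * lambda4 * d$dx, "x") +
       diff_adjoint(lambda3 * sign(d$dy) + 2 * lambda4 * d$dy, "y") +
       diff_adjoint(lambda3 * sign(d$dz) + 2 * lambda4 * d$dz, "z")
  list(grad = g,
       l1 = sum(abs(d$dx)) + sum(abs(d$dy)) + sum(abs(d$dz)),
       l2 = sum(d$dx^2) + sum(d$dy^2) + sum(d$dz^2))
}

#' Latent pose-decoupling constraint
#'
#' Pulls the latent code of an experimental image towards the codes
#' re-encoded from its clean projection (`z_t`) and from the clean
#' projection under a shuffled pose (`z_pt`):
#' `lambda_p * (|z - z_t|^2 + |z - z_pt|^2)`, summed over the batch.
#'
#' @param z,z_t,z_pt Latent vectors or row-wise latent batch matrices.
#' @param lambda_p Nonnegative weight.
#' @return Scalar.
#' @export
pose_decouple_loss <- function(z, z_t, z_pt, lambda_p = 0.1) {
  if (length(z) != length(z_t) || length(z) != length(z_pt))
    stop("latent dimension mismatch")
  lambda_p * (sum((z - z_t)^2) + sum((z - z_pt)^2))
}

#' Latent CTF-decoupling constraint
#'
#' Same structure as [pose_decouple_loss()] with the codes re-encoded
#' from the CTF-corrupted projection (`z_c`) and from the projection
#' corrupted by a shuffled CTF (`z_pc`).
#'
#' @param z,z_c,z_pc Latent vectors or row-wise latent batch matrices.
#' @param lambda_c Nonnegative weight.
#' @return Scalar.
#' @export
ctf_decouple_loss <- function(z, z_c, z_pc, lambda_c = 0.1) {
  if (length(z) != length(z_c) || length(z) != length(z_pc))
    stop("latent dimension mismatch")
  lambda_c * (sum((z - z_c)^2) + sum((z - z_pc)^2))
}

#' Voxel-statistics regularizer for focused reconstruction
#'
#' Keeps the distribution of decoded values inside the focus mask close
#' to the reference's: squared differences of max, min, mean and standard
#' deviation (population convention), summed over the batch.
#'
#' @param decoded_mask_values Numeric vector of decoded in-mask values, or
#'   a matrix with one batch member per row.
#' @param reference_mask_values Reference in-mask values, same layout.
#' @param lambda5 Nonnegative weight.
#' @return Scalar.
#' @export
focus_stats_loss <- function(decoded_mask_values, reference_mask_values,
                             lambda5 = 1) {
  d <- if (is.matrix(decoded_mask_values)) decoded_mask_values
       else matrix(decoded_mask_values, nrow = 1)
  r <- if (is.matrix(reference_mask_values)) reference_mask_values
       else matrix(reference_mask_values, nrow = 1)
  if (ncol(d) == 0) stop("empty mask in focus statistics loss")
  if (!all(dim(d) == dim(r))) stop("mask value shape mismatch")
  tot <- 0
  for (b in seq_len(nrow(d))) {
    vd <- d[b, ]; vr <- r[b, ]
    sdp <- function(x) sqrt(mean((x - mean(x))^2))
    tot <- tot + (max(vd) - max(vr))^2 + (min(vd) - min(vr))^2 +
      (mean(vd) - mean(vr))^2 + (sdp(vd) - sdp(vr))^2
  }
  lambda5 * tot
}

focus_stats_grad <- function(vd, vr, lambda5 = 1) {
  m <- length(vd)
  mu <- mean(vd); sdp <- sqrt(mean((vd - mu)^2))
  mur <- mean(vr); sdr <- sqrt(mean((vr - mur)^2))
  g <- numeric(m)
  g[which.max(vd)] <- g[which.max(vd)] + 2 * (max(vd) - max(vr))
  g[which.min(vd)] <- g[which.min(vd)] + 2 * (min(vd) - min(vr))
  g <- g + 2 * (mu - mur) / m
  if (sdp > 0) g <- g + 2 * (sdp - sdr) * (vd - mu) / (m * sdp)
  lambda5 * g
}

#' Loss weights
#'
#' @param lambda1,lambda2,lambda3,lambda4,lambda5,lambda_pose,lambda_ctf
#'   Nonnegative weights for the L1 density, negative-value, TV-L1,
#'   TV-L2, focus-statistics, pose-decoupling and CTF-decoupling terms.
#' @return Object of class `loss_weights`.
#' @export
loss_weights <- function(lambda1 = 1, lambda2 = 1, lambda3 = 0.1,
                         lambda4 = 0.1, lambda5 = 1, lambda_pose = 0.1,
                         lambda_ctf = 0.1) {
  w <- list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
            lambda4 = lambda4, lambda5 = lambda5,
            lambda_pose = lambda_pose, lambda_ctf = lambda_ctf)
  if (any(unlist(w) < 0)) stop("loss weights must be nonnegative")
  structure(w, class = "loss_weights")
}

#' Composite objective with per-term breakdown
#'
#' Assembles the full training objective: the multiresolution data term
#' plus all weighted regularizers. Regularizers are evaluated only on the
#' full-resolution composed volumes. Fields of the returned breakdown
#' hold each term's weighted contribution; `total` is their sum and is
#' reproducible by calling the individual loss functions.
#'
#' @param experimental,decoded `N x N x B` image arrays.
#' @param volumes List of composed volumes (arrays), one per batch item,
#'   or NULL to skip volume regularizers.
#' @param weights A [loss_weights()].
#' @param cutoffs Multiresolution levels, subset of `c("full", "half")`.
#' @param z,z_t,z_pt,z_c,z_pc Latent batches for the decoupling terms
#'   (NULL to skip; skipped terms contribute exactly 0).
#' @param decoded_mask_values,reference_mask_values Optional in-mask value
#'   matrices for the focus-statistics term.
#' @param use_correlation Use the correlation data term instead of MSE.
#' @return Object of class `loss_breakdown`.
#' @export
total_loss <- function(experimental, decoded, volumes = NULL,
                       weights = loss_weights(), cutoffs = c("full", "half"),
                       z = NULL, z_t = NULL, z_pt = NULL, z_c = NULL,
                       z_pc = NULL, decoded_mask_values = NULL,
                       reference_mask_values = NULL,
                       use_correlation = FALSE) {
  data_term <- if (use_correlation) data_correlation(experimental, decoded)
               else multires_data_loss(experimental, decoded, cutoffs)
  l1 <- neg <- tvl1 <- tvl2 <- 0
  if (!is.null(volumes)) {
    for (v in volumes) {
      l1 <- l1 + l1_density(v, weights$lambda1)
      neg <- neg + negative_penalty(v, weights$lambda2)
      tc <- tv_components(v)
      tvl1 <- tvl1 + weights$lambda3 * tc["l1"]
      tvl2 <- tvl2 + weights$lambda4 * tc["l2"]
    }
  }
  pd <- if (!is.null(z_t)) pose_decouple_loss(z, z_t, z_pt, weights$lambda_pose) else 0
  cd <- if (!is.null(z_c)) ctf_decouple_loss(z, z_c, z_pc, weights$lambda_ctf) else 0
  fs <- if (!is.null(decoded_mask_values))
    focus_stats_loss(decoded_mask_values, reference_mask_values,
                     weights$lambda5) else 0
  terms <- c(data = unname(data_term), l1 = unname(l1), negative = unname(neg),
             tv_l1 = unname(tvl1), tv_l2 = unname(tvl2),
             pose_decouple = unname(pd), ctf_decouple = unname(cd),
             focus_stats = unname(fs))
  structure(c(as.list(terms), list(total = sum(terms))),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  terms <- setdiff(names(x), "total")
  cat("loss breakdown:\n")
  for (t in terms) cat(sprintf("  %-14s %.6g\n", t, x[[t]]))
  cat(sprintf("  %-14s %.6g\n", "total", x$total))
  invisible(x)
}
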