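# Meta-sinusoidal decoder. Each hidden layer is a hypernetwork pair: a
# dense ReLU layer conditioned on the latent vector produces the weights
# (and biases) of a sine layer that evaluates sin(omega0 * (x W + b)) on
# the queried coordinates. Three hidden layers (the second and third with
# a residual skip over the whole pair) are followed by a dense linear
# output over the per-coordinate features. All gradients are hand-derived;
# they are validated against finite differences in the test suite.

runif_mat <- function(nr, nc, a) matrix(stats::runif(nr * nc, -a, a), nr, nc)

#' Parameters of one meta-sinusoidal layer
#'
#' The hyper branch maps a latent vector `z` through a dense ReLU layer of
#' `hyper_width` units, then linearly to the flattened `(W, b)` of the
#' sine layer. `A2` starts near zero so the generated weights initially
#' sit at the SIREN-initialized offsets `a2` for every `z`.
#'
#' @param d_in,d_out Sine-layer fan-in/fan-out.
#' @param latent_dim Latent dimension feeding the hyper branch.
#' @param hyper_width Neurons of the weight-generating dense ReLU layer.
#' @param omega0 Sine frequency scale.
#' @param first Is this the first layer (SIREN first-layer init)?
#' @return Parameter list of class `meta_layer`.
#' @export
meta_layer_params <- function(d_in, d_out, latent_dim,
                              hyper_width = latent_dim, omega0 = 30,
                              first = FALSE) {
  stopifnot(d_out >= 1, omega0 > 0)
  n_w <- d_in * d_out + d_out
  w_bound <- if (first) 1 / d_in else sqrt(6 / d_in) / omega0
  a2 <- c(stats::runif(d_in * d_out, -w_bound, w_bound),
          stats::runif(d_out, -1, 1) / sqrt(d_in))
  structure(list(
    A1 = runif_mat(latent_dim, hyper_width, sqrt(6 / latent_dim)),
    a1 = numeric(hyper_width),
    A2 = runif_mat(hyper_width, n_w, 0.01 / sqrt(hyper_width)),
    a2 = a2,
    d_in = d_in, d_out = d_out, omega0 = omega0), class = "meta_layer")
}

# Generated sine-layer weights for one latent vector.
meta_generate <- function(layer, z) {
  pre <- as.numeric(z %*% layer$A1) + layer$a1
  r <- pmax(pre, 0)
  wv <- as.numeric(r %*% layer$A2) + layer$a2
  nW <- layer$d_in * layer$d_out
  list(r = r,
       W = matrix(wv[seq_len(nW)], layer$d_in, layer$d_out),
       b = wv[nW + seq_len(layer$d_out)])
}

#' Evaluate one meta-sinusoidal layer
#'
#' Computes `sin(omega0 * (x W(z) + b(z)))` where `(W, b)` are generated
#' from `z` by the layer's dense ReLU hyper branch. Outputs are bounded
#' in `[-1, 1]`.
#'
#' @param x Feature matrix (rows = query points) or vector.
#' @param z Latent vector.
#' @param layer A [meta_layer_params()] object.
#' @return Matrix of sine activations.
#' @export
meta_siren_layer <- function(x, z, layer) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != layer$d_in) stop("feature dimension mismatch")
  if (length(z) != nrow(layer$A1)) stop("latent dimension mismatch")
  gen <- meta_generate(layer, z)
  sin(layer$omega0 * (x %*% gen$W + rep(gen$b, each = nrow(x))))
}

#' Build a meta-SIREN decoder
#'
#' Three hidden meta-sinusoidal layers (residual skips over layers 2 and
#' 3) followed by a dense linear output over coordinate features. Widths
#' default to the latent dimension. The output layer starts at zero so an
#' untrained decoder returns a zero density increment.
#'
#' @param latent_dim Latent dimension.
#' @param width Sine-layer width (default `latent_dim`).
#' @param hyper_width Hyper-layer width (default `latent_dim`).
#' @param omega0 Sine frequency scale (default 30).
#' @return Object of class `siren_decoder`.
#' @export
init_decoder <- function(latent_dim, width = latent_dim,
                         hyper_width = latent_dim, omega0 = 30) {
  layers <- list(
    meta_layer_params(3L, width, latent_dim, hyper_width, omega0, first = TRUE),
    meta_layer_params(width, width, latent_dim, hyper_width, omega0),
    meta_layer_params(width, width, latent_dim, hyper_width, omega0))
  structure(list(latent_dim = as.integer(latent_dim),
                 width = as.integer(width),
                 hyper_width = as.integer(hyper_width), omega0 = omega0,
                 layers = layers,
                 Wo = matrix(0, width, 1), bo = 0),
            class = "siren_decoder")
}

#' Normalized decoder coordinate lattice
#'
#' Centered voxel coordinates of an `N^3` grid scaled to `[-1, 1]^3`
#' (center voxel `floor(N/2)` maps to the origin), as an `N^3 x 3`
#' matrix in column-major voxel order.
#'
#' @param box Grid side N.
#' @return `N^3 x 3` coordinate matrix.
#' @export
decoder_coords <- function(box) {
  c0 <- floor(box / 2)
  ax <- ((0:(box - 1)) - c0) / (box / 2)
  as.matrix(expand.grid(x = ax, y = ax, z = ax))
}

# Forward pass with cached activations (for backprop).
decoder_forward <- function(dec, z, coords) {
  gens <- lapply(dec$layers, meta_generate, z = z)
  om <- dec$omega0
  u1 <- om * (coords %*% gens[[1]]$W + rep(gens[[1]]$b, each = nrow(coords)))
  h1 <- sin(u1)
  u2 <- om * (h1 %*% gens[[2]]$W + rep(gens[[2]]$b, each = nrow(h1)))
  h2 <- h1 + sin(u2)
  u3 <- om * (h2 %*% gens[[3]]$W + rep(gens[[3]]$b, each = nrow(h2)))
  h3 <- h2 + sin(u3)
  out <- as.numeric(h3 %*% dec$Wo) + dec$bo
  list(out = out, gens = gens, u = list(u1, u2, u3),
       h = list(h1, h2, h3), coords = coords, z = z)
}

#' Decode a density increment at query coordinates
#'
#' @param dec A [init_decoder()] object.
#' @param z Latent vector (length `latent_dim`).
#' @param coords `M x 3` matrix of normalized coordinates in `[-1, 1]^3`.
#' @return Numeric vector of `M` density values.
#' @export
decode_delta <- function(dec, z, coords) {
  stopifnot(inherits(dec, "siren_decoder"))
  if (length(z) != dec$latent_dim) stop("latent dimension mismatch")
  if (any(coords < -1 - 1e-9) || any(coords > 1 + 1e-9))
    stop("coordinates must lie in [-1, 1]^3")
  decoder_forward(dec, z, coords)$out
}

# Backward pass. gout: gradient w.r.t. the output values (length M).
# Returns parameter gradients (same shapes as the decoder), dz, and the
# gradient w.r.t. the input coordinates.
decoder_backward <- function(dec, cache, gout, grads = NULL) {
  om <- dec$omega0
  if (is.null(grads)) grads <- decoder_zero_grads(dec)
  h <- cache$h; u <- cache$u; gens <- cache$gens
  gout <- matrix(gout, ncol = 1)
  grads$Wo <- grads$Wo + crossprod(h[[3]], gout)
  grads$bo <- grads$bo + sum(gout)
  dh <- gout %*% t(dec$Wo)  # M x width, gradient w.r.t. h3
  dz <- numeric(dec$latent_dim)
  inputs <- list(cache$coords, h[[1]], h[[2]])
  dcoords <- NULL
  for (l in 3:1) {
    du <- (dh * cos(u[[l]])) * om          # M x d_out
    dW <- crossprod(inputs[[l]], du)       # d_in x d_out
    db <- colSums(du)
    dx <- du %*% t(gens[[l]]$W)            # M x d_in
    # residual skip over layers 2 and 3
    dh_prev <- if (l > 1) dh + dx else NULL
    if (l == 1) dcoords <- dx
    # hyper-branch gradients
    dwv <- c(as.numeric(dW), db)
    gl <- grads$layers[[l]]
    gl$A2 <- gl$A2 + outer(gens[[l]]$r, dwv)
    gl$a2 <- gl$a2 + dwv
    dr <- as.numeric(dec$layers[[l]]$A2 %*% dwv)
    dr[gens[[l]]$r <= 0] <- 0
    gl$A1 <- gl$A1 + outer(cache$z, dr)
    gl$a1 <- gl$a1 + dr
    grads$layers[[l]] <- gl
    dz <- dz + as.numeric(dec$layers[[l]]$A1 %*% dr)
    if (l > 1) dh <- dh_prev
  }
  list(grads = grads, dz = dz, dcoords = dcoords)
}

# Fast (compiled) decoder path used by training: numerically identical
# to decoder_forward / decoder_backward but without materializing the
# per-coordinate activations. Returns only the decoded values plus the
# generated weights needed for the backward call.
decoder_forward_fast <- function(dec, z, coords, want_cache = TRUE) {
  gens <- lapply(dec$layers, meta_generate, z = z)
  fw <- cpp_siren_forward(coords,
                          gens[[1]]$W, gens[[1]]$b, gens[[2]]$W, gens[[2]]$b,
                          gens[[3]]$W, gens[[3]]$b, dec$Wo[, 1], dec$bo,
                          dec$omega0, want_cache)
  c(fw, list(gens = gens, z = z))
}

decoder_backward_fast <- function(dec, fw, coords, gout, grads) {
  gens <- fw$gens
  bw <- cpp_siren_backward(coords,
                           gens[[1]]$W, gens[[2]]$W, gens[[3]]$W,
                           dec$Wo[, 1], dec$omega0, gout,
                           fw$u1, fw$u2, fw$u3, fw$h1, fw$h2)
  grads$Wo <- grads$Wo + matrix(bw$dWo, ncol = 1)
  grads$bo <- grads$bo + bw$dbo
  dz <- numeric(dec$latent_dim)
  dWs <- list(bw$dW1, bw$dW2, bw$dW3)
  dbs <- list(bw$db1, bw$db2, bw$db3)
  for (l in 1:3) {
    dwv <- c(as.numeric(dWs[[l]]), dbs[[l]])
    gl <- grads$layers[[l]]
    gl$A2 <- gl$A2 + outer(gens[[l]]$r, dwv)
    gl$a2 <- gl$a2 + dwv
    dr <- as.numeric(dec$layers[[l]]$A2 %*% dwv)
    dr[gens[[l]]$r <= 0] <- 0
    gl$A1 <- gl$A1 + outer(fw$z, dr)
    gl$a1 <- gl$a1 + dr
    grads$layers[[l]] <- gl
    dz <- dz + as.numeric(dec$layers[[l]]$A1 %*% dr)
  }
  list(grads = grads, dz = dz)
}

decoder_zero_grads <- function(dec) {
  list(layers = lapply(dec$layers, function(l)
    list(A1 = matrix(0, nrow(l$A1), ncol(l$A1)), a1 = numeric(length(l$a1)),
         A2 = matrix(0, nrow(l$A2), ncol(l$A2)), a2 = numeric(length(l$a2)))),
    Wo = matrix(0, nrow(dec$Wo), 1), bo = 0)
}

#' Gradient of the decoded density w.r.t. the query coordinates
#'
#' Analytic input-gradient of [decode_delta()], one 3-vector per query
#' point (the decoder acts pointwise, so outputs at different coordinates
#' are independent).
#'
#' @inheritParams decode_delta
#' @return `M x 3` matrix of gradients.
#' @export
decode_delta_coord_grad <- function(dec, z, coords) {
  cache <- decoder_forward(dec, z, coords)
  decoder_backward(dec, cache, rep(1, nrow(coords)))$dcoords
}

#' Add a decoded increment to the reference volume
#'
#' Elementwise `V0 + dV`; with an empty (zero) reference the result is
#' the increment itself.
#'
#' @param v0 Reference [volume_grid()] or array.
#' @param delta Increment [volume_grid()] or array of identical shape.
#' @return Same type as `v0` (volume_grid if either input is one).
#' @export
compose_volume <- function(v0, delta) {
  a <- as_any_array(v0); b <- as_any_array(delta)
  if (!identical(dim(a), dim(b))) stop("volume shape mismatch")
  out <- a + b
  if (inherits(v0, "volume_grid")) volume_grid(out, v0$voxel_size)
  else if (inherits(delta, "volume_grid")) volume_grid(out, delta$voxel_size)
  else out
}

#' Decode a full volume restricted to a focus mask
#'
#' Evaluates the decoder only at mask voxels; voxels outside the mask are
#' returned bit-exactly equal to the reference. With an all-ones mask the
#' result equals the unfocused decode-and-compose pathway elementwise.
#'
#' @param dec A [init_decoder()] object.
#' @param z Latent vector.
#' @param mask A [vol_mask()].
#' @param v0 Reference [volume_grid()] (zero allowed).
#' @return A [volume_grid()].
#' @export
focused_decode <- function(dec, z, mask, v0) {
  v <- as_any_array(v0)
  m <- mask$data
  if (!identical(dim(m), dim(v))) stop("mask / reference shape mismatch")
  if (mask$voxel_count == 0) {
    warning("empty focus mask; returning the reference volume")
    return(if (inherits(v0, "volume_grid")) v0 else volume_grid(v))
  }
  idx <- which(m == 1)
  coords <- decoder_coords(dim(v)[1])
  delta <- decode_delta(dec, z, coords[idx, , drop = FALSE])
  out <- v
  out[idx] <- out[idx] + delta
  if (inherits(v0, "volume_grid")) volume_grid(out, v0$voxel_size)
  else volume_grid(out)
}

#' Count trainable parameters
#'
#' Recursively sums the lengths of all numeric parameter arrays in an
#' encoder or decoder object (structural fields are skipped).
#'
#' @param x A `siren_decoder` or encoder object.
#' @return Integer parameter count.
#' @export
count_params <- function(x) {
  skip <- c("d_in", "d_out", "omega0", "latent_dim", "width", "hyper_width",
            "arch", "box", "input_dim", "channels")
  total <- 0L
  walk <- function(obj) {
    if (is.list(obj)) {
      nms <- names(obj)
      for (i in seq_along(obj)) {
        nm <- if (is.null(nms)) "" else nms[i]
        if (!nm %in% skip) walk(obj[[i]])
      }
    } else if (is.numeric(obj)) {
      total <<- total + length(obj)
    }
  }
  walk(x)
  total
}
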