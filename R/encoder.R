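# Image encoders. The MLP variant flattens the image through three dense
# ReLU layers (default width 1024); the conv variant is a residual
# convolutional stack (3x3 convolutions, instance normalization, skip
# connections, 2x mean-pool downsampling with channel doubling, global
# average pooling). Both end in two linear heads: the conformational
# latent code and a pose/shift refinement head whose final layer is
# zero-initialized so refinement starts at exactly zero.

he_mat <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nr)), nr, nc)

#' Build an image encoder
#'
#' @param box Image side in pixels.
#' @param latent_dim Latent dimension.
#' @param arch `"mlp"` (three dense ReLU hidden layers) or `"conv"`
#'   (residual convolutional stack).
#' @param width Hidden width of the MLP variant (default 1024).
#' @param base_channels First conv stage channels (conv variant).
#' @param normalize Standardize each input image to zero mean and unit
#'   variance before encoding (the field's usual input normalization; it
#'   also puts noisy experimental images and clean re-encoded
#'   projections on a common scale during the decoupling passes).
#' @return Encoder object of class `image_encoder`.
#' @export
init_encoder <- function(box, latent_dim, arch = c("mlp", "conv"),
                         width = 1024L, base_channels = 8L,
                         normalize = TRUE) {
  arch <- match.arg(arch)
  if (arch == "mlp") {
    d <- as.integer(box)^2
    enc <- list(arch = "mlp", box = as.integer(box), input_dim = d,
                width = as.integer(width), latent_dim = as.integer(latent_dim),
                W1 = he_mat(d, width), b1 = numeric(width),
                W2 = he_mat(width, width), b2 = numeric(width),
                W3 = he_mat(width, width), b3 = numeric(width),
                Wz = he_mat(width, latent_dim), bz = numeric(latent_dim),
                Wp = matrix(0, width, 5), bp = numeric(5))
  } else {
    ch <- base_channels * c(1L, 2L, 4L, 8L, 16L)
    blocks <- lapply(1:4, function(i) list(
      K1 = he_mat(9 * ch[i], ch[i]), c1 = numeric(ch[i]),
      K2 = he_mat(9 * ch[i], ch[i]), c2 = numeric(ch[i]),
      Kd = he_mat(ch[i], ch[i + 1]), cd = numeric(ch[i + 1])))
    enc <- list(arch = "conv", box = as.integer(box),
                latent_dim = as.integer(latent_dim),
                channels = ch,
                K0 = he_mat(9, ch[1]), c0 = numeric(ch[1]),
                blocks = blocks,
                Wz = he_mat(ch[5], latent_dim), bz = numeric(latent_dim),
                Wp = matrix(0, ch[5], 5), bp = numeric(5))
  }
  enc$normalize <- isTRUE(normalize)
  structure(enc, class = "image_encoder")
}

# Per-image standardization; inputs to the encoder are data or detached
# renders, so no gradient flows through these statistics.
standardize_rows <- function(X) {
  mu <- rowMeans(X)
  Xc <- X - mu
  s <- sqrt(rowMeans(Xc^2)) + 1e-8
  Xc / s
}

as_image_batch <- function(images, box) {
  if (is.matrix(images)) {
    if (!all(dim(images) == box))
      stop("image side does not match the encoder box")
    images <- array(images, c(box, box, 1))
  }
  if (is.array(images) && length(dim(images)) == 3) {
    if (dim(images)[1] != box || dim(images)[2] != box)
      stop("image side does not match the encoder box")
    b <- dim(images)[3]
    t(matrix(images, box * box, b))  # B x N^2, rows are flattened images
  } else stop("images must be an N x N matrix or N x N x B array")
}

relu <- function(x) pmax(x, 0)

encoder_forward <- function(enc, X) {
  if (isTRUE(enc$normalize)) X <- standardize_rows(X)
  if (enc$arch == "mlp") {
    addb <- function(m, b) sweep(m, 2, b, "+")
    a1 <- addb(X %*% enc$W1, enc$b1); h1 <- relu(a1)
    a2 <- addb(h1 %*% enc$W2, enc$b2); h2 <- relu(a2)
    a3 <- addb(h2 %*% enc$W3, enc$b3); h3 <- relu(a3)
    z <- addb(h3 %*% enc$Wz, enc$bz)
    p <- addb(h3 %*% enc$Wp, enc$bp)
    list(z = z, refine = p, cache = list(X = X, h1 = h1, h2 = h2, h3 = h3))
  } else {
    conv_encoder_forward(enc, X)
  }
}

encoder_backward <- function(enc, cache, dz, drefine = NULL,
                             grads = NULL) {
  if (is.null(grads)) grads <- encoder_zero_grads(enc)
  if (enc$arch == "mlp") {
    if (is.null(drefine)) drefine <- matrix(0, nrow(dz), 5)
    grads$Wz <- grads$Wz + crossprod(cache$h3, dz)
    grads$bz <- grads$bz + colSums(dz)
    grads$Wp <- grads$Wp + crossprod(cache$h3, drefine)
    grads$bp <- grads$bp + colSums(drefine)
    dh3 <- dz %*% t(enc$Wz) + drefine %*% t(enc$Wp)
    dh3[cache$h3 <= 0] <- 0
    grads$W3 <- grads$W3 + crossprod(cache$h2, dh3)
    grads$b3 <- grads$b3 + colSums(dh3)
    dh2 <- dh3 %*% t(enc$W3); dh2[cache$h2 <= 0] <- 0
    grads$W2 <- grads$W2 + crossprod(cache$h1, dh2)
    grads$b2 <- grads$b2 + colSums(dh2)
    dh1 <- dh2 %*% t(enc$W2); dh1[cache$h1 <= 0] <- 0
    grads$W1 <- grads$W1 + crossprod(cache$X, dh1)
    grads$b1 <- grads$b1 + colSums(dh1)
    grads
  } else {
    conv_encoder_backward(enc, cache, dz, drefine, grads)
  }
}

encoder_zero_grads <- function(enc) {
  if (enc$arch == "mlp") {
    list(W1 = 0 * enc$W1, b1 = 0 * enc$b1, W2 = 0 * enc$W2, b2 = 0 * enc$b2,
         W3 = 0 * enc$W3, b3 = 0 * enc$b3, Wz = 0 * enc$Wz, bz = 0 * enc$bz,
         Wp = 0 * enc$Wp, bp = 0 * enc$bp)
  } else {
    list(K0 = 0 * enc$K0, c0 = 0 * enc$c0,
         blocks = lapply(enc$blocks, function(b)
           list(K1 = 0 * b$K1, c1 = 0 * b$c1, K2 = 0 * b$K2, c2 = 0 * b$c2,
                Kd = 0 * b$Kd, cd = 0 * b$cd)),
         Wz = 0 * enc$Wz, bz = 0 * enc$bz, Wp = 0 * enc$Wp, bp = 0 * enc$bp)
  }
}

#' Encode images into latent codes and pose refinements
#'
#' Deterministic given the encoder parameters. The refinement head is
#' zero-initialized, so a fresh encoder returns exactly zero pose and
#' shift corrections.
#'
#' @param enc An [init_encoder()] object.
#' @param images `N x N` matrix or `N x N x B` array.
#' @return List with `z` (`B x latent_dim` matrix) and `refine` (`B x 5`
#'   matrix: three Euler deltas in degrees, two shift deltas in pixels).
#' @export
encode_images <- function(enc, images) {
  X <- as_image_batch(images, enc$box)
  fw <- encoder_forward(enc, X)
  list(z = fw$z, refine = fw$refine)
}

## ---- convolutional variant -------------------------------------------

pad1 <- function(x) {
  d <- dim(x)
  out <- array(0, c(d[1] + 2, d[2] + 2, d[3]))
  out[2:(d[1] + 1), 2:(d[2] + 1), ] <- x
  out
}

im2col3 <- function(x) {
  # x: H x W x C -> (H*W) x (9C), offset-major within each channel group
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  p <- pad1(x)
  cols <- matrix(0, H * W, 9 * C)
  k <- 1L
  for (c in seq_len(C)) for (dj in 0:2) for (di in 0:2) {
    cols[, k] <- as.numeric(p[di + seq_len(H), dj + seq_len(W), c])
    k <- k + 1L
  }
  cols
}

col2im3 <- function(cols, H, W, C) {
  p <- array(0, c(H + 2, W + 2, C))
  k <- 1L
  for (c in seq_len(C)) for (dj in 0:2) for (di in 0:2) {
    p[di + seq_len(H), dj + seq_len(W), c] <-
      p[di + seq_len(H), dj + seq_len(W), c] + matrix(cols[, k], H, W)
    k <- k + 1L
  }
  p[2:(H + 1), 2:(W + 1), , drop = FALSE]
}

conv3x3_fw <- function(x, K, b) {
  d <- dim(x)
  cols <- im2col3(x)
  y <- sweep(cols %*% K, 2, b, "+")
  list(y = array(y, c(d[1], d[2], ncol(K))), cols = cols)
}

conv3x3_bw <- function(dy, cols, K, d_in) {
  dym <- matrix(dy, ncol = dim(dy)[3])
  list(dK = crossprod(cols, dym), db = colSums(dym),
       dx = col2im3(dym %*% t(K), dim(dy)[1], dim(dy)[2], d_in))
}

inorm_fw <- function(x, eps = 1e-5) {
  d <- dim(x)
  y <- x; mu <- numeric(d[3]); s <- numeric(d[3])
  for (c in seq_len(d[3])) {
    v <- x[, , c]
    mu[c] <- mean(v); s[c] <- sqrt(mean((v - mu[c])^2) + eps)
    y[, , c] <- (v - mu[c]) / s[c]
  }
  list(y = y, s = s)
}

inorm_bw <- function(dy, y, s) {
  dx <- dy
  for (c in seq_len(dim(dy)[3])) {
    g <- dy[, , c]; yh <- y[, , c]
    dx[, , c] <- (g - mean(g) - yh * mean(g * yh)) / s[c]
  }
  dx
}

pool2_fw <- function(x) {
  d <- dim(x)
  H <- max(1L, d[1] %/% 2L); W <- max(1L, d[2] %/% 2L)
  y <- array(0, c(H, W, d[3]))
  for (c in seq_len(d[3]))
    y[, , c] <- 0.25 * (x[2 * seq_len(H) - 1, 2 * seq_len(W) - 1, c] +
                        x[2 * seq_len(H), 2 * seq_len(W) - 1, c] +
                        x[2 * seq_len(H) - 1, 2 * seq_len(W), c] +
                        x[2 * seq_len(H), 2 * seq_len(W), c])
  y
}

pool2_bw <- function(dy, d_in) {
  dx <- array(0, d_in)
  H <- dim(dy)[1]; W <- dim(dy)[2]
  for (c in seq_len(d_in[3])) {
    g <- 0.25 * dy[, , c]
    dx[2 * seq_len(H) - 1, 2 * seq_len(W) - 1, c] <- g
    dx[2 * seq_len(H), 2 * seq_len(W) - 1, c] <- g
    dx[2 * seq_len(H) - 1, 2 * seq_len(W), c] <- g
    dx[2 * seq_len(H), 2 * seq_len(W), c] <- g
  }
  dx
}

conv_sample_forward <- function(enc, img) {
  x <- array(img, c(enc$box, enc$box, 1))
  cache <- list()
  st <- conv3x3_fw(x, enc$K0, enc$c0)
  x <- relu(st$y)
  cache$stem <- list(cols = st$cols, act = x, d_in = dim(array(img, c(enc$box, enc$box, 1))))
  for (i in 1:4) {
    blk <- enc$blocks[[i]]
    c1 <- conv3x3_fw(x, blk$K1, blk$c1)
    n1 <- inorm_fw(c1$y)
    r1 <- relu(n1$y)
    c2 <- conv3x3_fw(r1, blk$K2, blk$c2)
    n2 <- inorm_fw(c2$y)
    s <- relu(x + n2$y)
    p <- pool2_fw(s)
    pm <- matrix(p, ncol = dim(p)[3])
    dn <- sweep(pm %*% blk$Kd, 2, blk$cd, "+")
    xn <- array(relu(dn), c(dim(p)[1], dim(p)[2], ncol(blk$Kd)))
    cache[[paste0("b", i)]] <- list(
      x_in = x, cols1 = c1$cols, n1 = n1, r1 = r1, cols2 = c2$cols,
      n2 = n2, s = s, p = p, pm = pm, dn = dn, x_out = xn)
    x <- xn
  }
  feat <- apply(x, 3, mean)
  cache$x_final <- x
  cache$feat <- feat
  cache
}

conv_encoder_forward <- function(enc, X) {
  B <- nrow(X)
  feats <- matrix(0, B, enc$channels[5])
  caches <- vector("list", B)
  for (b in seq_len(B)) {
    caches[[b]] <- conv_sample_forward(enc, matrix(X[b, ], enc$box, enc$box))
    feats[b, ] <- caches[[b]]$feat
  }
  z <- sweep(feats %*% enc$Wz, 2, enc$bz, "+")
  p <- sweep(feats %*% enc$Wp, 2, enc$bp, "+")
  list(z = z, refine = p, cache = list(samples = caches, feats = feats))
}

conv_encoder_backward <- function(enc, cache, dz, drefine, grads) {
  if (is.null(drefine)) drefine <- matrix(0, nrow(dz), 5)
  feats <- cache$feats
  grads$Wz <- grads$Wz + crossprod(feats, dz)
  grads$bz <- grads$bz + colSums(dz)
  grads$Wp <- grads$Wp + crossprod(feats, drefine)
  grads$bp <- grads$bp + colSums(drefine)
  dfeat <- dz %*% t(enc$Wz) + drefine %*% t(enc$Wp)
  for (b in seq_len(nrow(dz))) {
    sc <- cache$samples[[b]]
    xf <- sc$x_final
    dxf <- xf
    npix <- dim(xf)[1] * dim(xf)[2]
    for (c in seq_len(dim(xf)[3])) dxf[, , c] <- dfeat[b, c] / npix
    dx <- dxf
    for (i in 4:1) {
      blk <- enc$blocks[[i]]; bc <- sc[[paste0("b", i)]]
      g <- grads$blocks[[i]]
      ddn <- matrix(dx, ncol = dim(dx)[3])
      ddn[bc$dn <= 0] <- 0
      g$Kd <- g$Kd + crossprod(bc$pm, ddn)
      g$cd <- g$cd + colSums(ddn)
      dp <- array(ddn %*% t(blk$Kd), dim(bc$p))
      ds <- pool2_bw(dp, dim(bc$s))
      ds[bc$s <= 0] <- 0
      dn2 <- inorm_bw(ds, bc$n2$y, bc$n2$s)
      bw2 <- conv3x3_bw(dn2, bc$cols2, blk$K2, dim(bc$r1)[3])
      g$K2 <- g$K2 + bw2$dK; g$c2 <- g$c2 + bw2$db
      dr1 <- bw2$dx
      dr1[bc$r1 <= 0] <- 0
      dn1 <- inorm_bw(dr1, bc$n1$y, bc$n1$s)
      bw1 <- conv3x3_bw(dn1, bc$cols1, blk$K1, dim(bc$x_in)[3])
      g$K1 <- g$K1 + bw1$dK; g$c1 <- g$c1 + bw1$db
      grads$blocks[[i]] <- g
      dx <- bw1$dx + ds   # skip connection
    }
    dstem <- dx
    dstem[cache$samples[[b]]$stem$act <= 0] <- 0
    dsm <- matrix(dstem, ncol = dim(dstem)[3])
    grads$K0 <- grads$K0 + crossprod(sc$stem$cols, dsm)
    grads$c0 <- grads$c0 + colSums(dsm)
  }
  grads
}
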