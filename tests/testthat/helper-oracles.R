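# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the projector oracle is a plain R voxel loop,
# the convolution oracle is a direct spatial sum, and the PCA oracle is an
# eigendecomposition of the sample covariance.

# Brute-force projector: rotate every voxel coordinate, deposit with
# trilinear splatting into the rotated grid, then sum along z.
oracle_project <- function(v, euler) {
  n <- dim(v)[1]; c0 <- floor(n / 2)
  R <- rotation_matrix(euler)
  rot <- array(0, c(n, n, n))
  for (k in 1:n) for (j in 1:n) for (i in 1:n) {
    val <- v[i, j, k]
    if (val == 0) next
    y <- R %*% c(i - 1 - c0, j - 1 - c0, k - 1 - c0) + c0
    x0 <- floor(y); f <- y - x0
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      xi <- x0[1] + dx; yi <- x0[2] + dy; zi <- x0[3] + dz
      if (xi < 0 || xi >= n || yi < 0 || yi >= n || zi < 0 || zi >= n) next
      w <- (if (dx) f[1] else 1 - f[1]) * (if (dy) f[2] else 1 - f[2]) *
        (if (dz) f[3] else 1 - f[3])
      rot[xi + 1, yi + 1, zi + 1] <- rot[xi + 1, yi + 1, zi + 1] + val * w
    }
  }
  apply(rot, c(1, 2), sum)
}

# Direct circular convolution of two equal-size matrices.
oracle_circular_conv <- function(img, kernel) {
  n <- nrow(img)
  out <- matrix(0, n, n)
  for (p in 1:n) for (q in 1:n) {
    s <- 0
    for (i in 1:n) for (j in 1:n)
      s <- s + img[i, j] * kernel[((p - i) %% n) + 1, ((q - j) %% n) + 1]
    out[p, q] <- s
  }
  out
}

# Small two-lobe test volume (deterministic, smooth, compact support).
toy_volume <- function(n = 16, voxel = 1.5) {
  ax <- seq_len(n) - 1 - floor(n / 2)
  g <- function(cx, cy, cz, s, a) {
    a * (exp(-0.5 * ((ax - cx) / s)^2) %o%
         exp(-0.5 * ((ax - cy) / s)^2) %o%
         exp(-0.5 * ((ax - cz) / s)^2))
  }
  volume_grid(g(-2.5, 0, 0, 1.8, 1) + g(2.5, 0.5, -0.5, 1.4, 0.8), voxel)
}

python_ok <- function() nzchar(Sys.which("python"))

relmax <- function(a, b) max(abs(a - b)) / max(1e-12, max(abs(b)))
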