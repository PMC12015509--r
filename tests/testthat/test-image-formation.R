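test_that("rotation_matrix follows the ZYZ composition and is orthonormal", {
  expect_equal(rotation_matrix(c(0, 0, 0)), diag(3))
  # explicit elementwise axis-rotation product as an independent oracle
  rz <- function(t) {
    t <- t * pi / 180
    matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
  }
  ry <- function(t) {
    t <- t * pi / 180
    matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
  }
  set.seed(1)
  for (i in 1:10) {
    e <- runif(3, -360, 360)
    R <- rotation_matrix(e)
    expect_lt(max(abs(t(R) %*% R - diag(3))), 1e-10)
    expect_equal(det(R), 1, tolerance = 1e-10)
    expect_equal(R, rz(e[1]) %*% ry(e[2]) %*% rz(e[3]), tolerance = 1e-12)
  }
  expect_error(rotation_matrix(c(0, NA, 0)), "finite")
})

test_that("projector matches the brute-force voxel-loop oracle", {
  set.seed(2)
  v <- array(runif(16^3), c(16, 16, 16))
  for (i in 1:6) {
    e <- runif(3, -180, 180)
    got <- project(volume_grid(v), pose(e))
    want <- oracle_project(v, e)
    expect_lt(sqrt(mean((got - want)^2)) / sqrt(mean(want^2)), 1e-3)
  }
})

test_that("projector handles degenerate and point inputs exactly", {
  z <- array(0, c(12, 12, 12))
  expect_equal(project(volume_grid(z), pose(c(33, 50, -10), c(1, 2))),
               matrix(0, 12, 12))
  # unit voxel at the center projects to a unit mass at the center pixel
  v <- z; c0 <- floor(12 / 2) + 1
  v[c0, c0, c0] <- 1
  img <- project(volume_grid(v), pose())
  expect_equal(sum(img), 1, tolerance = 1e-12)
  expect_equal(img[c0, c0], 1, tolerance = 1e-12)
})

test_that("projector is linear and nearly mass-conserving", {
  set.seed(3)
  v1 <- toy_volume(16)$data
  v2 <- array(runif(16^3), c(16, 16, 16))
  ps <- pose(c(25, 70, 110), c(0.4, -0.8))
  lhs <- project(volume_grid(2.5 * v1 - 1.25 * v2), ps)
  rhs <- 2.5 * project(volume_grid(v1), ps) - 1.25 * project(volume_grid(v2), ps)
  expect_equal(lhs, rhs, tolerance = 1e-10)
  # mass near-conservation for a compact smooth phantom
  for (i in 1:5) {
    e <- runif(3, -180, 180)
    expect_lt(abs(sum(project(volume_grid(v1), pose(e))) - sum(v1)) / sum(v1),
              1e-2)
  }
})

test_that("projection of a spherically symmetric phantom is pose-invariant", {
  n <- 24; ax <- seq_len(n) - 1 - floor(n / 2)
  r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  v <- volume_grid(exp(-r2 / (2 * 3.2^2)))
  ref <- project(v, pose())
  set.seed(4)
  for (i in 1:5) {
    img <- project(v, pose(runif(3, -180, 180)))
    expect_lt(sqrt(mean((img - ref)^2)) / sqrt(mean(ref^2)), 0.02)
  }
})

test_that("backproject is the exact adjoint of project", {
  set.seed(5)
  n <- 12
  v <- array(rnorm(n^3), c(n, n, n))
  u <- matrix(rnorm(n^2), n, n)
  ps <- pose(c(15, 40, -70), c(0.3, 1.1))
  expect_equal(sum(project(volume_grid(v), ps) * u),
               sum(v * backproject(u, ps, n)), tolerance = 1e-10)
})

test_that("CTF has the analytic DC value, Friedel symmetry and bounded range", {
  p <- ctf_params(defocus_u = 12000, defocus_v = 16000, astig_angle = 40,
                  amplitude_contrast = 0.1, pixel_size = 1.5)
  C <- ctf_evaluate(p, 16)
  c0 <- floor(16 / 2) + 1
  expect_equal(C[c0, c0], -0.1, tolerance = 1e-12)
  expect_true(all(C >= -1 & C <= 1))
  # Friedel symmetry about the DC pixel (indices that have a mirror)
  for (i in 2:16) for (j in 2:16)
    expect_equal(C[i, j], C[2 * c0 - i, 2 * c0 - j], tolerance = 1e-10)
})

test_that("no astigmatism gives a radially symmetric CTF", {
  p <- ctf_params(defocus_u = 14000, defocus_v = 14000, pixel_size = 1)
  C <- ctf_evaluate(p, 32)
  c0 <- floor(32 / 2) + 1
  ax <- seq_len(32) - c0
  r <- sqrt(outer(ax^2, ax^2, "+"))
  for (rad in c(3, 5, 8)) {
    ring <- C[abs(r - rad) < 1e-9]
    expect_gt(length(ring), 3)
    expect_lt(diff(range(ring)), 1e-10)
  }
})

test_that("first CTF zero crossing matches a root-finding oracle", {
  p <- ctf_params(defocus_u = 15000, defocus_v = 15000, voltage = 300,
                  cs = 2.7, amplitude_contrast = 0.1, pixel_size = 1)
  lambda <- electron_wavelength(300)
  radial <- function(f) {
    chi <- pi * lambda * 15000 * f^2 - (pi / 2) * (2.7e7) * lambda^3 * f^4
    -sqrt(1 - 0.1^2) * sin(chi) - 0.1 * cos(chi)
  }
  f_oracle <- stats::uniroot(radial, c(1e-4, 0.2), tol = 1e-12)$root
  # scan a fine 1D frequency grid of the 2D evaluation for the sign change
  n <- 512
  C <- ctf_evaluate(p, n)
  c0 <- floor(n / 2) + 1
  prof <- C[c0:n, c0]
  f <- (0:(n - c0)) / n
  k <- which(prof[-1] * prof[-length(prof)] < 0)[1]
  f_grid <- f[k] + (f[k + 1] - f[k]) * prof[k] / (prof[k] - prof[k + 1])
  expect_equal(f_grid, f_oracle, tolerance = 1e-3)
})

test_that("apply_ctf is linear and equals real-space circular convolution", {
  set.seed(6)
  p <- ctf_params(defocus_u = 11000, defocus_v = 14000, astig_angle = 25,
                  pixel_size = 1.4)
  i1 <- matrix(rnorm(16^2), 16, 16)
  i2 <- matrix(rnorm(16^2), 16, 16)
  expect_equal(apply_ctf(3 * i1 - 2 * i2, p),
               3 * apply_ctf(i1, p) - 2 * apply_ctf(i2, p), tolerance = 1e-10)
  # forced CTF == 1 leaves the image unchanged
  expect_equal(apply_ctf(i1, ctf = matrix(1, 16, 16)), i1, tolerance = 1e-10)
  # convolution-theorem oracle
  C <- ctf_evaluate(p, 16)
  psf <- Re(stats::fft(cryosiren:::ifftshift2(C), inverse = TRUE)) / 256
  expect_lt(sqrt(mean((apply_ctf(i1, p) - oracle_circular_conv(i1, psf))^2)),
            1e-6)
})

test_that("fourier_shift translates by exact pixel amounts", {
  img <- matrix(0, 16, 16); img[9, 9] <- 1
  sh <- fourier_shift(img, c(2, -3))
  expect_equal(sh[11, 6], 1, tolerance = 1e-10)
  expect_equal(sum(abs(sh)) - 1, 0, tolerance = 1e-9)
})

test_that("forward_model composes projection and CTF deterministically", {
  v <- toy_volume(16, voxel = 1.5)
  rec <- particle_record(1, c(30, 60, -45), c(0.5, -0.25),
                         ctf_params(defocus_u = 9000, defocus_v = 12000,
                                    pixel_size = 1.5))
  expect_equal(forward_model(volume_grid(array(0, c(16, 16, 16)), 1.5), rec),
               matrix(0, 16, 16))
  # identity pose with forced unit CTF is the plain z-sum
  rec0 <- particle_record(1, c(0, 0, 0), c(0, 0), ctf_params(pixel_size = 1.5))
  expect_equal(forward_model(v, rec0, ctf = matrix(1, 16, 16)),
               apply(v$data, c(1, 2), sum), tolerance = 1e-10)
  # bit-identical to the two-step pipeline
  two_step <- apply_ctf(project(v, rec), rec$ctf)
  expect_identical(forward_model(v, rec), two_step)
  expect_identical(forward_model(v, rec), forward_model(v, rec))
})
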