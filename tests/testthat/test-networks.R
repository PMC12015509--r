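test_that("meta-sinusoidal layer obeys forced-weight closed forms and bounds", {
  set.seed(1)
  layer <- meta_layer_params(d_in = 3, d_out = 4, latent_dim = 5,
                             hyper_width = 6, omega0 = 7)
  z <- rnorm(5)
  x <- matrix(runif(12, -1, 1), 4, 3)
  # force the hyper branch to emit W = 0, b = 0 -> sin(0) = 0 everywhere
  l0 <- layer
  l0$A1[] <- 0; l0$a1[] <- 0; l0$A2[] <- 0; l0$a2[] <- 0
  expect_equal(meta_siren_layer(x, z, l0), matrix(0, 4, 4))
  # force a known (W, b) and compare with the closed form
  W <- matrix(seq(-0.5, 0.6, length.out = 12), 3, 4)
  b <- c(0.1, -0.2, 0.3, 0)
  lf <- l0
  lf$a2 <- c(as.numeric(W), b)
  got <- meta_siren_layer(x, z, lf)
  want <- sin(7 * (x %*% W + rep(b, each = 4)))
  expect_equal(got, want, tolerance = 1e-7)
  # outputs bounded by 1 for random inputs
  for (i in 1:5) {
    zz <- rnorm(5, 0, 3)
    xx <- matrix(runif(30, -1, 1), 10, 3)
    expect_true(all(abs(meta_siren_layer(xx, zz, layer)) <= 1))
  }
  expect_error(meta_siren_layer(matrix(0, 2, 2), z, layer), "dimension")
})

test_that("decoder is deterministic, zero at init, and range-checked", {
  set.seed(2)
  dec <- init_decoder(6, width = 8, hyper_width = 6, omega0 = 10)
  z <- rnorm(6)
  coords <- decoder_coords(8)
  # zero-initialized output layer -> identically zero increment
  expect_identical(decode_delta(dec, z, coords), rep(0, nrow(coords)))
  dec$Wo <- matrix(rnorm(8), 8, 1)
  d1 <- decode_delta(dec, z, coords)
  d2 <- decode_delta(dec, z, coords)
  expect_identical(d1, d2)
  expect_gt(stats::sd(d1), 0)
  expect_error(decode_delta(dec, z, matrix(2, 1, 3)), "\\[-1, 1\\]")
  expect_error(decode_delta(dec, rnorm(3), coords), "dimension")
})

test_that("decoder coordinate gradients match finite differences", {
  set.seed(3)
  dec <- init_decoder(4, width = 6, hyper_width = 5, omega0 = 9)
  dec$Wo <- matrix(rnorm(6), 6, 1)
  z <- rnorm(4)
  coords <- matrix(runif(24, -0.9, 0.9), 8, 3)
  g <- decode_delta_coord_grad(dec, z, coords)
  h <- 1e-6
  for (i in c(1, 4, 8)) for (j in 1:3) {
    cp <- coords; cp[i, j] <- cp[i, j] + h
    cm <- coords; cm[i, j] <- cm[i, j] - h
    fd <- (decode_delta(dec, z, cp)[i] - decode_delta(dec, z, cm)[i]) / (2 * h)
    expect_equal(g[i, j], fd, tolerance = 1e-3)
  }
})

test_that("compiled decoder path is numerically identical to the reference", {
  set.seed(4)
  dec <- init_decoder(5, width = 7, hyper_width = 5, omega0 = 11)
  dec$Wo <- matrix(rnorm(7), 7, 1); dec$bo <- 0.4
  z <- rnorm(5)
  coords <- matrix(runif(150, -1, 1), 50, 3)
  ref <- cryosiren:::decoder_forward(dec, z, coords)
  fast <- cryosiren:::decoder_forward_fast(dec, z, coords)
  expect_equal(fast$out, ref$out, tolerance = 1e-12)
  gout <- rnorm(50)
  bref <- cryosiren:::decoder_backward(dec, ref, gout)
  bfast <- cryosiren:::decoder_backward_fast(dec, fast, coords, gout,
                                             cryosiren:::decoder_zero_grads(dec))
  expect_equal(bfast$dz, bref$dz, tolerance = 1e-10)
  for (l in 1:3) {
    expect_equal(bfast$grads$layers[[l]]$A1, bref$grads$layers[[l]]$A1,
                 tolerance = 1e-10)
    expect_equal(bfast$grads$layers[[l]]$A2, bref$grads$layers[[l]]$A2,
                 tolerance = 1e-10)
  }
  expect_equal(bfast$grads$Wo, bref$grads$Wo, tolerance = 1e-10)
})

test_that("compose_volume follows the reference-plus-increment contract", {
  v0 <- toy_volume(12)
  dl <- volume_grid(array(rnorm(12^3), c(12, 12, 12)), 1.5)
  zero <- volume_grid(array(0, c(12, 12, 12)), 1.5)
  expect_equal(compose_volume(zero, dl)$data, dl$data)
  expect_equal(compose_volume(v0, zero)$data, v0$data)
  expect_equal(compose_volume(v0, dl)$data - v0$data, dl$data)
  expect_error(compose_volume(v0, volume_grid(array(0, c(8, 8, 8)))),
               "mismatch")
})

test_that("focused decode equals the reference outside the mask and the
          unfocused pathway inside", {
  set.seed(5)
  dec <- init_decoder(4, width = 6, hyper_width = 4)
  dec$Wo <- matrix(rnorm(6), 6, 1)
  z <- rnorm(4)
  n <- 10
  v0 <- toy_volume(n)
  coords <- decoder_coords(n)
  full <- v0$data + array(decode_delta(dec, z, coords), c(n, n, n))
  # all-ones mask reproduces the unfocused pathway elementwise
  m1 <- vol_mask(array(1, c(n, n, n)))
  expect_equal(focused_decode(dec, z, m1, v0)$data, full, tolerance = 1e-12)
  # all-zeros mask returns the reference exactly (with a warning)
  m0 <- vol_mask(array(0, c(n, n, n)))
  expect_warning(out0 <- focused_decode(dec, z, m0, v0), "empty")
  expect_identical(out0$data, v0$data)
  # random mask: bit-equal reference outside, unfocused values inside
  set.seed(6)
  mr <- vol_mask(array(as.numeric(runif(n^3) < 0.3), c(n, n, n)))
  out <- focused_decode(dec, z, mr, v0)
  outside <- mr$data == 0
  expect_identical(out$data[outside], v0$data[outside])
  expect_equal(out$data[!outside], full[!outside], tolerance = 1e-12)
})

test_that("encoder contracts: zero refinement at init, determinism, latent size", {
  set.seed(7)
  for (arch in c("mlp", "conv")) {
    enc <- init_encoder(16, 10, arch, width = 32, base_channels = 2)
    img <- matrix(rnorm(256), 16, 16)
    out <- encode_images(enc, img)
    expect_equal(ncol(out$z), 10)
    expect_identical(out$refine, matrix(0, 1, 5))
    # identical images give identical latents
    two <- encode_images(enc, array(rep(img, 2), c(16, 16, 2)))
    expect_identical(two$z[1, ], two$z[2, ])
    # same values across batch sizes up to BLAS summation order
    expect_equal(out$z[1, ], two$z[1, ], tolerance = 1e-12)
  }
  enc <- init_encoder(16, 10, "mlp", width = 32)
  expect_error(encode_images(enc, matrix(0, 8, 8)), "match")
})

test_that("pose refinement applies additive clamped corrections", {
  rec <- particle_record(1, c(10, 20, 30), c(1, -1), ctf_params())
  expect_equal(refine_pose(rec, pose_refinement())$euler, c(10, 20, 30))
  expect_equal(refine_pose(rec, pose_refinement())$shift, c(1, -1))
  r1 <- refine_pose(rec, pose_refinement(c(0, 0, 0), c(1, 0)))
  expect_equal(r1$shift, c(2, -1))
  r2 <- refine_pose(rec, pose_refinement(c(10, 0, 0), c(0, 0)), clamp_deg = 5)
  expect_equal(r2$euler[1], 15)
  r3 <- refine_pose(rec, pose_refinement(c(0, 0, 0), c(0, -9)), clamp_px = 2)
  expect_equal(r3$shift[2], -3)
})

test_that("parameter counts match the architecture computed analytically", {
  L <- 6; W <- 9; H <- 7
  dec <- init_decoder(L, width = W, hyper_width = H, omega0 = 30)
  per_layer <- function(d_in, d_out) {
    nw <- d_in * d_out + d_out
    L * H + H +      # A1, a1
      H * nw + nw    # A2, a2
  }
  want_dec <- per_layer(3, W) + 2 * per_layer(W, W) + W + 1
  expect_equal(count_params(dec), want_dec)
  box <- 16; wd <- 24
  enc <- init_encoder(box, L, "mlp", width = wd)
  d <- box^2
  want_enc <- d * wd + wd + 2 * (wd * wd + wd) + wd * L + L + wd * 5 + 5
  expect_equal(count_params(enc), want_enc)
  ch <- 3 * c(1, 2, 4, 8, 16)
  encc <- init_encoder(16, L, "conv", base_channels = 3)
  want_conv <- 9 * ch[1] + ch[1] +
    sum(vapply(1:4, function(i) {
      2 * (9 * ch[i] * ch[i] + ch[i]) + ch[i] * ch[i + 1] + ch[i + 1]
    }, 1)) +
    ch[5] * L + L + ch[5] * 5 + 5
  expect_equal(count_params(encc), want_conv)
})
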