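test_that("summed MSE data term matches its closed forms and a loop oracle", {
  a <- array(c(1, 2), c(1, 2, 1))
  b <- array(0, c(1, 2, 1))
  expect_equal(data_mse(a, b), 5)
  expect_equal(data_mse(b, b), 0)
  set.seed(1)
  x <- array(rnorm(6 * 6 * 3), c(6, 6, 3))
  y <- array(rnorm(6 * 6 * 3), c(6, 6, 3))
  loop <- 0
  for (k in 1:3) for (j in 1:6) for (i in 1:6)
    loop <- loop + (x[i, j, k] - y[i, j, k])^2
  expect_equal(data_mse(x, y), loop, tolerance = 1e-10)
  expect_error(data_mse(x, y[, , 1:2]), "mismatch")
})

test_that("correlation data term hits its analytic anchors", {
  set.seed(2)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  expect_equal(data_correlation(x, x), -1, tolerance = 1e-12)
  expect_equal(data_correlation(x, -x), 1, tolerance = 1e-12)
  expect_equal(data_correlation(x, 2.5 * x + 3), -1, tolerance = 1e-12)
  expect_error(data_correlation(x, array(1, dim(x))), "variance")
})

test_that("L1 density and negative penalties follow their definitions", {
  v <- array(c(1, -2, 3, rep(0, 24 - 3)), c(2, 3, 4))
  expect_equal(l1_density(v, 1), 6)
  expect_equal(l1_density(array(0, c(2, 2, 2)), 5), 0)
  expect_equal(l1_density(3 * v, 1), 3 * l1_density(v, 1))
  expect_equal(l1_density(-3 * v, 1), 3 * l1_density(v, 1))
  expect_equal(negative_penalty(v, 1), 2)
  expect_equal(negative_penalty(abs(v), 7), 0)
  expect_equal(negative_penalty(-abs(v), 2), 2 * sum(abs(v)))
})

test_that("TV losses match the ramp closed form and a triple-loop oracle", {
  n <- 6
  ramp <- array(rep(0:(n - 1), n * n), c(n, n, n))
  expect_equal(tv_loss(ramp, 1, 0), (n - 1) * n^2)
  expect_equal(tv_loss(array(3.7, c(5, 5, 5)), 0.3, 0.4), 0)
  set.seed(3)
  v <- array(rnorm(8^3), c(8, 8, 8))
  l1 <- 0; l2 <- 0
  for (k in 1:8) for (j in 1:8) for (i in 1:8) {
    dx <- if (i < 8) v[i + 1, j, k] - v[i, j, k] else 0
    dy <- if (j < 8) v[i, j + 1, k] - v[i, j, k] else 0
    dz <- if (k < 8) v[i, j, k + 1] - v[i, j, k] else 0
    l1 <- l1 + abs(dx) + abs(dy) + abs(dz)
    l2 <- l2 + dx^2 + dy^2 + dz^2
  }
  expect_equal(tv_loss(v, 1, 0), l1, tolerance = 1e-10)
  expect_equal(tv_loss(v, 0, 1), l2, tolerance = 1e-10)
  expect_equal(tv_loss(v, 0.3, 0.7), 0.3 * l1 + 0.7 * l2, tolerance = 1e-10)
})

test_that("multiresolution loss collapses to MSE at full resolution and
          matches a filter + decimation oracle at half", {
  set.seed(4)
  a <- array(rnorm(16 * 16 * 2), c(16, 16, 2))
  b <- array(rnorm(16 * 16 * 2), c(16, 16, 2))
  expect_equal(multires_data_loss(a, b, "full"), data_mse(a, b),
               tolerance = 1e-12)
  cst <- array(2.2, c(16, 16, 1))
  expect_equal(multires_data_loss(cst, cst, c("full", "half")), 0,
               tolerance = 1e-18)
  # oracle: spatial-domain Gaussian convolution + 2x decimation
  tr <- cryosiren:::lowpass_transfer(16)
  kern <- Re(stats::fft(cryosiren:::ifftshift2(tr), inverse = TRUE)) / 256
  half_oracle <- 0
  for (k in 1:2) {
    r <- oracle_circular_conv(a[, , k] - b[, , k], kern)
    half_oracle <- half_oracle + sum(r[seq(1, 16, 2), seq(1, 16, 2)]^2)
  }
  expect_equal(multires_data_loss(a, b, c("full", "half")),
               data_mse(a, b) + half_oracle, tolerance = 1e-8)
  expect_error(multires_data_loss(a, b, "third"), "invalid")
})

test_that("latent decoupling losses follow the squared-distance form", {
  z <- c(0, 0); zt <- c(1, 0); zpt <- c(0, 2)
  expect_equal(pose_decouple_loss(z, zt, zpt, 1), 5)
  expect_equal(pose_decouple_loss(zt, zt, zt, 3), 0)
  expect_equal(pose_decouple_loss(z, zt, zpt, 2),
               2 * pose_decouple_loss(z, zt, zpt, 1))
  expect_equal(ctf_decouple_loss(z, zt, zt, 1), 2)
  expect_equal(ctf_decouple_loss(z, c(1, 0), c(0, 0), 1),
               ctf_decouple_loss(z, c(0, 0), c(1, 0), 1))
  expect_error(pose_decouple_loss(z, c(1, 2, 3), zpt, 1), "mismatch")
})

test_that("focus statistics loss matches direct computation", {
  set.seed(5)
  vr <- rnorm(40)
  expect_equal(focus_stats_loss(vr, vr, 2), 0)
  cshift <- 0.7
  expect_equal(focus_stats_loss(vr + cshift, vr, 1.5), 1.5 * 3 * cshift^2,
               tolerance = 1e-10)
  vd <- rnorm(40)
  sdp <- function(x) sqrt(mean((x - mean(x))^2))
  want <- (max(vd) - max(vr))^2 + (min(vd) - min(vr))^2 +
    (mean(vd) - mean(vr))^2 + (sdp(vd) - sdp(vr))^2
  expect_equal(focus_stats_loss(vd, vr, 1), want, tolerance = 1e-10)
  # batch form sums over rows
  D <- rbind(vd, vd); R <- rbind(vr, vr)
  expect_equal(focus_stats_loss(D, R, 1), 2 * want, tolerance = 1e-10)
  expect_error(focus_stats_loss(numeric(0), numeric(0), 1), "empty")
})

test_that("total_loss assembles a reproducible weighted breakdown", {
  set.seed(6)
  a <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  b <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  vols <- list(array(rnorm(6^3), c(6, 6, 6)), array(rnorm(6^3), c(6, 6, 6)))
  z <- matrix(rnorm(4), 2, 2); zt <- z + 0.1; zpt <- z - 0.2
  w <- loss_weights(lambda1 = 0.5, lambda2 = 2, lambda3 = 0.1,
                    lambda4 = 0.2, lambda_pose = 0.3, lambda_ctf = 0.4)
  bd <- total_loss(a, b, volumes = vols, weights = w,
                   cutoffs = c("full", "half"),
                   z = z, z_t = zt, z_pt = zpt, z_c = zt, z_pc = zpt)
  manual <- multires_data_loss(a, b, c("full", "half")) +
    sum(vapply(vols, l1_density, 1, lambda1 = 0.5)) +
    sum(vapply(vols, negative_penalty, 1, lambda2 = 2)) +
    sum(vapply(vols, tv_loss, 1, lambda3 = 0.1, lambda4 = 0.2)) +
    pose_decouple_loss(z, zt, zpt, 0.3) +
    ctf_decouple_loss(z, zt, zpt, 0.4)
  expect_equal(bd$total, manual, tolerance = 1e-10)
  expect_equal(bd$total, bd$data + bd$l1 + bd$negative + bd$tv_l1 +
                 bd$tv_l2 + bd$pose_decouple + bd$ctf_decouple +
                 bd$focus_stats, tolerance = 1e-12)
  # all weights zero leaves only the data term
  bd0 <- total_loss(a, b, volumes = vols,
                    weights = loss_weights(0, 0, 0, 0, 0, 0, 0),
                    cutoffs = "full")
  expect_equal(bd0$total, data_mse(a, b), tolerance = 1e-12)
  # degenerate zero case
  zz <- array(0, c(8, 8, 1))
  bdz <- total_loss(zz, zz, volumes = list(array(0, c(4, 4, 4))),
                    z = matrix(0, 1, 2), z_t = matrix(0, 1, 2),
                    z_pt = matrix(0, 1, 2))
  expect_equal(bdz$total, 0)
})

test_that("regularizers are nonnegative and batch permutation-equivariant", {
  set.seed(7)
  for (i in 1:5) {
    v <- array(rnorm(5^3), c(5, 5, 5))
    expect_gte(l1_density(v, 0.7), 0)
    expect_gte(negative_penalty(v, 0.7), 0)
    expect_gte(tv_loss(v, 0.2, 0.3), 0)
  }
  a <- array(rnorm(6 * 6 * 4), c(6, 6, 4))
  b <- array(rnorm(6 * 6 * 4), c(6, 6, 4))
  perm <- c(3, 1, 4, 2)
  expect_equal(multires_data_loss(a, b, c("full", "half")),
               multires_data_loss(a[, , perm], b[, , perm],
                                  c("full", "half")), tolerance = 1e-10)
  expect_equal(data_correlation(a, b),
               data_correlation(a[, , perm], b[, , perm]), tolerance = 1e-12)
  z <- matrix(rnorm(8), 4, 2); zt <- matrix(rnorm(8), 4, 2)
  expect_equal(pose_decouple_loss(z, zt, z, 1),
               pose_decouple_loss(z[perm, ], zt[perm, ], z[perm, ], 1))
})

test_that("loss gradients match central finite differences on small toys", {
  set.seed(8)
  h <- 1e-6
  fd <- function(f, x) {
    g <- x * 0
    for (i in seq_along(x)) {
      x1 <- x; x1[i] <- x1[i] + h
      x2 <- x; x2[i] <- x2[i] - h
      g[i] <- (f(x1) - f(x2)) / (2 * h)
    }
    g
  }
  v <- array(rnorm(4^3), c(4, 4, 4))
  expect_lt(relmax(cryosiren:::tv_loss_grad(v, 0.3, 0.6),
                   fd(function(x) tv_loss(x, 0.3, 0.6), v)), 1e-4)
  expect_lt(relmax(cryosiren:::l1_density_grad(v, 0.8),
                   fd(function(x) l1_density(x, 0.8), v)), 1e-4)
  expect_lt(relmax(cryosiren:::negative_penalty_grad(v, 1.2),
                   fd(function(x) negative_penalty(x, 1.2), v)), 1e-4)
  vd <- rnorm(12); vr <- rnorm(12)
  expect_lt(relmax(cryosiren:::focus_stats_grad(vd, vr, 0.9),
                   fd(function(x) focus_stats_loss(x, vr, 0.9), vd)), 1e-4)
  a <- matrix(rnorm(16), 4, 4); b <- matrix(rnorm(16), 4, 4)
  gm <- cryosiren:::multires_data_grad(a, b, c("full", "half"))
  fdm <- fd(function(x) multires_data_loss(array(a, c(4, 4, 1)),
                                           array(x, c(4, 4, 1)),
                                           c("full", "half")), b)
  expect_lt(relmax(gm, fdm), 1e-4)
  gc_ <- cryosiren:::data_correlation_grad_pair(a, b, 1)
  fdc <- fd(function(x) data_correlation(array(a, c(4, 4, 1)),
                                         array(x, c(4, 4, 1))), b)
  expect_lt(relmax(gc_, fdc), 1e-4)
})
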