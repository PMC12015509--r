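# Ground-truthed synthetic datasets. A two-lobe Gaussian-blob phantom
# stands in for an open/close protein transition: one blob (the "lid")
# translates linearly with a scalar conformational coordinate t in
# [0, 1], so the ground-truth landscape is a straight line. Projections
# are sampled with uniform SO(3) poses and variable CTF, then corrupted
# with white Gaussian noise at a target signal-to-noise ratio.

gaussian_blob <- function(box, center, sigma, amplitude) {
  ax <- seq_len(box) - 1 - floor(box / 2)
  gx <- exp(-0.5 * ((ax - center[1]) / sigma[1])^2)
  gy <- exp(-0.5 * ((ax - center[2]) / sigma[2])^2)
  gz <- exp(-0.5 * ((ax - center[3]) / sigma[3])^2)
  amplitude * (gx %o% gy %o% gz)
}

#' Two-lobe phantom volume
#'
#' Sum of anisotropic Gaussian blobs forming two lobes joined by a
#' bridge, plus a movable "lid" blob. Nonnegative, compactly supported
#' well inside the box; blob geometry is jittered slightly by the seed.
#'
#' @param box Grid side N (>= 16).
#' @param voxel_size Voxel size in Angstrom.
#' @param seed RNG seed.
#' @return A [volume_grid()]; blob parameters are attached as the
#'   `"blobs"` attribute (the last blob is the lid).
#' @details The static lobes are multiplied by a smooth radial taper that
#'   reaches zero at 80\% of the half-box, giving true compact support;
#'   the lid blob is left analytic (its tails are negligible there) so
#'   that trajectory states conserve mass exactly up to grid sampling.
#' @export
make_phantom <- function(box, voxel_size = 1.5, seed = 1) {
  if (box < 16) stop("box must be at least 16")
  set.seed(seed)
  u <- box / 24  # geometry scales with the box
  jit <- function(x, s) x + stats::rnorm(length(x), 0, s)
  blobs <- list(
    list(center = jit(c(-4.5, 0, 0) * u, 0.2), sigma = c(3.2, 2.4, 2.4) * u,
         amplitude = 1.0),
    list(center = jit(c(4.5, 0, 0) * u, 0.2), sigma = c(2.4, 2.8, 2.4) * u,
         amplitude = 0.9),
    list(center = c(0, 0, 0), sigma = c(2.0, 1.4, 1.4) * u, amplitude = 0.5),
    # the lid: a mobile domain above the inter-lobe cleft at t = 0,
    # sized like a real lid domain (~12% of total mass)
    list(center = c(0, 4.0, 0) * u, sigma = c(2.1, 2.1, 2.1) * u,
         amplitude = 1.2))
  v <- array(0, c(box, box, box))
  for (bl in blobs[1:3])
    v <- v + gaussian_blob(box, bl$center, bl$sigma, bl$amplitude)
  v <- v * phantom_taper(box)
  lid <- blobs[[4]]
  v <- v + gaussian_blob(box, lid$center, lid$sigma, lid$amplitude)
  out <- volume_grid(v, voxel_size)
  attr(out, "blobs") <- blobs
  out
}

# Smooth radial taper: 1 inside 0.3 N, cosine ramp to 0 at 0.4 N.
phantom_taper <- function(box) {
  ax <- seq_len(box) - 1 - floor(box / 2)
  r <- sqrt(outer(outer(ax^2, ax^2, "+"), ax^2, "+"))
  r0 <- 0.3 * box; r1 <- 0.4 * box
  w <- array(1, c(box, box, box))
  ramp <- r > r0 & r < r1
  w[ramp] <- 0.5 * (1 + cos(pi * (r[ramp] - r0) / (r1 - r0)))
  w[r >= r1] <- 0
  w
}

#' Linear open-to-close trajectory specification
#'
#' The conformational family is parameterized by one scalar t in
#' `[0, 1]`: the lid blob translates from its base position by
#' `t * displacement` voxels while the rest of the phantom stays fixed,
#' so the ground-truth conformational landscape is a straight line.
#'
#' @param base_phantom A [make_phantom()] volume (with blob attributes).
#' @param displacement Lid displacement at t = 1, voxels (default closes
#'   the cleft: downward y translation scaled to the box).
#' @param n_states Number of nominal states (metadata only; t is
#'   continuous).
#' @return Object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(base_phantom, displacement = NULL,
                            n_states = 11) {
  blobs <- attr(base_phantom, "blobs")
  if (is.null(blobs)) stop("base phantom lacks blob parameters")
  box <- base_phantom$box
  if (is.null(displacement)) displacement <- c(0, -7, 2) * (box / 24)
  lid <- blobs[[length(blobs)]]
  end <- lid$center + displacement
  if (any(abs(end) + 3 * max(lid$sigma) > 0.45 * box))
    stop("displacement would carry the lid outside the supported region")
  structure(list(base_phantom = base_phantom, moving_component = lid,
                 displacement = displacement, n_states = n_states),
            class = "trajectory_spec")
}

#' Volume of one conformational state
#'
#' @param spec A [trajectory_spec()].
#' @param t Conformational coordinate in `[0, 1]`.
#' @return A [volume_grid()]; at t = 0 this is the base phantom exactly,
#'   and the volume sum is constant in t.
#' @export
state_volume <- function(spec, t) {
  if (t < 0 || t > 1) stop("t must lie in [0, 1]")
  if (t == 0) return(spec$base_phantom)
  box <- spec$base_phantom$box
  lid <- spec$moving_component
  v <- spec$base_phantom$data -
    gaussian_blob(box, lid$center, lid$sigma, lid$amplitude) +
    gaussian_blob(box, lid$center + t * spec$displacement, lid$sigma,
                  lid$amplitude)
  volume_grid(v, spec$base_phantom$voxel_size)
}

#' Draw a pose uniformly on SO(3)
#'
#' rot and psi uniform on `[0, 360)`; tilt with density proportional to
#' `sin(tilt)` on `[0, 180]` (inverse-CDF sampling), which together give
#' the uniform (Haar) distribution over orientations.
#'
#' @param n Number of poses.
#' @return Data.frame with columns rot, tilt, psi (degrees).
#' @export
sample_poses_uniform <- function(n) {
  data.frame(rot = stats::runif(n, 0, 360),
             tilt = acos(1 - 2 * stats::runif(n)) * 180 / pi,
             psi = stats::runif(n, 0, 360))
}

#' Simulate a ground-truthed heterogeneous particle dataset
#'
#' For each particle: draw t uniform on `[0, 1]`, a uniform SO(3) pose,
#' and defocus uniform within `defocus_range`; render the noise-free
#' image with the full forward model on the state volume, then add white
#' Gaussian noise with per-image variance `var(signal) / snr`.
#'
#' @param spec A [trajectory_spec()].
#' @param n_particles Number of particles (default 500).
#' @param snr Signal-to-noise ratio (signal variance / noise variance);
#'   `Inf` disables noise.
#' @param defocus_range Defocus range in Angstrom (default 0.5-2.5 um).
#' @param voltage,cs,amplitude_contrast Microscope parameters.
#' @param shift_range Max absolute in-plane shift in pixels (default 0).
#' @param seed RNG seed; the dataset is bit-reproducible given the seed.
#' @return List with `stack` ([image_stack()]), `records` (list of
#'   [particle_record()]) and `ground_truth` (data.frame with
#'   `particle_index`, `t`).
#' @export
simulate_dataset <- function(spec, n_particles = 500, snr = 0.5,
                             defocus_range = c(5000, 25000),
                             voltage = 300, cs = 2.7,
                             amplitude_contrast = 0.1, shift_range = 0,
                             seed = 1) {
  if (n_particles < 1) stop("need at least one particle")
  if (length(defocus_range) != 2 || diff(defocus_range) < 0 ||
      any(defocus_range <= 0))
    stop("invalid defocus range")
  if (!(snr > 0)) stop("snr must be positive")
  set.seed(seed)
  box <- spec$base_phantom$box
  px <- spec$base_phantom$voxel_size
  tvals <- stats::runif(n_particles)
  poses <- sample_poses_uniform(n_particles)
  du <- stats::runif(n_particles, defocus_range[1], defocus_range[2])
  dv <- stats::runif(n_particles, defocus_range[1], defocus_range[2])
  dang <- stats::runif(n_particles, 0, 180)
  sx <- if (shift_range > 0) stats::runif(n_particles, -shift_range, shift_range)
        else numeric(n_particles)
  sy <- if (shift_range > 0) stats::runif(n_particles, -shift_range, shift_range)
        else numeric(n_particles)
  images <- array(0, c(box, box, n_particles))
  records <- vector("list", n_particles)
  for (i in seq_len(n_particles)) {
    records[[i]] <- particle_record(
      image_index = i,
      euler = c(poses$rot[i], poses$tilt[i], poses$psi[i]),
      shift = c(sx[i], sy[i]),
      ctf = ctf_params(defocus_u = du[i], defocus_v = dv[i],
                       astig_angle = dang[i], voltage = voltage, cs = cs,
                       amplitude_contrast = amplitude_contrast,
                       pixel_size = px))
    img <- forward_model(state_volume(spec, tvals[i]), records[[i]])
    if (is.finite(snr)) {
      sd_noise <- sqrt(stats::var(as.numeric(img)) / snr)
      img <- img + matrix(stats::rnorm(box * box, 0, sd_noise), box, box)
    }
    images[, , i] <- img
  }
  list(stack = image_stack(images, px), records = records,
       ground_truth = data.frame(particle_index = seq_len(n_particles),
                                 t = tvals))
}

#' Write a simulated dataset to disk
#'
#' Writes `stack.mrcs`, `particles.star` and `ground_truth.csv` into a
#' directory.
#'
#' @param dataset Result of [simulate_dataset()].
#' @param out_dir Output directory.
#' @return The directory, invisibly.
#' @export
write_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_particles(dataset$stack, dataset$records,
                  file.path(out_dir, "particles.star"),
                  file.path(out_dir, "stack.mrcs"))
  utils::write.csv(dataset$ground_truth,
                   file.path(out_dir, "ground_truth.csv"), row.names = FALSE)
  invisible(out_dir)
}
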