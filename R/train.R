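# Training orchestration: the standard pass (encode -> decode -> project
# -> CTF -> multiresolution data term + real-space regularizers), the
# pose-shuffled and CTF-shuffled decoupling passes, and Adam updates.
#
# Gradient routing in the decoupling passes: the re-encoded projections
# are generated from the decoded volumes treated as constants (the
# decoder receives no gradient from passes 2-3); gradients flow into the
# encoder both through the re-encoded codes and through the pass-1 codes.

#' Uniform random permutation of a batch
#'
#' Used to shuffle the pose (or CTF) assignments within a batch; the
#' multiset of assignments is preserved, so the marginal pose
#' distribution is unchanged. Draws from R's RNG stream.
#'
#' @param items List or vector.
#' @return Permuted copy of `items`.
#' @export
shuffle_within_batch <- function(items) {
  n <- length(items)
  if (n <= 1) return(items)
  items[sample.int(n)]
}

record_pose <- function(record, refinement = NULL, cfg = NULL) {
  if (is.null(refinement)) pose(record$euler, record$shift)
  else refine_pose(record, refinement, cfg$pose_clamp_deg, cfg$shift_clamp_px)
}

# Forward and backward passes on one batch; no parameter update.
# batch: list(images = N x N x B array, records = list of particle_record,
#             ctfs = list of precomputed centered CTF grids)
# Returns encoder/decoder gradients, the loss breakdown and the latent batch.
training_gradients <- function(model, batch) {
  cfg <- model$config
  enc <- model$encoder; dec <- model$decoder
  box <- model$box
  B <- length(batch$records)
  X <- as_image_batch(batch$images, box)
  w <- loss_weights(cfg$lambda1, cfg$lambda2, cfg$lambda3, cfg$lambda4,
                    cfg$lambda5, cfg$lambda_pose, cfg$lambda_ctf)
  focused <- !is.null(model$mask)
  idx <- if (focused) model$mask_idx else model$support_idx
  restricted <- !is.null(idx)
  coords_q <- if (restricted) model$coords[idx, , drop = FALSE]
              else model$coords

  fw <- encoder_forward(enc, X)
  z <- fw$z
  refinement <- if (cfg$refine_pose)
    lapply(seq_len(B), function(b)
      pose_refinement(fw$refine[b, 1:3], fw$refine[b, 4:5])) else NULL

  dec_caches <- vector("list", B)
  volumes <- vector("list", B)
  poses <- vector("list", B)
  clean <- array(0, c(box, box, B))
  decoded <- array(0, c(box, box, B))
  for (b in seq_len(B)) {
    dec_caches[[b]] <- decoder_forward_fast(dec, z[b, ], coords_q)
    v <- model$v0
    if (restricted) v[idx] <- v[idx] + dec_caches[[b]]$out
    else v <- v + array(dec_caches[[b]]$out, dim(v))
    volumes[[b]] <- v
    poses[[b]] <- record_pose(batch$records[[b]],
                              if (cfg$refine_pose) refinement[[b]], cfg)
    clean[, , b] <- project(v, poses[[b]])
    decoded[, , b] <- apply_ctf(clean[, , b], ctf = batch$ctfs[[b]])
  }

  # ---- data term gradient, back through CTF and projector -------------
  transfer <- if ("half" %in% cfg$multires_levels) lowpass_transfer(box)
  enc_grads <- encoder_zero_grads(enc)
  dec_grads <- decoder_zero_grads(dec)
  dz <- matrix(0, B, cfg$latent_dim)
  term_data <- term_l1 <- term_neg <- term_tvl1 <- term_tvl2 <- term_fs <- 0
  for (b in seq_len(B)) {
    if (isTRUE(cfg$use_correlation)) {
      g_data <- data_correlation_grad_pair(batch$images[, , b],
                                           decoded[, , b], B)
    } else {
      gl <- multires_grad_loss(batch$images[, , b], decoded[, , b],
                               cfg$multires_levels, transfer)
      term_data <- term_data + gl$loss
      g_data <- gl$grad
    }
    g_clean <- apply_ctf(g_data, ctf = batch$ctfs[[b]])  # self-adjoint
    dV <- backproject(g_clean, poses[[b]], box)
    v <- volumes[[b]]
    tv <- tv_grad_components(v, w$lambda3, w$lambda4)
    term_l1 <- term_l1 + w$lambda1 * sum(abs(v))
    term_neg <- term_neg + w$lambda2 * sum(abs(pmin(v, 0)))
    term_tvl1 <- term_tvl1 + w$lambda3 * tv$l1
    term_tvl2 <- term_tvl2 + w$lambda4 * tv$l2
    dV <- dV + l1_density_grad(v, w$lambda1) +
      negative_penalty_grad(v, w$lambda2) + tv$grad
    if (focused && w$lambda5 > 0) {
      dV[idx] <- dV[idx] + focus_stats_grad(v[idx], model$v0[idx], w$lambda5)
      term_fs <- term_fs + focus_stats_loss(v[idx], model$v0[idx], w$lambda5)
    }
    gout <- if (restricted) dV[idx] else as.numeric(dV)
    bw <- decoder_backward_fast(dec, dec_caches[[b]], coords_q, gout,
                                dec_grads)
    dec_grads <- bw$grads
    dz[b, ] <- dz[b, ] + bw$dz
  }

  # ---- decoupling passes (decoder and volumes detached) ---------------
  z_t <- z_pt <- z_c <- z_pc <- NULL
  fw_t <- fw_pt <- fw_c <- fw_pc <- NULL
  do_pose <- isTRUE(cfg$decouple_pose) && w$lambda_pose > 0
  do_ctf <- isTRUE(cfg$decouple_ctf) && w$lambda_ctf > 0
  if (do_pose) {
    perm <- shuffle_within_batch(seq_len(B))
    shuffled <- array(0, c(box, box, B))
    for (b in seq_len(B))
      shuffled[, , b] <- project(volumes[[b]], poses[[perm[b]]])
    fw_t <- encoder_forward(enc, as_image_batch(clean, box))
    fw_pt <- encoder_forward(enc, as_image_batch(shuffled, box))
    z_t <- fw_t$z; z_pt <- fw_pt$z
    dz <- dz + 2 * w$lambda_pose * (2 * z - z_t - z_pt)
    enc_grads <- encoder_backward(enc, fw_t$cache,
                                  2 * w$lambda_pose * (z_t - z),
                                  grads = enc_grads)
    enc_grads <- encoder_backward(enc, fw_pt$cache,
                                  2 * w$lambda_pose * (z_pt - z),
                                  grads = enc_grads)
  }
  if (do_ctf) {
    perm_c <- shuffle_within_batch(seq_len(B))
    shuffled_ctf <- array(0, c(box, box, B))
    for (b in seq_len(B))
      shuffled_ctf[, , b] <- apply_ctf(clean[, , b],
                                       ctf = batch$ctfs[[perm_c[b]]])
    fw_c <- encoder_forward(enc, as_image_batch(decoded, box))
    fw_pc <- encoder_forward(enc, as_image_batch(shuffled_ctf, box))
    z_c <- fw_c$z; z_pc <- fw_pc$z
    dz <- dz + 2 * w$lambda_ctf * (2 * z - z_c - z_pc)
    enc_grads <- encoder_backward(enc, fw_c$cache,
                                  2 * w$lambda_ctf * (z_c - z),
                                  grads = enc_grads)
    enc_grads <- encoder_backward(enc, fw_pc$cache,
                                  2 * w$lambda_ctf * (z_pc - z),
                                  grads = enc_grads)
  }

  # ---- pose-refinement gradients (finite differences through the
  # projector); refinement is off by default --------------------------
  drefine <- NULL
  if (cfg$refine_pose) {
    drefine <- matrix(0, B, 5)
    hstep <- 1e-3
    for (b in seq_len(B)) {
      base <- fw$refine[b, ]
      for (j in 1:5) {
        for (s in c(1, -1)) {
          pert <- base; pert[j] <- pert[j] + s * hstep
          pp <- refine_pose(batch$records[[b]],
                            pose_refinement(pert[1:3], pert[4:5]),
                            cfg$pose_clamp_deg, cfg$shift_clamp_px)
          img <- apply_ctf(project(volumes[[b]], pp), ctf = batch$ctfs[[b]])
          l <- multires_data_loss(batch$images[, , b, drop = FALSE],
                                  array(img, c(box, box, 1)),
                                  cfg$multires_levels)
          drefine[b, j] <- drefine[b, j] + s * l / (2 * hstep)
        }
      }
    }
  }

  enc_grads <- encoder_backward(enc, fw$cache, dz, drefine,
                                grads = enc_grads)

  if (isTRUE(cfg$use_correlation))
    term_data <- data_correlation(batch$images, decoded)
  terms <- c(data = term_data, l1 = term_l1, negative = term_neg,
             tv_l1 = term_tvl1, tv_l2 = term_tvl2,
             pose_decouple = if (do_pose)
               pose_decouple_loss(z, z_t, z_pt, w$lambda_pose) else 0,
             ctf_decouple = if (do_ctf)
               ctf_decouple_loss(z, z_c, z_pc, w$lambda_ctf) else 0,
             focus_stats = term_fs)
  breakdown <- structure(c(as.list(terms), list(total = sum(terms))),
                         class = "loss_breakdown")
  if (!is.finite(breakdown$total))
    stop("non-finite loss encountered (total = ", breakdown$total,
         "); check learning rate and input scaling")

  list(enc_grads = enc_grads, dec_grads = dec_grads,
       breakdown = breakdown, z = z)
}

# One optimization step on a batch: gradients + a single Adam update.
training_step <- function(model, batch, opt_state = NULL) {
  gb <- training_gradients(model, batch)
  params <- list(encoder = model$encoder, decoder = model$decoder)
  grads <- list(encoder = gb$enc_grads, decoder = gb$dec_grads)
  if (is.null(opt_state)) opt_state <- adam_init(params)
  upd <- adam_update(params, grads, opt_state, model$config$learning_rate)
  model$encoder <- upd$params$encoder
  model$decoder <- upd$params$decoder
  list(model = model, opt_state = upd$state, breakdown = gb$breakdown)
}

precompute_ctfs <- function(records, box) {
  lapply(records, function(r) ctf_evaluate(r$ctf, box))
}

#' Train a heterogeneous-reconstruction model
#'
#' Runs the full training loop: per epoch, particles are shuffled into
#' batches; each batch performs the standard pass, the pose-shuffled and
#' CTF-shuffled decoupling passes (when enabled), and one Adam update.
#' Reproducible given the configuration seed (single-threaded).
#'
#' @param dataset List with `stack` ([image_stack()]) and `records`
#'   (list of [particle_record()]), as returned by [read_particles()] or
#'   [simulate_dataset()].
#' @param config Configuration list (see [default_config()]).
#' @param v0 Optional reference [volume_grid()].
#' @param mask Optional [vol_mask()] for focused reconstruction.
#' @param out_dir Optional directory for checkpoints and the loss log.
#' @param verbose Print per-epoch loss summaries.
#' @return Object of class `hetrec_fit`: list with `model`, `log`
#'   (per-step data.frame of loss terms) and `opt_state`.
#' @export
train <- function(dataset, config = list(), v0 = NULL, mask = NULL,
                  out_dir = NULL, verbose = FALSE) {
  stack <- dataset$stack
  if (stack$n < 1) stop("dataset is empty")
  model <- init_model(stack$box, config, v0 = v0, mask = mask,
                      voxel_size = stack$pixel_size)
  cfg <- model$config
  ctfs <- precompute_ctfs(dataset$records, stack$box)
  opt_state <- NULL
  log_rows <- list()
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  if (cfg$epochs >= 1) for (epoch in seq_len(cfg$epochs)) {
    order <- sample.int(stack$n)
    starts <- seq(1, stack$n, by = cfg$batch_size)
    for (s in starts) {
      sel <- order[s:min(s + cfg$batch_size - 1, stack$n)]
      batch <- list(images = stack$images[, , sel, drop = FALSE],
                    records = dataset$records[sel],
                    ctfs = ctfs[sel])
      step <- training_step(model, batch, opt_state)
      model <- step$model; opt_state <- step$opt_state
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(epoch = epoch, step = length(log_rows) + 1L,
                   as.list(unlist(step$breakdown)))
    }
    if (verbose) {
      last <- log_rows[[length(log_rows)]]
      message(sprintf("epoch %d/%d  data %.4g  total %.4g", epoch,
                      cfg$epochs, last$data, last$total))
    }
    if (!is.null(out_dir) && epoch %% cfg$checkpoint_every == 0) {
      model$opt <- opt_state
      save_checkpoint(model, file.path(out_dir,
                                       sprintf("checkpoint_%03d.rds", epoch)))
      model$opt <- NULL
    }
  }
  log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(epoch = integer(), step = integer())
  if (!is.null(out_dir))
    utils::write.csv(log, file.path(out_dir, "training_log.csv"),
                     row.names = FALSE)
  structure(list(model = model, log = log, opt_state = opt_state),
            class = "hetrec_fit")
}

#' @export
print.hetrec_fit <- function(x, ...) {
  cat(sprintf("<hetrec_fit: %d steps trained, final total loss %.5g>\n",
              nrow(x$log), if (nrow(x$log)) x$log$total[nrow(x$log)] else NA))
  invisible(x)
}

#' Fit the decoder to a single target volume (capacity check)
#'
#' Optimizes decoder parameters alone, at a fixed latent point, to
#' represent one volume by full-grid mean-square error. Used to verify
#' the meta-sinusoidal architecture has enough capacity to represent a
#' map before asking it to span a conformational family.
#'
#' @param target A [volume_grid()].
#' @param steps Adam steps.
#' @param lr Learning rate.
#' @param latent_dim,width,hyper_width,omega0 Decoder architecture.
#' @param support `"sphere"` to fit only the inscribed sphere (the
#'   region the package reconstructs by default), `"cube"` for the full
#'   grid.
#' @param stop_at Stop early once the full-grid correlation (checked
#'   every 100 steps) reaches this value; `NULL` runs all steps.
#' @param seed RNG seed for initialization.
#' @return List with `decoder`, `z`, `correlation` (final real-space
#'   Pearson correlation with the target over the full grid), `trace`
#'   (correlation every 100 steps) and `steps_run`.
#' @export
fit_decoder_to_volume <- function(target, steps = 2000, lr = 1e-3,
                                  latent_dim = 10, width = latent_dim,
                                  hyper_width = latent_dim, omega0 = 30,
                                  support = c("sphere", "cube"),
                                  stop_at = NULL, seed = 1) {
  stopifnot(inherits(target, "volume_grid"))
  support <- match.arg(support)
  set.seed(seed)
  dec <- init_decoder(latent_dim, width, hyper_width, omega0)
  z <- stats::rnorm(latent_dim, 0, 0.1)
  coords <- decoder_coords(target$box)
  tgt_full <- as.numeric(target$data)
  sidx <- if (support == "sphere") which(rowSums(coords^2) <= 1)
          else seq_len(nrow(coords))
  coords_q <- coords[sidx, , drop = FALSE]
  tgt <- tgt_full[sidx]
  opt <- NULL
  trace <- numeric()
  full_cor <- function(vals) {
    pred <- numeric(length(tgt_full))
    pred[sidx] <- vals
    stats::cor(pred, tgt_full)
  }
  for (s in seq_len(steps)) {
    cache <- decoder_forward_fast(dec, z, coords_q)
    resid <- cache$out - tgt
    bw <- decoder_backward_fast(dec, cache, coords_q, 2 * resid,
                                decoder_zero_grads(dec))
    if (is.null(opt)) opt <- adam_init(dec)
    upd <- adam_update(dec, bw$grads, opt, lr)
    dec <- upd$params; opt <- upd$state
    class(dec) <- "siren_decoder"
    if (s %% 100 == 0) {
      trace <- c(trace, full_cor(cache$out))
      if (!is.null(stop_at) && trace[length(trace)] >= stop_at) break
    }
  }
  final <- full_cor(decoder_forward_fast(dec, z, coords_q,
                                         want_cache = FALSE)$out)
  list(decoder = dec, z = z, correlation = final, trace = trace,
       steps_run = s)
}
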