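# Shared scaled study conditions for the verification experiments, plus
# lazy caching so several test blocks can interrogate the same trained
# models without retraining.
#
# Conditions (fixed; rationale in the methods vignette): two-lobe
# phantom at box 24 (1.5 A/voxel), 500 particles, SNR 0.5, defocus
# 0.5-2.5 um; latent 10, MLP encoder width 256, Adam lr 3e-4, batch 8,
# 12 epochs; decoupling weights 0.1. The entangled control sets
# lambda_p = lambda_c = 0 and the unregularized control sets
# lambda2 = 0, on identical data and seeds.

experiment_dataset <- function(seed) {
  ph <- make_phantom(24, seed = 100 + seed)
  spec <- trajectory_spec(ph)
  simulate_dataset(spec, n_particles = 500, snr = 0.5, seed = 200 + seed)
}

experiment_config <- function(seed, arm = c("decoupled", "entangled",
                                            "unregularized")) {
  arm <- match.arg(arm)
  cfg <- list(latent_dim = 10, encoder_width = 256, epochs = 12,
              learning_rate = 3e-4, seed = seed)
  if (arm == "entangled") {
    cfg$lambda_pose <- 0
    cfg$lambda_ctf <- 0
  }
  if (arm == "unregularized") cfg$lambda2 <- 0
  cfg
}

.experiment_cache <- new.env(parent = emptyenv())

experiment_fit <- function(seed, arm = "decoupled") {
  key <- paste(arm, seed, sep = "_")
  if (is.null(.experiment_cache[[key]])) {
    ds <- experiment_dataset(seed)
    fit <- train(ds, experiment_config(seed, arm))
    .experiment_cache[[key]] <- list(fit = fit, ds = ds)
  }
  .experiment_cache[[key]]
}

landscape_correlation <- function(run) {
  lt <- embed_dataset(run$fit, run$ds)
  pc <- pca_reduce(lt, k = 2)
  abs(stats::cor(lt$t, pc$scores[, 1]))
}

# Most negative voxel relative to the maximum, over decoded cluster
# representatives of the run's latent space.
negative_voxel_ratio <- function(run, k = 5) {
  lt <- embed_dataset(run$fit, run$ds)
  km <- kmeans_representatives(lt, k = k, seed = 1)
  ratios <- vapply(seq_len(k), function(i) {
    m <- decode_map(run$fit$model, km$centroids[i, ])
    min(m$data) / max(m$data)
  }, numeric(1))
  min(ratios)
}
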