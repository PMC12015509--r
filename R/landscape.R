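# Post-training latent-space analysis: embed every particle, reduce with
# PCA, cluster with K-means in the full latent space, and decode
# representative maps.

#' Embed a dataset into the conformational latent space
#'
#' Encodes every particle image; deterministic, one row per particle in
#' stack order. If the dataset carries a `ground_truth` data.frame with a
#' `t` column (synthetic data), it is joined onto the table.
#'
#' @param model A trained [init_model()] object (or a `hetrec_fit`).
#' @param dataset List with `stack` and optionally `ground_truth`.
#' @param batch_size Encoding batch size.
#' @return A `latent_table` data.frame: `particle_index`, `z_1..z_L`, and
#'   optionally `t`.
#' @export
embed_dataset <- function(model, dataset, batch_size = 64) {
  if (inherits(model, "hetrec_fit")) model <- model$model
  stack <- dataset$stack
  L <- model$config$latent_dim
  zs <- matrix(0, stack$n, L)
  for (s in seq(1, stack$n, by = batch_size)) {
    sel <- s:min(s + batch_size - 1, stack$n)
    zs[sel, ] <- encode_images(model$encoder,
                               stack$images[, , sel, drop = FALSE])$z
  }
  out <- data.frame(particle_index = seq_len(stack$n), zs)
  names(out) <- c("particle_index", paste0("z_", seq_len(L)))
  if (!is.null(dataset$ground_truth) && "t" %in% names(dataset$ground_truth))
    out$t <- dataset$ground_truth$t
  class(out) <- c("latent_table", "data.frame")
  out
}

latent_matrix <- function(table) {
  as.matrix(table[, grep("^z_", names(table)), drop = FALSE])
}

#' PCA reduction of a latent table
#'
#' Centered (not scaled) principal component analysis of the latent
#' cloud; invariant to translation of the cloud.
#'
#' @param table A `latent_table` from [embed_dataset()].
#' @param k Number of components (`k < latent_dim`).
#' @return List with `scores` (n x k), `rotation` (orthonormal columns),
#'   `center`, and `variance_ratio` (non-increasing, sums to <= 1).
#' @export
pca_reduce <- function(table, k = 3) {
  Z <- latent_matrix(table)
  if (k >= ncol(Z)) stop("k must be smaller than the latent dimension")
  if (nrow(Z) <= k) stop("need more rows than components")
  p <- stats::prcomp(Z, center = TRUE, scale. = FALSE)
  ratio <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x[, seq_len(k), drop = FALSE],
       rotation = p$rotation[, seq_len(k), drop = FALSE],
       center = p$center,
       variance_ratio = ratio[seq_len(k)])
}

#' K-means cluster representatives in the full latent space
#'
#' K-means++-style clustering via multiple restarts (`nstart = 10`),
#' deterministic given the seed. Centroids are the means of their
#' assigned points; decoding them yields representative maps of the
#' landscape.
#'
#' @param table A `latent_table`.
#' @param k Number of clusters (`k <=` number of rows).
#' @param seed RNG seed.
#' @return List with `centroids` (k x latent_dim matrix) and
#'   `assignments` (integer vector).
#' @export
kmeans_representatives <- function(table, k = 20, seed = 1) {
  Z <- latent_matrix(table)
  if (k > nrow(Z)) stop("more clusters than particles")
  set.seed(seed)
  km <- stats::kmeans(Z, centers = k, nstart = 10, iter.max = 100)
  list(centroids = km$centers, assignments = km$cluster)
}

#' Evenly sample a principal axis of the latent cloud
#'
#' Returns latent points evenly spaced along one principal component
#' between the axis's 1st and 99th score percentiles (robust to
#' outliers), mapped back to the full latent space. A single point is
#' the latent mean.
#'
#' @param table A `latent_table`.
#' @param pca Result of [pca_reduce()] on the same table.
#' @param component_index Which principal axis.
#' @param n_points Number of samples.
#' @return `n_points x latent_dim` matrix of latent vectors.
#' @export
sample_axis <- function(table, pca, component_index = 1, n_points = 5) {
  if (component_index > ncol(pca$scores)) stop("invalid component index")
  sc <- pca$scores[, component_index]
  lo <- stats::quantile(sc, 0.01, names = FALSE)
  hi <- stats::quantile(sc, 0.99, names = FALSE)
  pos <- if (n_points == 1) 0 else seq(lo, hi, length.out = n_points)
  dir <- pca$rotation[, component_index]
  t(vapply(pos, function(a) pca$center + a * dir,
           numeric(length(pca$center))))
}

#' Decode and write representative maps
#'
#' @param model A trained model (or `hetrec_fit`).
#' @param centroids Matrix of latent vectors (rows).
#' @param out_dir Output directory; maps are written as
#'   `representative_###.mrc`.
#' @return Character vector of written paths, invisibly.
#' @export
decode_representatives <- function(model, centroids, out_dir) {
  if (inherits(model, "hetrec_fit")) model <- model$model
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(nrow(centroids))
  for (i in seq_len(nrow(centroids))) {
    paths[i] <- file.path(out_dir, sprintf("representative_%03d.mrc", i))
    decode_map(model, centroids[i, ], out_path = paths[i])
  }
  invisible(paths)
}

#' Latent displacement under pose shuffling
#'
#' Post-training disentanglement diagnostic: for batches of particles,
#' encode the experimental images (codes `z`), decode their volumes,
#' re-project each volume under a pose shuffled within the batch (clean,
#' CTF-free), re-encode, and measure the mean Euclidean displacement
#' between the original and re-encoded codes. A pose-decoupled model
#' shows a smaller displacement than an entangled one trained on the
#' same data.
#'
#' @param model A trained model (or `hetrec_fit`).
#' @param dataset List with `stack` and `records`.
#' @param n_particles How many particles to evaluate (from the start of
#'   the stack).
#' @param batch_size Shuffling batch size.
#' @param seed RNG seed for the shuffles.
#' @return Mean latent displacement (scalar).
#' @export
pose_shuffle_displacement <- function(model, dataset, n_particles = 64,
                                      batch_size = 8, seed = 1) {
  if (inherits(model, "hetrec_fit")) model <- model$model
  set.seed(seed)
  n <- min(n_particles, dataset$stack$n)
  total <- 0; count <- 0
  for (s in seq(1, n, by = batch_size)) {
    sel <- s:min(s + batch_size - 1, n)
    imgs <- dataset$stack$images[, , sel, drop = FALSE]
    z <- encode_images(model$encoder, imgs)$z
    perm <- shuffle_within_batch(seq_along(sel))
    shuf <- array(0, c(model$box, model$box, length(sel)))
    for (k in seq_along(sel)) {
      vol <- decode_map(model, z[k, ])
      shuf[, , k] <- project(vol, dataset$records[[sel[perm[k]]]])
    }
    z_t <- encode_images(model$encoder, shuf)$z
    total <- total + sum(sqrt(rowSums((z - z_t)^2)))
    count <- count + length(sel)
  }
  total / count
}

#' Write a latent table as CSV
#'
#' @param table A `latent_table`.
#' @param path Output CSV path.
#' @export
write_latent_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
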