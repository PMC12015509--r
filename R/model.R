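# Model container: encoder + meta-SIREN decoder + reference volume and
# optional focus mask, plus the fixed normalized coordinate lattice the
# decoder is queried on.

#' Build a heterogeneous-reconstruction model
#'
#' @param box Box/image side in voxels.
#' @param config Configuration list (see [default_config()]); missing
#'   keys take defaults.
#' @param v0 Optional reference [volume_grid()] (NULL for an empty, zero
#'   reference).
#' @param mask Optional [vol_mask()] enabling focused reconstruction.
#' @param voxel_size Voxel size in Angstrom (taken from `v0` if given).
#' @return Object of class `hetrec_model`.
#' @export
init_model <- function(box, config = list(), v0 = NULL, mask = NULL,
                       voxel_size = 1) {
  cfg <- validate_config(utils::modifyList(default_config(), config))
  set.seed(cfg$seed)
  enc <- init_encoder(box, cfg$latent_dim, cfg$encoder_arch,
                      width = cfg$encoder_width,
                      normalize = cfg$normalize_images)
  dec <- init_decoder(cfg$latent_dim, cfg$decoder_width, cfg$hyper_width,
                      cfg$omega0)
  if (!is.null(v0)) {
    stopifnot(inherits(v0, "volume_grid"))
    if (v0$box != box) stop("reference volume box mismatch")
    voxel_size <- v0$voxel_size
  }
  v0_arr <- if (is.null(v0)) array(0, c(box, box, box)) else v0$data
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "vol_mask"))
    if (!identical(dim(mask$data), dim(v0_arr)))
      stop("focus mask box mismatch")
  }
  coords <- decoder_coords(box)
  support_idx <- if (cfg$decode_support == "sphere")
    which(rowSums(coords^2) <= 1) else NULL
  structure(list(box = as.integer(box), config = cfg, encoder = enc,
                 decoder = dec, v0 = v0_arr, mask = mask,
                 voxel_size = voxel_size,
                 coords = coords,
                 support_idx = support_idx,
                 mask_idx = if (!is.null(mask)) which(mask$data == 1) else NULL),
            class = "hetrec_model")
}

#' @export
print.hetrec_model <- function(x, ...) {
  cat(sprintf(paste0("<hetrec_model box %d, latent %d, encoder %s, ",
                     "%d + %d parameters%s>\n"),
              x$box, x$config$latent_dim, x$config$encoder_arch,
              count_params(x$encoder), count_params(x$decoder),
              if (is.null(x$mask)) "" else ", focused"))
  invisible(x)
}

#' Decode a volume from a latent point
#'
#' Runs the decoder over the full coordinate lattice (or the focus mask
#' if the model is focused) and composes the increment with the
#' reference. Deterministic; with a zero-initialized output layer the
#' result equals the reference.
#'
#' @param model A [init_model()] object.
#' @param z Latent vector.
#' @param out_path Optional MRC output path.
#' @return A [volume_grid()].
#' @export
decode_map <- function(model, z, out_path = NULL) {
  vol <- if (!is.null(model$mask)) {
    focused_decode(model$decoder, z, model$mask,
                   volume_grid(model$v0, model$voxel_size))
  } else if (!is.null(model$support_idx)) {
    v <- model$v0
    v[model$support_idx] <- v[model$support_idx] +
      decode_delta(model$decoder, z,
                   model$coords[model$support_idx, , drop = FALSE])
    volume_grid(v, model$voxel_size)
  } else {
    delta <- decode_delta(model$decoder, z, model$coords)
    volume_grid(model$v0 + array(delta, dim(model$v0)), model$voxel_size)
  }
  if (!is.null(out_path)) write_volume(vol, out_path)
  vol
}

#' Save / load a model checkpoint
#'
#' Single-file archive holding the parameters, configuration, reference,
#' mask and RNG state (format version 1). Resuming from a checkpoint
#' reproduces the next optimization step exactly.
#'
#' @param model A [init_model()] object (with optional `$opt` state).
#' @param path Checkpoint path (`.rds`).
#' @export
save_checkpoint <- function(model, path) {
  rng <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  saveRDS(list(version = 1L, model = model, rng = rng), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint` returns the model with RNG state restored.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (is.null(ck$version) || ck$version != 1L)
    stop("unsupported checkpoint version")
  if (!is.null(ck$rng)) assign(".Random.seed", ck$rng, envir = globalenv())
  ck$model
}
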