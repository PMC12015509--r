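# Run configuration. Defaults follow the published method: Adam with
# learning rate 1e-5, batch size 8, a 10-dimensional latent space,
# lambda1 = lambda2 = 1.0 (L1 density / negative-value penalties),
# lambda3 = lambda4 = 0.1 (TV terms), multiresolution levels at full and
# half resolution. Remaining knobs are package choices documented in the
# methods vignette.

#' Default run configuration
#'
#' @return Named list of configuration values (see Details).
#' @details Core optimization: `learning_rate` (1e-5), `batch_size` (8),
#'   `epochs` (25), `seed`. Model: `latent_dim` (10), `encoder_arch`
#'   ("mlp" or "conv"), `encoder_width` (1024, MLP hidden width),
#'   `decoder_width` / `hyper_width` (default `latent_dim`), `omega0`
#'   (30); `decode_support` ("sphere" to reconstruct only the sphere
#'   inscribed in the box, "cube" for the full grid); `normalize_images`
#'   (standardize encoder inputs per image). Loss weights: `lambda1` (1.0, L1 density), `lambda2` (1.0,
#'   negative penalty), `lambda3`/`lambda4` (0.1, TV L1/L2), `lambda5`
#'   (1.0, focus statistics), `lambda_pose`/`lambda_ctf` (0.1, latent
#'   decoupling). `multires_levels` is a subset of `c("full", "half")`.
#'   Flags: `decouple_pose`, `decouple_ctf` (TRUE), `refine_pose`
#'   (FALSE), `use_correlation` (FALSE); `pose_clamp_deg`,
#'   `shift_clamp_px` bound the refinement head; `checkpoint_every`
#'   epochs between checkpoints; `reference_path`, `focus_mask_path`
#'   optional MRC inputs.
#' @export
default_config <- function() {
  list(
    learning_rate = 1e-5,
    batch_size = 8L,
    latent_dim = 10L,
    epochs = 25L,
    seed = 1L,
    lambda1 = 1.0,
    lambda2 = 1.0,
    lambda3 = 0.1,
    lambda4 = 0.1,
    lambda5 = 1.0,
    lambda_pose = 0.1,
    lambda_ctf = 0.1,
    multires_levels = c("full", "half"),
    decode_support = "sphere",
    normalize_images = TRUE,
    encoder_arch = "mlp",
    encoder_width = 1024L,
    decoder_width = NULL,   # NULL -> latent_dim
    hyper_width = NULL,     # NULL -> latent_dim
    omega0 = 30,
    decouple_pose = TRUE,
    decouple_ctf = TRUE,
    refine_pose = FALSE,
    use_correlation = FALSE,
    pose_clamp_deg = 5,
    shift_clamp_px = 2,
    checkpoint_every = 5L,
    reference_path = NULL,
    focus_mask_path = NULL
  )
}

validate_config <- function(cfg) {
  pos <- c("learning_rate", "batch_size", "latent_dim", "omega0")
  for (k in pos)
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1 || cfg[[k]] <= 0)
      stop("config key '", k, "' must be a positive number")
  nonneg <- c("epochs", "lambda1", "lambda2", "lambda3", "lambda4",
              "lambda5", "lambda_pose", "lambda_ctf")
  for (k in nonneg)
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1 || cfg[[k]] < 0)
      stop("config key '", k, "' must be a nonnegative number")
  if (!all(cfg$multires_levels %in% c("full", "half")))
    stop("multires_levels must be a subset of c('full', 'half')")
  if (!cfg$encoder_arch %in% c("mlp", "conv"))
    stop("encoder_arch must be 'mlp' or 'conv'")
  if (!cfg$decode_support %in% c("sphere", "cube"))
    stop("decode_support must be 'sphere' or 'cube'")
  cfg$batch_size <- as.integer(cfg$batch_size)
  cfg$latent_dim <- as.integer(cfg$latent_dim)
  cfg$epochs <- as.integer(cfg$epochs)
  if (is.null(cfg$decoder_width)) cfg$decoder_width <- cfg$latent_dim
  if (is.null(cfg$hyper_width)) cfg$hyper_width <- cfg$latent_dim
  cfg
}

#' Load a run configuration from YAML
#'
#' Keys absent from the file take the published defaults (see
#' [default_config()]); unknown keys and invalid values raise errors.
#' Defaulting is idempotent: loading a dump of a loaded config reproduces
#' it.
#'
#' @param path Path to a YAML file (may be empty).
#' @return Validated configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  defaults <- default_config()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, user, keep.null = TRUE)
  # modifyList drops NULL overrides; restore explicit structure
  for (k in names(user)) cfg[[k]] <- user[[k]]
  validate_config(cfg)
}

#' Save a configuration as YAML
#'
#' @param cfg Configuration list.
#' @param path Output path.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))], path)
  invisible(path)
}
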