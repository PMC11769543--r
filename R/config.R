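# Experiment configuration: one flat, fully self-describing YAML file per
# experiment; every absent key takes a documented default, unknown keys are
# hard errors (typo protection), and the resolved config is echoed alongside
# outputs so no choice is hidden at a call site.

config_defaults <- function() {
  list(
    seed = 1L,
    paths = list(data = "data", output = "output",
                 checkpoints = "checkpoints"),
    preprocess = list(target_spacing = 1.0, lower_percentile = 0.005,
                      upper_percentile = 0.995, per_image = FALSE),
    augment = list(rotation_range = 30, scale_min = 0.85, scale_max = 1.25,
                   mirror_axes = c(1L, 2L, 3L), transpose_enabled = TRUE,
                   gamma_min = 0.7, gamma_max = 1.5,
                   p_rotation = 0.3, p_scale = 0.3, p_mirror = 0.5,
                   p_transpose = 0.2, p_gamma = 0.3),
    organ_net = list(backend = "swin", encoder_steps = 4L,
                     transformer_blocks_per_step = 2L,
                     window_input_size = 128L, window_size = 4L,
                     base_channels = 24L,
                     cnn_channels = c(8L, 16L, 32L),
                     cnn_blocks = c(1L, 1L, 1L)),
    tumor_net = list(n_stages = 6L,
                     channels = c(32L, 64L, 128L, 256L, 320L, 320L),
                     residual_blocks = c(1L, 3L, 4L, 6L, 6L, 6L),
                     decoder_convs_per_stage = 1L, leaky_slope = 0.01,
                     attention_gates = TRUE,
                     patch_size = c(192L, 128L, 128L), batch_size = 5L),
    train_organ = list(epochs = 20L, patch_size = c(32L, 32L, 32L),
                       batch_size = 2L, patches_per_volume = 1L,
                       foreground_oversampling = 0.5, lr = 3.5e-4,
                       weight_decay = 1e-5, use_augment = FALSE),
    train_tumor = list(epochs = 20L, patch_size = c(32L, 32L, 32L),
                       batch_size = 2L, patches_per_volume = 1L,
                       foreground_oversampling = 0.5, lr = 0.001,
                       momentum = 0.99, nesterov = TRUE,
                       use_augment = FALSE),
    pipeline = list(expansion = 0.25, kidney_threshold = 0.5,
                    tumor_threshold = 0.5, min_component_voxels = 50L,
                    overlap = 0.5, native_grid = FALSE),
    metrics = list(iou_threshold = 0.25, small_max_cm = 4,
                   medium_max_cm = 7, diameter_mode = "axial",
                   min_voxels = 5L),
    stats = NULL
  )
}

merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user) || !is.list(defaults)) return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0L)
    stopf("unknown config key%s: %s", if (length(unknown) > 1) "s" else "",
          paste0(sub("^\\.", "", paste0(path, ".", unknown)),
                 collapse = ", "))
  out <- defaults
  for (nm in names(user)) {
    out[[nm]] <- merge_config(defaults[[nm]], user[[nm]],
                              paste0(path, ".", nm))
  }
  out
}

validate_config <- function(cfg) {
  pp <- cfg$preprocess
  if (pp$target_spacing <= 0)
    stopf("invalid value for preprocess.target_spacing: must be > 0")
  if (pp$lower_percentile >= pp$upper_percentile)
    stopf("preprocess.lower_percentile must be below upper_percentile")
  if (cfg$pipeline$expansion < 0)
    stopf("invalid value for pipeline.expansion: must be >= 0")
  if (cfg$metrics$iou_threshold <= 0 || cfg$metrics$iou_threshold > 1)
    stopf("invalid value for metrics.iou_threshold: must be in (0, 1]")
  # instantiate sub-configs so their own validators run
  do.call(tumor_net_config, cfg$tumor_net)
  do.call(organ_net_config, cfg$organ_net)
  invisible(cfg)
}

#' Load an experiment configuration
#'
#' Reads a YAML config, fills every absent key with its documented default
#' (VOI expansion 0.25, target spacing 1.0 mm, detection IoU 0.25, ...),
#' rejects unknown keys naming the offender, and validates values. An empty
#' file yields the full default configuration.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return The resolved configuration (class `experiment_config`).
#' @export
load_config <- function(path = NULL) {
  user <- if (is.null(path)) list()
  else {
    if (!file.exists(path)) stopf("config file not found: %s", path)
    yaml::read_yaml(path) %||% list()
  }
  cfg <- merge_config(config_defaults(), user)
  if (!("stats" %in% names(cfg))) cfg["stats"] <- list(NULL)
  validate_config(cfg)
  structure(cfg, class = "experiment_config")
}

#' Write a resolved configuration
#' @param cfg An `experiment_config`.
#' @param path Output YAML path.
#' @return Invisibly, `path`.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Hash of a resolved configuration
#'
#' Every artifact written by the pipeline carries this hash, so outputs can
#' be traced to the exact configuration that produced them.
#'
#' @param cfg An `experiment_config`.
#' @return An md5 string.
#' @export
config_hash <- function(cfg) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(unclass(cfg), f)
  unname(tools::md5sum(f))
}

augment_from_config <- function(cfg) {
  a <- cfg$augment
  augment_params(rotation_range = a$rotation_range,
                 scale_range = c(a$scale_min, a$scale_max),
                 mirror_axes = a$mirror_axes,
                 transpose_enabled = a$transpose_enabled,
                 gamma_range = c(a$gamma_min, a$gamma_max),
                 p_rotation = a$p_rotation, p_scale = a$p_scale,
                 p_mirror = a$p_mirror, p_transpose = a$p_transpose,
                 p_gamma = a$p_gamma)
}

train_config_from <- function(cfg, stage) {
  tc <- if (stage == "tumor") cfg$train_tumor else cfg$train_organ
  train_config(stage = stage, epochs = tc$epochs,
               patch_size = tc$patch_size, batch_size = tc$batch_size,
               patches_per_volume = tc$patches_per_volume,
               foreground_oversampling = tc$foreground_oversampling,
               lr = tc$lr,
               momentum = tc$momentum %||% 0.99,
               nesterov = tc$nesterov %||% TRUE,
               weight_decay = tc$weight_decay %||% 1e-5,
               augment = if (isTRUE(tc$use_augment)) augment_from_config(cfg),
               seed = cfg$seed)
}
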