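## Experiment configuration: a plain YAML file with sections geometry,
## phantom, preprocess, model, losses, train. CLI flags override file values;
## every resolved value is echoed into the run manifest.

#' Default experiment configuration
#' @param grid_size volume/projection resolution.
#' @param seed master seed.
#' @return Nested configuration list.
#' @export
default_config <- function(grid_size = 128L, seed = 1L) {
  list(
    geometry = list(sdd_mm = 1085.6, sid_mm = 595, n_detector = grid_size,
                    detector_spacing_mm = NULL, n_image = grid_size,
                    voxel_spacing_mm = 2.5),
    phantom = list(grid_size = grid_size, voxel_spacing_mm = 2.5, seed = seed),
    preprocess = list(hu_min = -1024, hu_max = 3071, proj_norm = NULL),
    model = list(n_levels_gen = 4L, base_channels_gen = 64L,
                 base_channels_disc = 64L, base_channels_seg = 8L),
    losses = list(lambda_gen = 0.1, lambda_r = 10, lambda_proj = 10,
                  lambda_s = 2.0, lambda_p = 0.5, perceptual_kind = "l2"),
    train = list(epochs_gan = 100L, epochs_seg = 200L, lr_gan = 2e-4,
                 lr_seg = 5e-4, batch_size = 1L, seed = seed,
                 holdout_fraction = 0.2)
  )
}

#' Read / write an experiment configuration
#' @param path YAML file.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  for (sec in names(base)) {
    if (is.null(cfg[[sec]])) cfg[[sec]] <- base[[sec]]
    else for (k in names(base[[sec]]))
      if (is.null(cfg[[sec]][[k]]) && !is.null(base[[sec]][[k]]))
        cfg[[sec]][[k]] <- base[[sec]][[k]]
  }
  cfg
}

#' @rdname read_config
#' @param cfg configuration list.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

## Resolve the nested config into the flat train_config used by the drivers.
as_train_config <- function(cfg, checkpoint_dir = NULL) {
  train_config(
    grid_size = cfg$phantom$grid_size,
    voxel_spacing_mm = cfg$phantom$voxel_spacing_mm,
    epochs_gan = cfg$train$epochs_gan, epochs_seg = cfg$train$epochs_seg,
    lr_gan = cfg$train$lr_gan, lr_seg = cfg$train$lr_seg,
    batch_size = cfg$train$batch_size, seed = cfg$train$seed,
    weights = loss_weights(cfg$losses$lambda_gen, cfg$losses$lambda_r,
                           cfg$losses$lambda_proj, cfg$losses$lambda_s,
                           cfg$losses$lambda_p),
    n_levels_gen = cfg$model$n_levels_gen,
    base_channels_gen = cfg$model$base_channels_gen,
    base_channels_disc = cfg$model$base_channels_disc,
    base_channels_seg = cfg$model$base_channels_seg,
    hu_window = c(cfg$preprocess$hu_min, cfg$preprocess$hu_max),
    holdout_fraction = cfg$train$holdout_fraction,
    perceptual_kind = cfg$losses$perceptual_kind,
    checkpoint_dir = checkpoint_dir)
}
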