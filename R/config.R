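#' Write a run configuration to a plain-text file
#'
#' Configurations are flat `key: value` text (a YAML subset) covering every
#' studied experiment axis: pixel loss, lambda, switch epoch, generator
#' depth and width, discriminator variant and training mode.
#'
#' @param cfg named list of scalar options.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a run configuration
#'
#' Fills in defaults and materialises the package objects: a
#' [generator_spec()], a discriminator variant name, an
#' [objective_config()] and a [train_config()].
#'
#' @param path a `key: value` config file; missing keys take defaults.
#' @return List with `$generator`, `$disc_variant`, `$objective`, `$train`
#'   and the raw `$options`.
#' @export
read_run_config <- function(path) {
  opts <- if (is.null(path)) list() else yaml::read_yaml(path)
  gv <- function(key, default) if (!is.null(opts[[key]])) opts[[key]] else default
  crop <- as.integer(gv("crop_size", 64L))
  mode <- gv("mode", "cgan")
  epochs <- as.integer(gv("epochs", 100L))
  gen <- generator_spec(
    n_down = as.integer(gv("n_down", 5L)),
    min_channels = as.integer(gv("min_channels", 16L)),
    input_size = crop,
    dropout = as.numeric(gv("dropout", 0)))
  objective <- objective_config(
    pixel_loss = gv("pixel_loss", "L1"),
    lambda_weight = as.numeric(gv("lambda", if (mode == "unet") 1 else 100)),
    adversarial = mode == "cgan",
    switch_epoch = if (!is.null(opts$switch_epoch))
      as.integer(opts$switch_epoch),
    second_phase_pixel_loss = opts$second_phase_pixel_loss,
    epochs = epochs)
  tcfg <- train_config(
    epochs = epochs,
    learning_rate = as.numeric(gv("learning_rate", 2e-4)),
    beta1 = as.numeric(gv("beta1", 0.5)),
    beta2 = as.numeric(gv("beta2", 0.999)),
    crop_size = crop,
    jitter_resize = as.integer(gv("jitter_resize", round(crop * 542 / 512))),
    seed = as.integer(gv("seed", 1L)),
    mode = mode,
    pretrain_epochs = as.integer(gv("pretrain_epochs", 20L)))
  list(generator = gen, disc_variant = gv("discriminator", "patch_70"),
       objective = objective, train = tcfg, options = opts)
}
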