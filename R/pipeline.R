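#' Training configuration
#'
#' Adam with learning rate 0.0002 and momenta `beta1 = 0.5`,
#' `beta2 = 0.999`; 100 epochs and batch size 1 by default. Jitter
#' augmentation upscales both images of a pair (source: bicubic, label:
#' nearest-neighbour) to `jitter_resize` and randomly crops back to
#' `crop_size` at one shared offset — the 542/512 ratio of the original
#' protocol scaled to the working resolution.
#'
#' @param epochs total training epochs.
#' @param learning_rate,beta1,beta2 Adam hyper-parameters.
#' @param batch_size images per step; this engine implements batch size 1.
#' @param crop_size training image side in px.
#' @param jitter_resize upscale side in px, strictly greater than
#'   `crop_size`.
#' @param seed seed for initialisation, shuffling and jitter.
#' @param mode `"cgan"` (adversarial) or `"unet"` (generator only).
#' @param pretrain_epochs epochs on the pretraining dataset in
#'   [transfer_train()] (default 20).
#' @return A `train_config`.
#' @export
train_config <- function(epochs = 100L, learning_rate = 2e-4, beta1 = 0.5,
                         beta2 = 0.999, batch_size = 1L, crop_size = 64L,
                         jitter_resize = round(crop_size * 542 / 512),
                         seed = 1L, mode = c("cgan", "unet"),
                         pretrain_epochs = 20L) {
  mode <- match.arg(mode)
  if (epochs < 1L) stop("epochs must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (batch_size != 1L) stop("this engine trains with batch size 1")
  if (jitter_resize <= crop_size) stop("jitter_resize must exceed crop_size")
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 beta1 = beta1, beta2 = beta2, batch_size = 1L,
                 crop_size = as.integer(crop_size),
                 jitter_resize = as.integer(jitter_resize),
                 seed = as.integer(seed), mode = mode,
                 pretrain_epochs = as.integer(pretrain_epochs)),
            class = "train_config")
}

#' Jitter augmentation
#'
#' Resizes the source (bicubic) and label (nearest-neighbour, so colour
#' codes are never interpolated into the decode dead zones) to
#' `resize x resize`, then crops both back to `crop_size` at one shared
#' random offset drawn uniformly from `[0, resize - crop_size]` per axis.
#' Consumes two uniform draws from the current RNG stream.
#'
#' @param source H x W matrix in `[0, 1]`.
#' @param label a [label_image()] congruent with `source`.
#' @param crop_size output side in px.
#' @param resize intermediate upscale side in px, `> crop_size`.
#' @return `list(source, label)` of the augmented pair.
#' @export
jitter <- function(source, label, crop_size, resize) {
  if (resize <= crop_size) stop("resize must exceed crop_size")
  if (!identical(dim(source), dim(label$data)[1:2]))
    stop("source and label shapes differ")
  big_src <- pmin(pmax(resize_bicubic(source, resize, resize), 0), 1)
  nn_idx <- pmin(floor((seq_len(resize) - 0.5) * nrow(source) / resize) + 1L,
                 nrow(source))
  big_lab <- label$data[nn_idx, nn_idx, , drop = FALSE]
  off <- floor(runif(2, 0, resize - crop_size + 1))
  off <- pmin(off, resize - crop_size)
  ri <- off[1] + seq_len(crop_size)
  ci <- off[2] + seq_len(crop_size)
  list(source = big_src[ri, ci],
       label = label_image(big_lab[ri, ci, , drop = FALSE],
                           subject_id = label$subject_id,
                           slice_index = label$slice_index))
}

to_signed <- function(m) {
  x <- 2 * m - 1
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  x
}

label_to_signed <- function(label) label$data / 127.5 - 1

param_signature <- function(params) {
  v <- unlist(params, use.names = FALSE)
  c(sum = sum(v), sumsq = sum(v^2), n = length(v))
}

#' Parameter signature of a checkpoint
#'
#' A cheap content hash (sum, sum of squares and count over all generator —
#' and, if present, discriminator — parameters) used to assert weight
#' continuity across loss switches and resumes.
#'
#' @param ckpt a checkpoint from [train_model()].
#' @return Named numeric vector `(sum, sumsq, n)`.
#' @export
checkpoint_signature <- function(ckpt) {
  p <- list(g = ckpt$generator$params)
  if (!is.null(ckpt$discriminator)) p$d <- ckpt$discriminator$params
  param_signature(p)
}

d_score_grads <- function(scores, target_real, n_eff = length(scores)) {
  s <- clamp_scores(scores)
  if (target_real) array(-1 / s / n_eff, dim(scores))
  else array(1 / (1 - s) / n_eff, dim(scores))
}

#' Train a cGAN or plain U-Net on a paired dataset
#'
#' Alternates one discriminator update and one generator update per image
#' (`mode = "cgan"`), or runs generator-only pixel-loss updates
#' (`mode = "unet"`). Noise-only pairs are dropped before training. The
#' objective's [active_objective()] selects the pixel loss each epoch, so a
#' configured loss switch changes the objective mid-run while weights and
#' Adam state persist. All four loss components are logged per iteration
#' and a parameter signature is recorded at every epoch boundary. With a
#' fixed seed two runs produce identical logs and weights.
#'
#' @param dataset list of pairs (from [load_dataset()] or
#'   [generate_subject()]-style lists).
#' @param gen_spec a [generator_spec()] matching `tcfg$crop_size`.
#' @param disc_variant discriminator variant name (cgan mode).
#' @param objective an [objective_config()].
#' @param tcfg a [train_config()].
#' @param checkpoint optional checkpoint to resume from; training continues
#'   from its epoch counter up to `tcfg$epochs` on this dataset.
#' @param phase label stamped into the loss log rows (e.g. "pretrain").
#' @return A checkpoint: generator (and discriminator) models, Adam states,
#'   epoch counter, objective, loss log (`$loss_log`) and per-epoch
#'   parameter signatures (`$snapshots`).
#' @export
train_model <- function(dataset, gen_spec, disc_variant = "patch_70",
                        objective = objective_config(), tcfg = train_config(),
                        checkpoint = NULL, phase = "train") {
  stopifnot(inherits(objective, "objective_config"),
            inherits(tcfg, "train_config"))
  pairs <- filter_dataset(dataset, keep_noise_only = FALSE)
  if (length(pairs) == 0L) stop("dataset is empty after noise-only filtering")
  sz <- dim(pairs[[1]]$source)
  if (sz[1] != sz[2]) stop("training images must be square")
  cgan <- tcfg$mode == "cgan"

  if (is.null(checkpoint)) {
    set.seed(tcfg$seed)
    if (inherits(gen_spec, "generator_spec")) {
      if (gen_spec$input_size != tcfg$crop_size)
        stop("generator input_size must equal crop_size")
      arch <- build_generator(gen_spec)
    } else stop("gen_spec must be a generator_spec")
    gm <- init_generator(arch)
    g_adam <- adam_init(gm$params)
    dm <- NULL; d_adam <- NULL
    if (cgan) {
      dspec <- build_discriminator(disc_variant,
                                   in_channels = arch$spec$in_channels +
                                     arch$spec$out_channels)
      dm <- init_discriminator(dspec)
      d_adam <- adam_init(dm$params)
    }
    epoch0 <- 0L
    loss_log <- list()
    snapshots <- list()
  } else {
    gm <- checkpoint$generator
    g_adam <- checkpoint$g_adam
    dm <- checkpoint$discriminator
    d_adam <- checkpoint$d_adam
    epoch0 <- checkpoint$epoch
    loss_log <- list(checkpoint$loss_log)
    snapshots <- list(checkpoint$snapshots)
    assign(".Random.seed", checkpoint$rng_state, globalenv())
  }
  if (tcfg$crop_size %% 2L^gm$arch$spec$n_down != 0L)
    stop("image size incompatible with generator depth")
  if (sz[1] != tcfg$crop_size)
    stop("dataset image size must equal crop_size")

  lr <- tcfg$learning_rate; b1 <- tcfg$beta1; b2 <- tcfg$beta2
  for (epoch in seq(epoch0, tcfg$epochs - 1L)) {
    kind <- active_objective(objective, epoch)
    snapshots[[length(snapshots) + 1L]] <- data.frame(
      epoch = epoch, phase = phase, pixel_loss = kind,
      t(param_signature(list(g = gm$params,
                             d = if (cgan) dm$params else NULL))))
    ord <- sample(length(pairs))
    for (it in seq_along(ord)) {
      p <- pairs[[ord[it]]]
      aug <- jitter(p$source, p$label, tcfg$crop_size, tcfg$jitter_resize)
      x <- to_signed(aug$source)
      y <- label_to_signed(aug$label)

      l_gan_g <- NA_real_; l_d_real <- NA_real_; l_d_fake <- NA_real_
      fwd <- generator_forward(gm, x)
      g_out <- fwd$y
      l_pix <- if (kind != "none") pixel_loss(kind, y, g_out) else NA_real_

      if (cgan) {
        # --- discriminator step (generated image detached) ---
        fd_r <- discriminator_forward(dm, x, y)
        fd_f <- discriminator_forward(dm, x, g_out)
        l_d_real <- -mean(log(clamp_scores(fd_r$scores)))
        l_d_fake <- -mean(log(1 - clamp_scores(fd_f$scores)))
        gr_r <- discriminator_backward(dm, fd_r,
                                       d_score_grads(fd_r$scores, TRUE))
        gr_f <- discriminator_backward(dm, fd_f,
                                       d_score_grads(fd_f$scores, FALSE))
        d_grads <- mapply(function(a, b) mapply(`+`, a, b, SIMPLIFY = FALSE),
                          gr_r$grads, gr_f$grads, SIMPLIFY = FALSE)
        upd <- adam_step(dm$params, d_grads, d_adam, lr, b1, b2)
        dm$params <- upd$params; d_adam <- upd$state

        # --- generator step through the updated discriminator ---
        fd_g <- discriminator_forward(dm, x, g_out)
        l_gan_g <- -mean(log(clamp_scores(fd_g$scores)))
        s <- clamp_scores(fd_g$scores)
        dsc_map <- array(-1 / s / length(s), dim(s))
        gb <- discriminator_backward(dm, fd_g, dsc_map)
        n_src <- dim(x)[3]
        dg <- gb$dx[, , -seq_len(n_src), drop = FALSE]
        if (kind != "none")
          dg <- dg + objective$lambda_weight * pixel_loss_grad(kind, y, g_out)
      } else {
        dg <- pixel_loss_grad(kind, y, g_out)
      }
      gg <- generator_backward(gm, fwd, dg)
      upd <- adam_step(gm$params, gg$grads, g_adam, lr, b1, b2)
      gm$params <- upd$params; g_adam <- upd$state

      loss_log[[length(loss_log) + 1L]] <- data.frame(
        phase = phase, epoch = epoch, iter = it,
        L_cGAN_G = l_gan_g, L_pixel = l_pix,
        L_D_real = l_d_real, L_D_fake = l_d_fake,
        pixel_kind = kind, stringsAsFactors = FALSE)
    }
  }
  structure(list(generator = gm, g_adam = g_adam,
                 discriminator = dm, d_adam = d_adam,
                 epoch = tcfg$epochs, objective = objective, tcfg = tcfg,
                 loss_log = do.call(rbind, loss_log),
                 snapshots = do.call(rbind, snapshots),
                 rng_state = get(".Random.seed", globalenv())),
            class = "kneecgan_checkpoint")
}

#' @export
print.kneecgan_checkpoint <- function(x, ...) {
  cat("kneecgan checkpoint: mode ", x$tcfg$mode, ", ", x$epoch,
      " epochs, ", nrow(x$loss_log), " logged iterations\n", sep = "")
  invisible(x)
}

#' Pretrain on one dataset, fine-tune on another
#'
#' Trains for `tcfg$pretrain_epochs` on `pretrain_dataset`, then continues —
#' same weights and optimizer state, fresh data pipeline — on
#' `finetune_dataset` until `tcfg$epochs` total (the 20 + 80 protocol by
#' default). Both phases are tagged in the loss log. The fine-tuning label
#' scheme may annotate more tissues than the pretraining one; the generator
#' output space (a full RGB label map) is unchanged.
#'
#' @param pretrain_dataset,finetune_dataset paired datasets with one image
#'   size.
#' @inheritParams train_model
#' @return The final checkpoint, loss log covering both phases.
#' @export
transfer_train <- function(pretrain_dataset, finetune_dataset, gen_spec,
                           disc_variant = "patch_70",
                           objective = objective_config(),
                           tcfg = train_config()) {
  if (tcfg$pretrain_epochs < 0L || tcfg$pretrain_epochs >= tcfg$epochs)
    stop("pretrain_epochs must lie in [0, epochs)")
  if (tcfg$pretrain_epochs == 0L)
    return(train_model(finetune_dataset, gen_spec, disc_variant, objective,
                       tcfg, phase = "finetune"))
  pre_cfg <- tcfg
  pre_cfg$epochs <- tcfg$pretrain_epochs
  ck <- train_model(pretrain_dataset, gen_spec, disc_variant, objective,
                    pre_cfg, phase = "pretrain")
  ck$tcfg <- tcfg
  train_model(finetune_dataset, gen_spec, disc_variant, objective, tcfg,
              checkpoint = ck, phase = "finetune")
}

#' Segment source slices with a trained generator
#'
#' Augmentation-free forward pass per slice; generator outputs on `[-1, 1]`
#' are rescaled to `[0, 255]` and rounded half-up to integers. Per-tissue
#' Boolean masks are then obtained with [decode_tissue_mask()].
#'
#' @param ckpt a checkpoint from [train_model()].
#' @param sources list of H x W matrices in `[0, 1]` (or pairs, whose
#'   `$source` is used).
#' @return List of predicted [label_image()]s, order preserved.
#' @export
segment_slices <- function(ckpt, sources) {
  stopifnot(inherits(ckpt, "kneecgan_checkpoint"))
  lapply(seq_along(sources), function(i) {
    s <- sources[[i]]
    if (is.list(s)) s <- s$source
    if (nrow(s) != ckpt$generator$arch$spec$input_size)
      stop("source size does not match the checkpoint architecture")
    g <- generator_forward(ckpt$generator, to_signed(s), train = FALSE)$y
    vals <- pmin(pmax(floor((g + 1) * 127.5 + 0.5), 0), 255)
    label_image(vals, subject_id = "pred", slice_index = i - 1L)
  })
}

#' Segment and evaluate a paired test set
#'
#' Runs [segment_slices()] on every test pair, assembles per-subject 3D
#' label volumes in slice order, and delegates to [evaluate_subject()];
#' aggregation across subjects reports the unweighted mean and population
#' standard deviation. `include_noise_only` toggles whether all-background
#' slices take part in the evaluation.
#'
#' @param ckpt a checkpoint from [train_model()].
#' @param test_pairs list of pairs with `$source`, `$label`, `$subject`.
#' @param scheme a [label_scheme()].
#' @param include_noise_only keep noise-only slices in the test volumes.
#' @param which metrics to compute.
#' @param spacing voxel spacing (slice, row, column) in mm.
#' @return List with `per_subject` (one data.frame per subject) and
#'   `aggregate` (mean and sd across subjects).
#' @export
evaluate_model <- function(ckpt, test_pairs, scheme = default_label_scheme(),
                           include_noise_only = FALSE,
                           which = c("dsc", "voe"), spacing = c(1, 1, 1)) {
  pairs <- filter_dataset(test_pairs, keep_noise_only = include_noise_only)
  if (length(pairs) == 0L) stop("no test pairs left to evaluate")
  subj <- vapply(pairs, function(p) p$subject %||% "subject", character(1))
  reports <- lapply(split(seq_along(pairs), subj), function(idx) {
    preds <- segment_slices(ckpt, pairs[idx])
    truths <- lapply(pairs[idx], `[[`, "label")
    evaluate_subject(preds, truths, scheme, which = which, spacing = spacing)
  })
  list(per_subject = reports, aggregate = aggregate_reports(reports))
}
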