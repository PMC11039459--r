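## Training procedures: organ-segmenter pretraining (soft Dice), adversarial
## training of the reconstruction GAN with the segmenter and feature extractor
## frozen, inference, and the lambda-sweep ablation driver. All randomness is
## driven by the R session RNG seeded from the config, so two runs with the
## same config produce identical loss histories.

#' Training configuration
#'
#' Defaults are the full-scale study settings (100 GAN epochs, 200 segmenter
#' epochs, Adam 2e-4 / 5e-4, 128 grid); [desk_config()] gives the reduced
#' single-CPU profile used by the test-bench experiments.
#'
#' @param grid_size cubic volume size.
#' @param voxel_spacing_mm voxel pitch for the scanner geometry.
#' @param epochs_gan,epochs_seg training lengths.
#' @param lr_gan,lr_seg Adam learning rates.
#' @param batch_size gradients are averaged over this many volumes per update.
#' @param seed master seed for initialisation and data order.
#' @param weights a [loss_weights()].
#' @param n_levels_gen generator U-Net depth.
#' @param base_channels_gen,base_channels_disc,base_channels_seg widths.
#' @param hu_window HU normalisation window.
#' @param holdout_fraction fraction of the corpus (by index, from the end)
#'   held out from training.
#' @param perceptual_kind `"l2"` or `"l1"` feature distance.
#' @param extractor_seed seed of the fixed feature pyramid.
#' @param checkpoint_dir optional directory for per-epoch checkpoints.
#' @return Object of class `train_config`.
#' @export
train_config <- function(grid_size = 128L, voxel_spacing_mm = 2.5,
                         epochs_gan = 100L, epochs_seg = 200L,
                         lr_gan = 2e-4, lr_seg = 5e-4, batch_size = 1L,
                         seed = 1L, weights = loss_weights(),
                         n_levels_gen = 4L, base_channels_gen = 64L,
                         base_channels_disc = 64L, base_channels_seg = 8L,
                         hu_window = c(-1024, 3071), holdout_fraction = 0.2,
                         perceptual_kind = "l2", extractor_seed = 1234L,
                         checkpoint_dir = NULL) {
  stopifnot(lr_gan > 0, lr_seg > 0, epochs_gan >= 1L, epochs_seg >= 1L,
            batch_size >= 1L)
  structure(list(grid_size = as.integer(grid_size),
                 voxel_spacing_mm = voxel_spacing_mm,
                 epochs_gan = as.integer(epochs_gan),
                 epochs_seg = as.integer(epochs_seg),
                 lr_gan = lr_gan, lr_seg = lr_seg,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 weights = weights, n_levels_gen = as.integer(n_levels_gen),
                 base_channels_gen = as.integer(base_channels_gen),
                 base_channels_disc = as.integer(base_channels_disc),
                 base_channels_seg = as.integer(base_channels_seg),
                 hu_window = hu_window, holdout_fraction = holdout_fraction,
                 perceptual_kind = perceptual_kind,
                 extractor_seed = as.integer(extractor_seed),
                 checkpoint_dir = checkpoint_dir), class = "train_config")
}

#' Desk-scale configuration preset (single-CPU pipeline exercise)
#' @param grid_size reduced grid (default 32).
#' @param seed master seed.
#' @param ... overrides forwarded to [train_config()].
#' @return A `train_config`.
#' @export
desk_config <- function(grid_size = 32L, seed = 1L, ...) {
  args <- list(grid_size = grid_size, epochs_gan = 10L, epochs_seg = 20L,
               batch_size = 4L, seed = seed, base_channels_gen = 8L,
               base_channels_disc = 8L, base_channels_seg = 4L)
  over <- list(...)
  args[names(over)] <- over
  do.call(train_config, args)
}

## Accept either a manifest data frame or an in-memory list of phantoms.
load_phantoms <- function(data) {
  if (is.data.frame(data)) {
    lapply(seq_len(nrow(data)), function(i) {
      img <- RNifti::readNifti(data$path_image[i])
      lab <- if (!is.null(data$path_labels[i]) && nzchar(data$path_labels[i]) &&
                 file.exists(data$path_labels[i]))
        array(as.integer(RNifti::readNifti(data$path_labels[i])),
              dim = dim(RNifti::readNifti(data$path_labels[i]))) else NULL
      structure(list(hu_volume = array(as.numeric(img), dim = dim(img)),
                     labels = lab,
                     spacing_mm = RNifti::pixdim(img)[1]),
                class = "labeled_phantom")
    })
  } else if (is.list(data) && all(vapply(data, inherits, logical(1),
                                         "labeled_phantom"))) {
    data
  } else stop("expected a manifest data frame or a list of labeled_phantom")
}

split_indices <- function(n, holdout_fraction) {
  n_hold <- max(if (holdout_fraction > 0) 1L else 0L,
                floor(n * holdout_fraction))
  list(train = seq_len(n - n_hold),
       holdout = if (n_hold > 0) (n - n_hold + 1L):n else integer(0))
}

norm_volume <- function(ph, hu_window) {
  v <- normalize_hu(ph$hu_volume, hu_window[1], hu_window[2])
  attributes(v) <- list(dim = dim(ph$hu_volume))
  v
}

onehot_labels <- function(labels, n_classes = 4L) {
  n <- dim(labels)
  oh <- array(0, dim = c(n, n_classes))
  for (c in seq_len(n_classes)) oh[, , , c] <- as.numeric(labels == c - 1L)
  oh
}

## ---- segmenter pretraining ------------------------------------------------

#' Pretrain the organ segmenter on labelled phantoms
#'
#' Trains the 3-d U-Net with multi-class soft Dice (foreground classes)
#' against one-hot phantom labels, Adam at `lr_seg`, fixed seeded data order.
#'
#' @param data manifest data frame (with labels) or list of `labeled_phantom`s.
#' @param config a [train_config()].
#' @return Object of class `segnet_fit`: `params`, `cfg`, `history` (per-epoch
#'   training loss and held-out mean foreground DSC), `hu_window`.
#' @export
pretrain_segnet <- function(data, config = train_config()) {
  phantoms <- load_phantoms(data)
  if (any(vapply(phantoms, function(p) is.null(p$labels), logical(1))))
    stop("pretrain_segnet: corpus has unlabelled entries")
  n <- length(phantoms)
  sp <- split_indices(n, config$holdout_fraction)
  cfg <- segnet_config(config$grid_size, config$base_channels_seg)
  set.seed(config$seed)
  params <- init_segnet(cfg)
  opt <- adam_init(params, config$lr_seg)
  vols <- lapply(phantoms, norm_volume, hu_window = config$hu_window)
  ohs <- lapply(phantoms, function(p) onehot_labels(p$labels))

  hist_rows <- vector("list", config$epochs_seg)
  for (ep in seq_len(config$epochs_seg)) {
    order <- sp$train[sample.int(length(sp$train))]
    losses <- numeric(0)
    for (b in split(order, ceiling(seq_along(order) / config$batch_size))) {
      acc <- NULL
      for (i in b) {
        fw <- segnet_forward(vols[[i]], params, cfg, want_cache = TRUE)
        ## background is included in the pretraining Dice: without it the
        ## softmax slack collapses onto the weakest foreground class
        sd <- soft_dice(fw$prob, ohs[[i]], classes = 1:4, want_grad = TRUE)
        losses <- c(losses, sd$value)
        g <- segnet_backward(sd$grad, params, cfg, fw$cache)$grads
        acc <- grads_add(acc, g)
      }
      st <- adam_step(opt, params, grads_scale(acc, 1 / length(b)))
      opt <- st$opt; params <- st$params
    }
    hd <- NA_real_
    if (length(sp$holdout) > 0) {
      fit_tmp <- list(params = params, cfg = cfg)
      dscs <- vapply(sp$holdout, function(i)
        mean(dsc(segment_volume(vols[[i]], fit_tmp), phantoms[[i]]$labels)),
        numeric(1))
      hd <- mean(dscs)
    }
    hist_rows[[ep]] <- data.frame(epoch = ep, dice_loss = mean(losses),
                                  holdout_dsc = hd)
  }
  fit <- structure(list(params = params, cfg = cfg,
                        history = do.call(rbind, hist_rows),
                        hu_window = config$hu_window, config = config),
                   class = "segnet_fit")
  if (!is.null(config$checkpoint_dir))
    save_checkpoint(fit, file.path(config$checkpoint_dir, "segnet.rds"))
  fit
}

#' @export
print.segnet_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("Organ segmenter (3D U-Net, %d^3, base %d): %d epochs\n",
              x$cfg$grid_size, x$cfg$base_channels, nrow(h)))
  cat(sprintf("  final dice loss %.4f, held-out mean DSC %.3f\n",
              h$dice_loss[nrow(h)], h$holdout_dsc[nrow(h)]))
  invisible(x)
}

#' @export
predict.segnet_fit <- function(object, volume, type = c("mask", "prob"), ...) {
  type <- match.arg(type)
  if (type == "mask") segment_volume(volume, object)
  else segnet_forward(volume, object$params, object$cfg)$prob
}

## ---- GAN training ---------------------------------------------------------

gan_geometries <- function(config) {
  list(ap = fan_beam_geometry(n_image = config$grid_size,
                              n_detector = config$grid_size,
                              voxel_spacing_mm = config$voxel_spacing_mm,
                              view = "AP"),
       lat = fan_beam_geometry(n_image = config$grid_size,
                               n_detector = config$grid_size,
                               voxel_spacing_mm = config$voxel_spacing_mm,
                               view = "LAT"))
}

#' Train the two-view reconstruction GAN
#'
#' Per iteration: the generator maps the simulated topogram pair to a volume;
#' the discriminator is stepped on its least-squares loss and the generator on
#' the composite objective (adversarial + reconstruction + projection
#' consistency + frozen-segmenter Dice + perceptual), one discriminator step
#' per generator step. The segmenter and feature extractor receive no
#' updates.
#'
#' @param data manifest data frame or list of `labeled_phantom`s.
#' @param segnet a [pretrain_segnet()] fit (required when `lambda_s > 0`).
#' @param config a [train_config()].
#' @param resume_from path of a checkpoint written by an interrupted run of
#'   the same config; training continues bitwise-identically from it.
#' @return Object of class `ctgan_fit` with generator/discriminator
#'   parameters, configs, the per-epoch loss history, and the projection
#'   normalisation constant.
#' @export
train_gan <- function(data, segnet = NULL, config = train_config(),
                      resume_from = NULL) {
  w <- config$weights
  if (w$lambda_s > 0 && is.null(segnet))
    stop("train_gan: lambda_s > 0 requires a pretrained segmenter checkpoint (segnet)")
  phantoms <- load_phantoms(data)
  sp <- split_indices(length(phantoms), config$holdout_fraction)
  geoms <- gan_geometries(config)
  gcfg <- gen_config(config$grid_size, config$n_levels_gen,
                     config$base_channels_gen, geometry = geoms$ap)
  dcfg <- disc_config(config$grid_size, config$base_channels_disc)
  extractor <- if (w$lambda_p > 0) feature_extractor(seed = config$extractor_seed)

  vols <- lapply(phantoms, norm_volume, hu_window = config$hu_window)
  proj_norm <- compute_proj_norm(vols[sp$train], geoms$ap, geoms$lat)
  topos <- lapply(vols, simulate_topograms, geom_ap = geoms$ap,
                  geom_lat = geoms$lat, proj_norm = proj_norm)
  ## projection-consistency residuals are taken on the same normalised scale
  ## as the input topograms, so L_proj is commensurate with L_r under the
  ## study's weights; the scaled operator stays a fixed linear map
  proj_ops <- lapply(geoms, function(g) {
    p <- cached_projector(g)
    structure(list(weights = p$weights / proj_norm, geometry = p$geometry,
                   step_mm = p$step_mm), class = "fan_projector")
  })
  ym_cache <- if (w$lambda_s > 0)
    lapply(vols, function(v) segnet_forward(v, segnet$params, segnet$cfg)$prob)

  start_epoch <- 1L
  history <- NULL
  if (is.null(resume_from)) {
    set.seed(config$seed)
    gp <- init_generator(gcfg)
    dp <- init_discriminator(dcfg)
    gopt <- adam_init(gp, config$lr_gan)
    dopt <- adam_init(dp, config$lr_gan)
  } else {
    ck <- load_checkpoint(resume_from)
    gp <- ck$gen_params; dp <- ck$disc_params
    gopt <- ck$gen_opt; dopt <- ck$disc_opt
    start_epoch <- ck$epoch + 1L
    history <- ck$history
    assign(".Random.seed", ck$rng_state, globalenv())
  }

  for (ep in seq.int(start_epoch, config$epochs_gan)) {
    order <- sp$train[sample.int(length(sp$train))]
    comp_sums <- c(gen = 0, r = 0, proj = 0, s = 0, p = 0, total = 0, dis = 0)
    n_seen <- 0L
    for (b in split(order, ceiling(seq_along(order) / config$batch_size))) {
      gacc <- NULL; dacc <- NULL
      for (i in b) {
        y <- vols[[i]]
        gf <- generator_forward(topos[[i]]$ap, topos[[i]]$lat, gp, gcfg,
                                want_cache = TRUE)
        yp <- gf$y
        ## discriminator loss and gradients (generated volume detached)
        dr <- discriminator_forward(y, dp, dcfg, want_cache = TRUE)
        df <- discriminator_forward(yp, dp, dcfg, want_cache = TRUE)
        l_dis <- loss_discriminator(dr$score, df$score)
        dbr <- discriminator_backward((dr$score - 1) / length(dr$score),
                                      dp, dcfg, dr$cache)
        dbf <- discriminator_backward(df$score / length(df$score),
                                      dp, dcfg, df$cache)
        dacc <- grads_add(dacc, grads_add(dbr$grads, dbf$grads))

        ## generator objective (through the pre-update discriminator)
        l_gen <- loss_generator_adv(df$score)
        adv_bw <- discriminator_backward(2 * (df$score - 1) / length(df$score),
                                         dp, dcfg, df$cache)
        lr_ <- loss_reconstruction(yp, y, want_grad = TRUE)
        lproj <- loss_projection(yp, y, proj_ops$ap, proj_ops$lat, want_grad = TRUE)
        gy <- w$lambda_gen * adv_bw$gx + w$lambda_r * lr_$grad +
          w$lambda_proj * array(lproj$grad, dim = dim(yp))
        l_s <- 0; l_p <- 0
        if (w$lambda_s > 0) {
          sfw <- segnet_forward(yp, segnet$params, segnet$cfg, want_cache = TRUE)
          sd <- soft_dice(sfw$prob, ym_cache[[i]], classes = 2:4, want_grad = TRUE)
          l_s <- sd$value
          gy <- gy + w$lambda_s *
            segnet_backward(sd$grad, segnet$params, segnet$cfg, sfw$cache)$gx
        }
        if (w$lambda_p > 0) {
          lp <- loss_perceptual(yp, y, extractor, kind = config$perceptual_kind,
                                want_grad = TRUE)
          l_p <- lp$value
          gy <- gy + w$lambda_p * lp$grad
        }
        gacc <- grads_add(gacc, generator_backward(gy, gp, gcfg, gf$cache))

        total <- total_generator_loss(
          list(gen = l_gen, r = lr_$value, proj = lproj$value, s = l_s, p = l_p), w)
        comp_sums <- comp_sums + c(l_gen, lr_$value, lproj$value, l_s, l_p,
                                   total, l_dis)
        n_seen <- n_seen + 1L
      }
      st <- adam_step(dopt, dp, grads_scale(dacc, 1 / length(b)))
      dopt <- st$opt; dp <- st$params
      st <- adam_step(gopt, gp, grads_scale(gacc, 1 / length(b)))
      gopt <- st$opt; gp <- st$params
    }
    row <- as.data.frame(as.list(comp_sums / n_seen))
    names(row) <- c("gen", "r", "proj", "s", "p", "total", "dis")
    row$epoch <- ep
    history <- rbind(history, row[, c("epoch", "gen", "r", "proj", "s", "p",
                                      "total", "dis")])
    if (!is.null(config$checkpoint_dir)) {
      dir.create(config$checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
      save_checkpoint(list(gen_params = gp, disc_params = dp, gen_opt = gopt,
                           disc_opt = dopt, epoch = ep, history = history,
                           rng_state = get(".Random.seed", globalenv()),
                           config = config, proj_norm = proj_norm),
                      file.path(config$checkpoint_dir,
                                sprintf("gan_epoch%03d.rds", ep)))
    }
  }
  structure(list(gen_params = gp, gen_cfg = gcfg, disc_params = dp,
                 disc_cfg = dcfg, history = history, config = config,
                 proj_norm = proj_norm, hu_window = config$hu_window,
                 holdout = sp$holdout),
            class = "ctgan_fit")
}

#' @export
print.ctgan_fit <- function(x, ...) {
  h <- x$history
  w <- x$config$weights
  cat(sprintf("Two-view CT reconstruction GAN (%d^3, base %d, %d epochs)\n",
              x$gen_cfg$grid_size, x$gen_cfg$base_channels, nrow(h)))
  cat(sprintf("  lambdas: gen %.2g, r %.2g, proj %.2g, s %.2g, p %.2g\n",
              w$lambda_gen, w$lambda_r, w$lambda_proj, w$lambda_s, w$lambda_p))
  cat(sprintf("  final epoch: L_r %.5f, L_proj %.5f, total %.4f\n",
              h$r[nrow(h)], h$proj[nrow(h)], h$total[nrow(h)]))
  invisible(x)
}

#' @export
plot.ctgan_fit <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$r, h$proj, h$s, h$p), type = "l", lty = 1,
                    xlab = "epoch", ylab = "loss component",
                    main = "Generator loss components", ...)
  graphics::legend("topright", legend = c("L_r", "L_proj", "L_s", "L_p"),
                   col = 1:4, lty = 1, bty = "n")
  invisible(x)
}

#' Reconstruct a CT volume from a topogram pair
#'
#' A single deterministic generator forward pass; when a segmenter fit is
#' supplied the argmax organ mask of the reconstruction is returned as well.
#'
#' @param proj_ap,proj_lat normalised `(n, n)` projections.
#' @param gan a `ctgan_fit` (or checkpoint list with `gen_params`, `gen_cfg`).
#' @param segnet optional `segnet_fit`.
#' @return list with `volume` (in `[0,1]`) and optionally `mask`.
#' @export
reconstruct <- function(proj_ap, proj_lat, gan, segnet = NULL) {
  y <- generator_forward(proj_ap, proj_lat, gan$gen_params, gan$gen_cfg)$y
  out <- list(volume = y)
  if (!is.null(segnet)) out$mask <- segment_volume(y, segnet)
  out
}

#' @export
predict.ctgan_fit <- function(object, proj_ap, proj_lat, segnet = NULL, ...) {
  reconstruct(proj_ap, proj_lat, object, segnet)
}

## Simulate the topograms of a phantom with the fit's stored constants and
## reconstruct it.
reconstruct_phantom <- function(ph, gan, segnet = NULL) {
  geoms <- gan_geometries(gan$config)
  v <- norm_volume(ph, gan$hu_window)
  tp <- simulate_topograms(v, geoms$ap, geoms$lat, gan$proj_norm)
  reconstruct(tp$ap, tp$lat, gan, segnet)
}

#' Evaluate a trained GAN on held-out phantoms
#' @param gan a `ctgan_fit`.
#' @param phantoms list of `labeled_phantom`s (defaults would be the held-out
#'   part of the training corpus; pass it explicitly).
#' @param segnet the segmenter used for Dice evaluation.
#' @return list of per-phantom reports plus the aggregated table.
#' @export
evaluate_gan <- function(gan, phantoms, segnet) {
  reports <- lapply(phantoms, function(ph) {
    rec <- reconstruct_phantom(ph, gan)
    evaluate_reconstruction(rec$volume, ph, segnet, gan$hu_window)
  })
  list(reports = reports,
       M_analog = aggregate_reports(lapply(reports, `[[`, "M_analog")),
       S_analog = aggregate_reports(lapply(reports, `[[`, "S_analog")))
}

#' Lambda-sweep ablation driver
#'
#' Trains one GAN per `(lambda_s, lambda_p)` pair with a shared seed and data
#' split and evaluates all of them on the same held-out phantoms.
#'
#' @param data manifest or phantom list.
#' @param segnet pretrained segmenter (used for training when `lambda_s > 0`
#'   and always for evaluation).
#' @param lambda_grid data frame with columns `lambda_s`, `lambda_p`.
#' @param config a [train_config()].
#' @return data frame: lambda_s, lambda_p, psnr, ssim, rmse_hu, dsc_m, dsc_s.
#' @export
run_ablation <- function(data, segnet, lambda_grid, config = train_config()) {
  if (is.null(lambda_grid) || nrow(lambda_grid) == 0L)
    stop("run_ablation: empty lambda grid")
  phantoms <- load_phantoms(data)
  sp <- split_indices(length(phantoms), config$holdout_fraction)
  rows <- vector("list", nrow(lambda_grid))
  for (k in seq_len(nrow(lambda_grid))) {
    wk <- loss_weights(lambda_s = lambda_grid$lambda_s[k],
                       lambda_p = lambda_grid$lambda_p[k])
    cfg_k <- config
    cfg_k$weights <- wk
    fit <- train_gan(phantoms, segnet = segnet, config = cfg_k)
    ev <- evaluate_gan(fit, phantoms[sp$holdout], segnet)
    pick <- function(tab, m) tab$mean[tab$metric == m]
    rows[[k]] <- data.frame(lambda_s = wk$lambda_s, lambda_p = wk$lambda_p,
                            psnr = pick(ev$S_analog, "psnr_db"),
                            ssim = pick(ev$S_analog, "ssim"),
                            rmse_hu = pick(ev$S_analog, "rmse_hu"),
                            dsc_m = pick(ev$M_analog, "dsc_mean"),
                            dsc_s = pick(ev$S_analog, "dsc_mean"))
  }
  do.call(rbind, rows)
}

## ---- checkpoints ----------------------------------------------------------

#' Save / load a versioned single-file checkpoint
#' @param object any fit or training-state list.
#' @param path file path (`.rds`).
#' @export
save_checkpoint <- function(object, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(list(format_version = 1L, payload = object), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (is.null(ck$format_version) || ck$format_version != 1L)
    stop("load_checkpoint: unsupported checkpoint format")
  ck$payload
}
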