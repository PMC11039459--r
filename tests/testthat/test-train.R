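# Smoke-level training contracts at miniature scale; the full desk-scale
# behaviour (loss decrease, anatomy trend) lives in the acceptance suite.

tiny_cfg <- function(...) desk_config(grid_size = 32L, seed = 7L,
                                      epochs_seg = 2L, epochs_gan = 2L,
                                      batch_size = 2L, ...)

tiny_seg <- function() memo("tiny_seg", {
  pretrain_segnet(small_phantoms(5, seed = 11L), tiny_cfg())
})

test_that("segmenter pretraining runs, logs, checkpoints and reloads", {
  fit <- tiny_seg()
  expect_s3_class(fit, "segnet_fit")
  expect_equal(nrow(fit$history), 2L)
  expect_true(all(is.finite(fit$history$dice_loss)))
  expect_true(all(is.finite(fit$history$holdout_dsc)))
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(fit, ck)
  fit2 <- load_checkpoint(ck)
  v <- norm_vol(small_phantoms(5, seed = 11L)[[1]])
  expect_identical(predict(fit, v), predict(fit2, v))
  expect_error(pretrain_segnet(list(structure(list(hu_volume = v, labels = NULL),
                                             class = "labeled_phantom")),
                               tiny_cfg()),
               "unlabelled")
})

test_that("GAN training demands a segmenter when the Dice term is active", {
  expect_error(train_gan(small_phantoms(5, seed = 11L), segnet = NULL,
                         config = tiny_cfg()),
               "pretrained segmenter")
})

test_that("GAN training logs every loss component and stays finite", {
  fit <- memo("tiny_gan", train_gan(small_phantoms(5, seed = 11L), tiny_seg(),
                                    tiny_cfg()))
  expect_s3_class(fit, "ctgan_fit")
  expect_identical(names(fit$history),
                   c("epoch", "gen", "r", "proj", "s", "p", "total", "dis"))
  expect_true(all(is.finite(as.matrix(fit$history[-1]))))
  expect_gt(fit$proj_norm, 0)
})

test_that("reconstruction is deterministic, bounded, and mask-capable", {
  fit <- memo("tiny_gan", train_gan(small_phantoms(5, seed = 11L), tiny_seg(),
                                    tiny_cfg()))
  ph <- small_phantoms(5, seed = 11L)[[5]]
  geoms <- topo2ct:::gan_geometries(fit$config)
  tp <- simulate_topograms(norm_vol(ph), geoms$ap, geoms$lat, fit$proj_norm)
  r1 <- reconstruct(tp$ap, tp$lat, fit)
  r2 <- predict(fit, tp$ap, tp$lat, segnet = tiny_seg())
  expect_identical(r1$volume, r2$volume)
  expect_true(all(r1$volume >= 0 & r1$volume <= 1))
  expect_equal(dim(r1$volume), c(32, 32, 32))
  expect_true(all(r2$mask %in% 0:3))
  expect_error(reconstruct(tp$ap[1:16, ], tp$lat, fit), "projections")
})

test_that("a checkpointed run resumes bitwise-identically", {
  phs <- small_phantoms(5, seed = 11L)
  ckdir <- file.path(tempdir(), "resume_ck")
  unlink(ckdir, recursive = TRUE)
  cfg3 <- tiny_cfg(epochs_gan = 3L, checkpoint_dir = ckdir)
  full <- train_gan(phs, tiny_seg(), cfg3)
  resumed <- train_gan(phs, tiny_seg(), cfg3,
                       resume_from = file.path(ckdir, "gan_epoch002.rds"))
  expect_identical(full$history, resumed$history)
  expect_identical(full$gen_params, resumed$gen_params)
})

test_that("the ablation driver produces one evaluated row per lambda pair", {
  phs <- small_phantoms(5, seed = 11L)
  grid <- data.frame(lambda_s = c(0, 2), lambda_p = c(0, 0.5))
  tab <- memo("tiny_ablation", run_ablation(phs, tiny_seg(), grid, tiny_cfg()))
  expect_equal(nrow(tab), 2L)
  expect_identical(names(tab),
                   c("lambda_s", "lambda_p", "psnr", "ssim", "rmse_hu",
                     "dsc_m", "dsc_s"))
  expect_true(all(is.finite(as.matrix(tab))))
  expect_equal(tab$lambda_s[1], 0)   # first row is the baseline arm
  expect_error(run_ablation(phs, tiny_seg(), data.frame(), tiny_cfg()),
               "empty lambda grid")
})

test_that("training runs are reproducible from the config seed alone", {
  phs <- small_phantoms(5, seed = 11L)
  f1 <- train_gan(phs, tiny_seg(), tiny_cfg(epochs_gan = 1L))
  f2 <- train_gan(phs, tiny_seg(), tiny_cfg(epochs_gan = 1L))
  expect_identical(f1$history, f2$history)
})
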