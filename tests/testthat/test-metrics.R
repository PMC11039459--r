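test_that("PSNR and RMSE closed forms and oracles", {
  a <- array(0.4, c(8, 8, 8))
  expect_equal(psnr(a + 0.1, a), 20)
  expect_equal(psnr(a, a), Inf)
  set.seed(51)
  b <- array(runif(8^3), c(8, 8, 8))
  expect_lt(abs(psnr(a, b) - 10 * log10(1 / mean((a - b)^2))), 1e-10)
  expect_error(psnr(a, array(0, c(4, 4, 4))), "shape")

  hw <- c(-1024, 3071)
  width <- hw[2] - hw[1]
  expect_equal(rmse_hu(a + 100 / width, a, hw), 100, tolerance = 1e-9)
  expect_equal(rmse_hu(a, a, hw), 0)
  expect_equal(rmse_hu(a, b, hw), sqrt(mean((a - b)^2)) * width,
               tolerance = 1e-9)
  expect_error(rmse_hu(a, b), "hu_window")
})

test_that("SSIM: identity gives 1, independent noise gives ~0", {
  ph <- small_phantoms(1, grid = 64L, seed = 15L)[[1]]
  v <- norm_vol(ph)
  expect_equal(ssim(v, v), 1, tolerance = 1e-9)
  set.seed(52)
  n1 <- array(runif(64^3), c(64, 64, 64))
  n2 <- array(runif(64^3), c(64, 64, 64))
  expect_lt(abs(ssim(n1, n2)), 0.1)
  expect_error(ssim(array(0, c(8, 8, 8)), array(0, c(8, 8, 8))), "window")
})

test_that("3-d SSIM agrees with an established 2-d implementation slice-wise", {
  # smooth phantom pair: noise-free anatomy against a smoothly modulated copy
  spec <- phantom_spec(grid_size = 32L, seed = 16L, noise_hu_sd = 0)
  ph <- sample_phantom(spec, 1L)
  v <- norm_vol(ph)
  ax <- (seq_len(32) - 0.5) / 32
  mod <- array(rep(0.02 * sin(2 * pi * ax), each = 32 * 32), c(32, 32, 32))
  w <- pmin(pmax(0.95 * v + mod + 0.01, 0), 1)
  attributes(w) <- list(dim = dim(v))
  ours <- ssim(v, w)
  td <- tempfile(); dir.create(td)
  writeBin(as.numeric(v), file.path(td, "a.bin"))
  writeBin(as.numeric(w), file.path(td, "b.bin"))
  py <- sprintf("
import numpy as np
from skimage.metrics import structural_similarity
a = np.fromfile('%s/a.bin').reshape((32,32,32), order='F')
b = np.fromfile('%s/b.bin').reshape((32,32,32), order='F')
vals = [structural_similarity(a[:,:,z], b[:,:,z], gaussian_weights=True,
        sigma=1.5, use_sample_covariance=False, data_range=1.0)
        for z in range(32)]
print(np.mean(vals))
", td, td)
  res <- system2("python", c("-c", shQuote(py)), stdout = TRUE)
  ref <- as.numeric(res[length(res)])
  expect_lt(abs(ours - ref), 0.02)
})

test_that("per-organ Dice closed forms and edge rules", {
  a <- array(0L, c(10, 10, 10)); b <- array(0L, c(10, 10, 10))
  expect_equal(unname(dsc(a, b)), c(1, 1, 1))   # empty classes count as 1
  a[1:100] <- 1L; b[51:150] <- 1L                # half overlap
  expect_equal(unname(dsc(a, b)[1]), 0.5)
  a2 <- a; a2[a2 == 1L] <- 2L
  b2 <- b; b2[b2 == 1L] <- 3L                    # disjoint supports
  expect_equal(unname(dsc(a2, b2)[c("liver", "bone")]), c(0, 0))
  expect_equal(unname(dsc(a, a)), c(1, 1, 1))
  bad <- a; bad[1] <- 7L
  expect_error(dsc(bad, b), "unknown label")
})

test_that("dual-reference evaluation reports both protocols coherently", {
  ph <- small_phantoms(1)[[1]]
  v <- norm_vol(ph)
  cfg <- segnet_config(32L, 2L)
  set.seed(54)
  segnet <- list(params = init_segnet(cfg), cfg = cfg)
  rep2 <- evaluate_reconstruction(v, ph, segnet)
  expect_s3_class(rep2$M_analog, "metrics_report")
  expect_equal(rep2$M_analog$reference_kind, "M_analog")
  expect_equal(rep2$S_analog$reference_kind, "S_analog")
  # identical prediction: the segmenter agrees with itself exactly
  expect_equal(rep2$S_analog$dsc_mean, 1)
  expect_equal(unname(rep2$S_analog$dsc_per_organ), c(1, 1, 1))
  expect_equal(rep2$S_analog$psnr_db, Inf)
  expect_equal(rep2$M_analog$dsc_mean, mean(rep2$M_analog$dsc_per_organ),
               tolerance = 1e-12)
  # phantom without labels: M reference unavailable
  ph2 <- ph; ph2$labels <- NULL
  expect_warning(r3 <- evaluate_reconstruction(v, ph2, segnet), "M_analog")
  expect_null(r3$M_analog)

  agg <- aggregate_reports(list(rep2$S_analog, rep2$S_analog))
  expect_equal(agg$mean[agg$metric == "dsc_mean"], 1)
  expect_equal(agg$sd[agg$metric == "dsc_mean"], 0)
})
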