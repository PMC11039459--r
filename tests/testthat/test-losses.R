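test_that("least-squares adversarial losses hit their closed forms", {
  ones <- array(1, c(4, 4, 4)); zeros <- array(0, c(4, 4, 4))
  half <- array(0.5, c(4, 4, 4))
  expect_equal(loss_discriminator(ones, zeros), 0)
  expect_equal(loss_discriminator(half, half), 0.25)
  expect_equal(loss_discriminator(zeros, ones), 1)
  expect_equal(loss_generator_adv(ones), 0)
  expect_equal(loss_generator_adv(half), 0.25)
  expect_equal(loss_generator_adv(zeros), 1)
  expect_error(loss_discriminator(ones * NA, zeros), "non-finite")
})

test_that("reconstruction loss matches a brute-force double loop", {
  set.seed(31)
  a <- array(runif(8^3), c(8, 8, 8)); b <- array(runif(8^3), c(8, 8, 8))
  expect_equal(loss_reconstruction(a, a), 0)
  expect_equal(loss_reconstruction(a + 0.1, a), 0.01, tolerance = 1e-12)
  brute <- 0
  for (i in 1:8) for (j in 1:8) for (k in 1:8)
    brute <- brute + (a[i, j, k] - b[i, j, k])^2
  expect_lt(abs(loss_reconstruction(a, b) - brute / 512), 1e-12)
  expect_error(loss_reconstruction(a, array(0, c(4, 4, 4))), "shape")
  g <- loss_reconstruction(a, b, want_grad = TRUE)
  expect_equal(g$grad, 2 * (a - b) / 512)
})

test_that("projection-consistency loss is zero on identity, symmetric, and sensitive", {
  ph <- small_phantoms(2)
  ga <- small_geom(32L, "AP"); gl <- small_geom(32L, "LAT")
  v1 <- norm_vol(ph[[1]])
  expect_equal(loss_projection(v1, v1, ga, gl), 0)
  v2 <- v1
  v2[ph[[1]]$labels == 1L] <- v2[ph[[1]]$labels == 1L] + 0.05
  expect_equal(loss_projection(v1, v2, ga, gl), loss_projection(v2, v1, ga, gl))
  expect_gt(loss_projection(v1, v2, ga, gl), 0)
  # gradient matches finite differences through the sparse operator
  g <- loss_projection(v2, v1, ga, gl, want_grad = TRUE)
  eps <- 1e-6; err <- 0
  set.seed(32)
  for (k in sample(length(v2), 6)) {
    vp <- v2; vp[k] <- vp[k] + eps
    vm <- v2; vm[k] <- vm[k] - eps
    num <- (loss_projection(vp, v1, ga, gl) - loss_projection(vm, v1, ga, gl)) / (2 * eps)
    err <- max(err, abs(num - g$grad[k]))
  }
  expect_lt(err, 1e-7)
})

test_that("soft Dice matches its closed forms on hard masks", {
  # one class with |A|=|B|=100 and overlap 50, other foreground classes
  # identical -> per-class (0.5, 0, 0), mean 1/6
  pm <- matrix(0, 1000, 4); rm <- matrix(0, 1000, 4)
  pm[1:100, 2] <- 1; rm[51:150, 2] <- 1      # lung: half overlap
  pm[201:260, 3] <- 1; rm[201:260, 3] <- 1   # liver identical
  pm[301:340, 4] <- 1; rm[301:340, 4] <- 1   # bone identical
  sd <- topo2ct:::soft_dice(array(pm, c(10, 10, 10, 4)),
                            array(rm, c(10, 10, 10, 4)), classes = 2:4)
  expect_equal(sd$per_class, c(0.5, 0, 0), tolerance = 1e-5)
  expect_equal(sd$value, 1 / 6, tolerance = 1e-5)
  # zero overlap in every class -> 1
  rm2 <- matrix(0, 1000, 4)
  rm2[101:200, 2] <- 1; rm2[401:460, 3] <- 1; rm2[501:540, 4] <- 1
  sd2 <- topo2ct:::soft_dice(array(pm, c(10, 10, 10, 4)),
                             array(rm2, c(10, 10, 10, 4)), classes = 2:4)
  expect_equal(sd2$value, 1, tolerance = 1e-5)
})

test_that("segmentation loss through a frozen segmenter is 0 on identical inputs", {
  cfg <- segnet_config(32L, 2L)
  set.seed(33)
  segnet <- list(params = init_segnet(cfg), cfg = cfg)
  v <- norm_vol(small_phantoms(1)[[1]])
  expect_lt(abs(loss_segmentation(v, v, segnet)), 1e-6)
  v2 <- pmin(v + 0.1, 1)
  attributes(v2) <- list(dim = dim(v))
  expect_gt(loss_segmentation(v2, v, segnet), 0)
})

test_that("perceptual loss: zero on identity, non-negative, identity-extractor oracle", {
  ex <- feature_extractor(seed = 7)
  set.seed(34)
  a <- array(runif(16^3), c(16, 16, 16))
  b <- array(runif(16^3), c(16, 16, 16))
  expect_equal(loss_perceptual(a, a, ex), 0)
  expect_gt(loss_perceptual(a, b, ex), 0)

  # identity extractor: level 1 passes slices through unchanged, deeper
  # levels are all-zero; with mean aggregation over the three replicated
  # channels the loss equals the plain reconstruction MSE
  id_params <- lapply(1:4, function(l) {
    cin <- c(3L, 8L, 16L, 32L)[l]
    cout <- c(8L, 16L, 32L, 32L)[l]
    list(w = array(0, c(3, 3, 1, cin, cout)), b = numeric(cout))
  })
  id_params[[1]]$w <- array(0, c(3, 3, 1, 3, 3))
  for (c in 1:3) id_params[[1]]$w[2, 2, 1, c, c] <- 1
  ex_id <- feature_extractor(params = id_params)
  a8 <- array(runif(8^3), c(8, 8, 8)); b8 <- array(runif(8^3), c(8, 8, 8))
  expect_equal(loss_perceptual(a8, b8, ex_id), loss_reconstruction(a8, b8),
               tolerance = 1e-12)
})

test_that("perceptual loss gradient matches finite differences", {
  ex <- feature_extractor(seed = 7)
  set.seed(35)
  a <- array(runif(8^3), c(8, 8, 8)); b <- array(runif(8^3), c(8, 8, 8))
  g <- loss_perceptual(a, b, ex, want_grad = TRUE)
  eps <- 1e-6; err <- 0
  for (k in sample(512, 8)) {
    ap <- a; ap[k] <- ap[k] + eps
    am <- a; am[k] <- am[k] - eps
    err <- max(err, abs((loss_perceptual(ap, b, ex) - loss_perceptual(am, b, ex)) /
                          (2 * eps) - g$grad[k]))
  }
  expect_lt(err, 1e-6)
})

test_that("the composite objective aggregates with the study weights", {
  comp <- list(gen = 1, r = 1, proj = 1, s = 1, p = 1)
  expect_equal(total_generator_loss(comp, loss_weights()), 22.6)
  expect_equal(total_generator_loss(list(gen = 1, r = 1, proj = 1),
                                    loss_weights(lambda_s = 0, lambda_p = 0)),
               20.1)
  expect_equal(total_generator_loss(list(gen = 0, r = 0, proj = 0, s = 0, p = 0)),
               0)
  expect_error(loss_weights(lambda_s = -1), "non-negative")
})

test_that("non-adversarial losses grow monotonically with perturbation size", {
  ph <- small_phantoms(1)[[1]]
  v <- norm_vol(ph)
  ex <- feature_extractor(seed = 7)
  cfg <- segnet_config(32L, 2L)
  set.seed(36)
  segnet <- list(params = init_segnet(cfg), cfg = cfg)
  noise <- array(rnorm(length(v)), dim = dim(v))
  vals <- sapply(c(0, 0.05, 0.1), function(d) {
    vp <- pmin(pmax(v + d * noise, 0), 1)
    attributes(vp) <- list(dim = dim(v))
    c(r = loss_reconstruction(vp, v),
      proj = loss_projection(vp, v, small_geom(32L, "AP"), small_geom(32L, "LAT")),
      p = loss_perceptual(vp, v, ex),
      s = loss_segmentation(vp, v, segnet))
  })
  for (row in 1:4) expect_true(all(diff(vals[row, ]) > 0))
})
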