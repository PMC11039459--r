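gen_fixture <- function(n = 16L, base = 4L) memo(sprintf("gen_%d_%d", n, base), {
  cfg <- gen_config(n, n_levels = 3L, base_channels = base,
                    geometry = small_geom(n))
  set.seed(41)
  list(cfg = cfg, params = init_generator(cfg))
})

test_that("generator maps two projections to a [0,1] volume of the right shape", {
  fx <- gen_fixture()
  set.seed(42)
  pa <- matrix(runif(16 * 16), 16, 16)
  pl <- matrix(runif(16 * 16), 16, 16)
  out <- generator_forward(pa, pl, fx$params, fx$cfg)
  expect_equal(dim(out$y), c(16, 16, 16))
  expect_true(all(out$y >= 0 & out$y <= 1))
  expect_error(generator_forward(matrix(0, 8, 8), pl, fx$params, fx$cfg),
               "projections")
  expect_error(gen_config(30L, n_levels = 4L, geometry = small_geom(30L)),
               "divisible")
})

test_that("the two encoder pathways are not interchangeable", {
  fx <- gen_fixture()
  set.seed(43)
  pa <- matrix(runif(256), 16, 16); pl <- matrix(runif(256), 16, 16)
  y1 <- generator_forward(pa, pl, fx$params, fx$cfg)$y
  y2 <- generator_forward(pl, pa, fx$params, fx$cfg)$y
  expect_gt(max(abs(y1 - y2)), 0)
})

test_that("a scalar loss reaches both encoder pathways with nonzero gradients", {
  fx <- gen_fixture()
  set.seed(44)
  pa <- matrix(runif(256), 16, 16); pl <- matrix(runif(256), 16, 16)
  fw <- generator_forward(pa, pl, fx$params, fx$cfg, want_cache = TRUE)
  gy <- array(1, c(16, 16, 16)) / 16^3
  grads <- generator_backward(gy, fx$params, fx$cfg, fw$cache)
  expect_identical(names(grads), names(fx$params))
  gnorm <- vapply(grads, function(g) sum(abs(g$w)), numeric(1))
  expect_true(all(gnorm[grepl("^ap\\.", names(gnorm))] > 0))
  expect_true(all(gnorm[grepl("^lat\\.", names(gnorm))] > 0))
})

test_that("generator gradients agree with finite differences end to end", {
  fx <- gen_fixture(16L, 2L)
  set.seed(45)
  pa <- matrix(runif(256), 16, 16); pl <- matrix(runif(256), 16, 16)
  target <- array(runif(16^3), c(16, 16, 16))
  loss_of <- function(params) {
    y <- generator_forward(pa, pl, params, fx$cfg)$y
    mean((y - target)^2)
  }
  fw <- generator_forward(pa, pl, fx$params, fx$cfg, want_cache = TRUE)
  gy <- 2 * (fw$y - target) / length(target)
  grads <- generator_backward(gy, fx$params, fx$cfg, fw$cache)
  eps <- 1e-5; err <- 0
  for (blk in c("ap.enc0", "lat.dec1", "g3.up1", "g3.out")) {
    for (k in sample(length(fx$params[[blk]]$w), 3)) {
      pp <- fx$params; pp[[blk]]$w[k] <- pp[[blk]]$w[k] + eps
      pm <- fx$params; pm[[blk]]$w[k] <- pm[[blk]]$w[k] - eps
      num <- (loss_of(pp) - loss_of(pm)) / (2 * eps)
      err <- max(err, abs(num - grads[[blk]]$w[k]))
    }
  }
  expect_lt(err, 1e-6)
})

test_that("discriminator yields a patch score map at 1/8 resolution", {
  cfg <- disc_config(32L, 4L)
  set.seed(46)
  params <- init_discriminator(cfg)
  v <- array(runif(32^3), c(32, 32, 32))
  out <- discriminator_forward(v, params, cfg)
  expect_equal(dim(out$score), c(4, 4, 4))
  expect_true(all(is.finite(out$score)))
  expect_error(discriminator_forward(array(0, c(16, 16, 16)), params, cfg),
               "wrong input size")
})

test_that("discriminator scores shift with an 8-voxel input shift", {
  cfg <- disc_config(32L, 4L)
  set.seed(47)
  params <- init_discriminator(cfg)
  v <- array(runif(32^3), c(32, 32, 32))
  s1 <- discriminator_forward(v, params, cfg)$score
  vs <- array(0, c(32, 32, 32))
  vs[9:32, , ] <- v[1:24, , ]
  s2 <- discriminator_forward(vs, params, cfg)$score
  # an 8-voxel input shift moves the score map by one patch: the shifted
  # comparison must beat the unshifted one by a wide margin (instance norm
  # and zero-padding preclude exact equality at the borders)
  inner <- 2:3
  err_shift <- mean((s2[inner + 1, inner, inner] - s1[inner, inner, inner])^2)
  err_same <- mean((s2[inner, inner, inner] - s1[inner, inner, inner])^2)
  expect_lt(err_shift, 0.5 * err_same)
})

test_that("segmenter emits per-voxel distributions at input resolution", {
  cfg <- segnet_config(32L, 2L)
  set.seed(48)
  params <- init_segnet(cfg)
  v <- array(runif(32^3), c(32, 32, 32))
  out <- segnet_forward(v, params, cfg)
  expect_equal(dim(out$prob), c(32, 32, 32, 4))
  sums <- apply(out$prob, 1:3, sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  expect_error(segnet_forward(array(0, c(16, 16, 16)), params, cfg),
               "wrong input size")
  expect_error(segnet_config(24L), "divisible")
})
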