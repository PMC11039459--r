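test_that("geometry constructor enforces the scanner invariants", {
  expect_error(fan_beam_geometry(sdd_mm = 500, sid_mm = 595), "sdd_mm > sid_mm")
  expect_error(fan_beam_geometry(voxel_spacing_mm = 0), "voxel_spacing_mm")
  expect_error(fan_beam_geometry(n_detector = 32L, detector_spacing_mm = 0.1,
                                 n_image = 128L),
               "does not cover")
  g <- fan_beam_geometry(n_detector = 128L, n_image = 128L)
  # derived spacing makes the detector exactly cover the magnified FOV
  expect_equal(g$n_detector * g$detector_spacing_mm,
               g$n_image * g$voxel_spacing_mm * g$sdd_mm / g$sid_mm)
})

test_that("system matrix rows are interpolation rows: sum 1 inside, 0 outside", {
  for (view in c("AP", "LAT")) {
    tm <- build_system_matrix(small_geom(64L, view))
    rs <- Matrix::rowSums(tm$weights)
    expect_true(all(abs(rs) < 1e-12 | abs(rs - 1) < 1e-12))
    expect_gt(mean(abs(rs - 1) < 1e-12), 0.8)  # most pixels project inside
    nnz <- Matrix::rowSums(tm$weights != 0)
    expect_true(all(nnz <= 2))
    expect_true(all(tm$weights@x >= 0))
  }
})

test_that("the isocenter pixel projects onto the detector centre", {
  # odd grid puts a pixel exactly at the isocenter; even channel count puts
  # the detector centre between two channels, so the weight splits equally
  g <- fan_beam_geometry(n_detector = 16L, n_image = 17L,
                         voxel_spacing_mm = 2.5, view = "AP",
                         detector_spacing_mm = 10)
  tm <- build_system_matrix(g)
  centre_pix <- 9L + (9L - 1L) * 17L
  row <- tm$weights[centre_pix, ]
  expect_equal(as.numeric(row[8]), 0.5)
  expect_equal(as.numeric(row[9]), 0.5)
})

test_that("system matrix equals the dense brute-force construction", {
  for (view in c("AP", "LAT")) {
    g <- fan_beam_geometry(n_detector = 16L, n_image = 16L,
                           voxel_spacing_mm = 2.5, view = view)
    tm <- build_system_matrix(g)
    expect_lt(max(abs(as.matrix(tm$weights) - brute_force_system_matrix(g))),
              1e-12)
  }
})

test_that("forward projection is linear and rejects malformed volumes", {
  g <- small_geom(32L)
  expect_equal(forward_project(array(0, c(32, 32, 32)), g),
               matrix(0, 32, 32), ignore_attr = TRUE)
  set.seed(5)
  v <- array(runif(32^3), c(32, 32, 32))
  p1 <- forward_project(v, g)
  p2 <- forward_project(2 * v, g)
  expect_lt(max(abs(p2 - 2 * p1)) / max(abs(p2)), 1e-9)
  expect_error(forward_project(array(0, c(32, 32, 16)), g), "cubic")
  expect_error(forward_project(array(0, c(16, 16, 16)), g), "n_image")
})

test_that("projection of a centred uniform disk matches the analytic chord length", {
  g <- fan_beam_geometry(n_detector = 128L, n_image = 128L,
                         voxel_spacing_mm = 2.5, view = "AP")
  n <- 128L
  xc <- (seq_len(n) - (n + 1) / 2) * 2.5
  disk <- array(0, c(n, n, n))
  disk[, , 64] <- outer(xc, xc, function(x, y) as.numeric(x^2 + y^2 <= 50^2))
  p <- forward_project(disk, g)[, 64]
  uk <- (seq_len(n) - (n + 1) / 2) * g$detector_spacing_mm
  gam <- atan2(uk, g$sdd_mm)
  dist <- g$sid_mm * sin(gam)         # signed ray distance to the isocenter
  sel <- abs(dist) < 0.9 * 50
  chord <- 2 * sqrt(50^2 - dist[sel]^2)
  expect_lt(max(abs(p[sel] - chord) / chord), 0.02)
})

test_that("2D->3D lifting is linear, shape-correct and never mixes z rows", {
  tm <- build_system_matrix(small_geom(64L))
  expect_equal(lift_2d_to_3d(array(0, c(64, 64, 3)), tm),
               array(0, c(64, 64, 64, 3)))
  f <- array(0, c(64, 64, 3))
  f[, 10, 2] <- rnorm(64)
  lifted <- lift_2d_to_3d(f, tm)
  expect_equal(dim(lifted), c(64, 64, 64, 3))
  expect_true(all(lifted[, , -10, ] == 0))   # other z rows untouched
  expect_true(all(lifted[, , , c(1, 3)] == 0))
  expect_error(lift_2d_to_3d(array(0, c(32, 64, 3)), tm), "detector size")
})

test_that("lifting a row of ones marks exactly the in-detector pixels", {
  tm <- build_system_matrix(small_geom(32L, "LAT"))
  ones <- matrix(1, 32, 1)
  lifted <- lift_2d_to_3d(array(ones, c(32, 1, 1)), tm)
  rs <- Matrix::rowSums(tm$weights)
  expect_equal(as.numeric(lifted[, , 1, 1]), as.numeric(rs))
  expect_true(all(abs(rs) < 1e-12 | abs(rs - 1) < 1e-12))
})

test_that("stored operators satisfy the adjoint inner-product identity", {
  set.seed(42)
  for (view in c("AP", "LAT")) {
    g <- small_geom(32L, view)
    A <- build_forward_projector(g)
    v <- matrix(rnorm(32^2 * 4), 32^2, 4)
    p <- matrix(rnorm(32 * 4), 32, 4)
    lhs <- sum(as.matrix(A$weights %*% v) * p)
    rhs <- sum(v * adjoint_apply(p, A))
    expect_lt(abs(lhs - rhs) / abs(lhs), 1e-10)
    tm <- build_system_matrix(g)
    x <- matrix(rnorm(32^2 * 4), 32^2, 4)
    q <- matrix(rnorm(32 * 4), 32, 4)
    lhs <- sum(as.matrix(tm$weights %*% q) * x)
    rhs <- sum(q * adjoint_apply(x, tm))
    expect_lt(abs(lhs - rhs) / abs(lhs), 1e-10)
  }
  expect_error(adjoint_apply(matrix(0, 5, 2), build_forward_projector(small_geom(32L))),
               "projection rows")
})

test_that("adjoint of the sparse operator equals the dense-matrix adjoint", {
  g <- fan_beam_geometry(n_detector = 16L, n_image = 16L,
                         voxel_spacing_mm = 2.5)
  tm <- build_system_matrix(g)
  dense <- brute_force_system_matrix(g)
  set.seed(3)
  x <- matrix(rnorm(16 * 16 * 2), 256, 2)
  expect_equal(adjoint_apply(x, tm), t(dense) %*% x, ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("backprojecting one detector channel lights up only that ray", {
  g <- small_geom(32L, "AP")
  tm <- build_system_matrix(g)
  k <- 20L
  img <- matrix(lift_2d_to_3d(array(as.numeric(seq_len(32) == k),
                                    c(32, 1, 1)), tm)[, , 1, 1], 32, 32)
  hit <- which(img > 1e-12, arr.ind = TRUE)
  # every lit pixel must project onto detector coordinate within 1 channel of k
  px <- (hit[, 1] - 16.5) * g$voxel_spacing_mm
  py <- (hit[, 2] - 16.5) * g$voxel_spacing_mm
  cc <- g$sdd_mm * px / (g$sid_mm - py) / g$detector_spacing_mm + 16.5
  expect_true(all(abs(cc - k) < 1))
})

test_that("rotating the phantom by 90 degrees swaps the AP and LAT views", {
  ph <- small_phantoms(1)[[1]]
  v <- norm_vol(ph)
  p_lat <- forward_project(v, small_geom(32L, "LAT"))
  vr <- aperm(v, c(2, 1, 3))[32:1, , ]   # rotation about the vertical axis
  p_ap <- forward_project(vr, small_geom(32L, "AP"))
  expect_lt(mean(abs(p_ap - p_lat)), 0.01 * max(p_lat))
})

test_that("operator construction is deterministic", {
  g <- small_geom(32L)
  expect_identical(build_system_matrix(g)$weights, build_system_matrix(g)$weights)
  expect_identical(build_forward_projector(g)$weights,
                   build_forward_projector(g)$weights)
})
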