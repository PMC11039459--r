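# Shared fixtures. Everything is generated in code; heavier artefacts are
# memoised in .fixture_cache so several test files (and several blocks within
# the acceptance suite) can reuse one training run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

small_geom <- function(n = 32L, view = "AP", spacing = 2.5)
  fan_beam_geometry(n_detector = as.integer(n), n_image = as.integer(n),
                    voxel_spacing_mm = spacing, view = view)

small_phantoms <- function(n = 6L, grid = 32L, seed = 11L)
  memo(sprintf("ph_%d_%d_%d", n, grid, seed), {
    spec <- phantom_spec(grid_size = as.integer(grid), seed = as.integer(seed))
    lapply(seq_len(n), function(i) sample_phantom(spec, i))
  })

# Independent brute-force construction of the pixel-driven backprojection
# matrix: explicit per-pixel trigonometry, dense.
brute_force_system_matrix <- function(geom) {
  n <- geom$n_image
  Tb <- matrix(0, n * n, geom$n_detector)
  ang <- if (geom$view == "AP") list(a = c(0, 1), e = c(1, 0))
         else list(a = c(1, 0), e = c(0, -1))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    px <- (i - (n + 1) / 2) * geom$voxel_spacing_mm
    py <- (j - (n + 1) / 2) * geom$voxel_spacing_mm
    t <- geom$sdd_mm / (geom$sid_mm - (px * ang$a[1] + py * ang$a[2]))
    u <- t * (px * ang$e[1] + py * ang$e[2])
    cc <- u / geom$detector_spacing_mm + (geom$n_detector + 1) / 2
    if (cc >= 1 && cc <= geom$n_detector) {
      k0 <- floor(cc); fr <- cc - k0
      Tb[i + (j - 1) * n, k0] <- 1 - fr
      if (fr > 0) Tb[i + (j - 1) * n, k0 + 1] <- fr
    }
  }
  Tb
}

norm_vol <- function(ph, hw = c(-1024, 3071)) {
  v <- normalize_hu(ph$hu_volume, hw[1], hw[2])
  attributes(v) <- list(dim = dim(ph$hu_volume))
  v
}
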