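## Networks: the dual-encoder generator with geometry-based 2D->3D feature
## lifting, the least-squares patch discriminator, and the 3D U-Net organ
## segmenter. Parameters live in flat named lists of conv blocks (w, b);
## every forward has a matching hand-chained backward so the whole model is
## differentiable end to end on the compiled conv engine.

## conv + instance norm + (leaky) relu, the standard block everywhere;
## norm and activation run in the fused one-pass kernels.
cbr_fw <- function(x, p, stride = 1L, slope = 0) {
  y1 <- conv_fw(x, p$w, p$b, stride)
  d <- dim(y1)
  nc <- d[length(d)]
  f <- in_act_fw_cpp(y1, as.integer(prod(d) / nc), as.integer(nc), 1e-5, slope)
  y <- f$y
  dim(y) <- d
  list(y = y, x = x, xh = f$xh, sd = f$sd, d = d, slope = slope)
}

cbr_bw <- function(gy, p, cache, stride = 1L) {
  nc <- cache$d[length(cache$d)]
  g <- in_act_bw_cpp(cache$xh, cache$sd, gy,
                     as.integer(prod(cache$d) / nc), as.integer(nc),
                     cache$slope)
  dim(g) <- cache$d
  conv_bw(cache$x, p$w, g, stride)
}

level_channels <- function(base, n_levels, cap_mult = 8L) {
  pmin(base * 2^(seq_len(n_levels) - 1L), base * cap_mult)
}

## ---- generator ------------------------------------------------------------

#' Generator configuration
#'
#' @param grid_size cubic output size; must be divisible by
#'   `2^(n_levels - 1)`.
#' @param n_levels number of U-Net resolution levels in the 2-d pathways and
#'   the 3-d decoder.
#' @param base_channels channels at full resolution (doubled per level, capped
#'   at 8x).
#' @param geometry full-resolution [fan_beam_geometry()] (view ignored; AP and
#'   LAT variants and per-level rescalings are derived internally).
#' @return Object of class `gen_config`.
#' @export
gen_config <- function(grid_size = 128L, n_levels = 4L, base_channels = 64L,
                       geometry = fan_beam_geometry(n_image = grid_size,
                                                    n_detector = grid_size)) {
  if (grid_size %% 2^(n_levels - 1L) != 0L)
    stop("gen_config: grid_size must be divisible by 2^(n_levels-1)")
  if (geometry$n_image != grid_size || geometry$n_detector != grid_size)
    stop("gen_config: geometry n_image and n_detector must equal grid_size")
  structure(list(grid_size = as.integer(grid_size),
                 n_levels = as.integer(n_levels),
                 base_channels = as.integer(base_channels),
                 channels = level_channels(base_channels, n_levels),
                 geometry = geometry), class = "gen_config")
}

## Geometry at resolution level l (1-based; level 1 = full resolution), for a
## given view. Downsampling by 2 halves grid and detector and doubles pitches,
## keeping the physical field of view and the scanner distances unchanged.
level_geometry <- function(cfg, l, view) {
  g <- cfg$geometry
  f <- 2^(l - 1L)
  fan_beam_geometry(sdd_mm = g$sdd_mm, sid_mm = g$sid_mm,
                    n_detector = g$n_detector %/% f,
                    detector_spacing_mm = g$detector_spacing_mm * f,
                    n_image = g$n_image %/% f,
                    voxel_spacing_mm = g$voxel_spacing_mm * f,
                    view = view)
}

#' Initialise generator parameters (He init, driven by the session RNG)
#' @param cfg a [gen_config()].
#' @return Flat named list of conv blocks.
#' @export
init_generator <- function(cfg) {
  L <- cfg$n_levels; ch <- cfg$channels
  p <- list()
  for (v in c("ap", "lat")) {
    p[[paste0(v, ".enc0")]] <- init_conv(3L, 1L, ch[1], ndim = 2L)
    for (l in seq_len(L - 1L)) {
      p[[paste0(v, ".down", l)]] <- init_conv(3L, ch[l], ch[l + 1], ndim = 2L)
      p[[paste0(v, ".dec", l)]] <- init_conv(3L, ch[l + 1], ch[l], ndim = 2L)
    }
  }
  p[["g3.bott"]] <- init_conv(3L, ch[L], ch[L], ndim = 3L)
  for (l in seq_len(L - 1L))
    p[[paste0("g3.up", l)]] <- init_conv(3L, ch[l + 1], ch[l], ndim = 3L)
  p[["g3.out"]] <- init_conv(3L, ch[1], 1L, ndim = 3L)
  ## small output-layer init keeps the sigmoid away from saturation at the
  ## start of training regardless of seed
  p[["g3.out"]]$w <- p[["g3.out"]]$w * 0.1
  p
}

## 2-d U-Net pathway for one view; returns decoder features per level.
pathway_fw <- function(x, params, v, L) {
  e <- vector("list", L); ec <- vector("list", L)
  ec[[1]] <- cbr_fw(x, params[[paste0(v, ".enc0")]])
  e[[1]] <- ec[[1]]$y
  for (l in seq_len(L - 1L)) {
    ec[[l + 1]] <- cbr_fw(e[[l]], params[[paste0(v, ".down", l)]], stride = 2L)
    e[[l + 1]] <- ec[[l + 1]]$y
  }
  d <- vector("list", L); dc <- vector("list", L); du <- vector("list", L)
  d[[L]] <- e[[L]]
  for (l in rev(seq_len(L - 1L))) {
    du[[l]] <- upsample2_fw(d[[l + 1]])
    dc[[l]] <- cbr_fw(du[[l]], params[[paste0(v, ".dec", l)]])
    d[[l]] <- dc[[l]]$y + e[[l]]
  }
  list(d = d, ec = ec, dc = dc)
}

## Backward through one pathway given grads on decoder outputs d[[l]].
pathway_bw <- function(gd, fwd, params, v, L, grads) {
  ge <- vector("list", L)
  gcur <- gd[[1]]
  for (l in seq_len(L - 1L)) {
    ge[[l]] <- gcur
    g <- cbr_bw(gcur, params[[paste0(v, ".dec", l)]], fwd$dc[[l]])
    grads[[paste0(v, ".dec", l)]] <- list(w = g$gw, b = g$gb)
    gcur <- upsample2_bw(g$gx) + gd[[l + 1]]
  }
  ge[[L]] <- gcur
  gnext <- ge[[L]]
  for (l in rev(seq_len(L - 1L))) {
    g <- cbr_bw(gnext, params[[paste0(v, ".down", l)]], fwd$ec[[l + 1]], stride = 2L)
    grads[[paste0(v, ".down", l)]] <- list(w = g$gw, b = g$gb)
    gnext <- g$gx + ge[[l]]
  }
  g <- cbr_bw(gnext, params[[paste0(v, ".enc0")]], fwd$ec[[1]])
  grads[[paste0(v, ".enc0")]] <- list(w = g$gw, b = g$gb)
  grads
}

#' Generator forward pass: two topograms in, one volume out
#'
#' Each projection passes through its own 2-d U-Net; at every decoder level the
#' 2-d feature maps are lifted to 3-d through the level-appropriate
#' view-specific system matrix (the LAT matrix backprojects along x, so both
#' lifted stacks land in the common frame), the two stacks are fused by
#' elementwise addition, and a single 3-d decoder emits the volume through a
#' sigmoid.
#'
#' @param proj_ap,proj_lat `(n_detector, n_z)` projection matrices in `[0,1]`.
#' @param params from [init_generator()] (or a trained checkpoint).
#' @param cfg the [gen_config()].
#' @param want_cache keep intermediate activations for a backward pass.
#' @return list with `y` (the `grid_size^3` volume in `[0,1]`) and, if
#'   requested, `cache`.
#' @export
generator_forward <- function(proj_ap, proj_lat, params, cfg, want_cache = FALSE) {
  n <- cfg$grid_size; L <- cfg$n_levels
  if (!all(dim(proj_ap) == c(n, n)) || !all(dim(proj_lat) == c(n, n)))
    stop("generator_forward: projections must be n_detector x n_z = grid_size^2")
  xa <- array(proj_ap, dim = c(n, n, 1L))
  xl <- array(proj_lat, dim = c(n, n, 1L))
  fa <- pathway_fw(xa, params, "ap", L)
  fl <- pathway_fw(xl, params, "lat", L)

  tm <- lapply(seq_len(L), function(l) list(
    ap = cached_system_matrix(level_geometry(cfg, l, "AP")),
    lat = cached_system_matrix(level_geometry(cfg, l, "LAT"))))
  f3 <- lapply(seq_len(L), function(l)
    lift_2d_to_3d(fa$d[[l]], tm[[l]]$ap) + lift_2d_to_3d(fl$d[[l]], tm[[l]]$lat))

  gc3 <- vector("list", L)
  gc3[[L]] <- cbr_fw(f3[[L]], params[["g3.bott"]])
  g <- gc3[[L]]$y
  gu <- vector("list", L)
  for (l in rev(seq_len(L - 1L))) {
    gu[[l]] <- upsample2_fw(g)
    gc3[[l]] <- cbr_fw(gu[[l]], params[[paste0("g3.up", l)]])
    g <- gc3[[l]]$y + f3[[l]]
  }
  yout <- conv_fw(g, params[["g3.out"]]$w, params[["g3.out"]]$b)
  sg <- sigmoid_fw(yout)
  y <- array(sg$y, dim = c(n, n, n))
  if (!want_cache) return(list(y = y))
  list(y = y, cache = list(fa = fa, fl = fl, tm = tm, f3 = f3, gc3 = gc3,
                           gin = g, sg = sg))
}

#' Generator backward pass
#' @param gy gradient of a scalar loss with respect to the output volume.
#' @param params,cfg,cache as produced by [generator_forward()] with
#'   `want_cache = TRUE`.
#' @return gradient list matching `params`.
#' @export
generator_backward <- function(gy, params, cfg, cache) {
  n <- cfg$grid_size; L <- cfg$n_levels
  grads <- list()
  g <- sigmoid_bw(cache$sg, array(gy, dim = c(n, n, n, 1L)))
  gb <- conv_bw(cache$gin, params[["g3.out"]]$w, g)
  grads[["g3.out"]] <- list(w = gb$gw, b = gb$gb)
  gcur <- gb$gx
  gf3 <- vector("list", L)
  for (l in seq_len(L - 1L)) {
    gf3[[l]] <- gcur
    gb <- cbr_bw(gcur, params[[paste0("g3.up", l)]], cache$gc3[[l]])
    grads[[paste0("g3.up", l)]] <- list(w = gb$gw, b = gb$gb)
    gcur <- upsample2_bw(gb$gx)
  }
  gb <- cbr_bw(gcur, params[["g3.bott"]], cache$gc3[[L]])
  grads[["g3.bott"]] <- list(w = gb$gw, b = gb$gb)
  gf3[[L]] <- gb$gx

  gd_ap <- lapply(seq_len(L), function(l) lift_2d_to_3d_bw(gf3[[l]], cache$tm[[l]]$ap))
  gd_lat <- lapply(seq_len(L), function(l) lift_2d_to_3d_bw(gf3[[l]], cache$tm[[l]]$lat))
  grads <- pathway_bw(gd_ap, cache$fa, params, "ap", L, grads)
  grads <- pathway_bw(gd_lat, cache$fl, params, "lat", L, grads)
  grads[names(params)]
}

## ---- discriminator --------------------------------------------------------

#' Discriminator configuration (3-d patch classifier, three stride-2 blocks)
#' @param grid_size input volume size (divisible by 8).
#' @param base_channels width of the first block.
#' @return Object of class `disc_config`.
#' @export
disc_config <- function(grid_size = 128L, base_channels = 64L) {
  if (grid_size %% 8L != 0L) stop("disc_config: grid_size must be divisible by 8")
  structure(list(grid_size = as.integer(grid_size),
                 base_channels = as.integer(base_channels)),
            class = "disc_config")
}

#' @rdname disc_config
#' @param cfg a `disc_config`.
#' @export
init_discriminator <- function(cfg) {
  c0 <- cfg$base_channels
  list(b0 = init_conv(3L, 1L, c0, ndim = 3L),
       b1 = init_conv(3L, c0, 2L * c0, ndim = 3L),
       b2 = init_conv(3L, 2L * c0, 4L * c0, ndim = 3L),
       head = init_conv(3L, 4L * c0, 1L, ndim = 3L))
}

#' Discriminator forward: volume to patch score map
#'
#' @param volume `(n, n, n)` array in `[0,1]`.
#' @param params,cfg discriminator parameters and config.
#' @param want_cache keep activations for the backward pass.
#' @return list with `score` (`(n/8)^3` array, one score per receptive-field
#'   patch, no global pooling) and optional `cache`.
#' @export
discriminator_forward <- function(volume, params, cfg, want_cache = FALSE) {
  n <- cfg$grid_size
  if (!all(dim(volume)[1:3] == n)) stop("discriminator_forward: wrong input size")
  x <- array(volume, dim = c(n, n, n, 1L))
  c1 <- conv_fw(x, params$b0$w, params$b0$b, stride = 2L)
  a1 <- lrelu_fw(c1, 0.2)
  b1 <- cbr_fw(a1$y, params$b1, stride = 2L, slope = 0.2)
  b2 <- cbr_fw(b1$y, params$b2, stride = 2L, slope = 0.2)
  sc <- conv_fw(b2$y, params$head$w, params$head$b)
  score <- array(sc, dim = dim(sc)[1:3])
  if (!want_cache) return(list(score = score))
  list(score = score, cache = list(x = x, a1 = a1, b1 = b1, b2 = b2))
}

#' Discriminator backward
#' @param gscore gradient on the score map.
#' @param params,cfg,cache from [discriminator_forward()].
#' @return list `grads` (parameter gradients) and `gx` (gradient on the input
#'   volume, needed when the generator is trained through the discriminator).
#' @export
discriminator_backward <- function(gscore, params, cfg, cache) {
  g <- array(gscore, dim = c(dim(gscore), 1L))
  gh <- conv_bw(cache$b2$y, params$head$w, g)
  g2 <- cbr_bw(gh$gx, params$b2, cache$b2, stride = 2L)
  g1 <- cbr_bw(g2$gx, params$b1, cache$b1, stride = 2L)
  ga <- lrelu_bw(cache$a1, g1$gx)
  g0 <- conv_bw(cache$x, params$b0$w, ga, stride = 2L)
  list(grads = list(b0 = list(w = g0$gw, b = g0$gb),
                    b1 = list(w = g1$gw, b = g1$gb),
                    b2 = list(w = g2$gw, b = g2$gb),
                    head = list(w = gh$gw, b = gh$gb)),
       gx = array(g0$gx, dim = dim(cache$x)[1:3]))
}

## ---- organ segmenter ------------------------------------------------------

#' Segmentation network configuration (3-d U-Net, five downsampling levels)
#'
#' @param grid_size input size (divisible by 32).
#' @param base_channels width at full resolution.
#' @param n_classes number of output classes (background, lung, liver, bone).
#' @return Object of class `segnet_config`.
#' @export
segnet_config <- function(grid_size = 128L, base_channels = 4L,
                          n_classes = 4L) {
  n_levels <- 6L  # five downsamplings
  if (grid_size %% 2^(n_levels - 1L) != 0L)
    stop("segnet_config: grid_size must be divisible by 32")
  structure(list(grid_size = as.integer(grid_size), n_levels = n_levels,
                 base_channels = as.integer(base_channels),
                 channels = level_channels(base_channels, n_levels),
                 n_classes = as.integer(n_classes)), class = "segnet_config")
}

#' @rdname segnet_config
#' @param cfg a `segnet_config`.
#' @export
init_segnet <- function(cfg) {
  L <- cfg$n_levels; ch <- cfg$channels
  ## two convs at full resolution (vanilla U-Net style): organ boundaries are
  ## decided here and a single 3^3 kernel underfits them
  p <- list(enc0 = init_conv(3L, 1L, ch[1], ndim = 3L),
            enc0b = init_conv(3L, ch[1], ch[1], ndim = 3L))
  for (l in seq_len(L - 1L)) {
    p[[paste0("down", l)]] <- init_conv(3L, ch[l], ch[l + 1], ndim = 3L)
    p[[paste0("dec", l)]] <- init_conv(3L, ch[l + 1], ch[l], ndim = 3L)
  }
  p$out <- init_conv(1L, ch[1], cfg$n_classes, ndim = 3L)
  p
}

#' Organ segmenter forward: volume to per-class probabilities
#'
#' Vanilla 3-d U-Net with five downsampling levels and a softmax head; the
#' four channels sum to one at every voxel. When used inside GAN training the
#' parameters are frozen (gradients flow to the input only).
#'
#' @param volume `(n, n, n)` array (normalised HU).
#' @param params,cfg segmenter parameters and config.
#' @param want_cache keep activations for the backward pass.
#' @return list with `prob` (`(n, n, n, n_classes)`) and optional `cache`.
#' @export
segnet_forward <- function(volume, params, cfg, want_cache = FALSE) {
  n <- cfg$grid_size; L <- cfg$n_levels
  if (!all(dim(volume)[1:3] == n)) stop("segnet_forward: wrong input size")
  ## per-volume input standardisation (z-score): organ contrasts are a small
  ## fraction of the [0,1] window, and standardising the input is the usual
  ## way to bring them onto a scale the network can amplify; it is a smooth
  ## map, so gradients flow through it when the segmenter serves as a loss
  std <- in_act_fw_cpp(array(volume, dim = c(n, n, n, 1L)),
                       as.integer(n^3), 1L, 1e-5, 1.0)
  x <- std$y
  dim(x) <- c(n, n, n, 1L)
  fwd <- pathway_fw_named(x, params, L)
  logits <- conv_fw(fwd$d[[1]], params$out$w, params$out$b)
  sm <- softmax_fw(logits)
  if (!want_cache) return(list(prob = sm$y))
  list(prob = sm$y, cache = list(fwd = fwd, sm = sm, std = std))
}

## Shared U-Net body (encoder + additive-skip decoder) used by the segmenter;
## block names enc0/downL/decL as in init_segnet.
pathway_fw_named <- function(x, params, L) {
  e <- vector("list", L); ec <- vector("list", L)
  ec0 <- cbr_fw(x, params$enc0, slope = 0.2)
  ec[[1]] <- cbr_fw(ec0$y, params$enc0b, slope = 0.2)
  e[[1]] <- ec[[1]]$y
  for (l in seq_len(L - 1L)) {
    ec[[l + 1]] <- cbr_fw(e[[l]], params[[paste0("down", l)]], stride = 2L,
                          slope = 0.2)
    e[[l + 1]] <- ec[[l + 1]]$y
  }
  d <- vector("list", L); dc <- vector("list", L)
  d[[L]] <- e[[L]]
  for (l in rev(seq_len(L - 1L))) {
    du <- upsample2_fw(d[[l + 1]])
    dc[[l]] <- cbr_fw(du, params[[paste0("dec", l)]], slope = 0.2)
    d[[l]] <- dc[[l]]$y + e[[l]]
  }
  list(d = d, e = e, ec = ec, dc = dc, ec0 = ec0)
}

#' Segmenter backward
#' @param gprob gradient on the class-probability output.
#' @param params,cfg,cache from [segnet_forward()].
#' @return list `grads` and `gx` (gradient on the input volume).
#' @export
segnet_backward <- function(gprob, params, cfg, cache) {
  L <- cfg$n_levels
  grads <- list()
  g <- softmax_bw(cache$sm, gprob)
  go <- conv_bw(cache$fwd$d[[1]], params$out$w, g)
  grads$out <- list(w = go$gw, b = go$gb)
  ge <- vector("list", L)
  gcur <- go$gx
  for (l in seq_len(L - 1L)) {
    ge[[l]] <- gcur
    gb <- cbr_bw(gcur, params[[paste0("dec", l)]], cache$fwd$dc[[l]])
    grads[[paste0("dec", l)]] <- list(w = gb$gw, b = gb$gb)
    gcur <- upsample2_bw(gb$gx)
  }
  ge[[L]] <- gcur
  gnext <- ge[[L]]
  for (l in rev(seq_len(L - 1L))) {
    gb <- cbr_bw(gnext, params[[paste0("down", l)]], cache$fwd$ec[[l + 1]],
                 stride = 2L)
    grads[[paste0("down", l)]] <- list(w = gb$gw, b = gb$gb)
    gnext <- gb$gx + ge[[l]]
  }
  gb2 <- cbr_bw(gnext, params$enc0b, cache$fwd$ec[[1]])
  grads$enc0b <- list(w = gb2$gw, b = gb2$gb)
  gb <- cbr_bw(gb2$gx, params$enc0, cache$fwd$ec0)
  grads$enc0 <- list(w = gb$gw, b = gb$gb)
  n3 <- prod(dim(gb$gx)[1:3])
  gx <- in_act_bw_cpp(cache$std$xh, cache$std$sd, gb$gx,
                      as.integer(n3), 1L, 1.0)
  list(grads = grads[names(params)], gx = array(gx, dim = dim(gb$gx)[1:3]))
}
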