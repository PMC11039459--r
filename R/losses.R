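## Training objectives: least-squares adversarial terms, voxel reconstruction,
## projection consistency, frozen-segmenter Dice, slice-aggregated 3D
## perceptual loss, and their weighted aggregation. Losses return a plain
## scalar by default; `want_grad = TRUE` additionally returns the gradient
## with respect to the predicted volume (the only trainable input).

#' Loss weights for the composite generator objective
#'
#' Defaults are the study settings: adversarial 0.1, reconstruction 10,
#' projection consistency 10, segmentation Dice 2.0, perceptual 0.5. Setting
#' `lambda_s = lambda_p = 0` recovers the plain image-translation baseline.
#'
#' @param lambda_gen,lambda_r,lambda_proj,lambda_s,lambda_p non-negative
#'   scalars.
#' @return Object of class `loss_weights`.
#' @export
loss_weights <- function(lambda_gen = 0.1, lambda_r = 10, lambda_proj = 10,
                         lambda_s = 2.0, lambda_p = 0.5) {
  w <- c(lambda_gen = lambda_gen, lambda_r = lambda_r,
         lambda_proj = lambda_proj, lambda_s = lambda_s, lambda_p = lambda_p)
  if (any(w < 0)) stop("loss_weights: weights must be non-negative")
  structure(as.list(w), class = "loss_weights")
}

#' Least-squares discriminator loss
#'
#' `0.5 * (mean((D(real) - 1)^2) + mean(D(fake)^2))`, means taken over all
#' patch scores.
#'
#' @param d_real,d_fake discriminator score maps.
#' @return Scalar loss.
#' @export
loss_discriminator <- function(d_real, d_fake) {
  if (!all(is.finite(d_real)) || !all(is.finite(d_fake)))
    stop("loss_discriminator: non-finite scores")
  0.5 * (mean((d_real - 1)^2) + mean(d_fake^2))
}

#' Least-squares adversarial generator loss: `mean((D(fake) - 1)^2)`
#' @param d_fake discriminator score map on generated volumes.
#' @return Scalar loss.
#' @export
loss_generator_adv <- function(d_fake) {
  if (!all(is.finite(d_fake))) stop("loss_generator_adv: non-finite scores")
  mean((d_fake - 1)^2)
}

#' Voxel-wise reconstruction loss (mean squared difference)
#' @param y_pred,y_true volumes of identical shape.
#' @param want_grad also return the gradient with respect to `y_pred`.
#' @return Scalar, or `list(value, grad)`.
#' @export
loss_reconstruction <- function(y_pred, y_true, want_grad = FALSE) {
  if (!identical(dim(y_pred), dim(y_true)))
    stop("loss_reconstruction: shape mismatch")
  d <- y_pred - y_true
  v <- mean(d * d)
  if (!want_grad) return(v)
  list(value = v, grad = 2 * d / length(d))
}

#' Projection-consistency loss
#'
#' Half the sum of the mean squared AP and LAT fan-beam projection
#' differences between the predicted and true volumes.
#'
#' @param y_pred,y_true cubic volumes.
#' @param geom_ap,geom_lat AP/LAT [fan_beam_geometry()] objects (or prebuilt
#'   projectors).
#' @param want_grad also return the gradient with respect to `y_pred`.
#' @return Scalar, or `list(value, grad)`.
#' @export
loss_projection <- function(y_pred, y_true, geom_ap, geom_lat,
                            want_grad = FALSE) {
  if (!identical(dim(y_pred), dim(y_true)))
    stop("loss_projection: shape mismatch")
  pa <- if (inherits(geom_ap, "fan_projector")) geom_ap else cached_projector(geom_ap)
  pl <- if (inherits(geom_lat, "fan_projector")) geom_lat else cached_projector(geom_lat)
  ra <- forward_project(y_pred, pa) - forward_project(y_true, pa)
  rl <- forward_project(y_pred, pl) - forward_project(y_true, pl)
  v <- 0.5 * (mean(ra * ra) + mean(rl * rl))
  if (!want_grad) return(v)
  ga <- adjoint_apply(2 * ra / length(ra), pa)
  gl <- adjoint_apply(2 * rl / length(rl), pl)
  list(value = v, grad = array(0.5 * (ga + gl), dim = dim(y_pred)))
}

## Multi-class soft Dice against probability (or one-hot) reference masks,
## in the squared-denominator form 1 - 2<p,r>/(|p|^2 + |r|^2 + eps): it
## coincides with the plain-sum Dice on hard masks and is exactly zero for
## identical soft masks. Returns the mean over the requested classes; grad is
## with respect to `prob`.
soft_dice <- function(prob, ref, classes, eps = 1e-6, want_grad = FALSE) {
  d <- dim(prob)
  nch <- d[length(d)]
  pm <- matrix(prob, ncol = nch)
  rm <- matrix(ref, ncol = nch)
  vals <- numeric(length(classes))
  gm <- if (want_grad) matrix(0, nrow = nrow(pm), ncol = nch) else NULL
  nc <- length(classes)
  for (i in seq_along(classes)) {
    c <- classes[i]
    inter <- sum(pm[, c] * rm[, c])
    s <- sum(pm[, c]^2) + sum(rm[, c]^2) + eps
    vals[i] <- 1 - 2 * inter / s
    if (want_grad)
      gm[, c] <- (-2 * rm[, c] / s + 4 * inter * pm[, c] / s^2) / nc
  }
  list(value = mean(vals), per_class = vals,
       grad = if (want_grad) array(gm, dim = d) else NULL)
}

#' Segmentation Dice loss through a frozen organ segmenter
#'
#' Both volumes are passed through the frozen segmenter; the soft Dice
#' distance between the two probability maps, averaged over the three
#' foreground classes (lung, liver, bone), is returned. Gradients flow into
#' `y_pred` only; the segmenter parameters are never touched.
#'
#' @param y_pred,y_true volumes matching the segmenter's input size.
#' @param segnet a list with `params` and `cfg` (e.g. a [pretrain_segnet()]
#'   fit).
#' @param eps Dice smoothing constant.
#' @param want_grad also return the gradient with respect to `y_pred`.
#' @return Scalar, or `list(value, grad)`.
#' @export
loss_segmentation <- function(y_pred, y_true, segnet, eps = 1e-6,
                              want_grad = FALSE) {
  cfg <- segnet$cfg
  if (cfg$n_classes != 4L) stop("loss_segmentation: segmenter must have 4 classes")
  ym <- segnet_forward(y_true, segnet$params, cfg)$prob
  fw <- segnet_forward(y_pred, segnet$params, cfg, want_cache = want_grad)
  sd <- soft_dice(fw$prob, ym, classes = 2:4, eps = eps, want_grad = want_grad)
  if (!want_grad) return(sd$value)
  gx <- segnet_backward(sd$grad, segnet$params, cfg, fw$cache)$gx
  list(value = sd$value, grad = gx)
}

## ---- fixed multi-scale feature extractor ---------------------------------

#' Fixed 2-d convolutional feature pyramid for the perceptual loss
#'
#' Four conv+ReLU levels (strides 1, 2, 2, 2) over 3-channel slices. Weights
#' are drawn once from a seeded He initialisation and are immutable; random
#' multi-scale projections preserve the metric properties the perceptual term
#' relies on. Weights exported from a natural-image-pretrained backbone can be
#' plugged in through `params`.
#'
#' @param channels widths of the four levels.
#' @param seed seed for the weight draw (ignored when `params` given).
#' @param params optional externally supplied parameter list (four conv
#'   blocks, 3 input channels).
#' @return Object of class `feature_extractor`.
#' @export
feature_extractor <- function(channels = c(8L, 16L, 32L, 32L), seed = 1234L,
                              params = NULL) {
  if (is.null(params)) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(seed)
    cin <- c(3L, channels[-4L])
    params <- lapply(1:4, function(l) init_conv(3L, cin[l], channels[l], ndim = 2L))
  }
  structure(list(params = params, n_levels = 4L), class = "feature_extractor")
}

extractor_fw <- function(slice3, ex, want_cache = FALSE) {
  f <- vector("list", 4L); cc <- vector("list", 4L); aa <- vector("list", 4L)
  x <- slice3
  for (l in 1:4) {
    s <- if (l == 1L) 1L else 2L
    cc[[l]] <- x
    y <- conv_fw(x, ex$params[[l]]$w, ex$params[[l]]$b, stride = s)
    aa[[l]] <- lrelu_fw(y, 0)
    f[[l]] <- aa[[l]]$y
    x <- f[[l]]
  }
  if (!want_cache) return(list(f = f))
  list(f = f, cache = list(cc = cc, aa = aa))
}

## Backward: gf[[l]] are gradients on the level features; returns grad on the
## 3-channel input slice. Extractor weights receive nothing (frozen).
extractor_bw <- function(gf, ex, cache) {
  g <- NULL
  for (l in 4:1) {
    s <- if (l == 1L) 1L else 2L
    gtot <- if (is.null(g)) gf[[l]] else gf[[l]] + g
    ga <- lrelu_bw(cache$aa[[l]], gtot)
    g <- conv_bw(cache$cc[[l]], ex$params[[l]]$w, ga, stride = s)$gx
  }
  g
}

#' Slice-aggregated 3D perceptual loss
#'
#' Both volumes are sliced along the vertical (z) axis; each slice is
#' replicated to three channels and passed through the fixed feature
#' extractor. The squared feature difference (mean per level, summed over the
#' four levels) is averaged over slices.
#'
#' @param y_pred,y_true cubic volumes of identical shape.
#' @param extractor a [feature_extractor()].
#' @param kind `"l2"` (squared feature distance, the default) or `"l1"`
#'   (absolute feature distance), selectable because the two readings differ
#'   only in this norm.
#' @param want_grad also return the gradient with respect to `y_pred`.
#' @return Scalar, or `list(value, grad)`.
#' @export
loss_perceptual <- function(y_pred, y_true, extractor, kind = c("l2", "l1"),
                            want_grad = FALSE) {
  kind <- match.arg(kind)
  if (!identical(dim(y_pred), dim(y_true)))
    stop("loss_perceptual: shape mismatch")
  d3 <- dim(y_pred)
  ## the extractor's 2-d kernels leave z untouched, so the whole slice stack
  ## runs through it at once with z acting as a batch axis; the per-level
  ## mean over (x, y, z, channels) equals the average of per-slice means
  xp <- array(as.numeric(y_pred), dim = c(d3, 3L))
  xt <- array(as.numeric(y_true), dim = c(d3, 3L))
  fp <- extractor_fw(xp, extractor, want_cache = want_grad)
  ft <- extractor_fw(xt, extractor)
  total <- 0
  gf <- vector("list", 4L)
  for (l in 1:4) {
    d <- fp$f[[l]] - ft$f[[l]]
    if (kind == "l2") {
      total <- total + mean(d * d)
      if (want_grad) gf[[l]] <- 2 * d / length(d)
    } else {
      total <- total + mean(abs(d))
      if (want_grad) gf[[l]] <- sign(d) / length(d)
    }
  }
  if (!want_grad) return(total)
  gs <- extractor_bw(gf, extractor, fp$cache)
  list(value = total, grad = gs[, , , 1] + gs[, , , 2] + gs[, , , 3])
}

#' Aggregate the composite generator objective
#'
#' `lambda_gen*L_gen + lambda_r*L_r + lambda_proj*L_proj + lambda_s*L_s +
#' lambda_p*L_p`. With `lambda_s = lambda_p = 0` this is the plain baseline
#' objective.
#'
#' @param components named list or vector with elements `gen`, `r`, `proj`,
#'   `s`, `p` (missing anatomy terms are treated as 0).
#' @param w a [loss_weights()].
#' @return Scalar total loss.
#' @export
total_generator_loss <- function(components, w = loss_weights()) {
  if (any(unlist(w) < 0)) stop("total_generator_loss: negative weights")
  cm <- as.list(components)
  g <- function(k) if (is.null(cm[[k]])) 0 else cm[[k]]
  if (!all(vapply(cm, is.finite, logical(1))))
    stop("total_generator_loss: non-finite loss component")
  w$lambda_gen * g("gen") + w$lambda_r * g("r") + w$lambda_proj * g("proj") +
    w$lambda_s * g("s") + w$lambda_p * g("p")
}
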