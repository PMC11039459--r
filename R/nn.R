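## Small neural-network engine: convolution wrappers over the compiled
## im2col/GEMM kernels, instance normalisation, activations and Adam.
## Feature tensors are plain R arrays, channels last:
##   2-d maps  (nx, nz, C)      -- internally padded to (nx, nz, 1, C)
##   3-d maps  (nx, ny, nz, C)
## Convolution weights are arrays (kx, ky, kz, c_in, c_out); 2-d layers use
## kz = 1. Padding is always "same" for odd kernels ((k-1)/2 per axis).

## The compiled kernels take the tensor dims as a separate argument, so a
## 2-d map is presented as (nx, nz, 1, C) without copying the array.
nn_dim4 <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) c(d[1L], d[2L], 1L, d[3L]) else d
}

conv_pad <- function(wdim) as.integer((wdim[1:3] - 1L) %/% 2L)

#' Convolution forward pass (2-d or 3-d, "same" padding)
#' @param x input array, channels last
#' @param w weight array (kx, ky, kz, c_in, c_out)
#' @param b bias vector, length c_out
#' @param stride integer stride applied to the axes the kernel spans
#' @keywords internal
conv_fw <- function(x, w, b, stride = 1L) {
  was2d <- length(dim(x)) == 3L
  wd <- dim(w)
  sd3 <- as.integer(c(stride, stride, if (wd[3L] > 1L) stride else 1L))
  y <- convnd_fw_cpp(x, as.integer(nn_dim4(x)), w, wd, b, sd3, conv_pad(wd))
  if (was2d) dim(y) <- dim(y)[c(1L, 2L, 4L)]
  y
}

conv_bw <- function(x, w, gy, stride = 1L) {
  was2d <- length(dim(x)) == 3L
  wd <- dim(w)
  sd3 <- as.integer(c(stride, stride, if (wd[3L] > 1L) stride else 1L))
  g <- convnd_bw_cpp(x, as.integer(nn_dim4(x)), w, wd, gy, sd3, conv_pad(wd))
  if (was2d) dim(g$gx) <- dim(g$gx)[c(1L, 2L, 4L)]
  g
}

upsample2_fw <- function(x) {
  was2d <- length(dim(x)) == 3L
  f <- c(2L, 2L, if (was2d) 1L else 2L)
  y <- upsample_nn_fw_cpp(x, as.integer(nn_dim4(x)), f)
  if (was2d) dim(y) <- dim(y)[c(1L, 2L, 4L)]
  y
}

upsample2_bw <- function(gy) {
  was2d <- length(dim(gy)) == 3L
  f <- c(2L, 2L, if (was2d) 1L else 2L)
  gx <- upsample_nn_bw_cpp(gy, as.integer(nn_dim4(gy)), f)
  if (was2d) dim(gx) <- dim(gx)[c(1L, 2L, 4L)]
  gx
}

## Instance norm over all spatial positions, per channel, no affine terms.
inorm_fw <- function(x, eps = 1e-5) {
  d <- dim(x)
  nc <- d[length(d)]
  n <- prod(d) / nc
  xm <- matrix(x, nrow = n, ncol = nc)
  mu <- colMeans(xm)
  xc <- xm - rep(mu, each = n)
  sd <- sqrt(colMeans(xc * xc) + eps)
  xh <- xc / rep(sd, each = n)
  y <- array(xh, dim = d)
  list(y = y, xh = xh, sd = sd)
}

inorm_bw <- function(cache, gy) {
  d <- dim(gy)
  nc <- d[length(d)]
  n <- prod(d) / nc
  g <- matrix(gy, nrow = n, ncol = nc)
  xh <- cache$xh
  gm <- colMeans(g)
  gxh <- colMeans(g * xh)
  gx <- (g - rep(gm, each = n) - xh * rep(gxh, each = n)) / rep(cache$sd, each = n)
  array(gx, dim = d)
}

lrelu_fw <- function(x, slope = 0.2) {
  fac <- slope + (1 - slope) * (x > 0)
  list(y = x * fac, fac = fac)
}

lrelu_bw <- function(cache, gy) gy * cache$fac

sigmoid_fw <- function(x) {
  y <- 1 / (1 + exp(-x))
  list(y = y)
}

sigmoid_bw <- function(cache, gy) gy * cache$y * (1 - cache$y)

## Channel-wise softmax for (spatial..., C) arrays.
softmax_fw <- function(x) {
  d <- dim(x)
  nc <- d[length(d)]
  xm <- matrix(x, ncol = nc)
  mx <- xm[, 1L]
  for (c in seq_len(nc)[-1L]) mx <- pmax(mx, xm[, c])
  e <- exp(xm - mx)
  p <- e / rowSums(e)
  list(y = array(p, dim = d), p = p)
}

softmax_bw <- function(cache, gy) {
  d <- dim(gy)
  nc <- d[length(d)]
  g <- matrix(gy, ncol = nc)
  p <- cache$p
  dot <- rowSums(g * p)
  array(p * (g - dot), dim = d)
}

## ---- parameter containers -------------------------------------------------

## He-style initialisation, driven by the session RNG so callers control seeds.
init_conv <- function(k, c_in, c_out, ndim = 3L) {
  kd <- if (ndim == 3L) c(k, k, k) else c(k, k, 1L)
  fan_in <- prod(kd) * c_in
  w <- array(stats::rnorm(prod(kd) * c_in * c_out, sd = sqrt(2 / fan_in)),
             dim = c(kd, c_in, c_out))
  list(w = w, b = numeric(c_out))
}

zero_like_params <- function(params) {
  lapply(params, function(p) lapply(p, function(a) {
    z <- a
    z[] <- 0
    z
  }))
}

#' Adam optimiser state for a list of conv parameter blocks
#' @keywords internal
adam_init <- function(params, lr, beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = zero_like_params(params), v = zero_like_params(params))
}

adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  corr1 <- 1 - b1^opt$t
  corr2 <- 1 - b2^opt$t
  for (i in seq_along(params)) {
    for (j in seq_along(params[[i]])) {
      g <- grads[[i]][[j]]
      opt$m[[i]][[j]] <- b1 * opt$m[[i]][[j]] + (1 - b1) * g
      opt$v[[i]][[j]] <- b2 * opt$v[[i]][[j]] + (1 - b2) * g * g
      mhat <- opt$m[[i]][[j]] / corr1
      vhat <- opt$v[[i]][[j]] / corr2
      params[[i]][[j]] <- params[[i]][[j]] - opt$lr * mhat / (sqrt(vhat) + opt$eps)
    }
  }
  list(opt = opt, params = params)
}

## Accumulate one gradient list into another (for batching).
grads_add <- function(acc, g) {
  if (is.null(acc)) return(g)
  for (i in seq_along(g)) for (j in seq_along(g[[i]]))
    acc[[i]][[j]] <- acc[[i]][[j]] + g[[i]][[j]]
  acc
}

grads_scale <- function(g, s) {
  for (i in seq_along(g)) for (j in seq_along(g[[i]]))
    g[[i]][[j]] <- g[[i]][[j]] * s
  g
}
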