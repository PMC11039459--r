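## Preprocessing: resampling, centre crop/pad, HU windowing to [0,1], and
## topogram simulation. Every step is deterministic and driven by constants
## stored in the run config so the same raw volume always yields the same
## network input.

#' Trilinear resampling to a target voxel pitch
#'
#' The output grid spans the same physical extent as the input (to within one
#' voxel); samples outside the source grid clamp to the border.
#'
#' @param vol 3-d array.
#' @param spacing_mm source voxel pitch (scalar or length 3).
#' @param target_spacing_mm target pitch (scalar or length 3).
#' @return Resampled array with attribute `"spacing_mm"`.
#' @export
resample_volume <- function(vol, spacing_mm, target_spacing_mm) {
  sp <- rep_len(spacing_mm, 3L)
  tp <- rep_len(target_spacing_mm, 3L)
  if (any(sp <= 0) || any(tp <= 0))
    stop("resample_volume: spacings must be positive")
  d <- dim(vol)
  if (all(abs(sp - tp) < 1e-12)) {
    attr(vol, "spacing_mm") <- tp
    return(vol)
  }
  nd <- pmax(1L, as.integer(round(d * sp / tp)))
  ## target voxel centre i -> source fractional index
  src_idx <- function(ax) pmin(pmax(((seq_len(nd[ax]) - 0.5) * tp[ax]) / sp[ax] + 0.5, 1), d[ax])
  gx <- src_idx(1); gy <- src_idx(2); gz <- src_idx(3)
  i0 <- pmin(floor(gx), d[1] - 1L); fx <- gx - i0
  j0 <- pmin(floor(gy), d[2] - 1L); fy <- gy - j0
  k0 <- pmin(floor(gz), d[3] - 1L); fz <- gz - k0
  if (d[1] == 1L) { i0 <- rep(1L, nd[1]); fx <- rep(0, nd[1]) }
  if (d[2] == 1L) { j0 <- rep(1L, nd[2]); fy <- rep(0, nd[2]) }
  if (d[3] == 1L) { k0 <- rep(1L, nd[3]); fz <- rep(0, nd[3]) }
  out <- array(0, dim = nd)
  FX <- array(fx, nd); FY <- array(rep(fy, each = nd[1]), nd)
  FZ <- array(rep(fz, each = nd[1] * nd[2]), nd)
  for (dz in 0:1) for (dyy in 0:1) for (dxx in 0:1) {
    w <- (if (dxx) FX else 1 - FX) * (if (dyy) FY else 1 - FY) *
      (if (dz) FZ else 1 - FZ)
    out <- out + w * vol[i0 + dxx, j0 + dyy, k0 + dz, drop = FALSE]
  }
  attr(out, "spacing_mm") <- tp
  out
}

#' Centre crop or symmetric air-pad to a cubic size
#'
#' Axes larger than `size` are centre-cropped; smaller axes are padded
#' symmetrically with air HU (default -1000), original content centred.
#'
#' @param vol 3-d array in HU.
#' @param size target edge length.
#' @param pad_value fill value for padding.
#' @return `size^3` array.
#' @export
crop_or_pad <- function(vol, size = 128L, pad_value = -1000) {
  d <- dim(vol)
  out <- array(pad_value, dim = rep(as.integer(size), 3L))
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    if (d[ax] >= size) {
      start <- (d[ax] - size) %/% 2L + 1L
      src[[ax]] <- start:(start + size - 1L)
      dst[[ax]] <- seq_len(size)
    } else {
      off <- (size - d[ax]) %/% 2L
      src[[ax]] <- seq_len(d[ax])
      dst[[ax]] <- (off + 1L):(off + d[ax])
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- vol[src[[1]], src[[2]], src[[3]]]
  out
}

#' Window and scale HU values to [0, 1]
#'
#' Clips to `[hu_min, hu_max]` then maps affinely to `[0,1]`. The same fixed
#' window must be applied to every volume of a run (it is recorded in the run
#' config); the default is the standard 12-bit CT range.
#'
#' @param vol array in HU.
#' @param hu_min,hu_max window endpoints (`hu_max > hu_min`).
#' @return Array in `[0,1]` with attribute `"hu_window"`.
#' @export
normalize_hu <- function(vol, hu_min = -1024, hu_max = 3071) {
  if (hu_max <= hu_min) stop("normalize_hu: requires hu_max > hu_min")
  out <- (pmin(pmax(vol, hu_min), hu_max) - hu_min) / (hu_max - hu_min)
  attr(out, "hu_window") <- c(hu_min, hu_max)
  out
}

#' Invert [normalize_hu()]: recover (clipped) HU values exactly
#' @param vol array in `[0,1]`.
#' @param hu_window length-2 window used for normalisation.
#' @return Array in HU.
#' @export
denormalize_hu <- function(vol, hu_window = attr(vol, "hu_window")) {
  if (is.null(hu_window)) stop("denormalize_hu: missing hu_window")
  out <- vol * (hu_window[2] - hu_window[1]) + hu_window[1]
  attributes(out) <- list(dim = dim(vol))
  out
}

#' Simulate the AP/LAT topogram pair for a normalised volume
#'
#' Fan-beam forward projection in both views, each divided by a fixed
#' run-level constant (the maximum projection value over the training corpus)
#' and clipped to `[0,1]`.
#'
#' @param vol cubic volume in `[0,1]` of the geometry's `n_image`.
#' @param geom_ap,geom_lat view geometries (or prebuilt projectors).
#' @param proj_norm the run-level normalisation constant; see
#'   [compute_proj_norm()].
#' @return list with `ap` and `lat` projection matrices in `[0,1]`.
#' @export
simulate_topograms <- function(vol, geom_ap, geom_lat, proj_norm) {
  if (missing(proj_norm) || is.null(proj_norm) || !is.finite(proj_norm))
    stop("simulate_topograms: projection normalisation constant missing; ",
         "supply proj_norm from the run config (see compute_proj_norm)")
  pa <- forward_project(vol, geom_ap)
  pl <- forward_project(vol, geom_lat)
  list(ap = pmin(pmax(pa / proj_norm, 0), 1),
       lat = pmin(pmax(pl / proj_norm, 0), 1))
}

#' Corpus-level projection normalisation constant
#'
#' The maximum raw line-integral value over both views of all supplied
#' volumes. Stored in the run config so training and inference share one
#' scaling.
#'
#' @param volumes list of normalised cubic volumes.
#' @param geom_ap,geom_lat view geometries.
#' @return Positive scalar.
#' @export
compute_proj_norm <- function(volumes, geom_ap, geom_lat) {
  mx <- 0
  for (v in volumes)
    mx <- max(mx, max(forward_project(v, geom_ap)), max(forward_project(v, geom_lat)))
  if (mx <= 0) stop("compute_proj_norm: corpus projections are empty")
  mx
}
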