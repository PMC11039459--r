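## Reconstruction and segmentation evaluation: PSNR, 3-d SSIM, RMSE in HU,
## per-organ Dice, and the dual-reference protocol (phantom labels vs. the
## frozen segmenter's own masks as ground truth).

#' Peak signal-to-noise ratio in dB
#' @param y_pred,y_true volumes of identical shape (normalised).
#' @param data_range dynamic range of the data (1 for `[0,1]` volumes).
#' @return `10*log10(data_range^2 / MSE)`; `Inf` for identical inputs.
#' @export
psnr <- function(y_pred, y_true, data_range = 1.0) {
  if (!identical(dim(y_pred), dim(y_true))) stop("psnr: shape mismatch")
  mse <- mean((y_pred - y_true)^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

#' Root-mean-square error in Hounsfield units
#'
#' Both normalised volumes are mapped back to HU through the normalisation
#' window before the RMS difference is taken.
#'
#' @param y_pred,y_true normalised volumes.
#' @param hu_window the `(hu_min, hu_max)` window used for normalisation.
#' @return RMSE in HU.
#' @export
rmse_hu <- function(y_pred, y_true, hu_window) {
  if (missing(hu_window) || is.null(hu_window))
    stop("rmse_hu: hu_window is required")
  if (!identical(dim(y_pred), dim(y_true))) stop("rmse_hu: shape mismatch")
  d <- denormalize_hu(y_pred, hu_window) - denormalize_hu(y_true, hu_window)
  sqrt(mean(d * d))
}

## Separable Gaussian filtering of a 3-d array (zero-padded "same").
gauss_filter3 <- function(x, sigma = 1.5, width = 11L) {
  half <- (width - 1L) %/% 2L
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k <- k / sum(k)
  x4 <- array(x, dim = c(dim(x), 1L))
  for (ax in 1:3) {
    kd <- c(1L, 1L, 1L); kd[ax] <- width
    w <- array(k, dim = c(kd, 1L, 1L))
    x4 <- convnd_fw_cpp(x4, dim(x4), w, dim(w), 0, c(1L, 1L, 1L),
                        as.integer((kd - 1L) %/% 2L))
  }
  array(x4, dim = dim(x))
}

#' Structural similarity index, computed in 3-d
#'
#' Mean local SSIM over the volume using a separable Gaussian window
#' (sigma 1.5, width 11) and the standard stabilisation constants
#' `C1 = (0.01 R)^2`, `C2 = (0.03 R)^2`; the window half-width is cropped
#' from each border before averaging.
#'
#' @param y_pred,y_true volumes of identical shape.
#' @param data_range dynamic range `R`.
#' @return SSIM scalar in `[-1, 1]`.
#' @export
ssim <- function(y_pred, y_true, data_range = 1.0) {
  if (!identical(dim(y_pred), dim(y_true))) stop("ssim: shape mismatch")
  if (any(dim(y_pred) < 11L)) stop("ssim: volume smaller than the 11-voxel window")
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  mu1 <- gauss_filter3(y_pred); mu2 <- gauss_filter3(y_true)
  s11 <- gauss_filter3(y_pred * y_pred) - mu1 * mu1
  s22 <- gauss_filter3(y_true * y_true) - mu2 * mu2
  s12 <- gauss_filter3(y_pred * y_true) - mu1 * mu2
  map <- ((2 * mu1 * mu2 + c1) * (2 * s12 + c2)) /
    ((mu1^2 + mu2^2 + c1) * (s11 + s22 + c2))
  d <- dim(map)
  idx <- lapply(d, function(n) 6:(n - 5))
  mean(map[idx[[1]], idx[[2]], idx[[3]]])
}

#' Dice similarity coefficient per organ class
#'
#' `2|A n B| / (|A| + |B|)` for each foreground class (1 lung, 2 liver,
#' 3 bone). A class absent from both masks scores 1; absent from exactly one
#' scores 0.
#'
#' @param mask_pred,mask_ref integer label volumes with codes 0..3.
#' @return Named numeric vector `c(lung, liver, bone)`.
#' @export
dsc <- function(mask_pred, mask_ref) {
  codes <- c(mask_pred, mask_ref)
  if (!all(codes %in% 0:3)) stop("dsc: unknown label codes (expected 0..3)")
  out <- numeric(3L)
  names(out) <- c("lung", "liver", "bone")
  for (c in 1:3) {
    a <- mask_pred == c; b <- mask_ref == c
    na <- sum(a); nb <- sum(b)
    out[c] <- if (na + nb == 0L) 1.0 else 2 * sum(a & b) / (na + nb)
  }
  out
}

new_metrics_report <- function(psnr_db, ssim, rmse_hu, dsc_per_organ,
                               reference_kind) {
  structure(list(psnr_db = psnr_db, ssim = ssim, rmse_hu = rmse_hu,
                 dsc_per_organ = dsc_per_organ,
                 dsc_mean = mean(dsc_per_organ),
                 reference_kind = reference_kind), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Metrics (%s reference): PSNR %.2f dB, SSIM %.3f, RMSE %.1f HU\n",
              x$reference_kind, x$psnr_db, x$ssim, x$rmse_hu))
  cat(sprintf("  DSC lung %.3f, liver %.3f, bone %.3f (mean %.3f)\n",
              x$dsc_per_organ["lung"], x$dsc_per_organ["liver"],
              x$dsc_per_organ["bone"], x$dsc_mean))
  invisible(x)
}

#' Evaluate a reconstructed volume against its phantom
#'
#' Image metrics (PSNR, SSIM, RMSE in HU) are computed once; organ Dice is
#' computed twice following the dual-reference protocol: `M_analog` compares
#' the segmenter's masks on the reconstruction against the phantom's own
#' labels (the manual-annotation analogue), `S_analog` compares them against
#' the segmenter's masks on the true volume.
#'
#' @param y_pred reconstructed volume in `[0,1]`.
#' @param phantom the `labeled_phantom` it was reconstructed from.
#' @param segnet a fitted segmenter (list with `params`, `cfg`).
#' @param hu_window normalisation window for HU-scale metrics.
#' @return list with elements `M_analog` and `S_analog`, both
#'   `metrics_report`s (`M_analog` is `NULL` with a warning when the phantom
#'   has no labels).
#' @export
evaluate_reconstruction <- function(y_pred, phantom, segnet,
                                    hu_window = c(-1024, 3071)) {
  y_true <- normalize_hu(phantom$hu_volume, hu_window[1], hu_window[2])
  attributes(y_true) <- list(dim = dim(phantom$hu_volume))
  p <- psnr(y_pred, y_true)
  s <- ssim(y_pred, y_true)
  r <- rmse_hu(y_pred, y_true, hu_window)
  seg_pred <- segment_volume(y_pred, segnet)
  seg_true <- segment_volume(y_true, segnet)
  s_rep <- new_metrics_report(p, s, r, dsc(seg_pred, seg_true), "S_analog")
  m_rep <- NULL
  if (is.null(phantom$labels)) {
    warning("evaluate_reconstruction: phantom has no labels; M_analog omitted")
  } else {
    m_rep <- new_metrics_report(p, s, r, dsc(seg_pred, phantom$labels), "M_analog")
  }
  list(M_analog = m_rep, S_analog = s_rep)
}

## Hard organ mask (codes 0..3) from the segmenter's probabilities.
segment_volume <- function(volume, segnet) {
  prob <- segnet_forward(volume, segnet$params, segnet$cfg)$prob
  n <- dim(prob)
  am <- max.col(matrix(prob, ncol = n[4]), ties.method = "first") - 1L
  array(as.integer(am), dim = n[1:3])
}

#' Aggregate a list of metric reports into mean/sd rows
#' @param reports list of `metrics_report`s.
#' @return data frame with one row per metric, columns `mean` and `sd`.
#' @export
aggregate_reports <- function(reports) {
  reports <- Filter(Negate(is.null), reports)
  grab <- function(f) vapply(reports, f, numeric(1))
  m <- rbind(psnr_db = grab(function(r) r$psnr_db),
             ssim = grab(function(r) r$ssim),
             rmse_hu = grab(function(r) r$rmse_hu),
             dsc_lung = grab(function(r) r$dsc_per_organ["lung"]),
             dsc_liver = grab(function(r) r$dsc_per_organ["liver"]),
             dsc_bone = grab(function(r) r$dsc_per_organ["bone"]),
             dsc_mean = grab(function(r) r$dsc_mean))
  data.frame(metric = rownames(m), mean = rowMeans(m),
             sd = apply(m, 1L, stats::sd), row.names = NULL)
}
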