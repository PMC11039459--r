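## Fan-beam geometry: per-slice 2-d acquisition model shared by every z slice.
## In-slice coordinates are centred on the isocenter; z is the vertical
## (slice-stacking) axis. The source sits at SID from the isocenter on the +y
## axis for the AP view and on the +x axis for the LAT view; the detector is a
## flat line at SDD from the source, perpendicular to the source axis.

#' Fan-beam scanner geometry
#'
#' Describes the per-slice fan-beam acquisition model from which the forward
#' projector and the pixel-driven backprojection (lifting) matrix are derived.
#' Defaults model a Siemens Somatom Force scout acquisition (SDD 1085.6 mm,
#' SID 595 mm) on a 128-voxel grid at 2.5 mm.
#'
#' @param sdd_mm source-to-detector distance in mm.
#' @param sid_mm source-to-isocenter distance in mm.
#' @param n_detector number of detector channels.
#' @param detector_spacing_mm channel pitch at the detector in mm. When `NULL`
#'   it is derived so the detector exactly covers the magnified field of view:
#'   `n_image * voxel_spacing_mm * sdd_mm / sid_mm / n_detector`.
#' @param n_image in-slice grid size (square).
#' @param voxel_spacing_mm voxel pitch in mm.
#' @param view `"AP"` (source on +y) or `"LAT"` (source on +x).
#' @return An object of class `fan_geometry`.
#' @export
fan_beam_geometry <- function(sdd_mm = 1085.6, sid_mm = 595,
                              n_detector = 128L, detector_spacing_mm = NULL,
                              n_image = 128L, voxel_spacing_mm = 2.5,
                              view = c("AP", "LAT")) {
  view <- match.arg(view)
  if (!(sdd_mm > sid_mm && sid_mm > 0))
    stop("fan_beam_geometry: requires sdd_mm > sid_mm > 0")
  if (n_detector < 1L || n_image < 1L)
    stop("fan_beam_geometry: n_detector and n_image must be >= 1")
  if (voxel_spacing_mm <= 0)
    stop("fan_beam_geometry: voxel_spacing_mm must be positive")
  if (is.null(detector_spacing_mm))
    detector_spacing_mm <- n_image * voxel_spacing_mm * sdd_mm / sid_mm / n_detector
  if (detector_spacing_mm <= 0)
    stop("fan_beam_geometry: detector_spacing_mm must be positive")
  if (n_detector * detector_spacing_mm <
      n_image * voxel_spacing_mm * sdd_mm / sid_mm - 1e-9)
    stop("fan_beam_geometry: detector does not cover the magnified field of view")
  structure(list(sdd_mm = sdd_mm, sid_mm = sid_mm,
                 n_detector = as.integer(n_detector),
                 detector_spacing_mm = detector_spacing_mm,
                 n_image = as.integer(n_image),
                 voxel_spacing_mm = voxel_spacing_mm, view = view),
            class = "fan_geometry")
}

#' @export
print.fan_geometry <- function(x, ...) {
  cat(sprintf("Fan-beam geometry (%s view)\n", x$view))
  cat(sprintf("  SDD %.1f mm, SID %.1f mm (magnification %.3f)\n",
              x$sdd_mm, x$sid_mm, x$sdd_mm / x$sid_mm))
  cat(sprintf("  detector: %d channels x %.3f mm\n",
              x$n_detector, x$detector_spacing_mm))
  cat(sprintf("  image grid: %d x %d at %.2f mm\n",
              x$n_image, x$n_image, x$voxel_spacing_mm))
  invisible(x)
}

## View frame: a = unit vector isocenter -> source, e = detector axis.
view_frame <- function(view) {
  if (view == "AP") list(a = c(0, 1), e = c(1, 0))
  else list(a = c(1, 0), e = c(0, -1))
}

## Pixel-centre coordinates (mm), 1-based index i -> (i - (n+1)/2) * spacing.
pixel_coords <- function(n, spacing) (seq_len(n) - (n + 1) / 2) * spacing

## Continuous detector channel index for in-slice points (vectorised).
## Channel k has its centre at u_k = (k - (n_det+1)/2) * spacing.
detector_channel <- function(geom, px, py) {
  fr <- view_frame(geom$view)
  pa <- px * fr$a[1] + py * fr$a[2]
  pe <- px * fr$e[1] + py * fr$e[2]
  u <- geom$sdd_mm * pe / (geom$sid_mm - pa)
  u / geom$detector_spacing_mm + (geom$n_detector + 1) / 2
}

#' Build the pixel-driven backprojection (lifting) matrix
#'
#' For every in-slice pixel centre, the ray from the source through the pixel
#' is intersected with the flat detector; the continuous detector coordinate
#' distributes unit weight onto its two neighbouring channels by linear
#' interpolation. Pixels projecting outside the channel-centre range get an
#' all-zero row (no clamping).
#'
#' @param geom a [fan_beam_geometry()] object.
#' @return An object of class `system_matrix` with fields `weights`
#'   (sparse `n_image^2 x n_detector` matrix) and `geometry`.
#' @export
build_system_matrix <- function(geom) {
  stopifnot(inherits(geom, "fan_geometry"))
  n <- geom$n_image
  xc <- pixel_coords(n, geom$voxel_spacing_mm)
  px <- rep(xc, times = n)
  py <- rep(xc, each = n)
  cc <- detector_channel(geom, px, py)
  inside <- cc >= 1 & cc <= geom$n_detector
  pix <- which(inside)
  k0 <- floor(cc[inside])
  fr <- cc[inside] - k0
  i <- c(pix, pix[fr > 0])
  j <- c(k0, k0[fr > 0] + 1)
  w <- c(1 - fr, fr[fr > 0])
  structure(list(
    weights = Matrix::sparseMatrix(i = i, j = j, x = w,
                                   dims = c(n * n, geom$n_detector)),
    geometry = geom), class = "system_matrix")
}

#' Build the ray-driven fan-beam forward projector
#'
#' Joseph-style sampling: for each detector channel, points along the ray from
#' the source to the channel centre are sampled at `step_frac` of the voxel
#' pitch and gathered with bilinear in-slice interpolation; the line integral
#' is the sample sum scaled by the step in mm. Stored as a sparse
#' `n_detector x n_image^2` matrix so projection is a (differentiable) fixed
#' linear map and its adjoint is the exact transpose.
#'
#' @param geom a [fan_beam_geometry()] object.
#' @param step_frac sampling step as a fraction of the voxel pitch.
#' @return An object of class `fan_projector`.
#' @export
build_forward_projector <- function(geom, step_frac = 0.5) {
  stopifnot(inherits(geom, "fan_geometry"))
  n <- geom$n_image
  fr <- view_frame(geom$view)
  src <- geom$sid_mm * fr$a
  det0 <- (geom$sid_mm - geom$sdd_mm) * fr$a
  spacing <- geom$voxel_spacing_mm
  half <- n * spacing / sqrt(2) + spacing
  step <- step_frac * spacing
  ts <- seq(geom$sid_mm - half, geom$sid_mm + half, by = step)
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  for (k in seq_len(geom$n_detector)) {
    uk <- (k - (geom$n_detector + 1) / 2) * geom$detector_spacing_mm
    dk <- det0 + uk * fr$e - src
    dk <- dk / sqrt(sum(dk * dk))
    x <- src[1] + ts * dk[1]
    y <- src[2] + ts * dk[2]
    gx <- x / spacing + (n + 1) / 2
    gy <- y / spacing + (n + 1) / 2
    i0 <- floor(gx); fx <- gx - i0
    j0 <- floor(gy); fy <- gy - j0
    for (q in 1:4) {
      iq <- i0 + (q == 2 | q == 4)
      jq <- j0 + (q >= 3)
      wq <- (if (q %% 2 == 1) 1 - fx else fx) * (if (q <= 2) 1 - fy else fy)
      ok <- iq >= 1 & iq <= n & jq >= 1 & jq <= n & wq > 0
      if (any(ok)) {
        ii <- c(ii, rep.int(k, sum(ok)))
        jj <- c(jj, iq[ok] + (jq[ok] - 1) * n)
        ww <- c(ww, wq[ok] * step)
      }
    }
  }
  structure(list(
    weights = Matrix::sparseMatrix(i = ii, j = jj, x = ww,
                                   dims = c(geom$n_detector, n * n)),
    geometry = geom, step_mm = step), class = "fan_projector")
}

## Cache operators per geometry (they are deterministic and reused at every
## resolution level of the generator).
.op_cache <- new.env(parent = emptyenv())

geom_key <- function(geom, kind) {
  paste(kind, geom$view, geom$n_image, geom$n_detector,
        signif(geom$voxel_spacing_mm, 12), signif(geom$detector_spacing_mm, 12),
        signif(geom$sdd_mm, 12), signif(geom$sid_mm, 12), sep = "|")
}

cached_system_matrix <- function(geom) {
  key <- geom_key(geom, "T")
  if (is.null(.op_cache[[key]])) .op_cache[[key]] <- build_system_matrix(geom)
  .op_cache[[key]]
}

cached_projector <- function(geom) {
  key <- geom_key(geom, "P")
  if (is.null(.op_cache[[key]])) .op_cache[[key]] <- build_forward_projector(geom)
  .op_cache[[key]]
}

#' Forward-project a volume into a fan-beam topogram
#'
#' Applies the fan-beam line-integral operator slice by slice: every z slice of
#' the volume is projected with the same in-slice geometry, giving a projection
#' image with detector channels along axis 1 and z along axis 2.
#'
#' @param volume cubic 3-d array (`n_image` per axis).
#' @param geom a [fan_beam_geometry()] or a prebuilt [build_forward_projector()].
#' @return `n_detector x n_image` matrix with attribute `"geometry"`.
#' @export
forward_project <- function(volume, geom) {
  proj <- if (inherits(geom, "fan_projector")) geom else cached_projector(geom)
  g <- proj$geometry
  d <- dim(volume)
  if (length(d) != 3L || d[1] != d[2] || d[2] != d[3])
    stop("forward_project: volume must be cubic")
  if (d[1] != g$n_image)
    stop("forward_project: volume size does not match geometry n_image")
  vm <- matrix(volume, nrow = g$n_image^2)
  out <- as.matrix(proj$weights %*% vm)
  attr(out, "geometry") <- g
  out
}

#' Lift 2-d feature maps to 3-d by pixel-driven backprojection
#'
#' Multiplies each (channel, z) detector row by the sparse system matrix,
#' smearing detector values along their rays into one in-slice map; maps are
#' stacked over z and channels. z rows never mix, so the operation is the
#' volumetric analogue of per-slice backprojection.
#'
#' @param features `(n_detector, n_z)` matrix or `(n_detector, n_z, C)` array.
#' @param tmat a `system_matrix`.
#' @return `(n_image, n_image, n_z, C)` array.
#' @export
lift_2d_to_3d <- function(features, tmat) {
  stopifnot(inherits(tmat, "system_matrix"))
  d <- dim(features)
  if (length(d) == 2L) dim(features) <- d <- c(d, 1L)
  n <- tmat$geometry$n_image
  if (d[1] != ncol(tmat$weights))
    stop("lift_2d_to_3d: detector size does not match system matrix")
  out <- array(0, dim = c(n, n, d[2], d[3]))
  for (c in seq_len(d[3]))
    out[, , , c] <- as.matrix(tmat$weights %*% features[, , c])
  out
}

## Adjoint of the lift: (n, n, n_z, C) -> (n_detector, n_z, C).
lift_2d_to_3d_bw <- function(gy, tmat) {
  d <- dim(gy)
  n <- tmat$geometry$n_image
  nd <- ncol(tmat$weights)
  out <- array(0, dim = c(nd, d[3], d[4]))
  for (c in seq_len(d[4]))
    out[, , c] <- as.matrix(Matrix::crossprod(tmat$weights,
                                              matrix(gy[, , , c], nrow = n * n)))
  out
}

#' Apply the exact adjoint of a stored sparse operator
#'
#' For a `fan_projector` this backprojects a projection image into a slice
#' stack; for a `system_matrix` it projects an image stack back onto the
#' detector. In both cases the transpose of the stored sparse matrix is
#' applied, so the inner-product identity `<A x, p> == <x, A^T p>` holds to
#' machine precision.
#'
#' @param projection matrix whose first axis matches the operator output axis.
#' @param op a `fan_projector` or `system_matrix`.
#' @return The adjoint image (matrix, columns = z).
#' @export
adjoint_apply <- function(projection, op) {
  w <- op$weights
  pm <- as.matrix(projection)
  if (nrow(pm) != nrow(w))
    stop("adjoint_apply: projection rows do not match operator output size")
  as.matrix(Matrix::crossprod(w, pm))
}
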