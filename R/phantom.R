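## Synthetic thorax phantoms: a soft-tissue body ellipsoid on air, two low-HU
## lungs, a liver in the lower body, a vertical spine cylinder and rib arcs in
## bone HU, with voxel-wise labels painted from the same geometric primitives.
## These phantoms play the role of the chest-CT reconstruction corpus and the
## labelled organ-segmentation corpus in one.

#' Specification of the synthetic thorax phantom generator
#'
#' @param grid_size voxels per axis (default 128, the training grid; tests use
#'   32 via the same spec).
#' @param voxel_spacing_mm voxel pitch in mm.
#' @param hu_values named list `tissue = c(mean, jitter)` in HU; one value per
#'   organ per phantom is drawn uniformly from mean +- jitter.
#' @param noise_hu_sd voxel-level Gaussian texture (clamped at 4 sd so label-HU
#'   consistency is preserved by construction).
#' @param seed integer seed; with the phantom index it fully determines a
#'   phantom.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_size = 128L, voxel_spacing_mm = 2.5,
                         hu_values = list(air = c(-1000, 0),
                                          soft = c(40, 20),
                                          lung = c(-800, 50),
                                          liver = c(60, 15),
                                          bone = c(700, 100)),
                         noise_hu_sd = 5, seed = 1L) {
  stopifnot(grid_size >= 8L, voxel_spacing_mm > 0)
  means <- vapply(hu_values, `[`, numeric(1), 1L)
  if (!(means["lung"] < means["soft"] && means["soft"] < means["liver"] &&
        means["liver"] < means["bone"]))
    stop("phantom_spec: HU ordering lung < soft < liver < bone violated")
  structure(list(grid_size = as.integer(grid_size),
                 voxel_spacing_mm = voxel_spacing_mm, hu_values = hu_values,
                 noise_hu_sd = noise_hu_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

## Content hash (djb2-style polynomial over the deparsed spec) so manifests
## can record which generator settings produced a corpus.
spec_hash <- function(spec) {
  s <- paste(deparse(spec, control = "all"), collapse = "")
  h <- 5381
  for (v in utf8ToInt(s)) h <- (h * 33 + v) %% 2147483647
  sprintf("%08x", h)
}

runif1 <- function(lo, hi) stats::runif(1L, lo, hi)

ellipsoid_mask <- function(X, Y, Z, cen, semi, rot = 0) {
  xr <- (X - cen[1]) * cos(rot) + (Y - cen[2]) * sin(rot)
  yr <- -(X - cen[1]) * sin(rot) + (Y - cen[2]) * cos(rot)
  (xr / semi[1])^2 + (yr / semi[2])^2 + ((Z - cen[3]) / semi[3])^2 <= 1
}

#' Draw one labelled thorax phantom
#'
#' Deterministic given `(spec$seed, index)`. Label codes: 0 background/other,
#' 1 lung, 2 liver, 3 bone. Per-organ HU is drawn once per phantom from the
#' spec's `(mean, jitter)` range; a small clamped voxel-level texture is added
#' on top, keeping every lung voxel below -500 HU and every bone voxel above
#' 300 HU by construction.
#'
#' @param spec a [phantom_spec()].
#' @param index phantom index within the corpus (>= 1).
#' @return An object of class `labeled_phantom`: `hu_volume`, `labels`,
#'   `spacing_mm`, plus the drawn organ geometry in `meta`.
#' @export
sample_phantom <- function(spec, index = 1L) {
  stopifnot(inherits(spec, "phantom_spec"), index >= 1L)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed((spec$seed %% 100000L) * 20011L + as.integer(index))

  n <- spec$grid_size
  ax <- (seq_len(n) - 0.5) / n
  X <- array(rep(ax, times = n * n), dim = c(n, n, n))
  Y <- array(rep(rep(ax, each = n), times = n), dim = c(n, n, n))
  Z <- array(rep(ax, each = n * n), dim = c(n, n, n))

  hu_of <- function(tis, lo_floor = -Inf) {
    v <- spec$hu_values[[tis]]
    lo <- max(v[1] - v[2], lo_floor)
    hi <- max(v[1] + v[2], lo)
    if (hi > lo) runif1(lo, hi) else lo
  }

  ## The body is an elliptical cylinder: a thorax window cut from a torso is
  ## roughly constant in cross-section over its z extent.
  body_semi <- c(runif1(0.37, 0.43), runif1(0.28, 0.33), Inf)
  body <- ((X - 0.5) / body_semi[1])^2 + ((Y - 0.5) / body_semi[2])^2 <= 1 &
    Z > 0.01 & Z < 0.99

  draw_organ <- function(name, draw) {
    for (try in 1:25) {
      o <- draw()
      m <- ellipsoid_mask(X, Y, Z, o$cen, o$semi, o$rot)
      if (sum(m & !body) == 0 && sum(m) > 0) return(list(mask = m, par = o))
    }
    stop(sprintf("sample_phantom: could not place organ '%s' inside the body", name))
  }

  lungs <- lapply(c(-1, 1), function(side) {
    draw_organ(if (side < 0) "left lung" else "right lung", function() {
      list(cen = c(0.5 + side * runif1(0.15, 0.20), runif1(0.44, 0.50),
                   runif1(0.56, 0.64)),
           semi = c(runif1(0.10, 0.135), runif1(0.14, 0.18), runif1(0.22, 0.28)),
           rot = side * runif1(0, 0.15))
    })
  })
  liver <- draw_organ("liver", function() {
    list(cen = c(runif1(0.60, 0.66), runif1(0.47, 0.54), runif1(0.18, 0.24)),
         semi = c(runif1(0.13, 0.17), runif1(0.11, 0.15), runif1(0.10, 0.14)),
         rot = runif1(-0.1, 0.1))
  })

  spine_cen <- c(0.5, runif1(0.70, 0.74))
  spine_r <- runif1(0.035, 0.05)
  spine <- (X - spine_cen[1])^2 + (Y - spine_cen[2])^2 <= spine_r^2 &
    Z > 0.04 & Z < 0.96 & body

  n_ribs <- sample(4:8, 1L)
  rib_z <- seq(0.40, 0.88, length.out = n_ribs)
  rib_sx <- body_semi[1] * runif1(0.82, 0.90)
  rib_sy <- body_semi[2] * runif1(0.82, 0.90)
  rho <- sqrt(((X - 0.5) / rib_sx)^2 + ((Y - 0.5) / rib_sy)^2)
  phi <- atan2(Y - 0.5, X - 0.5)
  rib_t <- max(0.015, 1.2 / n)
  ribs <- array(FALSE, dim = dim(X))
  for (zk in rib_z)
    ribs <- ribs | (abs(rho - 1) < 0.06 & abs(Z - zk) < rib_t &
                      !(phi < -1.2 & phi > -1.9) & body)

  labels <- array(0L, dim = c(n, n, n))
  hu <- array(hu_of("air"), dim = c(n, n, n))
  soft_hu <- hu_of("soft")
  hu[body] <- soft_hu
  for (l in lungs) { hu[l$mask] <- hu_of("lung"); labels[l$mask] <- 1L }
  ## liver tracks this phantom's soft-tissue value with a stable positive
  ## contrast (real livers are consistently hyperdense to surrounding soft
  ## tissue), clipped into the liver mean +- jitter range
  lv <- spec$hu_values$liver
  liver_hu <- min(lv[1] + lv[2], max(lv[1] - lv[2], soft_hu + runif1(18, 32)))
  hu[liver$mask] <- liver_hu
  labels[liver$mask] <- 2L
  bone_hu <- hu_of("bone")
  bone <- spine | ribs
  hu[bone] <- bone_hu; labels[bone] <- 3L

  if (spec$noise_hu_sd > 0) {
    noise <- stats::rnorm(length(hu), sd = spec$noise_hu_sd)
    clamp <- 4 * spec$noise_hu_sd
    hu <- hu + pmin(pmax(noise, -clamp), clamp)
  }

  structure(list(hu_volume = hu, labels = labels,
                 spacing_mm = spec$voxel_spacing_mm,
                 meta = list(index = as.integer(index), body_semi = body_semi,
                             lungs = lapply(lungs, `[[`, "par"),
                             liver = liver$par, n_ribs = n_ribs)),
            class = "labeled_phantom")
}

#' Check the label/HU consistency contract of a phantom
#' @param ph a `labeled_phantom`.
#' @return `TRUE` invisibly; stops on violation.
#' @export
validate_labeled_phantom <- function(ph) {
  stopifnot(identical(dim(ph$hu_volume), dim(ph$labels)))
  if (any(ph$hu_volume[ph$labels == 1L] >= -500))
    stop("labeled_phantom: lung voxel with HU >= -500")
  if (any(ph$hu_volume[ph$labels == 3L] <= 300))
    stop("labeled_phantom: bone voxel with HU <= 300")
  invisible(TRUE)
}

#' @export
print.labeled_phantom <- function(x, ...) {
  n <- dim(x$hu_volume)
  cat(sprintf("Labelled thorax phantom %d^3 at %.2f mm\n", n[1], x$spacing_mm))
  tab <- table(factor(x$labels, levels = 0:3,
                      labels = c("other", "lung", "liver", "bone")))
  cat("  label voxels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write a phantom corpus to disk as paired NIfTI files
#'
#' @param spec a [phantom_spec()].
#' @param n number of phantoms.
#' @param out_dir output directory (created if needed).
#' @return The manifest data frame (`index`, `path_image`, `path_labels`) with
#'   attributes `seed` and `spec_hash`, also written as `manifest.tsv`.
#' @export
make_dataset <- function(spec, n, out_dir) {
  stopifnot(n >= 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("make_dataset: cannot create ", out_dir)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- sample_phantom(spec, i)
    fi <- file.path(out_dir, sprintf("image_%04d.nii", i))
    fl <- file.path(out_dir, sprintf("labels_%04d.nii", i))
    RNifti::writeNifti(RNifti::asNifti(ph$hu_volume,
                                       pixdim = rep(spec$voxel_spacing_mm, 3)), fi)
    RNifti::writeNifti(RNifti::asNifti(ph$labels,
                                       pixdim = rep(spec$voxel_spacing_mm, 3),
                                       datatype = "uint8"), fl)
    rows[[i]] <- data.frame(index = i, path_image = fi, path_labels = fl,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  attr(manifest, "seed") <- spec$seed
  attr(manifest, "spec_hash") <- spec_hash(spec)
  mf <- file.path(out_dir, "manifest.tsv")
  con <- file(mf, "w")
  writeLines(c(sprintf("# seed=%d", spec$seed),
               sprintf("# spec_hash=%s", spec_hash(spec))), con)
  utils::write.table(manifest, con, sep = "\t", row.names = FALSE, quote = FALSE)
  close(con)
  manifest
}

#' Read a corpus manifest written by [make_dataset()]
#' @param path the manifest file or its directory.
#' @return Manifest data frame with `seed` and `spec_hash` attributes.
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.tsv")
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  manifest <- utils::read.table(text = lines[!grepl("^#", lines)], sep = "\t",
                                header = TRUE, stringsAsFactors = FALSE)
  seed <- sub("^# seed=", "", grep("^# seed=", hdr, value = TRUE))
  hash <- sub("^# spec_hash=", "", grep("^# spec_hash=", hdr, value = TRUE))
  attr(manifest, "seed") <- as.integer(seed)
  attr(manifest, "spec_hash") <- hash
  manifest
}
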