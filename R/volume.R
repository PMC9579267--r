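#' Image volume
#'
#' A 3-D scalar voxel grid with physical geometry and value semantics. A 4-D
#' time series is represented by `frames`: an ordered list of 3-D arrays
#' sharing the volume's geometry, with acquisition times in seconds.
#'
#' @param voxels a 3-D numeric array (i,j,k order).
#' @param geometry a [grid_geometry()]; defaults to unit spacing at the origin.
#' @param modality DICOM modality code (CT, PT, NM, MR, ...).
#' @param value_kind one of `"HU"`, `"activity_conc"` (Bq/ml), `"SUV"`,
#'   `"dose_rate"` (Gy/h), `"unitless"`.
#' @param frames optional named list with elements `arrays` (list of 3-D
#'   arrays) and `times` (numeric seconds).
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, geometry = NULL, modality = "OT",
                         value_kind = c("unitless", "HU", "activity_conc",
                                        "SUV", "dose_rate"),
                         frames = NULL) {
  value_kind <- match.arg(value_kind)
  voxels <- as.array(voxels)
  if (length(dim(voxels)) == 2L) dim(voxels) <- c(dim(voxels), 1L)
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3-D array")
  if (is.null(geometry)) geometry <- grid_geometry(dim(voxels))
  if (!identical(as.integer(dim(voxels)), geometry$dims))
    stop("voxel array shape does not match geometry dims")
  if (!is.null(frames)) {
    for (f in frames$arrays)
      if (!identical(as.integer(dim(f)), geometry$dims))
        stop("all frames must share the volume geometry")
  }
  structure(list(geometry = geometry, voxels = voxels, modality = modality,
                 value_kind = value_kind, frames = frames),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("image_volume [%s, %s] ", x$modality, x$value_kind))
  print(x$geometry)
  cat(sprintf("  value range: [%g, %g]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

# convenience: new volume reusing geometry/metadata of `like`
vol_like <- function(like, voxels, value_kind = like$value_kind) {
  image_volume(voxels, like$geometry, like$modality, value_kind)
}

#' Binary volume-of-interest mask
#'
#' @param mask a logical (or 0/1 numeric) 3-D array on the grid of `geometry`.
#' @param geometry a [grid_geometry()].
#' @param name VOI name.
#' @param color RGB triple in 0..255.
#' @return An object of class `voi_mask`.
#' @export
voi_mask <- function(mask, geometry = NULL, name = "VOI",
                     color = c(255L, 0L, 0L)) {
  mask <- array(as.logical(mask), dim = dim(as.array(mask)))
  if (length(dim(mask)) == 2L) dim(mask) <- c(dim(mask), 1L)
  if (is.null(geometry)) geometry <- grid_geometry(dim(mask))
  if (!identical(as.integer(dim(mask)), geometry$dims))
    stop("mask shape does not match geometry dims")
  structure(list(geometry = geometry, mask = mask, name = as.character(name),
                 color = as.integer(color)),
            class = "voi_mask")
}

#' @export
print.voi_mask <- function(x, ...) {
  cat(sprintf("voi_mask '%s': %d voxels (%.3f ml)\n", x$name, sum(x$mask),
              sum(x$mask) * voxel_volume_ml(x$geometry)))
  invisible(x)
}

#' Display window/level
#' @param window value-range width, > 0.
#' @param level center value.
#' @return An object of class `window_level`.
#' @export
window_level <- function(window, level) {
  if (window <= 0) stop("window must be > 0")
  structure(list(window = as.numeric(window), level = as.numeric(level)),
            class = "window_level")
}

#' Per-VOI descriptive statistics
#'
#' Computes the statistics reported for a segmented region: volume in ml,
#' total, mean, min, max, peak, and standard deviation of the voxels inside
#' the mask. `peak` is the SUVpeak convention: the mean within a 1 ml sphere
#' centered on the hottest voxel (falling back to the max when the VOI holds
#' fewer voxels than a 1 ml sphere). `sd` is the population standard
#' deviation. For SUV volumes, total lesion glycolysis
#' `tlg = mean * volume_ml` is also filled in.
#'
#' @param vol an [image_volume()].
#' @param voi a [voi_mask()] on the same grid.
#' @return A list of class `voi_statistics` with fields `name`, `voxel_count`,
#'   `volume_ml`, `total`, `mean`, `min`, `max`, `peak`, `sd`, `tlg`.
#' @export
compute_statistics <- function(vol, voi) {
  stop_if_geometry_mismatch(vol$geometry, voi$geometry, "volume and VOI")
  v <- vol$voxels[voi$mask]
  if (length(v) == 0L)
    stop(sprintf("VOI '%s' is empty", voi$name))
  vvol <- voxel_volume_ml(vol$geometry)
  n <- length(v)
  m <- mean(v)
  stats <- list(
    name = voi$name,
    voxel_count = n,
    volume_ml = n * vvol,
    total = sum(v),
    mean = m,
    min = min(v),
    max = max(v),
    peak = peak_value(vol, voi),
    sd = sqrt(sum((v - m)^2) / n),
    tlg = if (vol$value_kind == "SUV") m * n * vvol else NA_real_
  )
  class(stats) <- "voi_statistics"
  stats
}

#' @export
print.voi_statistics <- function(x, ...) {
  cat(sprintf("VOI '%s': %.3f ml | mean %.4g | min %.4g | max %.4g | peak %.4g | sd %.4g\n",
              x$name, x$volume_ml, x$mean, x$min, x$max, x$peak, x$sd))
  if (!is.na(x$tlg)) cat(sprintf("  TLG: %.4g\n", x$tlg))
  invisible(x)
}

# SUVpeak-style statistic: mean over a 1 ml sphere centered on the VOI's
# hottest voxel, intersected with the grid. Falls back to the plain max when
# the VOI is smaller than the sphere.
peak_value <- function(vol, voi) {
  vvol <- voxel_volume_ml(vol$geometry)
  n_sphere <- 1 / vvol
  if (sum(voi$mask) < n_sphere) return(max(vol$voxels[voi$mask]))
  hot <- which(voi$mask & vol$voxels == max(vol$voxels[voi$mask]),
               arr.ind = TRUE)[1, ] - 1L
  r_mm <- (3 * 1000 / (4 * pi))^(1 / 3)   # radius of a 1 ml sphere, mm
  g <- vol$geometry
  center <- voxel_to_world(g, hot)
  # bounding box of the sphere in index space
  lo <- pmax(floor(hot - r_mm / g$spacing), 0)
  hi <- pmin(ceiling(hot + r_mm / g$spacing), g$dims - 1L)
  ii <- seq(lo[1], hi[1]); jj <- seq(lo[2], hi[2]); kk <- seq(lo[3], hi[3])
  idx <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
  w <- voxel_to_world(g, idx, check = FALSE)
  d2 <- rowSums(sweep(w, 2, center)^2)
  sel <- idx[d2 <= r_mm^2, , drop = FALSE] + 1L
  mean(vol$voxels[sel])
}
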