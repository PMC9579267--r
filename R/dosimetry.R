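#' Tissue assignment map
#'
#' Maps CT Hounsfield ranges to tissue labels and densities, with optional
#' VOI overrides that take precedence over the HU lookup (e.g. forcing a
#' delineated tumor to a specific tissue).
#'
#' @param entries data.frame with columns `hu_lower`, `hu_upper` (inclusive
#'   lower, exclusive upper except the last), `tissue`, `density_g_ml`.
#' @param overrides list of `list(voi = voi_mask, tissue = label)`.
#' @param default_tissue label assigned (with a warning count) to voxels
#'   outside every range.
#' @return An object of class `tissue_map`.
#' @export
tissue_map <- function(entries = data.frame(
                         hu_lower = c(-1050, -120, 120),
                         hu_upper = c(-120, 120, 3000),
                         tissue = c("lung", "soft_tissue", "bone"),
                         density_g_ml = c(0.26, 1.00, 1.85),
                         stringsAsFactors = FALSE),
                       overrides = list(), default_tissue = "soft_tissue") {
  o <- order(entries$hu_lower)
  entries <- entries[o, , drop = FALSE]
  if (any(entries$density_g_ml <= 0)) stop("densities must be > 0")
  if (nrow(entries) > 1 &&
      any(entries$hu_lower[-1] < entries$hu_upper[-nrow(entries)] - 1e-9))
    stop("HU ranges must not overlap")
  if (!default_tissue %in% entries$tissue)
    stop("default_tissue must appear in entries")
  structure(list(entries = entries, overrides = overrides,
                 default_tissue = default_tissue),
            class = "tissue_map")
}

#' Assign a tissue label to every voxel
#'
#' HU ranges are applied first; VOI overrides then take precedence. Voxels
#' outside all ranges get the map's default tissue, and their count is
#' attached as attribute `"unassigned"` with a warning.
#'
#' @param ct an [image_volume()] in HU.
#' @param map a [tissue_map()].
#' @return A character 3-D array of tissue labels (attribute `"unassigned"` =
#'   count of out-of-range voxels).
#' @export
assign_tissue <- function(ct, map) {
  if (ct$value_kind != "HU") stop("assign_tissue expects a CT volume in HU")
  e <- map$entries
  labels <- array(NA_character_, dim(ct$voxels))
  for (r in seq_len(nrow(e))) {
    upper_ok <- if (r == nrow(e)) ct$voxels <= e$hu_upper[r] else
      ct$voxels < e$hu_upper[r]
    labels[ct$voxels >= e$hu_lower[r] & upper_ok] <- e$tissue[r]
  }
  n_un <- sum(is.na(labels))
  if (n_un > 0) {
    warning(sprintf("%d voxels outside all HU ranges assigned to '%s'",
                    n_un, map$default_tissue))
    labels[is.na(labels)] <- map$default_tissue
  }
  for (ov in map$overrides) {
    stop_if_geometry_mismatch(ct$geometry, ov$voi$geometry, "CT and override VOI")
    labels[ov$voi$mask] <- ov$tissue
  }
  attr(labels, "unassigned") <- n_un
  labels
}

tissue_density <- function(map, tissue) {
  i <- match(tissue, map$entries$tissue)
  d <- map$entries$density_g_ml[i]
  # overrides may introduce labels absent from the HU table; treat them as
  # the default tissue's density
  d[is.na(d)] <- map$entries$density_g_ml[match(map$default_tissue,
                                                map$entries$tissue)]
  d
}

#' Dose-rate estimation by tissue-specific kernel convolution
#'
#' Converts an activity-concentration image into a dose-rate image by
#' region-wise convolution: for each tissue present in `labels`, the activity
#' masked to that tissue is convolved with that tissue's dose kernel (each
#' kernel is first resampled onto the image grid), and the contributions are
#' summed. With `density_correction`, every voxel's dose is scaled by
#' (reference density / local density), reference = 1 g/ml (water).
#'
#' @param activity an [image_volume()] in Bq/ml.
#' @param kernels named list of [kernel3d()], one per tissue label present.
#'   Kernel values are Gy/h per (Bq/ml) per voxel after grid resampling.
#' @param labels tissue-label array from [assign_tissue()] (or a single label
#'   string for a homogeneous volume).
#' @param map the [tissue_map()] (required when `density_correction = TRUE`).
#' @param density_correction logical, default FALSE.
#' @param method convolution path, `"fft"` (default) or `"direct"`.
#' @return An [image_volume()] with `value_kind = "dose_rate"` (Gy/h).
#' @export
dose_rate <- function(activity, kernels, labels, map = NULL,
                      density_correction = FALSE, method = "fft") {
  if (length(labels) == 1L)
    labels <- array(labels, dim(activity$voxels))
  present <- unique(as.vector(labels))
  missing_k <- setdiff(present, names(kernels))
  if (length(missing_k))
    stop(sprintf("no dose kernel supplied for tissue label(s): %s",
                 paste(missing_k, collapse = ", ")))
  out <- array(0, dim(activity$voxels))
  for (t in present) {
    sel <- labels == t
    masked <- activity$voxels * sel
    k <- resample_kernel(kernels[[t]], activity$geometry$spacing)
    out <- out + convolve_array(masked, k, method)
  }
  if (density_correction) {
    if (is.null(map)) stop("density_correction requires the tissue_map")
    rho <- array(tissue_density(map, as.vector(labels)), dim(out))
    out <- out * (1.0 / rho)
  }
  image_volume(out, activity$geometry, activity$modality, "dose_rate")
}

#' Cumulative dose-volume histogram
#'
#' Fraction of the VOI volume receiving at least each dose level, over
#' `n_bins` equal-width bins from 0 to the VOI's maximum dose.
#'
#' @param dose an [image_volume()] (dose rate or dose).
#' @param voi a nonempty [voi_mask()] on the same grid.
#' @param n_bins number of bins (default 200).
#' @return An object of class `dvh_curve`: list with `dose_edges`
#'   (length `n_bins + 1`), `volume_fraction` (same length, non-increasing,
#'   starting at 1), `volume_ml`, `mean`, `min`, `max`, `total`, `name`.
#' @export
compute_dvh <- function(dose, voi, n_bins = 200L) {
  stop_if_geometry_mismatch(dose$geometry, voi$geometry, "dose and VOI")
  v <- dose$voxels[voi$mask]
  if (!length(v)) stop(sprintf("VOI '%s' is empty", voi$name))
  top <- max(v)
  edges <- seq(0, if (top > 0) top else 1, length.out = n_bins + 1L)
  frac <- vapply(edges, function(e) mean(v >= e), numeric(1))
  frac[1] <- 1.0  # by definition every voxel receives >= 0 dose
  structure(list(dose_edges = edges, volume_fraction = frac,
                 volume_ml = length(v) * voxel_volume_ml(dose$geometry),
                 mean = mean(v), min = min(v), max = top, total = sum(v),
                 name = voi$name),
            class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("DVH '%s': %.3f ml | mean %.4g | min %.4g | max %.4g\n",
              x$name, x$volume_ml, x$mean, x$min, x$max))
  invisible(x)
}

#' Mean dose reconstructed from a DVH curve
#'
#' Trapezoidal integral of the cumulative curve; matches the voxelwise mean
#' up to binning error.
#'
#' @param dvh a `dvh_curve`.
#' @return numeric scalar.
#' @export
dvh_mean <- function(dvh) {
  e <- dvh$dose_edges; f <- dvh$volume_fraction
  sum(diff(e) * (utils::head(f, -1) + utils::tail(f, -1)) / 2)
}

#' Export DVH curves as CSV
#'
#' One summary row per curve (volume ml, mean, total dose, min, max) plus, in
#' `curves = TRUE` mode, the full cumulative curves in long format.
#'
#' @param dvhs list of `dvh_curve`.
#' @param path output file.
#' @param curves write the full curves instead of the summary table.
#' @return the path, invisibly.
#' @export
write_dvh_csv <- function(dvhs, path, curves = FALSE) {
  if (curves) {
    df <- do.call(rbind, lapply(dvhs, function(d)
      data.frame(name = d$name, dose = d$dose_edges,
                 volume_fraction = d$volume_fraction,
                 stringsAsFactors = FALSE)))
  } else {
    df <- do.call(rbind, lapply(dvhs, function(d)
      data.frame(name = d$name, volume_ml = d$volume_ml, mean = d$mean,
                 total = d$total, min = d$min, max = d$max,
                 stringsAsFactors = FALSE)))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a tissue map as a config file
#'
#' Plain-text format: lines `hu_lower hu_upper tissue density_g_ml`, comments
#' with `#`.
#'
#' @param path file path.
#' @param map a [tissue_map()].
#' @export
read_tissue_map <- function(path) {
  ln <- readLines(path)
  ln <- trimws(sub("#.*", "", ln))
  ln <- ln[nzchar(ln)]
  parts <- strsplit(ln, "[[:space:],]+")
  entries <- data.frame(
    hu_lower = vapply(parts, function(p) as.numeric(p[1]), numeric(1)),
    hu_upper = vapply(parts, function(p) as.numeric(p[2]), numeric(1)),
    tissue = vapply(parts, `[`, "", 3),
    density_g_ml = vapply(parts, function(p) as.numeric(p[4]), numeric(1)),
    stringsAsFactors = FALSE)
  tissue_map(entries, default_tissue = entries$tissue[
    which.min(abs((entries$hu_lower + entries$hu_upper) / 2))])
}

#' @rdname read_tissue_map
#' @export
write_tissue_map <- function(map, path) {
  writeLines(c("# hu_lower hu_upper tissue density_g_ml",
               sprintf("%g %g %s %g", map$entries$hu_lower,
                       map$entries$hu_upper, map$entries$tissue,
                       map$entries$density_g_ml)), path)
  invisible(path)
}
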