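#' Phantom specification
#'
#' Declarative description of a synthetic test volume: a background value
#' plus a list of shapes in patient mm. Every fixture in the test suite is
#' built this way — nothing is downloaded or bundled.
#'
#' Shape lists: `list(type = "sphere", center = c(x,y,z), radius = r,
#' value = v)`, `list(type = "ellipsoid", center, semiaxes = c(a,b,c),
#' value)`, `list(type = "box", center, size = c(lx,ly,lz), value)`,
#' `list(type = "gaussian_blob", center, sigma (mm, scalar or length 3),
#' peak)`.
#'
#' A voxel takes a solid shape's value iff its center is inside (no
#' antialiasing), so brute-force oracles are exact; overlapping solid shapes
#' resolve last-writer-wins. Gaussian blobs add to the running image
#' (activity is additive), so a blob's realized maximum slightly exceeds its
#' nominal peak when blobs overlap.
#'
#' @param dims,spacing,origin grid geometry (see [grid_geometry()]).
#' @param background background voxel value.
#' @param shapes list of shape descriptions.
#' @param noise `"none"`, `"gaussian"` or `"poisson"`.
#' @param noise_sd standard deviation for Gaussian noise.
#' @param seed integer seed fixing all randomness.
#' @param modality,value_kind passed to [image_volume()].
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dims, spacing = c(1, 1, 1), origin = NULL,
                         background = 0, shapes = list(),
                         noise = c("none", "gaussian", "poisson"),
                         noise_sd = 0, seed = 1L, modality = "OT",
                         value_kind = "unitless") {
  noise <- match.arg(noise)
  if (is.null(origin)) origin <- -(as.numeric(dims) - 1) / 2 * spacing
  structure(list(dims = as.integer(dims), spacing = as.numeric(spacing),
                 origin = as.numeric(origin), background = background,
                 shapes = shapes, noise = noise, noise_sd = noise_sd,
                 seed = as.integer(seed), modality = modality,
                 value_kind = value_kind),
            class = "phantom_spec")
}

#' Read / write a phantom specification as a YAML config file
#'
#' @param path file path.
#' @param spec a [phantom_spec()].
#' @return `read_phantom_spec` returns a [phantom_spec()].
#' @export
read_phantom_spec <- function(path) {
  y <- yaml::read_yaml(path)
  shapes <- lapply(y$shapes, function(s) {
    s$center <- as.numeric(s$center)
    if (!is.null(s$size)) s$size <- as.numeric(s$size)
    if (!is.null(s$semiaxes)) s$semiaxes <- as.numeric(s$semiaxes)
    s
  })
  phantom_spec(dims = as.integer(y$dims), spacing = as.numeric(y$spacing),
               origin = if (!is.null(y$origin)) as.numeric(y$origin),
               background = if (is.null(y$background)) 0 else y$background,
               shapes = shapes,
               noise = if (is.null(y$noise)) "none" else y$noise,
               noise_sd = if (is.null(y$noise_sd)) 0 else y$noise_sd,
               seed = if (is.null(y$seed)) 1L else y$seed,
               modality = if (is.null(y$modality)) "OT" else y$modality,
               value_kind = if (is.null(y$value_kind)) "unitless" else
                 y$value_kind)
}

#' @rdname read_phantom_spec
#' @export
write_phantom_spec <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' Generate a phantom volume with analytic ground truth
#'
#' Deterministic given the spec's seed. The returned volume carries a
#' `"ground_truth"` attribute: per shape, the analytic volume (ml), the
#' voxelized volume (ml), the voxel count, the maximum value and the analytic
#' centroid (mm).
#'
#' @param spec a [phantom_spec()].
#' @return An [image_volume()] with attribute `"ground_truth"`.
#' @export
make_phantom <- function(spec) {
  g <- grid_geometry(spec$dims, spec$spacing, spec$origin)
  pts <- all_voxel_centers(g)
  v <- rep(as.numeric(spec$background), nrow(pts))
  gt <- list()
  for (s in spec$shapes) {
    ctr <- as.numeric(s$center)
    dd <- sweep(pts, 2, ctr)
    if (s$type == "sphere") {
      inside <- rowSums(dd^2) <= s$radius^2
      v[inside] <- s$value
      gt[[length(gt) + 1]] <- list(
        type = "sphere", analytic_volume_ml = 4 / 3 * pi * s$radius^3 / 1000,
        voxel_volume_ml = sum(inside) * voxel_volume_ml(g),
        voxel_count = sum(inside), max = s$value, centroid = ctr)
    } else if (s$type == "ellipsoid") {
      ax <- as.numeric(s$semiaxes)
      inside <- rowSums(sweep(dd, 2, ax, `/`)^2) <= 1
      v[inside] <- s$value
      gt[[length(gt) + 1]] <- list(
        type = "ellipsoid", analytic_volume_ml = 4 / 3 * pi * prod(ax) / 1000,
        voxel_volume_ml = sum(inside) * voxel_volume_ml(g),
        voxel_count = sum(inside), max = s$value, centroid = ctr)
    } else if (s$type == "box") {
      half <- as.numeric(s$size) / 2
      inside <- abs(dd[, 1]) <= half[1] & abs(dd[, 2]) <= half[2] &
        abs(dd[, 3]) <= half[3]
      v[inside] <- s$value
      gt[[length(gt) + 1]] <- list(
        type = "box", analytic_volume_ml = prod(s$size) / 1000,
        voxel_volume_ml = sum(inside) * voxel_volume_ml(g),
        voxel_count = sum(inside), max = s$value, centroid = ctr)
    } else if (s$type == "gaussian_blob") {
      sg <- rep(as.numeric(s$sigma), length.out = 3)
      blob <- s$peak * exp(-rowSums(sweep(dd, 2, sg, `/`)^2) / 2)
      v <- v + blob  # activity adds; nominal peak is per-blob
      gt[[length(gt) + 1]] <- list(
        type = "gaussian_blob", peak = s$peak, sigma = sg, centroid = ctr)
    } else stop(sprintf("unknown shape type '%s'", s$type))
  }
  if (spec$noise != "none") {
    set.seed(spec$seed)
    v <- switch(spec$noise,
                gaussian = v + stats::rnorm(length(v), 0, spec$noise_sd),
                poisson = stats::rpois(length(v), pmax(v, 0)))
  }
  vol <- image_volume(array(v, spec$dims), g, spec$modality, spec$value_kind)
  attr(vol, "ground_truth") <- gt
  vol
}

#' Conjugate anterior/posterior planar pair
#'
#' Two planar projections of the same activity distribution as a gamma
#' camera sees them: the posterior view is the anterior view mirrored
#' left-right, optionally displaced by a known pixel shift (center-of-
#' rotation error). Useful as a fixture for the conjugate-view geometric
#' mean.
#'
#' @param spec a [phantom_spec()] with `dims[3] == 1` (planar).
#' @param shift_px integer (x, y) pixel displacement applied to the posterior
#'   view.
#' @return A list with `ant` and `post` (planar [image_volume()]s) and
#'   `shift_px`.
#' @export
make_conjugate_pair <- function(spec, shift_px = c(0L, 0L)) {
  base <- make_phantom(spec)
  ant <- base
  post_v <- base$voxels[dim(base$voxels)[1]:1, , , drop = FALSE]  # mirrored
  post_v <- shift_array(post_v, c(as.integer(shift_px), 0L))
  post <- vol_like(base, post_v)
  list(ant = ant, post = post, shift_px = as.integer(shift_px))
}

#' Synthetic thorax CT
#'
#' Background air at -1000 HU, an elliptical body at +40 HU, and two lung
#' ellipsoids at -800 HU with known analytic volumes — the fixture for lung
#' segmentation.
#'
#' @param dims,spacing grid shape, default 64 x 48 x 40 voxels at
#'   4 x 4 x 5 mm.
#' @return An [image_volume()] in HU with attribute `"ground_truth"` holding
#'   per-lung analytic volumes (ml) and centers.
#' @export
make_thorax_ct <- function(dims = c(64, 48, 40), spacing = c(4, 4, 5)) {
  ext <- dims * spacing
  body_ax <- c(ext[1] * 0.42, ext[2] * 0.36, ext[3] * 0.55)
  lung_ax <- c(ext[1] * 0.14, ext[2] * 0.22, ext[3] * 0.32)
  lx <- ext[1] * 0.20
  spec <- phantom_spec(
    dims, spacing, background = -1000,
    shapes = list(
      list(type = "ellipsoid", center = c(0, 0, 0), semiaxes = body_ax,
           value = 40),
      list(type = "ellipsoid", center = c(+lx, 0, 0), semiaxes = lung_ax,
           value = -800),  # patient left (+x in LPS)
      list(type = "ellipsoid", center = c(-lx, 0, 0), semiaxes = lung_ax,
           value = -800)),
    modality = "CT", value_kind = "HU")
  vol <- make_phantom(spec)
  gt <- attr(vol, "ground_truth")
  attr(vol, "ground_truth") <- list(
    left = list(volume_ml = gt[[2]]$voxel_volume_ml,
                analytic_volume_ml = gt[[2]]$analytic_volume_ml,
                center = c(+lx, 0, 0)),
    right = list(volume_ml = gt[[3]]$voxel_volume_ml,
                 analytic_volume_ml = gt[[3]]$analytic_volume_ml,
                 center = c(-lx, 0, 0)))
  vol
}

#' Synthetic multi-peak PET
#'
#' Gaussian lesions with configurable peak ratios on a zero background — the
#' fixture for the total-tumor-burden workflow. Two blobs placed
#' `separation_mm` apart merge into one candidate object at the 10% growing
#' threshold while separating at the 42% local threshold (for the default
#' sigma = 6 mm and separation = 20 mm).
#'
#' @param peaks numeric vector of blob peak values (SUV).
#' @param centers n x 3 matrix of blob centers (mm); default places them
#'   along +x `separation_mm` apart.
#' @param sigma_mm Gaussian sigma per blob (recycled).
#' @param separation_mm default center spacing along x.
#' @param dims,spacing grid shape (default 64^3 at 2 mm).
#' @return An [image_volume()] in SUV with attribute `"ground_truth"`.
#' @export
make_multipeak_pet <- function(peaks = c(10, 5), centers = NULL,
                               sigma_mm = 6, separation_mm = 20,
                               dims = c(64, 64, 64), spacing = c(2, 2, 2)) {
  n <- length(peaks)
  if (is.null(centers)) {
    x0 <- -(n - 1) / 2 * separation_mm
    centers <- cbind(x0 + (seq_len(n) - 1) * separation_mm, 0, 0)
  }
  sig <- rep(sigma_mm, length.out = n)
  shapes <- lapply(seq_len(n), function(i)
    list(type = "gaussian_blob", center = centers[i, ], sigma = sig[i],
         peak = peaks[i]))
  spec <- phantom_spec(dims, spacing, background = 0, shapes = shapes,
                       modality = "PT", value_kind = "SUV")
  make_phantom(spec)
}
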