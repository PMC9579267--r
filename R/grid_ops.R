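#' Resample a volume onto a reference grid
#'
#' Samples the moving volume in patient space at every voxel center of the
#' reference geometry. This is the operation behind fusing one modality onto
#' another's matrix and behind up/down-sampling thick-slice series onto a
#' thin-slice reference.
#'
#' @param moving an [image_volume()].
#' @param ref a [grid_geometry()] (or an `image_volume`, whose geometry is
#'   used).
#' @param interpolation one of `"nearest"`, `"linear"`, `"cubic"`,
#'   `"bilinear"`, `"bicubic"`. The 2-D modes interpolate within slices only.
#' @param fill value assigned outside the moving volume's support; defaults
#'   to -1000 for HU volumes and 0 otherwise.
#' @return An [image_volume()] on the reference grid.
#' @export
resample_to_reference <- function(moving, ref, interpolation = "linear",
                                  fill = default_fill(moving)) {
  check_interp(interpolation)
  if (inherits(ref, "image_volume")) ref <- ref$geometry
  if (same_geometry(moving$geometry, ref)) {
    out <- moving; out$geometry <- ref
    return(out)
  }
  pts <- all_voxel_centers(ref)
  vals <- sample_at_world(moving, pts, interpolation, fill)
  image_volume(array(vals, dim = ref$dims), ref, moving$modality,
               moving$value_kind)
}

# Patient-position codes: columns of each matrix give the patient-space (LPS)
# direction of the scanner's x, y, z axes for an axial acquisition in that
# position. Gantry +y points toward the table (down), +z toward the gantry
# bore's far end.
PATIENT_POSITIONS <- list(
  HFS  = diag(3),                                        # head first supine
  FFS  = diag(c(-1, 1, -1)),                             # feet first supine
  HFP  = diag(c(-1, -1, 1)),                             # head first prone
  FFP  = diag(c(1, -1, -1)),                             # feet first prone
  HFDL = matrix(c(0, -1, 0,  1, 0, 0,  0, 0, 1), 3, 3),  # head first, left side down
  HFDR = matrix(c(0, 1, 0,  -1, 0, 0,  0, 0, 1), 3, 3),  # head first, right side down
  FFDL = matrix(c(0, 1, 0,   1, 0, 0,  0, 0, -1), 3, 3), # feet first, left side down
  FFDR = matrix(c(0, -1, 0, -1, 0, 0,  0, 0, -1), 3, 3)  # feet first, right side down
)

patient_position_matrix <- function(code) {
  m <- PATIENT_POSITIONS[[toupper(code)]]
  if (is.null(m))
    stop(sprintf("unsupported patient position '%s'; supported: %s", code,
                 paste(names(PATIENT_POSITIONS), collapse = ", ")),
         call. = FALSE)
  m
}

#' Correct a wrongly declared patient orientation
#'
#' When a series was acquired with the patient in position `actual` but the
#' console recorded `declared` (e.g. feet-first recorded as head-first), the
#' anatomy is mirrored/rotated on screen. This permutes and flips the voxel
#' axes so the data are correct under the declared interpretation. Values are
#' never interpolated: the fix is a pure axis permutation/flip. The grid
#' center is kept fixed in patient space.
#'
#' @param vol an [image_volume()].
#' @param declared,actual patient-position codes: HFS, FFS, HFP, FFP, or the
#'   decubitus codes HFDL, HFDR, FFDL, FFDR.
#' @return The corrected [image_volume()].
#' @export
reorient <- function(vol, declared, actual) {
  Pd <- patient_position_matrix(declared)
  Pa <- patient_position_matrix(actual)
  R <- t(Pd) %*% Pa   # signed permutation in grid-axis space
  if (max(abs(R - diag(3))) < 1e-12) return(vol)
  # new grid axis b draws from old axis perm[b], reversed when sgn[b] < 0
  perm <- apply(abs(R), 2, which.max)
  sgn <- R[cbind(perm, 1:3)]
  v <- aperm(vol$voxels, perm)
  idx <- lapply(1:3, function(b) {
    n <- dim(v)[b]
    if (sgn[b] < 0) n:1 else 1:n
  })
  v <- v[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  g <- vol$geometry
  new_spacing <- g$spacing[perm]
  new_dims <- g$dims[perm]
  # keep the volume center fixed in patient space; direction is retained as
  # declared (the whole point is that the header becomes truthful)
  center <- g$origin + g$direction %*% (g$spacing * (g$dims - 1) / 2)
  new_origin <- as.numeric(center - g$direction %*% (new_spacing * (new_dims - 1) / 2))
  image_volume(v, grid_geometry(new_dims, new_spacing, new_origin, g$direction),
               vol$modality, vol$value_kind)
}

#' Reslice a volume along an arbitrary oblique plane
#'
#' Extracts a 2-D plane (or a stack of parallel planes) sampled at the given
#' in-plane spacing, with the chosen interpolation.
#'
#' @param vol an [image_volume()].
#' @param plane_origin mm position of the output plane's first sample.
#' @param plane_axes 2 x 3 (or list of two) orthonormal mm direction vectors
#'   spanning the plane.
#' @param out_spacing length-2 in-plane sample spacing in mm (a third element
#'   gives the spacing between stacked planes).
#' @param out_dims length-2 sample counts (third element = number of stacked
#'   planes, default 1).
#' @param interpolation interpolation mode, default `"linear"`.
#' @param fill out-of-support fill value.
#' @return An [image_volume()] whose grid axes are the plane axes (k = plane
#'   normal).
#' @export
reslice_oblique <- function(vol, plane_origin, plane_axes, out_spacing,
                            out_dims, interpolation = "linear",
                            fill = default_fill(vol)) {
  if (is.list(plane_axes)) plane_axes <- rbind(plane_axes[[1]], plane_axes[[2]])
  u <- as.numeric(plane_axes[1, ]); v <- as.numeric(plane_axes[2, ])
  if (abs(sum(u * u) - 1) > 1e-6 || abs(sum(v * v) - 1) > 1e-6 ||
      abs(sum(u * v)) > 1e-6)
    stop("plane axes must be orthonormal unit vectors")
  nrm <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
  if (length(out_dims) < 3) out_dims <- c(out_dims, 1)
  if (length(out_spacing) < 3) out_spacing <- c(out_spacing, 1)
  geom <- grid_geometry(out_dims, out_spacing, plane_origin, cbind(u, v, nrm))
  resample_to_reference(vol, geom, interpolation, fill)
}

#' Maximum intensity projection
#'
#' Per-ray maximum along a grid axis or an arbitrary direction. Axis-aligned
#' projections are exact per-axis maxima; oblique directions are ray-sampled
#' at half-voxel steps with linear interpolation.
#'
#' @param vol an [image_volume()].
#' @param direction `"i"`, `"j"`, `"k"` (grid axes), `"x"`, `"y"`, `"z"`
#'   (synonyms), or a length-3 patient-space direction vector.
#' @return A 2-D matrix of per-ray maxima (for axis projections, the
#'   remaining two grid axes in order).
#' @export
mip <- function(vol, direction = "k") {
  if (is.character(direction)) {
    ax <- match(tolower(direction), c("i", "j", "k", "x", "y", "z"))
    if (is.na(ax)) stop("unknown axis name")
    ax <- ((ax - 1) %% 3) + 1
    return(apply(vol$voxels, setdiff(1:3, ax), max))
  }
  dirw <- as.numeric(direction)
  nd <- sqrt(sum(dirw^2))
  if (nd == 0) stop("direction must be nonzero")
  dirw <- dirw / nd
  # build an orthonormal basis (u, v, dirw) and project the volume's corner
  # extent onto it
  seed <- if (abs(dirw[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- seed - sum(seed * dirw) * dirw; u <- u / sqrt(sum(u * u))
  v <- c(dirw[2] * u[3] - dirw[3] * u[2], dirw[3] * u[1] - dirw[1] * u[3],
         dirw[1] * u[2] - dirw[2] * u[1])
  g <- vol$geometry
  corners <- as.matrix(expand.grid(c(0, g$dims[1] - 1), c(0, g$dims[2] - 1),
                                   c(0, g$dims[3] - 1)))
  cw <- voxel_to_world(g, corners, check = FALSE)
  B <- cbind(u, v, dirw)
  pc <- cw %*% B
  step <- min(g$spacing) / 2
  su <- seq(min(pc[, 1]), max(pc[, 1]), by = step)
  sv <- seq(min(pc[, 2]), max(pc[, 2]), by = step)
  sw <- seq(min(pc[, 3]), max(pc[, 3]), by = step)
  out <- matrix(-Inf, length(su), length(sv))
  base <- as.matrix(expand.grid(su, sv))
  for (w in sw) {
    pts <- cbind(base[, 1], base[, 2], w) %*% t(B)
    vals <- sample_at_world(vol, pts, "linear", fill = -Inf)
    out <- pmax(out, matrix(vals, length(su), length(sv)))
  }
  out[!is.finite(out)] <- min(vol$voxels)
  out
}
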