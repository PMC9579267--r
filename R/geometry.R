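#' Grid geometry of a voxel volume
#'
#' Describes where a voxel grid sits in patient space. The frame is DICOM
#' patient LPS (+x left, +y posterior, +z superior), millimetres. Voxel
#' indices are 0-based and `origin` is the patient-space position of the
#' *center* of voxel (0,0,0), matching DICOM ImagePositionPatient semantics.
#'
#' @param dims integer vector of length 3: voxel counts along (i,j,k).
#' @param spacing numeric vector of length 3: voxel size in mm, all > 0.
#' @param origin numeric vector of length 3: mm position of the center of the
#'   first voxel.
#' @param direction 3x3 orthonormal matrix of direction cosines; column `a`
#'   is the patient-space direction of grid axis `a`.
#' @return An object of class `grid_geometry`.
#' @export
grid_geometry <- function(dims, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                          direction = diag(3)) {
  dims <- as.integer(dims)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  direction <- matrix(as.numeric(direction), 3, 3)
  stopifnot(length(dims) == 3, length(spacing) == 3, length(origin) == 3)
  if (any(dims < 1L)) stop("dims must be positive integers")
  if (any(spacing <= 0)) stop("spacing must be strictly positive")
  if (max(abs(crossprod(direction) - diag(3))) > 1e-6)
    stop("direction matrix must be orthonormal")
  structure(list(dims = dims, spacing = spacing, origin = origin,
                 direction = direction),
            class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat("grid_geometry:", paste(x$dims, collapse = " x "),
      "voxels @", paste(signif(x$spacing, 4), collapse = " x "), "mm\n")
  cat("  origin (mm):", paste(signif(x$origin, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Compare two geometries for equality within tolerance
#' @param a,b `grid_geometry` objects.
#' @param tol numeric tolerance in mm / dimensionless for cosines.
#' @return logical scalar.
#' @export
same_geometry <- function(a, b, tol = 1e-6) {
  identical(a$dims, b$dims) &&
    max(abs(a$spacing - b$spacing)) <= tol &&
    max(abs(a$origin - b$origin)) <= tol &&
    max(abs(a$direction - b$direction)) <= tol
}

stop_if_geometry_mismatch <- function(a, b, what = "volumes") {
  if (!same_geometry(a, b))
    stop(sprintf("%s are on different grids; resample one to the other's geometry first",
                 what), call. = FALSE)
  invisible(TRUE)
}

#' Map voxel indices to patient-space coordinates
#'
#' Voxel-center convention: `world = origin + direction %*% (spacing * index)`
#' with 0-based indices.
#'
#' @param geom a `grid_geometry`.
#' @param index a length-3 integer vector or an n x 3 matrix of 0-based
#'   voxel indices.
#' @param check if TRUE (default), indices must lie within the grid.
#' @return A length-3 numeric vector, or an n x 3 matrix, of mm coordinates.
#' @export
voxel_to_world <- function(geom, index, check = TRUE) {
  vec <- is.null(dim(index))
  idx <- if (vec) matrix(as.numeric(index), 1, 3) else
    matrix(as.numeric(index), ncol = 3)
  if (check) {
    for (a in 1:3)
      if (any(idx[, a] < 0 | idx[, a] > geom$dims[a] - 1L))
        stop(sprintf("voxel index out of range along axis %d", a))
  }
  w <- sweep(idx, 2, geom$spacing, `*`) %*% t(geom$direction)
  w <- sweep(w, 2, geom$origin, `+`)
  if (vec) as.numeric(w[1, ]) else w
}

#' Map patient-space coordinates to continuous voxel indices
#'
#' Inverse of [voxel_to_world()]; returns fractional 0-based indices (not
#' rounded, not clipped).
#'
#' @param geom a `grid_geometry`.
#' @param world a length-3 numeric vector or an n x 3 matrix of mm points.
#' @return Continuous 0-based indices, same shape convention as the input.
#' @export
world_to_voxel <- function(geom, world) {
  vec <- is.null(dim(world))
  w <- if (vec) matrix(as.numeric(world), 1, 3) else
    matrix(as.numeric(world), ncol = 3)
  w <- sweep(w, 2, geom$origin, `-`) %*% geom$direction # t(D^-1) = D for orthonormal
  idx <- sweep(w, 2, geom$spacing, `/`)
  if (vec) as.numeric(idx[1, ]) else idx
}

#' Physical volume of one voxel in ml
#' @param geom a `grid_geometry`.
#' @return numeric scalar, ml (1 ml = 1000 mm^3).
#' @export
voxel_volume_ml <- function(geom) prod(geom$spacing) / 1000

# world coordinates of every voxel center, as an (prod(dims) x 3) matrix in
# R array order (i fastest)
all_voxel_centers <- function(geom) {
  d <- geom$dims
  ii <- rep.int(seq_len(d[1]) - 1L, d[2] * d[3])
  jj <- rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3])
  kk <- rep(seq_len(d[3]) - 1L, each = d[1] * d[2])
  voxel_to_world(geom, cbind(ii, jj, kk), check = FALSE)
}
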