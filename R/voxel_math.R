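#' Voxelwise arithmetic between volumes
#'
#' Elementwise arithmetic between two volumes on the same grid, or between a
#' volume and a scalar. Division by zero yields 0, and the number of affected
#' voxels is recorded in attribute `"div_by_zero"` of the result.
#'
#' @param a an [image_volume()].
#' @param b an [image_volume()] on the same grid, or a scalar.
#' @param op `"add"`, `"sub"`, `"mul"`, `"div"`, or a unary function name
#'   `"sqrt"`, `"log"`, `"exp"` applied to `a` (with `b` ignored).
#' @return An [image_volume()].
#' @export
voxelwise <- function(a, b = NULL, op = c("add", "sub", "mul", "div",
                                          "sqrt", "log", "exp")) {
  op <- match.arg(op)
  if (op %in% c("sqrt", "log", "exp")) {
    f <- match.fun(op)
    return(vol_like(a, f(a$voxels), value_kind = "unitless"))
  }
  bv <- if (inherits(b, "image_volume")) {
    stop_if_geometry_mismatch(a$geometry, b$geometry)
    b$voxels
  } else {
    if (!is.numeric(b) || length(b) != 1L) stop("b must be a volume or a scalar")
    b
  }
  out <- switch(op,
    add = a$voxels + bv,
    sub = a$voxels - bv,
    mul = a$voxels * bv,
    div = {
      z <- array(bv == 0, dim(a$voxels))
      r <- a$voxels / (bv + z)  # add 1 where zero, then overwrite
      r[z] <- 0
      attr(r, "nz") <- sum(z)
      r
    })
  nz <- attr(out, "nz"); attr(out, "nz") <- NULL
  res <- vol_like(a, array(as.numeric(out), dim(a$voxels)))
  if (op == "div") attr(res, "div_by_zero") <- if (length(nz)) nz else 0L
  res
}

#' Conjugate-view geometric mean
#'
#' Combines anterior and posterior planar gamma-camera views: the anterior
#' frame is left-right flipped, optionally translation-registered to the
#' posterior (to correct center-of-rotation displacement), and the pixelwise
#' geometric mean `sqrt(ANT_flipped * POST)` is formed. Negative inputs are
#' clamped to zero before the product.
#'
#' @param ant,post planar [image_volume()] objects (single-slice volumes or
#'   slice stacks) with matching array shapes.
#' @param coregister if TRUE (default), an integer-pixel translation aligning
#'   the flipped anterior to the posterior is estimated by cross-correlation
#'   and applied before the mean.
#' @return An [image_volume()] on the posterior grid; attribute
#'   `"applied_shift"` holds the pixel shift used.
#' @export
geometric_mean <- function(ant, post, coregister = TRUE) {
  if (!identical(dim(ant$voxels), dim(post$voxels)))
    stop("anterior and posterior frames have mismatched shapes after flip")
  a <- ant$voxels[dim(ant$voxels)[1]:1, , , drop = FALSE]  # L-R flip
  shift <- c(0L, 0L)
  if (coregister) {
    am <- a - mean(a); pm <- post$voxels - mean(post$voxels)
    cc <- Re(fft(fft(pm) * Conj(fft(am)), inverse = TRUE))
    d <- dim(cc)
    sh <- which(cc == max(cc), arr.ind = TRUE)[1, ] - 1L
    sh <- ifelse(sh > d / 2, sh - d, sh)
    shift <- as.integer(unname(sh[1:2]))
    a <- shift_array(a, c(shift, 0L))
  }
  out <- sqrt(pmax(a, 0) * pmax(post$voxels, 0))
  res <- vol_like(post, out)
  attr(res, "applied_shift") <- shift
  res
}

# integer shift with zero fill (positive shift moves content toward higher
# indices)
shift_array <- function(x, sh) {
  d <- dim(x)
  out <- array(0, d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    s <- sh[a]
    if (abs(s) >= d[a]) return(out)
    if (s >= 0) { src[[a]] <- 1:(d[a] - s); dst[[a]] <- (1 + s):d[a] }
    else { src[[a]] <- (1 - s):d[a]; dst[[a]] <- 1:(d[a] + s) }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  out
}

#' Gaussian post-filter
#'
#' Convolution with a Gaussian of the given full width at half maximum in mm,
#' converted per axis by the voxel spacing. `mode = "2D"` filters within
#' slices only. The kernel is normalized to unit sum so interior counts are
#' preserved.
#'
#' @param vol an [image_volume()].
#' @param fwhm_mm full width at half maximum, mm, >= 0 (0 = identity).
#' @param mode `"3D"` (default) or `"2D"`.
#' @return The filtered [image_volume()].
#' @export
gaussian_filter <- function(vol, fwhm_mm, mode = c("3D", "2D")) {
  mode <- match.arg(mode)
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0")
  if (fwhm_mm == 0) return(vol)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  axes <- if (mode == "2D") 1:2 else 1:3
  v <- vol$voxels
  for (a in axes) {
    s_vox <- sigma_mm / vol$geometry$spacing[a]
    r <- max(1L, ceiling(4 * s_vox))
    k <- exp(-((-r:r)^2) / (2 * s_vox^2))
    k <- k / sum(k)
    kd <- c(1L, 1L, 1L); kd[a] <- 2L * r + 1L
    v <- convolve_array(v, array(k, kd))
  }
  vol_like(vol, v)
}

# zero-padded linear convolution of a 3-D array with a (small, odd-dims)
# kernel; method "fft" (default) or "direct" (shift-and-add, the slow
# reference path)
convolve_array <- function(x, k, method = c("fft", "direct")) {
  method <- match.arg(method)
  dk <- dim(k); dx <- dim(x)
  if (any(dk %% 2 == 0)) stop("kernel dims must be odd")
  if (any(dk > 2 * dx - 1)) stop("kernel is larger than the image")
  if (method == "direct") {
    out <- array(0, dx)
    c0 <- (dk + 1L) %/% 2L
    for (ik in seq_len(dk[1])) for (jk in seq_len(dk[2])) for (kk in seq_len(dk[3])) {
      w <- k[ik, jk, kk]
      if (w == 0) next
      out <- out + w * shift_array(x, c(ik, jk, kk) - c0)
    }
    return(out)
  }
  dp <- dx + dk - 1L
  xp <- array(0, dp); xp[1:dx[1], 1:dx[2], 1:dx[3]] <- x
  kp <- array(0, dp); kp[1:dk[1], 1:dk[2], 1:dk[3]] <- k
  full <- Re(fft(fft(xp) * fft(kp), inverse = TRUE)) / prod(dp)
  off <- (dk - 1L) %/% 2L
  full[off[1] + 1:dx[1], off[2] + 1:dx[2], off[3] + 1:dx[3], drop = FALSE]
}

#' User-defined 3-D convolution kernel
#'
#' A kernel carries its own grid spacing; before use it is resampled onto the
#' image grid (see [convolve_volume()]).
#'
#' @param values 3-D numeric array with odd dims per axis (centered).
#' @param spacing mm per axis, > 0.
#' @param normalization `"preserve_sum"` (total kernel weight is preserved
#'   under resampling; the right choice for dose kernels) or `"none"`.
#' @return An object of class `kernel3d`.
#' @export
kernel3d <- function(values, spacing = c(1, 1, 1),
                     normalization = c("preserve_sum", "none")) {
  values <- as.array(values)
  if (length(dim(values)) == 2L) dim(values) <- c(dim(values), 1L)
  if (any(as.numeric(spacing) <= 0)) stop("kernel spacing must be > 0")
  structure(list(values = values, spacing = as.numeric(spacing),
                 normalization = match.arg(normalization)),
            class = "kernel3d")
}

#' Delta (identity) kernel
#' @param spacing mm per axis.
#' @param value central value (default 1).
#' @return A [kernel3d()].
#' @export
delta_kernel <- function(spacing = c(1, 1, 1), value = 1)
  kernel3d(array(value, c(1, 1, 1)), spacing)

# resample a kernel from its native spacing onto image spacing; output dims
# odd, centered; preserve_sum rescales by the voxel-volume ratio
resample_kernel <- function(kernel, target_spacing, interpolation = "linear") {
  ks <- kernel$spacing
  if (max(abs(ks - target_spacing)) < 1e-9) return(kernel$values)
  dk <- dim(kernel$values)
  half_extent <- (dk - 1) / 2 * ks
  nd <- 2L * as.integer(floor(half_extent / target_spacing + 1e-9)) + 1L
  kg <- grid_geometry(dk, ks, origin = -half_extent)
  kvol <- image_volume(kernel$values, kg)
  og <- grid_geometry(nd, target_spacing, origin = -(nd - 1) / 2 * target_spacing)
  out <- resample_to_reference(kvol, og, interpolation, fill = 0)$voxels
  if (kernel$normalization == "preserve_sum") {
    s_old <- sum(kernel$values)
    s_new <- sum(out)
    if (s_new != 0) out <- out * (s_old / s_new)
  }
  out
}

#' Convolve a volume with a user-defined kernel
#'
#' The kernel is first resampled from its native spacing onto the image's
#' voxel spacing (with `preserve_sum` normalization the total kernel weight
#' is unchanged), then linearly convolved with the image under zero-padding
#' boundaries. With a mask, the input is zeroed outside the mask before
#' convolution (no edge renormalization).
#'
#' @param vol an [image_volume()].
#' @param kernel a [kernel3d()].
#' @param mask optional [voi_mask()] on the volume's grid.
#' @param interpolation mode used to resample the kernel.
#' @param method `"fft"` (default) or `"direct"`.
#' @return The convolved [image_volume()].
#' @export
convolve_volume <- function(vol, kernel, mask = NULL, interpolation = "linear",
                            method = c("fft", "direct")) {
  method <- match.arg(method)
  k <- resample_kernel(kernel, vol$geometry$spacing, interpolation)
  if (any(dim(k) > 2 * vol$geometry$dims - 1))
    stop("kernel is larger than the image after resampling")
  x <- vol$voxels
  if (!is.null(mask)) {
    stop_if_geometry_mismatch(vol$geometry, mask$geometry, "volume and mask")
    x <- x * mask$mask
  }
  vol_like(vol, convolve_array(x, k, method))
}

#' Read / write a kernel as a plain-text file
#'
#' Format: a header line `dims: i j k`, a line `spacing_mm: sx sy sz`, an
#' optional `normalization:` line, then whitespace-separated values in
#' k-then-j-then-i order (i fastest).
#'
#' @param path file path.
#' @param kernel a [kernel3d()].
#' @return `read_kernel` returns a [kernel3d()].
#' @export
read_kernel <- function(path) {
  ln <- readLines(path)
  get <- function(key, default = NULL) {
    m <- grep(paste0("^", key, ":"), ln, value = TRUE)
    if (!length(m)) return(default)
    scan(text = sub(paste0("^", key, ":"), "", m[1]), quiet = TRUE,
         what = character())
  }
  dims <- as.integer(get("dims"))
  spacing <- as.numeric(get("spacing_mm"))
  norm <- get("normalization", "preserve_sum")
  body <- ln[!grepl("^[a-z_]+:", ln) & nzchar(trimws(ln))]
  vals <- scan(text = paste(body, collapse = " "), quiet = TRUE)
  if (length(vals) != prod(dims)) stop("kernel file: value count != prod(dims)")
  kernel3d(array(vals, dims), spacing, norm)
}

#' @rdname read_kernel
#' @export
write_kernel <- function(kernel, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(paste("dims:", paste(dim(kernel$values), collapse = " ")),
               paste("spacing_mm:", paste(kernel$spacing, collapse = " ")),
               paste("normalization:", kernel$normalization)), con)
  writeLines(paste(format(as.numeric(kernel$values), digits = 17),
                   collapse = " "), con)
  invisible(path)
}
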