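#' Transform specification
#'
#' A 4x4 homogeneous patient-space transform mapping reference-space points
#' into the moving volume's space (the resampling convention: to render the
#' moving volume on the reference grid, each reference voxel center is pushed
#' through the matrix and the moving volume is sampled there).
#'
#' @param matrix 4x4 homogeneous transform matrix.
#' @param model `"rigid"`, `"similarity"`, or `"affine"`.
#' @param interpolation interpolation mode used when the transform is applied.
#' @return An object of class `transform_spec`.
#' @export
transform_spec <- function(matrix = diag(4), model = "affine",
                           interpolation = "linear") {
  matrix <- base::matrix(as.numeric(matrix), 4, 4)
  A <- matrix[1:3, 1:3]
  if (model == "rigid") {
    if (max(abs(crossprod(A) - diag(3))) > 1e-4 || det(A) < 0)
      stop("rigid transform requires an orthonormal rotation block with det +1")
  } else if (model == "similarity") {
    s <- det(A)^(1 / 3)
    if (max(abs(crossprod(A / s) - diag(3))) > 1e-4)
      stop("similarity transform requires rotation times uniform scale")
  }
  structure(list(matrix = matrix, model = model,
                 interpolation = check_interp(interpolation)),
            class = "transform_spec")
}

#' @export
print.transform_spec <- function(x, ...) {
  cat(sprintf("transform_spec (%s, %s):\n", x$model, x$interpolation))
  print(signif(x$matrix, 6))
  invisible(x)
}

# parameters -> 4x4: translation t, rotation (Euler xyz, radians), scale
params_to_matrix <- function(t = c(0, 0, 0), angles = c(0, 0, 0), scale = 1) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  M <- diag(4)
  M[1:3, 1:3] <- (Rz %*% Ry %*% Rx) * scale
  M[1:3, 4] <- t
  M
}

#' Apply a transform: render the moving volume on a reference grid
#'
#' @param moving an [image_volume()].
#' @param transform a [transform_spec()].
#' @param ref reference [grid_geometry()] (default: the moving volume's own).
#' @param fill out-of-support fill value.
#' @return An [image_volume()] on `ref`.
#' @export
apply_transform <- function(moving, transform, ref = moving$geometry,
                            fill = default_fill(moving)) {
  if (inherits(ref, "image_volume")) ref <- ref$geometry
  pts <- all_voxel_centers(ref)
  ph <- cbind(pts, 1) %*% t(transform$matrix)
  vals <- sample_at_world(moving, ph[, 1:3, drop = FALSE],
                          transform$interpolation, fill)
  image_volume(array(vals, ref$dims), ref, moving$modality, moving$value_kind)
}

# mean-squared-error metric between ref voxels and transformed moving
# samples; out-of-support samples take the modality's background fill so the
# metric stays smooth at the support boundary (dropping them would bias the
# mean discontinuously)
mse_metric <- function(par, moving, ref_vals, pts, model) {
  M <- switch(model,
    rigid      = params_to_matrix(par[1:3], par[4:6]),
    similarity = params_to_matrix(par[1:3], par[4:6], exp(par[7])),
    affine     = { m <- diag(4); m[1:3, ] <- matrix(par, 3, 4); m })
  ph <- cbind(pts, 1) %*% t(M)
  mv <- sample_at_index(moving$voxels,
                        world_to_voxel(moving$geometry, ph[, 1:3, drop = FALSE]),
                        "linear", fill = default_fill(moving))
  mean((ref_vals - mv)^2)
}

# negative mutual information from a joint histogram (cross-modality metric)
nmi_metric <- function(par, moving, ref_vals, pts, model, nbins = 32) {
  M <- switch(model,
    rigid      = params_to_matrix(par[1:3], par[4:6]),
    similarity = params_to_matrix(par[1:3], par[4:6], exp(par[7])),
    affine     = { m <- diag(4); m[1:3, ] <- matrix(par, 3, 4); m })
  ph <- cbind(pts, 1) %*% t(M)
  mv <- sample_at_index(moving$voxels,
                        world_to_voxel(moving$geometry, ph[, 1:3, drop = FALSE]),
                        "linear", fill = NA_real_)
  ok <- !is.na(mv)
  if (sum(ok) < length(mv) * 0.05) return(1e12)
  a <- ref_vals[ok]; b <- mv[ok]
  ba <- pmin(pmax(findInterval(a, seq(min(a), max(a), length.out = nbins + 1),
                               all.inside = TRUE), 1), nbins)
  bb <- pmin(pmax(findInterval(b, seq(min(b), max(b), length.out = nbins + 1),
                               all.inside = TRUE), 1), nbins)
  h <- table(factor(ba, 1:nbins), factor(bb, 1:nbins)) / length(a)
  px <- rowSums(h); py <- colSums(h)
  nz <- h > 0
  -sum(h[nz] * log(h[nz] / outer(px, py)[nz]))
}

# integer-voxel translation initialization by FFT cross-correlation of the
# two volumes resampled onto a common coarse grid
init_translation <- function(moving, ref) {
  g <- ref$geometry
  a <- ref$voxels - mean(ref$voxels)
  b <- resample_to_reference(moving, g, "linear", fill = 0)$voxels
  b <- b - mean(b)
  d <- dim(a)
  cc <- Re(fft(fft(a) * Conj(fft(b)), inverse = TRUE))
  cc <- abs(cc)  # anticorrelated content (cross-modality) still aligns
  sh <- which(cc == max(cc), arr.ind = TRUE)[1, ] - 1L
  sh <- ifelse(sh > d / 2, sh - d, sh)  # wrap to signed shifts
  # ref(x) ~ moving(x - shift*spacing) => transform translation = -shift
  as.numeric(g$direction %*% (-sh * g$spacing))
}

#' Register a moving volume to a reference
#'
#' Estimates the transform that best maps reference-space points onto the
#' moving volume by minimizing an intensity metric over the reference grid:
#' mean squared error for same-modality pairs, negative mutual information
#' across modalities. Optimization is deterministic: an FFT
#' cross-correlation seeds the translation, then Nelder-Mead refines at a
#' coarse and a fine resolution.
#'
#' @param moving,ref [image_volume()] objects with overlapping support.
#' @param model `"rigid"` (default), `"similarity"`, or `"affine"`.
#' @param interpolation interpolation recorded on the returned transform.
#' @param metric `"auto"` (MSE if modalities match, MI otherwise), `"mse"`,
#'   or `"mi"`.
#' @param max_samples voxel sample budget per resolution level.
#' @return A [transform_spec()].
#' @export
register_volumes <- function(moving, ref, model = c("rigid", "similarity", "affine"),
                             interpolation = "linear",
                             metric = c("auto", "mse", "mi"),
                             max_samples = 12000) {
  model <- match.arg(model)
  metric <- match.arg(metric)
  if (metric == "auto")
    metric <- if (identical(moving$modality, ref$modality)) "mse" else "mi"
  fn <- if (metric == "mse") mse_metric else nmi_metric

  t0 <- init_translation(moving, ref)

  pts_all <- all_voxel_centers(ref$geometry)
  rv_all <- as.numeric(ref$voxels)
  sample_level <- function(stride) {
    keep <- seq(1L, nrow(pts_all), by = stride)
    if (length(keep) > max_samples)
      keep <- keep[round(seq(1, length(keep), length.out = max_samples))]
    list(pts = pts_all[keep, , drop = FALSE], rv = rv_all[keep])
  }
  lv1 <- sample_level(4L)
  lv2 <- sample_level(1L)

  # stage 1: translation-only, multi-start. The sampled MSE surface has
  # grid-commensurate ripple under linear interpolation, so a single descent
  # can sit down in a half-voxel trap; probing a half/full-voxel neighborhood
  # around the correlation peak and descending from the best few escapes it.
  lv <- lv1
  fn_t <- function(p) fn(c(p, 0, 0, 0), moving, lv$rv, lv$pts, "rigid")
  sp <- ref$geometry$spacing
  offsets <- rbind(0, diag(3) * (sp / 2), -diag(3) * (sp / 2),
                   diag(3) * sp, -diag(3) * sp)
  cand <- sweep(offsets, 2, t0, `+`)
  sc <- apply(cand, 1, fn_t)
  starts <- cand[order(sc)[1:3], , drop = FALSE]
  fits <- lapply(seq_len(nrow(starts)), function(i)
    optim(starts[i, ], fn_t, method = "Nelder-Mead",
          control = list(maxit = 200, reltol = 1e-10)))
  t0 <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]$par
  par <- switch(model,
    rigid = c(t0, 0, 0, 0),
    similarity = c(t0, 0, 0, 0, 0),
    affine = { m <- diag(4); m[1:3, 4] <- t0; as.numeric(m[1:3, ]) })
  # stage 2: full model, coarse then fine sampling; parscale balances mm
  # translations against radian rotations / log scale / matrix entries
  pscale <- switch(model,
    rigid = c(rep(1, 3), rep(0.02, 3)),
    similarity = c(rep(1, 3), rep(0.05, 3), 0.1),
    affine = c(rep(0.05, 9), rep(1, 3)))  # 3x3 block then translation
  budgets <- if (model == "rigid") c(500L, 500L) else c(800L, 800L)
  levels <- list(lv1, lv2)
  nm <- function(par, lv, maxit)
    optim(par, fn, moving = moving, ref_vals = lv$rv, pts = lv$pts,
          model = model, method = "Nelder-Mead",
          control = list(maxit = maxit, reltol = 1e-12, parscale = pscale))
  for (lev in 1:2) {
    lv <- levels[[lev]]
    # Nelder-Mead with one restart per level: rebuilding the simplex around
    # the current optimum escapes premature contraction
    for (round in 1:2) par <- nm(par, lv, budgets[lev])$par
    if (lev == 1 && model %in% c("rigid", "similarity")) {
      # the sampled-MSE surface ripples at roughly the voxel scale, leaving
      # nearby local minima about a degree apart; perturbation restarts on
      # the rotation parameters hop between them
      best <- nm(par, lv, 100L)
      for (ax in 4:6) for (dd in c(-0.02, 0.02)) {
        p2 <- par; p2[ax] <- p2[ax] + dd
        cand <- nm(p2, lv, 250L)
        if (cand$value < best$value) best <- cand
      }
      par <- best$par
    }
  }
  # coordinate-wise golden-section polish: one-dimensional searches are
  # robust to the interpolation kinks that stall simplex and quasi-Newton
  # steps near the optimum
  lv <- lv2
  f1 <- function(p) fn(p, moving, lv$rv, lv$pts, model)
  fcur <- f1(par)
  for (cycle in 1:2) {
    for (i in seq_along(par)) {
      w <- 1.5 * pscale[i]
      o <- stats::optimize(function(x) { p <- par; p[i] <- x; f1(p) },
                           lower = par[i] - w, upper = par[i] + w,
                           tol = pscale[i] * 1e-5)
      if (o$objective < fcur) { par[i] <- o$minimum; fcur <- o$objective }
    }
  }
  M <- switch(model,
    rigid      = params_to_matrix(par[1:3], par[4:6]),
    similarity = params_to_matrix(par[1:3], par[4:6], exp(par[7])),
    affine     = { m <- diag(4); m[1:3, ] <- matrix(par, 3, 4); m })
  transform_spec(M, model, interpolation)
}

#' Write / read a transform as a plain-text 4x4 matrix sidecar
#' @param transform a [transform_spec()].
#' @param path file path.
#' @export
write_transform <- function(transform, path) {
  hdr <- sprintf("# voxquant transform: model=%s interpolation=%s",
                 transform$model, transform$interpolation)
  writeLines(c(hdr, apply(format(transform$matrix, digits = 17), 1, paste,
                          collapse = " ")), path)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  ln <- readLines(path)
  hdr <- ln[startsWith(ln, "#")][1]
  model <- sub(".*model=(\\w+).*", "\\1", hdr)
  interp <- sub(".*interpolation=(\\w+).*", "\\1", hdr)
  vals <- scan(text = ln[!startsWith(ln, "#")], quiet = TRUE)
  transform_spec(matrix(vals, 4, 4, byrow = TRUE), model, interp)
}
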