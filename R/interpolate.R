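# Point sampling of an image volume at arbitrary patient-space positions.
#
# Five interpolation modes are supported, named as users of viewer software
# know them: "nearest", "linear" (trilinear), "cubic" (tricubic Catmull-Rom),
# and the slice-wise variants "bilinear"/"bicubic" which interpolate within
# slices only and take the nearest slice along k. Points outside the volume's
# support evaluate to `fill`.

INTERP_MODES <- c("nearest", "linear", "cubic", "bilinear", "bicubic")

check_interp <- function(interpolation) {
  if (!interpolation %in% INTERP_MODES)
    stop(sprintf("unknown interpolation '%s'; choose one of: %s",
                 interpolation, paste(INTERP_MODES, collapse = ", ")),
         call. = FALSE)
  interpolation
}

# default out-of-support fill by value semantics: air for CT, zero for counts
default_fill <- function(vol) if (vol$value_kind == "HU") -1000 else 0

# gather voxel values at integer 0-based indices (n x 3), `fill` outside
gather_vox <- function(voxels, idx, fill) {
  d <- dim(voxels)
  ok <- idx[, 1] >= 0 & idx[, 1] <= d[1] - 1 &
        idx[, 2] >= 0 & idx[, 2] <= d[2] - 1 &
        idx[, 3] >= 0 & idx[, 3] <= d[3] - 1
  out <- rep(fill, nrow(idx))
  if (any(ok)) {
    lin <- idx[ok, 1] + d[1] * (idx[ok, 2] + d[2] * idx[ok, 3]) + 1
    out[ok] <- voxels[lin]
  }
  out
}

# Catmull-Rom cubic weights for fractional offset t in [0,1), 4 taps at -1..2
cubic_weights <- function(t) {
  t2 <- t * t; t3 <- t2 * t
  cbind(-0.5 * t3 + t2 - 0.5 * t,
         1.5 * t3 - 2.5 * t2 + 1,
        -1.5 * t3 + 2 * t2 + 0.5 * t,
         0.5 * t3 - 0.5 * t2)
}

# sample at continuous 0-based grid indices (n x 3 matrix)
sample_at_index <- function(voxels, cidx, interpolation, fill) {
  n <- nrow(cidx)
  if (n == 0L) return(numeric(0))
  d <- dim(voxels)
  # support test: within half a voxel of the outer voxel centers for nearest,
  # strict hull of voxel centers for the interpolating modes
  eps <- 1e-9
  if (interpolation == "nearest") {
    inside <- cidx[, 1] >= -0.5 & cidx[, 1] <= d[1] - 0.5 &
              cidx[, 2] >= -0.5 & cidx[, 2] <= d[2] - 0.5 &
              cidx[, 3] >= -0.5 & cidx[, 3] <= d[3] - 0.5
    out <- rep(fill, n)
    out[inside] <- gather_vox(voxels,
                              cbind(pmin(pmax(round(cidx[inside, 1]), 0), d[1] - 1),
                                    pmin(pmax(round(cidx[inside, 2]), 0), d[2] - 1),
                                    pmin(pmax(round(cidx[inside, 3]), 0), d[3] - 1)),
                              fill)
    return(out)
  }
  inside <- cidx[, 1] >= -eps & cidx[, 1] <= d[1] - 1 + eps &
            cidx[, 2] >= -eps & cidx[, 2] <= d[2] - 1 + eps &
            cidx[, 3] >= -eps & cidx[, 3] <= d[3] - 1 + eps
  out <- rep(fill, n)
  if (!any(inside)) return(out)
  p <- pmin(pmax(cidx[inside, , drop = FALSE], 0),
            matrix(d - 1, sum(inside), 3, byrow = TRUE))
  i0 <- floor(p); t <- p - i0

  lin_axes <- switch(interpolation,
                     linear = 1:3, bilinear = 1:2,
                     cubic = integer(0), bicubic = integer(0))
  cub_axes <- switch(interpolation,
                     cubic = 1:3, bicubic = 1:2,
                     linear = integer(0), bilinear = integer(0))
  near_axes <- setdiff(1:3, c(lin_axes, cub_axes)) # slice axis of 2-D modes

  taps <- vector("list", 3); wts <- vector("list", 3)
  for (a in 1:3) {
    if (a %in% near_axes) {
      taps[[a]] <- matrix(round(p[, a]), ncol = 1)
      wts[[a]] <- matrix(1, nrow(p), 1)
    } else if (a %in% lin_axes) {
      taps[[a]] <- cbind(i0[, a], i0[, a] + 1)
      wts[[a]] <- cbind(1 - t[, a], t[, a])
    } else {
      taps[[a]] <- cbind(i0[, a] - 1, i0[, a], i0[, a] + 1, i0[, a] + 2)
      wts[[a]] <- cubic_weights(t[, a])
    }
  }
  # clamp taps to the grid (replicate border); weights unchanged so cubic
  # stays exact in the interior and degrades gracefully at edges
  for (a in 1:3) taps[[a]] <- pmin(pmax(taps[[a]], 0), d[a] - 1)

  acc <- 0
  for (ci in seq_len(ncol(taps[[1]])))
    for (cj in seq_len(ncol(taps[[2]])))
      for (ck in seq_len(ncol(taps[[3]]))) {
        w <- wts[[1]][, ci] * wts[[2]][, cj] * wts[[3]][, ck]
        lin <- taps[[1]][, ci] + d[1] * (taps[[2]][, cj] + d[2] * taps[[3]][, ck]) + 1
        acc <- acc + w * voxels[lin]
      }
  out[inside] <- acc
  out
}

# sample an image_volume at patient-space mm points (n x 3)
sample_at_world <- function(vol, pts, interpolation, fill = default_fill(vol)) {
  check_interp(interpolation)
  cidx <- world_to_voxel(vol$geometry, pts)
  sample_at_index(vol$voxels, cidx, interpolation, fill)
}
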