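#' Threshold specification
#'
#' @param mode `"min_to_value"`, `"value_to_max"`, or `"between"`.
#' @param bounds one value (the first two modes) or two increasing values.
#' @param unit `"raw"` (volume's native units: SUV, HU, counts...) or
#'   `"percent_of_max"` (bounds are fractions of the maximum within the
#'   allowed region, e.g. 0.42).
#' @return An object of class `threshold_spec`.
#' @export
threshold_spec <- function(mode = c("between", "min_to_value", "value_to_max"),
                           bounds, unit = c("raw", "percent_of_max")) {
  mode <- match.arg(mode)
  unit <- match.arg(unit)
  bounds <- as.numeric(bounds)
  if (mode == "between") {
    if (length(bounds) != 2L || bounds[1] >= bounds[2])
      stop("'between' needs two bounds with lower < upper")
  } else if (length(bounds) != 1L) {
    stop(sprintf("'%s' needs exactly one bound", mode))
  }
  structure(list(mode = mode, bounds = bounds, unit = unit),
            class = "threshold_spec")
}

#' Constraint region for segmentation
#'
#' Restricts an operation to the inside or outside of a region: either an
#' existing [voi_mask()] or an axis-aligned index box.
#'
#' @param region a [voi_mask()], or a 2x3 matrix of 0-based inclusive index
#'   bounds (row 1 = lower corner, row 2 = upper corner).
#' @param polarity `"inside"` or `"outside"`.
#' @return An object of class `constraint_region`.
#' @export
constraint_region <- function(region, polarity = c("inside", "outside")) {
  polarity <- match.arg(polarity)
  structure(list(region = region, polarity = polarity),
            class = "constraint_region")
}

# logical array of allowed voxels for a constraint on geometry `geom`
allowed_mask <- function(constraint, geom) {
  if (is.null(constraint)) return(array(TRUE, geom$dims))
  r <- constraint$region
  m <- if (inherits(r, "voi_mask")) {
    stop_if_geometry_mismatch(geom, r$geometry, "volume and constraint")
    r$mask
  } else {
    b <- matrix(as.numeric(r), 2, 3)
    d <- geom$dims
    ii <- seq_len(d[1]) - 1; jj <- seq_len(d[2]) - 1; kk <- seq_len(d[3]) - 1
    outer(outer(ii >= b[1, 1] & ii <= b[2, 1],
                jj >= b[1, 2] & jj <= b[2, 2], `&`),
          kk >= b[1, 3] & kk <= b[2, 3], `&`)
  }
  if (!any(m)) stop("constraint region is empty")
  if (constraint$polarity == "outside") !m else m
}

#' Threshold segmentation with an optional constraint region
#'
#' A voxel enters the mask iff its value satisfies the threshold predicate
#' (bounds inclusive) and it lies on the allowed side of the constraint. In
#' `percent_of_max` units the bounds are relative to the maximum within the
#' allowed region. An empty result is legal.
#'
#' @param vol an [image_volume()].
#' @param spec a [threshold_spec()].
#' @param constraint optional [constraint_region()].
#' @param name name for the resulting VOI.
#' @return A [voi_mask()].
#' @export
threshold_mask <- function(vol, spec, constraint = NULL, name = "threshold") {
  allowed <- allowed_mask(constraint, vol$geometry)
  b <- spec$bounds
  if (spec$unit == "percent_of_max") {
    if (!any(allowed)) stop("no voxels in the allowed region")
    b <- b * max(vol$voxels[allowed])
  }
  v <- vol$voxels
  keep <- switch(spec$mode,
    min_to_value = v <= b[1],
    value_to_max = v >= b[1],
    between      = v >= b[1] & v <= b[2])
  voi_mask(keep & allowed, vol$geometry, name = name)
}

#' Replace masked voxels by a custom value
#'
#' Used to remove confounding structures (table, prostheses, bladder
#' contents) before analysis or 3-D printing, and to de-identify patients by
#' masking out recognizable anatomy.
#'
#' @param vol an [image_volume()].
#' @param mask a [voi_mask()] on the same grid.
#' @param value replacement value.
#' @return The edited [image_volume()].
#' @export
replace_voxels <- function(vol, mask, value) {
  stop_if_geometry_mismatch(vol$geometry, mask$geometry, "volume and mask")
  v <- vol$voxels
  v[mask$mask] <- value
  vol_like(vol, v)
}

# ---- connected components ----------------------------------------------

# neighbor index offsets for 6/18/26 connectivity
neighbor_offsets <- function(connectivity = 26L) {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  nm <- rowSums(abs(g))
  switch(as.character(connectivity),
         "6" = g[nm == 1, , drop = FALSE],
         "18" = g[nm <= 2, , drop = FALSE],
         "26" = g,
         stop("connectivity must be 6, 18 or 26"))
}

# integer label array of connected foreground components (0 = background)
label_array <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  lab <- array(0L, d)
  fg <- which(mask)
  if (!length(fg)) return(lab)
  off <- neighbor_offsets(connectivity)
  # forward half of the neighborhood is enough for an undirected graph
  off <- off[off[, 3] > 0 | (off[, 3] == 0 & (off[, 2] > 0 |
             (off[, 2] == 0 & off[, 1] > 0))), , drop = FALSE]
  pos <- arrayInd(fg, d)
  idmap <- array(0L, d); idmap[fg] <- seq_along(fg)
  edges <- NULL
  for (r in seq_len(nrow(off))) {
    nb <- sweep(pos, 2, off[r, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nlin <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1) + d[1] * d[2] * (nb[ok, 3] - 1)
    tgt <- idmap[nlin]
    src <- seq_along(fg)[ok]
    good <- tgt > 0L
    if (any(good)) edges <- c(edges, rbind(src[good], tgt[good]))
  }
  g <- igraph::make_graph(if (is.null(edges)) integer(0) else edges,
                          n = length(fg), directed = FALSE)
  comp <- igraph::components(g)$membership
  lab[fg] <- comp
  lab
}

#' Label connected objects in a mask
#'
#' Splits a binary mask into connected components (default 26-connectivity)
#' and records, for each, its voxel set, peak value and peak location in the
#' accompanying volume.
#'
#' @param mask a [voi_mask()].
#' @param vol optional [image_volume()] on the same grid supplying voxel
#'   values (peak value/index are `NA` without it).
#' @param connectivity 6, 18 or 26 (default).
#' @return A list of `segment_object`s, each with fields `id`, `voxels`
#'   (linear indices into the grid), `n`, `peak_value`, `peak_index`
#'   (0-based), `provenance`.
#' @export
label_objects <- function(mask, vol = NULL, connectivity = 26L) {
  lab <- label_array(mask$mask, connectivity)
  nlab <- max(lab)
  if (nlab == 0L) return(list())
  d <- dim(mask$mask)
  out <- vector("list", nlab)
  for (l in seq_len(nlab)) {
    vox <- which(lab == l)
    pv <- NA_real_; pidx <- rep(NA_integer_, 3)
    if (!is.null(vol)) {
      vals <- vol$voxels[vox]
      w <- which.max(vals)
      pv <- vals[w]
      pidx <- as.integer(arrayInd(vox[w], d) - 1L)
    }
    out[[l]] <- structure(list(id = l, voxels = vox, n = length(vox),
                               peak_value = pv, peak_index = pidx,
                               provenance = "label_objects"),
                          class = "segment_object")
  }
  out
}

#' Aggregate VOIs into one union mask
#'
#' Statistics over the union represent the total tumor burden.
#'
#' @param vois list of [voi_mask()] on a shared grid.
#' @param name name for the union VOI.
#' @return A [voi_mask()].
#' @export
aggregate_vois <- function(vois, name = "aggregate") {
  if (!length(vois)) stop("no VOIs to aggregate")
  g <- vois[[1]]$geometry
  m <- array(FALSE, g$dims)
  for (v in vois) {
    stop_if_geometry_mismatch(g, v$geometry, "VOIs")
    m <- m | v$mask
  }
  voi_mask(m, g, name = name)
}

# ---- edge detection ------------------------------------------------------

sobel_x <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
prewitt_x <- matrix(c(-1, 0, 1, -1, 0, 1, -1, 0, 1), 3, 3, byrow = TRUE)

conv2_slice <- function(sl, k) {
  # replicate-padded 2-D convolution (zero padding would invent edges at the
  # image border)
  r <- (dim(k) - 1L) %/% 2L
  d <- dim(sl)
  pi_ <- c(rep(1L, r[1]), seq_len(d[1]), rep(d[1], r[1]))
  pj <- c(rep(1L, r[2]), seq_len(d[2]), rep(d[2], r[2]))
  p <- sl[pi_, pj, drop = FALSE]
  a <- array(p, c(dim(p), 1L))
  out <- convolve_array(a, array(k, c(dim(k), 1L)))[, , 1]
  out[r[1] + seq_len(d[1]), r[2] + seq_len(d[2]), drop = FALSE]
}

slice_gradients <- function(sl, kx) {
  gx <- conv2_slice(sl, kx)
  gy <- conv2_slice(sl, t(kx))
  mag <- sqrt(gx^2 + gy^2)
  # flush FFT roundoff so flat regions have exactly zero gradient
  mag[mag <= 1e-9 * max(1, diff(range(sl)))] <- 0
  list(gx = gx, gy = gy, mag = mag)
}

canny_slice <- function(sl, sigma = 1, low_q = 0.70, high_q = 0.90,
                        hysteresis = TRUE) {
  if (sigma > 0) {
    r <- max(1L, ceiling(4 * sigma))
    k1 <- exp(-((-r:r)^2) / (2 * sigma^2)); k1 <- k1 / sum(k1)
    sl <- conv2_slice(conv2_slice(sl, matrix(k1, ncol = 1)),
                      matrix(k1, nrow = 1))
  }
  g <- slice_gradients(sl, sobel_x)
  mag <- g$mag
  if (max(mag) == 0) return(matrix(FALSE, nrow(sl), ncol(sl)))
  # non-maximum suppression with direction quantized to 4 sectors; the
  # gradient vector in (i, j) axes is (gy, gx) given the kernel layout
  ang <- atan2(g$gx, g$gy) %% pi
  sector <- findInterval(ang, c(pi / 8, 3 * pi / 8, 5 * pi / 8, 7 * pi / 8)) %% 4
  d <- dim(mag)
  offs <- list(c(1L, 0L), c(1L, 1L), c(0L, 1L), c(-1L, 1L))
  nms <- matrix(FALSE, d[1], d[2])
  padget <- function(m, di, dj) {
    out <- matrix(0, d[1], d[2])
    si <- seq_len(d[1]) + di; sj <- seq_len(d[2]) + dj
    oki <- si >= 1 & si <= d[1]; okj <- sj >= 1 & sj <= d[2]
    out[oki, okj] <- m[si[oki], sj[okj]]
    out
  }
  for (s in 0:3) {
    o <- offs[[s + 1]]
    sel <- sector == s
    nb1 <- padget(mag, o[1], o[2]); nb2 <- padget(mag, -o[1], -o[2])
    nms[sel] <- mag[sel] >= nb1[sel] & mag[sel] >= nb2[sel]
  }
  pos <- mag[mag > 0]
  hi <- stats::quantile(pos, high_q, names = FALSE)
  lo <- stats::quantile(pos, low_q, names = FALSE)
  strong <- nms & mag >= hi
  if (!hysteresis) return(strong)
  weak <- nms & mag >= lo
  if (!any(strong)) return(strong)
  lab <- label_array(array(weak, c(d, 1L)), 26L)[, , 1]
  keep_labels <- unique(lab[strong])
  weak & (lab %in% keep_labels[keep_labels > 0])
}

#' Edge detection
#'
#' Slice-wise (default) Sobel, Prewitt, Canny or Approx-Canny edge maps.
#' Sobel/Prewitt threshold the gradient magnitude at its 90th nonzero
#' percentile; Canny uses Gaussian smoothing, non-maximum suppression and
#' hysteresis at the 70th/90th gradient percentiles; Approx-Canny is Canny
#' without the hysteresis step (single high threshold). Set
#' `slice_wise = FALSE` for a 3-D gradient (Sobel/Prewitt only).
#'
#' @param vol an [image_volume()].
#' @param method `"sobel"`, `"prewitt"`, `"canny"`, or `"approx_canny"`.
#' @param slice_wise apply the 2-D operator per slice (default TRUE).
#' @param threshold_q magnitude quantile for Sobel/Prewitt (default 0.90).
#' @return A [voi_mask()] of edge voxels.
#' @export
edge_detect <- function(vol, method = c("sobel", "prewitt", "canny",
                                        "approx_canny"),
                        slice_wise = TRUE, threshold_q = 0.90) {
  if (is.character(method) && length(method) == 1 &&
      !method %in% c("sobel", "prewitt", "canny", "approx_canny"))
    stop(sprintf("unknown edge method '%s'; choose one of: sobel, prewitt, canny, approx_canny",
                 method))
  method <- match.arg(method)
  d <- vol$geometry$dims
  out <- array(FALSE, d)
  if (method %in% c("canny", "approx_canny")) {
    for (k in seq_len(d[3]))
      out[, , k] <- canny_slice(vol$voxels[, , k],
                                hysteresis = method == "canny")
  } else {
    kx <- if (method == "sobel") sobel_x else prewitt_x
    if (slice_wise) {
      for (k in seq_len(d[3])) {
        g <- slice_gradients(vol$voxels[, , k], kx)
        pos <- g$mag[g$mag > 0]
        if (!length(pos)) next
        out[, , k] <- g$mag >= stats::quantile(pos, threshold_q, names = FALSE)
      }
    } else {
      k3 <- array(0, c(3, 3, 3))
      for (kk in 1:3) k3[, , kk] <- kx * c(1, 2, 1)[kk]
      gx <- convolve_array(vol$voxels, k3)
      gy <- convolve_array(vol$voxels, aperm(k3, c(2, 1, 3)))
      gz <- convolve_array(vol$voxels, aperm(k3, c(3, 2, 1)))
      mag <- sqrt(gx^2 + gy^2 + gz^2)
      pos <- mag[mag > 0]
      if (length(pos))
        out <- mag >= stats::quantile(pos, threshold_q, names = FALSE)
    }
  }
  voi_mask(out, vol$geometry, name = paste0("edges_", method))
}

# ---- morphology ----------------------------------------------------------

ball_kernel <- function(radius_mm, spacing) {
  r <- pmax(0L, floor(radius_mm / spacing))
  dims <- 2L * r + 1L
  ctr <- r + 1L
  idx <- as.matrix(expand.grid(1:dims[1], 1:dims[2], 1:dims[3]))
  d2 <- rowSums((sweep(idx, 2, ctr) * matrix(spacing, nrow(idx), 3,
                                             byrow = TRUE))^2)
  array(as.numeric(d2 <= radius_mm^2 + 1e-9), dims)
}

dilate_mask <- function(mask, kernel) {
  convolve_array(mask * 1, kernel) > 0.5
}

erode_mask <- function(mask, kernel) {
  convolve_array(mask * 1, kernel) > sum(kernel) - 0.5
}

#' Segment left and right lungs on CT
#'
#' Threshold at `hu_threshold` (default -320 HU, generous enough to include
#' the bronchi), remove components touching the image border (exterior air),
#' keep the two largest components, close with a 3 mm ball to reincorporate
#' vessels, and — if only one fused component remains — split it by erosion
#' until separation followed by competitive geodesic dilation (a
#' watershed-by-dilation). Laterality is assigned by centroid patient-L
#' coordinate: the left lung has the larger +x (L) centroid.
#'
#' @param ct an [image_volume()] in HU.
#' @param hu_threshold air/lung HU cutoff (default -320).
#' @return A list with [voi_mask()] elements `left` and `right`.
#' @export
segment_lungs <- function(ct, hu_threshold = -320) {
  if (ct$value_kind != "HU") stop("segment_lungs expects a CT volume in HU")
  d <- ct$geometry$dims
  air <- ct$voxels < hu_threshold
  lab <- label_array(air, 26L)
  # drop components touching the volume border (exterior air)
  border <- unique(c(lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ],
                     lab[, , 1], lab[, , d[3]]))
  lab[lab %in% border] <- 0L
  sizes <- tabulate(lab)
  if (sum(sizes > 0) < 2) {
    # maybe one fused component: try erosion split below; else give up
    if (sum(sizes > 0) < 1)
      stop("fewer than two lung-like components found; try overriding hu_threshold")
  }
  keep <- order(sizes, decreasing = TRUE)[1:min(2, sum(sizes > 0))]
  kb <- ball_kernel(3, ct$geometry$spacing)
  comps <- list()
  for (l in keep) {
    m <- lab == l
    m <- erode_mask(dilate_mask(m, kb), kb)  # morphological closing
    m <- m & (ct$voxels < -300)  # never admit soft tissue
    comps[[length(comps) + 1]] <- m
  }
  if (length(comps) == 1 ||
      sizes[keep[2]] < 0.05 * sizes[keep[1]]) {
    split <- split_fused_component(comps[[1]], ct$geometry)
    if (is.null(split))
      stop("fewer than two lung-like components found; try overriding hu_threshold")
    comps <- split
  }
  cx <- vapply(comps, function(m) {
    w <- which(m, arr.ind = TRUE)
    mean(voxel_to_world(ct$geometry, w - 1L, check = FALSE)[, 1])
  }, numeric(1))
  left_i <- which.max(cx)  # +x is patient left in LPS
  list(left = voi_mask(comps[[left_i]], ct$geometry, "lung_left",
                       c(0L, 128L, 255L)),
       right = voi_mask(comps[[3 - left_i]], ct$geometry, "lung_right",
                        c(255L, 128L, 0L)))
}

# erode until two components appear, then reassign all original voxels by
# alternating constrained dilation from the two seeds
split_fused_component <- function(mask, geom) {
  kb <- ball_kernel(min(geom$spacing) * 1.01, geom$spacing)
  er <- mask
  for (it in 1:25) {
    er <- erode_mask(er, kb)
    if (!any(er)) return(NULL)
    lab <- label_array(er, 26L)
    if (max(lab) >= 2) {
      sizes <- tabulate(lab)
      top <- order(sizes, decreasing = TRUE)[1:2]
      a <- lab == top[1]; b <- lab == top[2]
      nb <- ball_kernel(min(geom$spacing) * 1.01, geom$spacing)
      repeat {
        grew <- FALSE
        na <- dilate_mask(a, nb) & mask & !b
        nbm <- dilate_mask(b, nb) & mask & !na
        if (any(na & !a)) { a <- na; grew <- TRUE }
        if (any(nbm & !b)) { b <- nbm; grew <- TRUE }
        if (!grew) break
      }
      return(list(a, b))
    }
  }
  NULL
}
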