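#' Write a triangle mesh as binary STL (mm units)
#'
#' @param mesh a `mesh_surface` (see [isosurface()]).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_stl <- function(mesh, path) {
  if (nrow(mesh$vertices) < 4) stop("mesh has fewer than 4 vertices")
  used <- sort(unique(as.vector(mesh$faces)))
  if (length(used) < nrow(mesh$vertices))
    stop("degenerate mesh: unreferenced vertices present")
  p1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  p2 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  p3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  nrm <- cross3(p2 - p1, p3 - p1)
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm <- nrm / len
  con <- file(path, "wb"); on.exit(close(con))
  hdr <- charToRaw(sprintf("%-80s", "voxquant binary STL (mm)"))
  writeBin(hdr[1:80], con)
  writeBin(as.integer(nrow(mesh$faces)), con, size = 4, endian = "little")
  # interleave: normal, v1, v2, v3 (float32 each), attribute count (uint16)
  block <- matrix(0, nrow(mesh$faces), 12)
  block[, 1:3] <- nrm; block[, 4:6] <- p1; block[, 7:9] <- p2
  block[, 10:12] <- p3
  for (f in seq_len(nrow(block))) {
    writeBin(as.numeric(block[f, ]), con, size = 4, endian = "little")
    writeBin(as.integer(0), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a binary STL file
#' @param path STL file.
#' @return A list with `normals` (n x 3), plus `vertices`/`faces` where
#'   vertices are the raw per-facet corners (3n x 3) and faces index them.
#' @export
read_stl <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  nfac <- readBin(bytes[81:84], "integer", size = 4, endian = "little")
  # each facet record: 12 float32 (normal + 3 vertices) + 1 uint16 attribute
  normals <- matrix(0, nfac, 3)
  verts <- matrix(0, 3 * nfac, 3)
  pos <- 85
  for (f in seq_len(nfac)) {
    v <- readBin(bytes[pos:(pos + 47)], "numeric", n = 12, size = 4,
                 endian = "little")
    normals[f, ] <- v[1:3]
    verts[3 * f - 2, ] <- v[4:6]
    verts[3 * f - 1, ] <- v[7:9]
    verts[3 * f, ] <- v[10:12]
    pos <- pos + 50
  }
  faces <- matrix(seq_len(3 * nfac), ncol = 3, byrow = TRUE)
  list(normals = normals, vertices = verts, faces = faces)
}

# minimal 24-bit BMP writer for RGB slices (r, g, b matrices in [0,1])
write_bmp24 <- function(r, g, b, path) {
  w <- nrow(r); h <- ncol(r)
  rowbytes <- ((3 * w + 3) %/% 4) * 4
  datasize <- rowbytes * h
  offset <- 14 + 40
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(charToRaw("BM"), con)
  writeBin(as.integer(offset + datasize), con, size = 4, endian = "little")
  writeBin(as.integer(0), con, size = 4, endian = "little")
  writeBin(as.integer(offset), con, size = 4, endian = "little")
  writeBin(as.integer(40), con, size = 4, endian = "little")
  writeBin(as.integer(w), con, size = 4, endian = "little")
  writeBin(as.integer(h), con, size = 4, endian = "little")
  writeBin(as.integer(1), con, size = 2, endian = "little")
  writeBin(as.integer(24), con, size = 2, endian = "little")
  writeBin(as.integer(0), con, size = 4, endian = "little")
  writeBin(as.integer(datasize), con, size = 4, endian = "little")
  writeBin(as.integer(c(2835, 2835, 0, 0)), con, size = 4, endian = "little")
  to8 <- function(m) as.integer(pmin(pmax(round(m * 255), 0), 255))
  pad <- raw(rowbytes - 3 * w)
  for (j in seq_len(h)) {   # bottom-up, pixels as B, G, R
    px <- rbind(to8(b[, j]), to8(g[, j]), to8(r[, j]))
    writeBin(as.raw(px), con)
    if (length(pad)) writeBin(pad, con)
  }
  invisible(path)
}

#' Export an RGB volume (from the fusion operations) as a color bitmap stack
#'
#' @param rgb a list with 3-D arrays `r`, `g`, `b` in `[0, 1]` (as returned
#'   by [blend_layers()] or [rgb_multitracer()]).
#' @param directory output directory.
#' @return the directory, invisibly; attribute `"files"` lists files written.
#' @export
write_rgb_stack <- function(rgb, directory) {
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create directory '%s'", directory))
  files <- character(0)
  for (k in seq_len(dim(rgb$r)[3])) {
    f <- file.path(directory, sprintf("fused_%04d.bmp", k))
    write_bmp24(rgb$r[, , k], rgb$g[, , k], rgb$b[, , k], f)
    files <- c(files, f)
  }
  out <- directory
  attr(out, "files") <- files
  invisible(out)
}

# minimal 8-bit grayscale BMP writer (bottom-up, 256-entry palette)
write_bmp8 <- function(img, path) {
  # img: matrix of 0..255, rows = x (width), cols = y (height)
  w <- nrow(img); h <- ncol(img)
  rowbytes <- ((w + 3) %/% 4) * 4
  datasize <- rowbytes * h
  offset <- 14 + 40 + 256 * 4
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(charToRaw("BM"), con)
  writeBin(as.integer(offset + datasize), con, size = 4, endian = "little")
  writeBin(as.integer(0), con, size = 4, endian = "little")
  writeBin(as.integer(offset), con, size = 4, endian = "little")
  writeBin(as.integer(40), con, size = 4, endian = "little")   # BITMAPINFOHEADER
  writeBin(as.integer(w), con, size = 4, endian = "little")
  writeBin(as.integer(h), con, size = 4, endian = "little")
  writeBin(as.integer(1), con, size = 2, endian = "little")    # planes
  writeBin(as.integer(8), con, size = 2, endian = "little")    # bpp
  writeBin(as.integer(0), con, size = 4, endian = "little")    # compression
  writeBin(as.integer(datasize), con, size = 4, endian = "little")
  writeBin(as.integer(c(2835, 2835)), con, size = 4, endian = "little")
  writeBin(as.integer(c(256, 0)), con, size = 4, endian = "little")
  pal <- raw(1024)  # grayscale palette, entries (B, G, R, 0)
  for (i in 0:255) pal[4 * i + 1:3] <- as.raw(i)
  writeBin(pal, con)
  pad <- raw(rowbytes - w)
  for (j in seq_len(h)) {  # bottom-up
    writeBin(as.raw(pmin(pmax(round(img[, j]), 0), 255)), con)
    if (length(pad)) writeBin(pad, con)
  }
  invisible(path)
}

#' Export a mask or mesh interior as a bitmap slice stack
#'
#' Writes binary cross-sections of the object at the requested slice
#' thickness as 8-bit `.bmp` files (0 = outside, 255 = inside), the format
#' used to feed 3-D printers. A `mesh_surface` is first voxelized onto its
#' bounding grid at the in-plane resolution `xy_spacing_mm`.
#'
#' @param x a [voi_mask()] or a `mesh_surface`.
#' @param slice_thickness_mm spacing between output slices, > 0.
#' @param directory output directory.
#' @param xy_spacing_mm in-plane sample spacing for meshes (default 1 mm).
#' @return the directory, invisibly; attribute `"files"` lists files written.
#' @export
write_bitmap_stack <- function(x, slice_thickness_mm, directory,
                               xy_spacing_mm = 1) {
  if (slice_thickness_mm <= 0) stop("slice_thickness_mm must be > 0")
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create directory '%s'", directory))
  centered_planes <- function(zmin, zmax) {
    # center the planes in the z extent so the first/last are not degenerate
    # tangent cuts
    nsl <- max(1L, floor((zmax - zmin) / slice_thickness_mm) + 1L)
    start <- zmin + ((zmax - zmin) - (nsl - 1) * slice_thickness_mm) / 2
    start + (seq_len(nsl) - 1L) * slice_thickness_mm
  }
  files <- character(0)
  if (inherits(x, "mesh_surface")) {
    # rasterize the mesh interior directly on each requested plane
    lo <- apply(x$vertices, 2, min); hi <- apply(x$vertices, 2, max)
    nx <- as.integer(ceiling((hi[1] - lo[1]) / xy_spacing_mm)) + 3L
    ny <- as.integer(ceiling((hi[2] - lo[2]) / xy_spacing_mm)) + 3L
    p1 <- x$vertices[x$faces[, 1], , drop = FALSE]
    p2 <- x$vertices[x$faces[, 2], , drop = FALSE]
    p3 <- x$vertices[x$faces[, 3], , drop = FALSE]
    zs <- centered_planes(lo[3], hi[3])
    for (n in seq_along(zs)) {
      sl <- rasterize_mesh_plane(p1, p2, p3, zs[n], lo - xy_spacing_mm,
                                 nx, ny, xy_spacing_mm)
      f <- file.path(directory, sprintf("slice_%04d.bmp", n))
      write_bmp8(sl * 255, f)
      files <- c(files, f)
    }
  } else {
    g <- x$geometry
    z0 <- voxel_to_world(g, c(0, 0, 0))[3]
    z1 <- voxel_to_world(g, g$dims - 1L)[3]
    zs <- centered_planes(min(z0, z1), max(z0, z1))
    for (n in seq_along(zs)) {
      k <- round((zs[n] - min(z0, z1)) / g$spacing[3])
      k <- min(max(k, 0), g$dims[3] - 1)
      f <- file.path(directory, sprintf("slice_%04d.bmp", n))
      write_bmp8(x$mask[, , k + 1] * 255, f)
      files <- c(files, f)
    }
  }
  out <- directory
  attr(out, "files") <- files
  invisible(out)
}

# even-odd rasterization of the mesh cross-section at plane z
rasterize_mesh_plane <- function(p1, p2, p3, z, origin, nx, ny, spacing) {
  sl <- matrix(FALSE, nx, ny)
  segs <- mesh_plane_segments(p1, p2, p3, z)
  if (!nrow(segs)) return(sl)
  gx <- origin[1] + (seq_len(nx) - 1) * spacing
  a <- segs[, c(1, 2), drop = FALSE]; b <- segs[, c(3, 4), drop = FALSE]
  for (j in seq_len(ny)) {
    y <- origin[2] + (j - 1) * spacing
    cr <- (a[, 2] <= y & b[, 2] > y) | (b[, 2] <= y & a[, 2] > y)
    if (!any(cr)) next
    t <- (y - a[cr, 2]) / (b[cr, 2] - a[cr, 2])
    xc <- sort(a[cr, 1] + t * (b[cr, 1] - a[cr, 1]))
    inside <- rep(FALSE, nx)
    for (q in seq(1, length(xc) - 1, by = 2))
      inside <- inside | (gx > xc[q] & gx < xc[q + 1])
    sl[, j] <- inside
  }
  sl
}

# intersect all triangles with plane z = const; returns segments as
# (x1, y1, x2, y2) rows
mesh_plane_segments <- function(p1, p2, p3, z) {
  segs <- matrix(0, 0, 3)  # (x, y, triangle id) per edge crossing
  for (pair in list(list(p1, p2, p3), list(p2, p3, p1), list(p3, p1, p2))) {
    a <- pair[[1]]; b <- pair[[2]]
    cr <- (a[, 3] <= z & b[, 3] > z) | (b[, 3] <= z & a[, 3] > z)
    if (!any(cr)) next
    t <- (z - a[cr, 3]) / (b[cr, 3] - a[cr, 3])
    pt <- a[cr, 1:2, drop = FALSE] +
      t * (b[cr, 1:2, drop = FALSE] - a[cr, 1:2, drop = FALSE])
    segs <- rbind(segs, cbind(pt, which(cr)))
  }
  if (!nrow(segs)) return(matrix(0, 0, 4))
  # pair up the two crossings of each triangle
  out <- matrix(0, 0, 4)
  for (f in unique(segs[, 3])) {
    pts <- segs[segs[, 3] == f, 1:2, drop = FALSE]
    if (nrow(pts) >= 2)
      out <- rbind(out, c(pts[1, ], pts[2, ]))
  }
  out
}

#' Write VOI statistics or DVH summaries as CSV
#'
#' One header line, one row per entry, locale-independent decimal point.
#' Column order: name, volume_ml, total, mean, min, max, peak, sd, tlg.
#'
#' @param rows a list of `voi_statistics` (from [compute_statistics()]), a
#'   list of `dvh_curve`s, or a data.frame.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_statistics_csv <- function(rows, path) {
  if (is.data.frame(rows)) {
    df <- rows
  } else {
    if (!length(rows)) stop("no rows to write")
    if (inherits(rows[[1]], "dvh_curve")) {
      df <- do.call(rbind, lapply(rows, function(d)
        data.frame(name = d$name, volume_ml = d$volume_ml, mean = d$mean,
                   total = d$total, min = d$min, max = d$max,
                   stringsAsFactors = FALSE)))
    } else {
      df <- do.call(rbind, lapply(rows, function(s)
        data.frame(name = s$name, volume_ml = s$volume_ml, total = s$total,
                   mean = s$mean, min = s$min, max = s$max, peak = s$peak,
                   sd = s$sd, tlg = if (is.na(s$tlg)) NA_real_ else s$tlg,
                   stringsAsFactors = FALSE)))
    }
  }
  utils::write.csv(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
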