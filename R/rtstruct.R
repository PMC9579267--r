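# VOI <-> planar-contour conversion and DICOM RT structure set I/O.
#
# Masks are cut into per-slice closed contours by iso-level 0.5 contouring of
# the binary mask (holes become separate rings and are recovered by even-odd
# rasterization on read).

# closed contour rings (list of n x 2 matrices of continuous 0-based (i,j)
# indices) of one binary slice
slice_contours <- function(sl) {
  d <- dim(sl)
  # pad with a zero border so boundary-touching masks still close
  p <- matrix(0, d[1] + 2, d[2] + 2)
  p[2:(d[1] + 1), 2:(d[2] + 1)] <- sl
  cl <- grDevices::contourLines(x = seq_len(d[1] + 2) - 2, # 0-based index coords
                                y = seq_len(d[2] + 2) - 2,
                                z = p, levels = 0.5)
  lapply(cl, function(cc) {
    m <- cbind(cc$x, cc$y)
    # drop duplicated closing point if present; keep implicit closure
    if (nrow(m) > 1 && all(abs(m[1, ] - m[nrow(m), ]) < 1e-9))
      m <- m[-nrow(m), , drop = FALSE]
    m
  })
}

# even-odd rasterization of one polygon (n x 2, 0-based (i,j) continuous
# index coordinates) onto a d1 x d2 logical slice: toggles voxel centers
# inside the ring
rasterize_ring <- function(ring, d1, d2) {
  n <- nrow(ring)
  xs <- ring[, 1]; ys <- ring[, 2]
  xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
  out <- matrix(FALSE, d1, d2)
  gx <- seq_len(d1) - 1
  for (j in seq_len(d2)) {
    yj <- j - 1
    # edges crossing the horizontal line y = yj (half-open rule)
    cr <- (ys <= yj & ye > yj) | (ye <= yj & ys > yj)
    if (!any(cr)) next
    xc <- xs[cr] + (yj - ys[cr]) / (ye[cr] - ys[cr]) * (xe[cr] - xs[cr])
    xc <- sort(xc)
    # toggle parity between successive crossings
    inside <- rep(FALSE, d1)
    for (q in seq(1, length(xc) - 1, by = 2))
      inside <- inside | (gx > xc[q] & gx < xc[q + 1])
    out[, j] <- inside
  }
  out
}

# mask -> list of per-slice rings in patient mm (each with its slice index)
mask_to_contours <- function(voi) {
  g <- voi$geometry
  out <- list()
  for (k in seq_len(g$dims[3])) {
    sl <- voi$mask[, , k] * 1
    if (!any(sl > 0)) next
    for (ring in slice_contours(sl)) {
      pts <- voxel_to_world(g, cbind(ring, k - 1), check = FALSE)
      out[[length(out) + 1]] <- list(slice = k, points = pts)
    }
  }
  out
}

# contours (list of mm point matrices) -> mask on ref geometry (even-odd)
contours_to_mask <- function(contours, ref) {
  m <- array(FALSE, ref$dims)
  for (cc in contours) {
    idx <- world_to_voxel(ref, cc$points)
    k <- round(mean(idx[, 3])) + 1
    if (k < 1 || k > ref$dims[3])
      stop("contour references a slice outside the reference geometry")
    ring <- idx[, 1:2, drop = FALSE]
    m[, , k] <- xor(m[, , k], rasterize_ring(ring, ref$dims[1], ref$dims[2]))
  }
  m
}

#' Write VOIs as a DICOM RT structure set
#'
#' Each mask is cut into closed planar contours (patient mm, CLOSED_PLANAR)
#' on its grid's slices. VOIs with zero voxels are skipped with a warning.
#'
#' @param vois list of [voi_mask()] sharing one geometry.
#' @param ref the shared [grid_geometry()].
#' @param path output file.
#' @param frame_uid FrameOfReferenceUID to reference.
#' @return the path, invisibly.
#' @export
write_rtstruct <- function(vois, ref, path, frame_uid = new_uid()) {
  roi_seq <- list(); contour_seq <- list(); obs_seq <- list()
  nroi <- 0L
  for (v in vois) {
    stop_if_geometry_mismatch(ref, v$geometry, "reference and VOI")
    if (!any(v$mask)) {
      warning(sprintf("VOI '%s' has zero voxels; skipped", v$name))
      next
    }
    nroi <- nroi + 1L
    contours <- mask_to_contours(v)
    roi_seq[[nroi]] <- list(ROINumber = nroi,
                            ReferencedFrameOfReferenceUID = frame_uid,
                            ROIName = v$name,
                            ROIGenerationAlgorithm = "AUTOMATIC")
    contour_seq[[nroi]] <- list(
      ROIDisplayColor = v$color,
      ContourSequence = lapply(contours, function(cc) list(
        ContourGeometricType = "CLOSED_PLANAR",
        NumberOfContourPoints = nrow(cc$points),
        ContourData = as.numeric(t(cc$points)))),
      ReferencedROINumber = nroi)
    obs_seq[[nroi]] <- list(ObservationNumber = nroi,
                            ReferencedROINumber = nroi,
                            RTROIInterpretedType = "ORGAN")
  }
  ds <- list(
    SOPClassUID = UID_RTS,
    SOPInstanceUID = new_uid(),
    StudyDate = "20260101", StudyTime = "000000",
    Modality = "RTSTRUCT",
    PatientName = "PHANTOM^VOXQUANT", PatientID = "VOXQUANT",
    StudyInstanceUID = new_uid(),
    SeriesInstanceUID = new_uid(),
    StructureSetLabel = "voxquant",
    ReferencedFrameOfReferenceSequence = list(
      list(FrameOfReferenceUID = frame_uid)),
    StructureSetROISequence = roi_seq,
    ROIContourSequence = contour_seq,
    RTROIObservationsSequence = obs_seq)
  write_dicom_file(ds, path)
  invisible(path)
}

#' Read a DICOM RT structure set back into masks
#'
#' Rasterizes each ROI's planar contours onto the reference geometry with
#' even-odd filling (so holes written as separate rings are recovered).
#'
#' @param path RT structure set file.
#' @param ref [grid_geometry()] to rasterize onto.
#' @return A list of [voi_mask()]s, one per ROI (possibly empty masks).
#' @export
read_rtstruct <- function(path, ref) {
  ds <- read_dicom_file(path)
  if (!identical(ds$SOPClassUID, UID_RTS))
    stop(sprintf("'%s' is not an RT structure set", path))
  rois <- ds$StructureSetROISequence
  cont <- ds$ROIContourSequence
  out <- list()
  for (rc in cont) {
    nr <- rc$ReferencedROINumber
    name <- "ROI"
    for (r in rois) if (identical(r$ROINumber, nr)) name <- r$ROIName
    color <- if (is.null(rc$ROIDisplayColor)) c(255L, 0L, 0L) else
      as.integer(rc$ROIDisplayColor)
    contours <- lapply(rc$ContourSequence, function(cs)
      list(points = matrix(cs$ContourData, ncol = 3, byrow = TRUE)))
    m <- contours_to_mask(contours, ref)
    out[[length(out) + 1]] <- voi_mask(m, ref, name, color)
  }
  out
}
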