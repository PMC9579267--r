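#' Series header
#'
#' Acquisition metadata carried alongside an [image_volume()]: patient
#' position code, modality, radiopharmaceutical information for SUV
#' conversion, and the per-slice positions the series was read with.
#'
#' @param modality DICOM modality code.
#' @param patient_position HFS/FFS/HFP/FFP or a decubitus code.
#' @param patient_weight_kg patient weight in kg (SUV).
#' @param injected_dose_bq injected activity in Bq (SUV).
#' @param injection_time_s radiopharmaceutical injection time, seconds since
#'   midnight.
#' @param series_time_s series (scan start) time, seconds since midnight.
#' @param half_life_s radionuclide half-life in seconds.
#' @param units pixel units code (`"HU"`, `"BQML"`, `"SUV"`, ...).
#' @param slice_positions numeric vector of per-slice positions along the
#'   slice normal, mm.
#' @param series_uid,study_uid,frame_uid DICOM UIDs (generated if missing).
#' @return An object of class `series_header`.
#' @export
series_header <- function(modality = "OT", patient_position = "HFS",
                          patient_weight_kg = NA_real_,
                          injected_dose_bq = NA_real_,
                          injection_time_s = NA_real_,
                          series_time_s = NA_real_,
                          half_life_s = NA_real_,
                          units = NA_character_,
                          slice_positions = numeric(0),
                          series_uid = new_uid(), study_uid = new_uid(),
                          frame_uid = new_uid()) {
  structure(list(modality = modality, patient_position = patient_position,
                 patient_weight_kg = patient_weight_kg,
                 injected_dose_bq = injected_dose_bq,
                 injection_time_s = injection_time_s,
                 series_time_s = series_time_s, half_life_s = half_life_s,
                 units = units, slice_positions = slice_positions,
                 series_uid = series_uid, study_uid = study_uid,
                 frame_uid = frame_uid),
            class = "series_header")
}

tm_string <- function(seconds) {
  if (is.na(seconds)) return(NULL)
  h <- floor(seconds / 3600); m <- floor((seconds - 3600 * h) / 60)
  s <- seconds - 3600 * h - 60 * m
  sprintf("%02d%02d%09.6f", as.integer(h), as.integer(m), s)
}

tm_seconds <- function(tm) {
  if (is.null(tm) || !nzchar(tm)) return(NA_real_)
  as.numeric(substr(tm, 1, 2)) * 3600 + as.numeric(substr(tm, 3, 4)) * 60 +
    as.numeric(substr(tm, 5, nchar(tm)))
}

value_kind_of <- function(modality, units) {
  if (identical(modality, "CT")) return("HU")
  if (identical(units, "BQML")) return("activity_conc")
  if (identical(units, "SUV")) return("SUV")
  if (identical(units, "GYH")) return("dose_rate")
  "unitless"
}

units_of <- function(value_kind) {
  switch(value_kind, HU = "HU", activity_conc = "BQML", SUV = "SUV",
         dose_rate = "GYH", "NONE")
}

#' Write an image volume as a DICOM series
#'
#' One explicit-VR little-endian file per slice, secondary-capture-style
#' minimal tag set plus full geometry, modality and (when available)
#' radiopharmaceutical tags. Voxel values are quantized to 16-bit with a
#' per-series rescale slope/intercept, so a write/read round trip reproduces
#' them to one rescale quantum. A fresh SeriesInstanceUID is generated on
#' every write.
#'
#' @param vol an [image_volume()].
#' @param directory output directory (created if needed).
#' @param header optional [series_header()] template supplying patient and
#'   radiopharmaceutical metadata.
#' @return The directory, invisibly; attribute `"files"` lists the files.
#' @export
write_dicom_series <- function(vol, directory, header = NULL) {
  if (is.null(header)) header <- series_header(modality = vol$modality)
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create directory '%s'", directory))
  g <- vol$geometry
  rng <- range(vol$voxels)
  slope <- if (rng[2] > rng[1]) (rng[2] - rng[1]) / 65535 else 1
  intercept <- rng[1]
  stored <- round((vol$voxels - intercept) / slope)
  series_uid <- new_uid()
  files <- character(g$dims[3])
  for (k in seq_len(g$dims[3])) {
    ipp <- voxel_to_world(g, c(0L, 0L, k - 1L))
    sl <- stored[, , k]
    pix <- writeBin(as.integer(sl), raw(), size = 2, endian = "little")
    ds <- list(
      SOPClassUID = UID_SC,
      SOPInstanceUID = new_uid(),
      StudyDate = "20260101", StudyTime = "000000",
      Modality = vol$modality,
      PatientName = "PHANTOM^VOXQUANT", PatientID = "VOXQUANT",
      PatientPosition = header$patient_position,
      StudyInstanceUID = header$study_uid,
      SeriesInstanceUID = series_uid,
      FrameOfReferenceUID = header$frame_uid,
      InstanceNumber = k,
      ImagePositionPatient = ipp,
      ImageOrientationPatient = c(g$direction[, 1], g$direction[, 2]),
      PixelSpacing = c(g$spacing[2], g$spacing[1]),
      SliceThickness = g$spacing[3],
      SamplesPerPixel = 1, PhotometricInterpretation = "MONOCHROME2",
      Rows = g$dims[2], Columns = g$dims[1],
      BitsAllocated = 16, BitsStored = 16, HighBit = 15,
      PixelRepresentation = 0,
      RescaleIntercept = intercept, RescaleSlope = slope,
      Units = units_of(vol$value_kind),
      PixelData = pix)
    if (!is.na(header$series_time_s))
      ds$SeriesTime <- tm_string(header$series_time_s)
    if (!is.na(header$patient_weight_kg))
      ds$PatientWeight <- header$patient_weight_kg
    if (!is.na(header$injected_dose_bq)) {
      rph <- list(RadionuclideTotalDose = header$injected_dose_bq)
      if (!is.na(header$injection_time_s))
        rph$RadiopharmaceuticalStartTime <- tm_string(header$injection_time_s)
      if (!is.na(header$half_life_s))
        rph$RadionuclideHalfLife <- header$half_life_s
      ds$RadiopharmaceuticalInformationSequence <- list(rph)
    }
    files[k] <- file.path(directory, sprintf("slice_%04d.dcm", k))
    write_dicom_file(ds, files[k])
  }
  out <- directory
  attr(out, "files") <- files
  invisible(out)
}

#' Load a DICOM image series from a directory
#'
#' Reads every `.dcm` file, verifies they belong to one series, sorts slices
#' by the projection of ImagePositionPatient onto the slice normal, applies
#' the rescale slope/intercept, and reconstructs the grid geometry from the
#' position/orientation/spacing tags. Nonuniform slice spacing beyond 1% of
#' the mean triggers a warning and the mean spacing is used.
#'
#' @param directory directory containing the series.
#' @return A list with elements `volume` ([image_volume()]) and `header`
#'   ([series_header()]).
#' @export
load_dicom_series <- function(directory) {
  paths <- list.files(directory, pattern = "\\.dcm$", ignore.case = TRUE,
                      full.names = TRUE)
  if (!length(paths))
    stop(sprintf("no DICOM files found in '%s'", directory))
  sets <- lapply(paths, read_dicom_file)
  uids <- unique(vapply(sets, function(d)
    if (is.null(d$SeriesInstanceUID)) "" else d$SeriesInstanceUID, ""))
  if (length(uids) > 1)
    stop(sprintf("directory mixes multiple series: %s",
                 paste(uids, collapse = ", ")))
  d1 <- sets[[1]]
  row_dir <- d1$ImageOrientationPatient[1:3]
  col_dir <- d1$ImageOrientationPatient[4:6]
  normal <- c(row_dir[2] * col_dir[3] - row_dir[3] * col_dir[2],
              row_dir[3] * col_dir[1] - row_dir[1] * col_dir[3],
              row_dir[1] * col_dir[2] - row_dir[2] * col_dir[1])
  proj <- vapply(sets, function(d) sum(d$ImagePositionPatient * normal),
                 numeric(1))
  ord <- order(proj)
  sets <- sets[ord]; proj <- proj[ord]
  ncol_ <- as.integer(d1$Columns); nrow_ <- as.integer(d1$Rows)
  nk <- length(sets)
  if (nk > 1) {
    dz <- diff(proj)
    if (any(dz <= 0)) stop("duplicate or non-monotone slice positions")
    kz <- mean(dz)
    if (max(abs(dz - kz)) > 0.01 * kz)
      warning("nonuniform slice spacing beyond 1%; using the mean spacing")
  } else {
    kz <- if (!is.null(d1$SliceThickness)) d1$SliceThickness else 1
  }
  vox <- array(0, c(ncol_, nrow_, nk))
  for (k in seq_len(nk)) {
    d <- sets[[k]]
    pix <- readBin(d$PixelData, "integer", n = ncol_ * nrow_, size = 2,
                   endian = "little",
                   signed = !is.null(d$PixelRepresentation) &&
                     d$PixelRepresentation == 1)
    if (any(pix < 0) && (is.null(d$PixelRepresentation) ||
                         d$PixelRepresentation == 0))
      pix <- pix + 65536 * (pix < 0)
    slope <- if (is.null(d$RescaleSlope)) 1 else d$RescaleSlope
    icpt <- if (is.null(d$RescaleIntercept)) 0 else d$RescaleIntercept
    vox[, , k] <- matrix(pix * slope + icpt, ncol_, nrow_)
  }
  geom <- grid_geometry(c(ncol_, nrow_, nk),
                        c(d1$PixelSpacing[2], d1$PixelSpacing[1], kz),
                        sets[[1]]$ImagePositionPatient,
                        cbind(row_dir, col_dir, normal))
  rph <- if (!is.null(d1$RadiopharmaceuticalInformationSequence))
    d1$RadiopharmaceuticalInformationSequence[[1]] else list()
  hdr <- series_header(
    modality = if (is.null(d1$Modality)) "OT" else d1$Modality,
    patient_position = if (is.null(d1$PatientPosition)) "HFS" else
      d1$PatientPosition,
    patient_weight_kg = if (is.null(d1$PatientWeight)) NA_real_ else
      d1$PatientWeight,
    injected_dose_bq = if (is.null(rph$RadionuclideTotalDose)) NA_real_ else
      rph$RadionuclideTotalDose,
    injection_time_s = tm_seconds(rph$RadiopharmaceuticalStartTime),
    series_time_s = tm_seconds(d1$SeriesTime),
    half_life_s = if (is.null(rph$RadionuclideHalfLife)) NA_real_ else
      rph$RadionuclideHalfLife,
    units = if (is.null(d1$Units)) NA_character_ else d1$Units,
    slice_positions = proj,
    series_uid = uids,
    study_uid = if (is.null(d1$StudyInstanceUID)) new_uid() else
      d1$StudyInstanceUID,
    frame_uid = if (is.null(d1$FrameOfReferenceUID)) new_uid() else
      d1$FrameOfReferenceUID)
  vol <- image_volume(vox, geom, hdr$modality,
                      value_kind_of(hdr$modality, hdr$units))
  list(volume = vol, header = hdr)
}

#' Convert an activity-concentration volume to body-weight SUV
#'
#' `SUVbw = concentration (Bq/ml) / (decayed injected dose (Bq) / weight (g))`
#' with the injected dose decay-corrected from injection time to the series
#' (scan start) time.
#'
#' @param vol an [image_volume()] with `value_kind = "activity_conc"`.
#' @param header a [series_header()] carrying weight, dose, times and
#'   half-life.
#' @return An [image_volume()] in SUV.
#' @export
to_suv <- function(vol, header) {
  if (vol$value_kind != "activity_conc")
    stop("to_suv expects an activity-concentration volume (Bq/ml)")
  if (is.na(header$patient_weight_kg))
    stop("missing PatientWeight (0010,1030); cannot compute SUV")
  if (is.na(header$injected_dose_bq))
    stop("missing RadionuclideTotalDose (0018,1074); cannot compute SUV")
  dose <- header$injected_dose_bq
  if (!is.na(header$injection_time_s) && !is.na(header$series_time_s) &&
      !is.na(header$half_life_s)) {
    dt <- header$series_time_s - header$injection_time_s
    dose <- dose * 2^(-dt / header$half_life_s)
  }
  suv <- vol$voxels / (dose / (header$patient_weight_kg * 1000))
  image_volume(suv, vol$geometry, vol$modality, "SUV")
}
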