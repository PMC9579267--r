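# Minimal DICOM codec: explicit-VR little-endian read/write of Part-10
# files. Only the tags the toolkit itself uses are interpreted; anything
# else (including vendor private elements) is carried as raw bytes on read
# and never written. This is deliberately a small, auditable subset of the
# standard, not a general DICOM library.

DICOM_TRANSFER_SYNTAX_LE <- "1.2.840.10008.1.2.1"
UID_SC  <- "1.2.840.10008.5.1.4.1.1.7"       # secondary capture image
UID_RTS <- "1.2.840.10008.5.1.4.1.1.481.3"   # RT structure set

# tag dictionary: name -> c(group, element, VR)
DICOM_DICT <- list(
  FileMetaInformationGroupLength = c(0x0002, 0x0000, "UL"),
  FileMetaInformationVersion     = c(0x0002, 0x0001, "OB"),
  MediaStorageSOPClassUID        = c(0x0002, 0x0002, "UI"),
  MediaStorageSOPInstanceUID     = c(0x0002, 0x0003, "UI"),
  TransferSyntaxUID              = c(0x0002, 0x0010, "UI"),
  ImplementationClassUID         = c(0x0002, 0x0012, "UI"),
  SOPClassUID            = c(0x0008, 0x0016, "UI"),
  SOPInstanceUID         = c(0x0008, 0x0018, "UI"),
  StudyDate              = c(0x0008, 0x0020, "DA"),
  SeriesDate             = c(0x0008, 0x0021, "DA"),
  StudyTime              = c(0x0008, 0x0030, "TM"),
  SeriesTime             = c(0x0008, 0x0031, "TM"),
  AcquisitionTime        = c(0x0008, 0x0032, "TM"),
  Modality               = c(0x0008, 0x0060, "CS"),
  SeriesDescription      = c(0x0008, 0x103E, "LO"),
  PatientName            = c(0x0010, 0x0010, "PN"),
  PatientID              = c(0x0010, 0x0020, "LO"),
  PatientWeight          = c(0x0010, 0x1030, "DS"),
  SliceThickness         = c(0x0018, 0x0050, "DS"),
  RadiopharmaceuticalStartTime = c(0x0018, 0x1072, "TM"),
  RadionuclideTotalDose  = c(0x0018, 0x1074, "DS"),
  RadionuclideHalfLife   = c(0x0018, 0x1075, "DS"),
  PatientPosition        = c(0x0018, 0x5100, "CS"),
  StudyInstanceUID       = c(0x0020, 0x000D, "UI"),
  SeriesInstanceUID      = c(0x0020, 0x000E, "UI"),
  InstanceNumber         = c(0x0020, 0x0013, "IS"),
  ImagePositionPatient   = c(0x0020, 0x0032, "DS"),
  ImageOrientationPatient = c(0x0020, 0x0037, "DS"),
  FrameOfReferenceUID    = c(0x0020, 0x0052, "UI"),
  SamplesPerPixel        = c(0x0028, 0x0002, "US"),
  PhotometricInterpretation = c(0x0028, 0x0004, "CS"),
  Rows                   = c(0x0028, 0x0010, "US"),
  Columns                = c(0x0028, 0x0011, "US"),
  PixelSpacing           = c(0x0028, 0x0030, "DS"),
  BitsAllocated          = c(0x0028, 0x0100, "US"),
  BitsStored             = c(0x0028, 0x0101, "US"),
  HighBit                = c(0x0028, 0x0102, "US"),
  PixelRepresentation    = c(0x0028, 0x0103, "US"),
  RescaleIntercept       = c(0x0028, 0x1052, "DS"),
  RescaleSlope           = c(0x0028, 0x1053, "DS"),
  RadiopharmaceuticalInformationSequence = c(0x0054, 0x0016, "SQ"),
  Units                  = c(0x0054, 0x1001, "CS"),
  StructureSetLabel      = c(0x3006, 0x0002, "SH"),
  StructureSetName       = c(0x3006, 0x0004, "LO"),
  ReferencedFrameOfReferenceSequence = c(0x3006, 0x0010, "SQ"),
  StructureSetROISequence = c(0x3006, 0x0020, "SQ"),
  ROINumber              = c(0x3006, 0x0022, "IS"),
  ReferencedFrameOfReferenceUID = c(0x3006, 0x0024, "UI"),
  ROIName                = c(0x3006, 0x0026, "LO"),
  ROIGenerationAlgorithm = c(0x3006, 0x0036, "CS"),
  ROIContourSequence     = c(0x3006, 0x0039, "SQ"),
  ROIDisplayColor        = c(0x3006, 0x002A, "IS"),
  ContourSequence        = c(0x3006, 0x0040, "SQ"),
  ContourGeometricType   = c(0x3006, 0x0042, "CS"),
  NumberOfContourPoints  = c(0x3006, 0x0046, "IS"),
  ContourData            = c(0x3006, 0x0050, "DS"),
  ReferencedROINumber    = c(0x3006, 0x0084, "IS"),
  RTROIObservationsSequence = c(0x3006, 0x0080, "SQ"),
  ObservationNumber      = c(0x3006, 0x0082, "IS"),
  RTROIInterpretedType   = c(0x3006, 0x00A4, "CS"),
  PixelData              = c(0x7FE0, 0x0010, "OW")
)

dicom_tag_key <- function(group, element)
  sprintf("%04X,%04X", group, element)

DICOM_KEY_TO_NAME <- local({
  keys <- vapply(DICOM_DICT, function(e)
    dicom_tag_key(as.integer(e[1]), as.integer(e[2])), "")
  stats::setNames(names(DICOM_DICT), keys)
})

uint16le <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                 endian = "little")
uint32le <- function(x) {
  # writeBin has no unsigned 32-bit; our lengths stay far below 2^31
  writeBin(as.integer(x), raw(), size = 4, endian = "little")
}

pad_even <- function(bytes, pad = as.raw(0x20)) {
  if (length(bytes) %% 2 == 1) c(bytes, pad) else bytes
}

# encode one data element (defined length) as raw
dicom_element_raw <- function(name, value) {
  e <- DICOM_DICT[[name]]
  if (is.null(e)) stop(sprintf("tag '%s' not in dictionary", name))
  group <- as.integer(e[1]); element <- as.integer(e[2]); vr <- e[3]
  body <- dicom_value_raw(vr, value)
  hdr <- c(uint16le(group), uint16le(element), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(hdr, as.raw(c(0, 0)), uint32le(length(body)), body)
  } else {
    if (length(body) > 65534) stop("value too long for short-form VR")
    c(hdr, uint16le(length(body)), body)
  }
}

dicom_value_raw <- function(vr, value) {
  switch(vr,
    US = writeBin(as.integer(value), raw(), size = 2, endian = "little"),
    UL = uint32le(value),
    OB = ,
    OW = as.raw(value),
    SQ = {
      # value: list of item datasets (each a named list of elements)
      items <- lapply(value, function(item) {
        body <- dicom_dataset_raw(item)
        c(uint16le(0xFFFE), uint16le(0xE000), uint32le(length(body)), body)
      })
      do.call(c, c(items, list(raw(0))))
    },
    UI = pad_even(charToRaw(paste(value, collapse = "\\")), as.raw(0)),
    DS = pad_even(charToRaw(paste(formatC(value, digits = 10, format = "g"),
                                  collapse = "\\"))),
    IS = pad_even(charToRaw(paste(as.integer(value), collapse = "\\"))),
    pad_even(charToRaw(paste(value, collapse = "\\"))))
}

# encode a dataset: named list (names from DICOM_DICT), tag order enforced
dicom_dataset_raw <- function(ds) {
  ord <- order(vapply(names(ds), function(n) {
    e <- DICOM_DICT[[n]]
    as.numeric(e[1]) * 65536 + as.numeric(e[2])
  }, numeric(1)))
  parts <- lapply(names(ds)[ord], function(n) dicom_element_raw(n, ds[[n]]))
  do.call(c, c(parts, list(raw(0))))
}

# write a Part-10 file: 128-byte preamble, DICM, file meta, dataset
write_dicom_file <- function(ds, path) {
  sop_class <- ds$SOPClassUID
  sop_inst <- ds$SOPInstanceUID
  meta <- list(FileMetaInformationVersion = c(0x00, 0x01),
               MediaStorageSOPClassUID = sop_class,
               MediaStorageSOPInstanceUID = sop_inst,
               TransferSyntaxUID = DICOM_TRANSFER_SYNTAX_LE,
               ImplementationClassUID = "2.25.999999999999999999.1")
  meta_raw <- dicom_dataset_raw(meta)
  meta_raw <- c(dicom_element_raw("FileMetaInformationGroupLength",
                                  length(meta_raw)), meta_raw)
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(meta_raw, con)
  writeBin(dicom_dataset_raw(ds), con)
  invisible(path)
}

# ---- reading --------------------------------------------------------------

read_uint <- function(bytes, pos, n) {
  v <- as.integer(bytes[pos:(pos + n - 1)])
  sum(v * 256^(0:(n - 1)))
}

# parse a dataset from raw bytes; returns list(values, attrs) keyed by tag
# name (dictionary tags) or "GGGG,EEEE" (unknown tags, raw value)
parse_dataset <- function(bytes, pos = 1L, end = length(bytes) + 1L) {
  out <- list()
  while (pos < end) {
    group <- read_uint(bytes, pos, 2)
    element <- read_uint(bytes, pos + 2, 2)
    pos <- pos + 4L
    if (group == 0xFFFE) {  # item/sequence delimiters at dataset level
      len <- read_uint(bytes, pos, 4); pos <- pos + 4L
      if (element == 0xE0DD || element == 0xE00D) break
      pos <- pos + len
      next
    }
    vr <- rawToChar(bytes[pos:(pos + 1)])
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- read_uint(bytes, pos + 4, 4)
      pos <- pos + 8L
    } else if (grepl("^[A-Z]{2}$", vr)) {
      len <- read_uint(bytes, pos + 2, 2)
      pos <- pos + 4L
    } else {
      # implicit VR fallback: 4-byte length, VR unknown
      len <- read_uint(bytes, pos, 4)
      vr <- "UN"
      pos <- pos + 4L
    }
    key <- dicom_tag_key(group, element)
    name <- DICOM_KEY_TO_NAME[key]
    if (vr == "SQ") {
      if (len == 0xFFFFFFFF) {
        parsed <- parse_sequence(bytes, pos, length(bytes) + 1L,
                                 undefined = TRUE)
      } else {
        parsed <- parse_sequence(bytes, pos, pos + len, undefined = FALSE)
      }
      value <- parsed$items
      pos <- parsed$pos
    } else {
      if (len == 0xFFFFFFFF) stop("undefined length outside SQ unsupported")
      vraw <- if (len > 0) bytes[pos:(pos + len - 1)] else raw(0)
      pos <- pos + len
      value <- parse_value(vr, vraw)
    }
    out[[if (is.na(name)) key else name]] <- value
  }
  attr(out, "end_pos") <- pos
  out
}

parse_sequence <- function(bytes, pos, end, undefined) {
  items <- list()
  while (pos < end) {
    group <- read_uint(bytes, pos, 2)
    element <- read_uint(bytes, pos + 2, 2)
    len <- read_uint(bytes, pos + 4, 4)
    pos <- pos + 8L
    if (group == 0xFFFE && element == 0xE0DD) break     # sequence delimiter
    if (!(group == 0xFFFE && element == 0xE000))
      stop("malformed sequence: expected item tag")
    if (len == 0xFFFFFFFF) {
      ds <- parse_dataset(bytes, pos, end)
      pos <- attr(ds, "end_pos")
    } else {
      ds <- parse_dataset(bytes, pos, pos + len)
      pos <- pos + len
    }
    attr(ds, "end_pos") <- NULL
    items[[length(items) + 1]] <- ds
    if (!undefined && pos >= end) break
  }
  list(items = items, pos = pos)
}

parse_value <- function(vr, vraw) {
  txt <- function() {
    s <- rawToChar(vraw[vraw != as.raw(0)])
    trimws(s)
  }
  switch(vr,
    US = {
      n <- length(vraw) %/% 2
      vapply(seq_len(n), function(i) read_uint(vraw, 2 * i - 1, 2), numeric(1))
    },
    UL = {
      n <- length(vraw) %/% 4
      vapply(seq_len(n), function(i) read_uint(vraw, 4 * i - 3, 4), numeric(1))
    },
    DS = as.numeric(strsplit(txt(), "\\\\")[[1]]),
    IS = as.integer(strsplit(txt(), "\\\\")[[1]]),
    OB = ,
    OW = ,
    UN = vraw,
    {
      parts <- strsplit(txt(), "\\\\")[[1]]
      if (length(parts) == 0) "" else parts
    })
}

read_dicom_file <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  if (length(bytes) < 140 || rawToChar(bytes[129:132]) != "DICM")
    stop(sprintf("'%s' is not a Part-10 DICOM file", path))
  ds <- parse_dataset(bytes, 133L)
  if (!is.null(ds$TransferSyntaxUID) &&
      ds$TransferSyntaxUID != DICOM_TRANSFER_SYNTAX_LE)
    stop(sprintf("unsupported transfer syntax '%s' (only explicit VR little endian)",
                 ds$TransferSyntaxUID))
  attr(ds, "end_pos") <- NULL
  ds
}

# monotonically unique UID under a fixed root; wall-clock plus a counter
.uid_state <- new.env(parent = emptyenv())
.uid_state$n <- 0L
new_uid <- function() {
  .uid_state$n <- .uid_state$n + 1L
  sprintf("2.25.%.0f.%d.%d", as.numeric(Sys.time()) * 1000,
          Sys.getpid() %% 100000L, .uid_state$n)
}
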