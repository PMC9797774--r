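#' Minimal single-frame DICOM codec (Explicit VR Little Endian)
#'
#' The dataset layout stores one anonymized single-frame 16-bit CT slice per
#' image id. This codec reads and writes exactly that profile: a 128-byte
#' preamble, the "DICM" magic, a file-meta group (group 0002) and a flat
#' Explicit-VR-Little-Endian dataset. Sequences (VR SQ) and undefined-length
#' elements are out of scope and rejected on read.
#'
#' Elements are held as a list of `list(group, element, vr, bytes)` in tag
#' order; raw value bytes are preserved verbatim, which is what guarantees
#' the anonymizer's byte-identical pixel-data contract.
#'
#' @name dicom
NULL

# Tags with a 4-byte length field in Explicit VR.
.long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# Minimal data dictionary: the anonymization whitelist, the structural
# file-meta elements, and common identifying tags used by the generator.
dicom_dict <- function() {
  d <- rbind(
    c(0x0002, 0x0000, "UL", "FileMetaInformationGroupLength"),
    c(0x0002, 0x0001, "OB", "FileMetaInformationVersion"),
    c(0x0002, 0x0002, "UI", "MediaStorageSOPClassUID"),
    c(0x0002, 0x0003, "UI", "MediaStorageSOPInstanceUID"),
    c(0x0002, 0x0010, "UI", "TransferSyntaxUID"),
    c(0x0002, 0x0012, "UI", "ImplementationClassUID"),
    c(0x0008, 0x0016, "UI", "SOPClassUID"),
    c(0x0008, 0x0018, "UI", "SOPInstanceUID"),
    c(0x0008, 0x0020, "DA", "StudyDate"),
    c(0x0008, 0x0030, "TM", "StudyTime"),
    c(0x0008, 0x0050, "SH", "AccessionNumber"),
    c(0x0008, 0x0060, "CS", "Modality"),
    c(0x0008, 0x0070, "LO", "Manufacturer"),
    c(0x0008, 0x0080, "LO", "InstitutionName"),
    c(0x0008, 0x0090, "PN", "ReferringPhysicianName"),
    c(0x0008, 0x1030, "LO", "StudyDescription"),
    c(0x0008, 0x1010, "SH", "StationName"),
    c(0x0010, 0x0010, "PN", "PatientName"),
    c(0x0010, 0x0020, "LO", "PatientID"),
    c(0x0010, 0x0030, "DA", "PatientBirthDate"),
    c(0x0010, 0x0040, "CS", "PatientSex"),
    c(0x0010, 0x1010, "AS", "PatientAge"),
    c(0x0018, 0x0050, "DS", "SliceThickness"),
    c(0x0018, 0x0060, "DS", "KVP"),
    c(0x0020, 0x000D, "UI", "StudyInstanceUID"),
    c(0x0020, 0x000E, "UI", "SeriesInstanceUID"),
    c(0x0020, 0x0013, "IS", "InstanceNumber"),
    c(0x0028, 0x0002, "US", "SamplesPerPixel"),
    c(0x0028, 0x0004, "CS", "PhotometricInterpretation"),
    c(0x0028, 0x0010, "US", "Rows"),
    c(0x0028, 0x0011, "US", "Columns"),
    c(0x0028, 0x0030, "DS", "PixelSpacing"),
    c(0x0028, 0x0100, "US", "BitsAllocated"),
    c(0x0028, 0x0101, "US", "BitsStored"),
    c(0x0028, 0x0102, "US", "HighBit"),
    c(0x0028, 0x0103, "US", "PixelRepresentation"),
    c(0x0028, 0x0120, "US", "PixelPaddingValue"),
    c(0x0028, 0x1050, "DS", "WindowCenter"),
    c(0x0028, 0x1051, "DS", "WindowWidth"),
    c(0x0028, 0x1052, "DS", "RescaleIntercept"),
    c(0x0028, 0x1053, "DS", "RescaleSlope"),
    c(0x0028, 0x1054, "LO", "RescaleType"),
    c(0x7FE0, 0x0010, "OW", "PixelData")
  )
  data.frame(group = strtoi(d[, 1]), element = strtoi(d[, 2]),
             vr = d[, 3], name = d[, 4], stringsAsFactors = FALSE)
}

dict_lookup_name <- function(name) {
  d <- dicom_dict()
  i <- match(name, d$name)
  if (is.na(i)) stop("unknown DICOM tag name: ", name, call. = FALSE)
  d[i, ]
}

# Little-endian unsigned encodings; hand-rolled so values >= 2^15 / 2^31
# (e.g. group 0x7FE0, large pixel lengths) never hit writeBin's signed range.
uint16_bytes <- function(x) {
  x <- as.numeric(x)
  as.raw(as.vector(rbind(x %% 256, x %/% 256 %% 256)))
}
uint32_bytes <- function(x) {
  x <- as.numeric(x)
  as.raw(as.vector(rbind(x %% 256, x %/% 256 %% 256,
                         x %/% 65536 %% 256, x %/% 16777216 %% 256)))
}

encode_value <- function(vr, value) {
  if (is.raw(value)) {
    bytes <- value
  } else if (vr == "US") {
    bytes <- uint16_bytes(value)
  } else if (vr == "UL") {
    bytes <- uint32_bytes(value)
  } else {
    s <- paste(as.character(value), collapse = "\\")
    bytes <- charToRaw(s)
  }
  if (length(bytes) %% 2L == 1L) {
    pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
    if (vr %in% c("OB", "OW", "UN")) pad <- as.raw(0L)
    bytes <- c(bytes, pad)
  }
  bytes
}

#' Create a DICOM element by dictionary name
#'
#' @param name tag keyword present in the package's data dictionary.
#' @param value character, numeric or raw value; encoded per the tag's VR.
#' @return element list (`group`, `element`, `vr`, `bytes`).
#' @export
dicom_element <- function(name, value) {
  row <- dict_lookup_name(name)
  list(group = row$group, element = row$element, vr = row$vr,
       bytes = encode_value(row$vr, value))
}

#' Assemble a DICOM object from dataset elements
#'
#' Fills in the file-meta group (transfer syntax Explicit VR Little Endian)
#' around the supplied dataset elements. The media-storage SOP instance UID
#' mirrors the dataset `SOPInstanceUID` when present.
#'
#' @param elements list of elements from [dicom_element()] (group >= 0008).
#' @return object of class `dicom`.
#' @export
dicom_create <- function(elements) {
  sop_instance <- "1.2.826.0.1.3680043.8.498.1"
  for (el in elements)
    if (el$group == 0x0008 && el$element == 0x0018)
      sop_instance <- decode_string(el$bytes)
  meta <- list(
    dicom_element("FileMetaInformationVersion", as.raw(c(0L, 1L))),
    dicom_element("MediaStorageSOPClassUID", "1.2.840.10008.5.1.4.1.1.2"),
    dicom_element("MediaStorageSOPInstanceUID", sop_instance),
    dicom_element("TransferSyntaxUID", "1.2.840.10008.1.2.1"),
    dicom_element("ImplementationClassUID", "1.2.826.0.1.3680043.8.498.2")
  )
  structure(list(elements = sort_elements(c(meta, elements))), class = "dicom")
}

sort_elements <- function(elements) {
  key <- vapply(elements, function(e) e$group * 2^16 + e$element, numeric(1))
  elements[order(key)]
}

encode_element <- function(el) {
  hdr <- c(uint16_bytes(el$group), uint16_bytes(el$element), charToRaw(el$vr))
  if (el$vr %in% .long_vrs) {
    c(hdr, raw(2L), uint32_bytes(length(el$bytes)), el$bytes)
  } else {
    c(hdr, uint16_bytes(length(el$bytes)), el$bytes)
  }
}

#' Write a DICOM object to disk
#'
#' Emits preamble, magic, a file-meta group with a recomputed group length,
#' and the dataset in Explicit VR Little Endian.
#'
#' @param ds object of class `dicom`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dicom <- function(ds, path) {
  stopifnot(inherits(ds, "dicom"))
  els <- sort_elements(ds$elements)
  is_meta <- vapply(els, function(e) e$group == 0x0002, logical(1))
  keep <- vapply(els, function(e) !(e$group == 0x0002 && e$element == 0x0000), logical(1))
  els <- els[keep]
  is_meta <- is_meta[keep]
  meta_bytes <- do.call(c, c(list(raw(0)), lapply(els[is_meta], encode_element)))
  group_len <- encode_element(dicom_element("FileMetaInformationGroupLength",
                                            length(meta_bytes)))
  body_bytes <- do.call(c, c(list(raw(0)), lapply(els[!is_meta], encode_element)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(group_len, meta_bytes, body_bytes), con)
  invisible(path)
}

#' Read a DICOM file written in Explicit VR Little Endian
#'
#' @param path input file path.
#' @return object of class `dicom`.
#' @export
read_dicom <- function(path) {
  bytes <- readBin(path, raw(), file.size(path))
  if (length(bytes) < 132L || rawToChar(bytes[129:132]) != "DICM")
    stop("format error: not a DICOM file (missing DICM magic): ", path, call. = FALSE)
  pos <- 133L
  n <- length(bytes)
  elements <- list()
  u16 <- function(i) as.integer(bytes[i]) + 256L * as.integer(bytes[i + 1L])
  u32 <- function(i) u16(i) + 65536 * u16(i + 2L)
  while (pos + 7L <= n) {
    group <- u16(pos); element <- u16(pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("format error: invalid VR at offset ", pos, " (implicit VR unsupported)",
           call. = FALSE)
    if (vr == "SQ")
      stop("format error: sequence elements are not supported", call. = FALSE)
    if (vr %in% .long_vrs) {
      len <- u32(pos + 8L); pos <- pos + 12L
    } else {
      len <- u16(pos + 6L); pos <- pos + 8L
    }
    if (len > n - pos + 1L)
      stop("format error: truncated element (", sprintf("%04X,%04X", group, element),
           ")", call. = FALSE)
    value <- if (len > 0L) bytes[pos:(pos + len - 1L)] else raw(0)
    pos <- pos + len
    elements[[length(elements) + 1L]] <- list(group = group, element = element,
                                              vr = vr, bytes = value)
  }
  structure(list(elements = sort_elements(elements)), class = "dicom")
}

decode_string <- function(bytes) {
  s <- rawToChar(bytes[bytes != as.raw(0L)])
  trimws(s)
}

dicom_find <- function(ds, name) {
  row <- dict_lookup_name(name)
  for (el in ds$elements)
    if (el$group == row$group && el$element == row$element) return(el)
  NULL
}

#' Extract a decoded tag value from a DICOM object
#'
#' @param ds object of class `dicom`.
#' @param name tag keyword.
#' @return decoded value (numeric for US/UL/DS/IS, character otherwise, raw
#'   for OB/OW), or `NULL` when absent.
#' @export
dicom_value <- function(ds, name) {
  el <- dicom_find(ds, name)
  if (is.null(el)) return(NULL)
  switch(el$vr,
    US = readBin(el$bytes, integer(), n = length(el$bytes) / 2L, size = 2L,
                 signed = FALSE, endian = "little"),
    UL = readBin(el$bytes, integer(), n = length(el$bytes) / 4L, size = 4L,
                 endian = "little"),
    DS = as.numeric(strsplit(decode_string(el$bytes), "\\\\")[[1]]),
    IS = as.integer(strsplit(decode_string(el$bytes), "\\\\")[[1]]),
    OB = el$bytes,
    OW = el$bytes,
    decode_string(el$bytes)
  )
}

#' List the tags present in a DICOM object
#'
#' @param ds object of class `dicom`.
#' @return data frame with columns `group`, `element`, `vr`, `name` (NA for
#'   tags absent from the package dictionary).
#' @export
dicom_tags <- function(ds) {
  d <- dicom_dict()
  out <- do.call(rbind, lapply(ds$elements, function(e)
    data.frame(group = e$group, element = e$element, vr = e$vr,
               stringsAsFactors = FALSE)))
  if (is.null(out)) return(data.frame(group = integer(), element = integer(),
                                      vr = character(), name = character()))
  out$name <- d$name[match(paste(out$group, out$element),
                           paste(d$group, d$element))]
  out
}

#' Decode the pixel data of a single-frame 16-bit DICOM object
#'
#' @param ds object of class `dicom` carrying Rows, Columns and PixelData.
#' @return integer matrix (Rows x Columns), pixels in raster order.
#' @export
dicom_pixel_matrix <- function(ds) {
  rows <- dicom_value(ds, "Rows"); cols <- dicom_value(ds, "Columns")
  px <- dicom_value(ds, "PixelData")
  if (is.null(rows) || is.null(cols) || is.null(px))
    stop("format error: missing Rows/Columns/PixelData", call. = FALSE)
  v <- readBin(px, integer(), n = length(px) / 2L, size = 2L,
               signed = FALSE, endian = "little")
  matrix(v, nrow = rows, ncol = cols, byrow = TRUE)
}
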