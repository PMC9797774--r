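#' DICOM anonymization by tag whitelist
#'
#' De-identification removes every DICOM tag except a fixed whitelist of 20
#' technical tags needed to interpret the pixel data (geometry, bit depth,
#' rescale and window parameters) plus the pixel data itself. A handful of
#' structural file-meta elements absent from the whitelist
#' (FileMetaInformationVersion, MediaStorageSOPClassUID,
#' ImplementationClassUID) are retained as well, because without them the
#' output container is not a parsable DICOM file; this retention is
#' deliberate and documented. Pixel data passes through byte-identical.
#'
#' @name anonymization
NULL

#' The default anonymization whitelist
#'
#' @return data frame with columns `group`, `element`, `name`: the 20 kept
#'   tags (FileMetaInformationGroupLength, MediaStorageSOPInstanceUID,
#'   TransferSyntaxUID, SliceThickness, SamplesPerPixel,
#'   PhotometricInterpretation, Rows, Columns, PixelSpacing, BitsAllocated,
#'   BitsStored, HighBit, PixelRepresentation, PixelPaddingValue,
#'   WindowCenter, WindowWidth, RescaleIntercept, RescaleSlope, RescaleType,
#'   PixelData).
#' @export
anonymization_profile <- function() {
  keep <- c("FileMetaInformationGroupLength", "MediaStorageSOPInstanceUID",
            "TransferSyntaxUID", "SliceThickness", "SamplesPerPixel",
            "PhotometricInterpretation", "Rows", "Columns", "PixelSpacing",
            "BitsAllocated", "BitsStored", "HighBit", "PixelRepresentation",
            "PixelPaddingValue", "WindowCenter", "WindowWidth",
            "RescaleIntercept", "RescaleSlope", "RescaleType", "PixelData")
  d <- dicom_dict()
  d[match(keep, d$name), c("group", "element", "name")]
}

# File-meta elements required for a parsable container, kept beyond the
# whitelist.
structural_elements <- function() {
  data.frame(group = c(0x0002, 0x0002, 0x0002),
             element = c(0x0001, 0x0002, 0x0012),
             name = c("FileMetaInformationVersion", "MediaStorageSOPClassUID",
                      "ImplementationClassUID"))
}

#' Strip a DICOM object down to the anonymization whitelist
#'
#' @param ds object of class `dicom`.
#' @param profile whitelist data frame with columns `group` and `element`;
#'   default [anonymization_profile()].
#' @return anonymized object of class `dicom`; value bytes of kept elements
#'   (including PixelData) are untouched.
#' @export
anonymize_dataset <- function(ds, profile = anonymization_profile()) {
  stopifnot(inherits(ds, "dicom"))
  allowed <- paste(c(profile$group, structural_elements()$group),
                   c(profile$element, structural_elements()$element))
  keep <- vapply(ds$elements, function(e)
    (e$group %% 2 == 0) && paste(e$group, e$element) %in% allowed, logical(1))
  structure(list(elements = ds$elements[keep]), class = "dicom")
}

#' Anonymize a DICOM file
#'
#' Reads `input`, removes every element outside the whitelist (private tags
#' included) and writes the result to `output`. Idempotent: running it on
#' its own output changes nothing but the recomputed file-meta group length.
#'
#' @param input path to a parsable DICOM file.
#' @param output path for the anonymized file.
#' @inheritParams anonymize_dataset
#' @return `output`, invisibly.
#' @export
anonymize_dicom <- function(input, output, profile = anonymization_profile()) {
  ds <- read_dicom(input)
  write_dicom(anonymize_dataset(ds, profile), output)
  invisible(output)
}
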