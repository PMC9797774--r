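#' Write a label mask as a single-channel 8-bit PNG
#'
#' Pixel values are stored literally (0 background, 1 ischemic,
#' 2 hemorrhagic), with no display scaling: the file is a machine-readable
#' label image, not a picture. `read_mask_png(write_mask_png(m))` is the
#' identity.
#'
#' @param mask label mask (integer matrix, values 0/1/2).
#' @param path output path, conventionally `MASK/{imageid}.png`.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  assert_label_mask(mask)
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' Read a label mask from a single-channel 8-bit PNG
#'
#' @param path input path.
#' @return label mask (integer matrix).
#' @export
read_mask_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) != 2L)
    stop("format error: mask PNG must be single-channel, got ",
         dim(a)[3L], " channels: ", path, call. = FALSE)
  m <- matrix(as.integer(round(a * 255)), nrow(a), ncol(a))
  assert_label_mask(m, paste0("mask file ", path))
  m
}

# Nonzero pixels whose 4-connected neighborhood (zero padding off-grid)
# contains a different label.
mask_boundary <- function(mask) {
  is_diff <- matrix(FALSE, nrow(mask), ncol(mask))
  for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L)))
    is_diff <- is_diff | (shift_mat(mask, d[1L], d[2L], 0L) != mask)
  is_diff & mask != 0L
}

#' Render a semi-transparent lesion overlay on a base image
#'
#' Blends lesion interiors over the grayscale base with a fixed fill alpha
#' of 0.4 and draws lesion boundaries opaque: blue for ischemic (class 1),
#' green for hemorrhagic (class 2). A boundary pixel is a lesion pixel with
#' a 4-connected neighbor of a different label (off-grid counts as
#' background). Background pixels are unchanged.
#'
#' @param base_image numeric matrix of display intensities in \[0, 255\].
#' @param mask label mask of the same dimensions.
#' @param fill_alpha blend weight of the lesion color over the base, in
#'   \[0, 1\]; default 0.4.
#' @return RGBA array (rows x cols x 4) with values in \[0, 1\].
#' @export
render_overlay <- function(base_image, mask, fill_alpha = 0.4) {
  if (!is.matrix(base_image)) stop("base image must be a matrix", call. = FALSE)
  assert_label_mask(mask)
  assert_same_dim(base_image, mask)
  g <- pmin(pmax(base_image / 255, 0), 1)
  out <- array(0, c(nrow(g), ncol(g), 4L))
  out[, , 1] <- g; out[, , 2] <- g; out[, , 3] <- g; out[, , 4] <- 1
  colors <- list(`1` = c(0, 0, 1), `2` = c(0, 1, 0))  # blue ischemic, green hemorrhagic
  boundary <- mask_boundary(mask)
  for (cls in c(1L, 2L)) {
    col <- colors[[as.character(cls)]]
    fill <- mask == cls & !boundary
    edge <- mask == cls & boundary
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[fill] <- (1 - fill_alpha) * plane[fill] + fill_alpha * col[ch]
      plane[edge] <- col[ch]
      out[, , ch] <- plane
    }
  }
  out
}

#' Render the display PNG for a CT slice
#'
#' Applies the DICOM rescale (slope/intercept) followed by linear window
#' leveling from the file's WindowCenter/WindowWidth tags, and returns the
#' resulting 8-bit grayscale matrix in \[0, 255\].
#'
#' @param ds object of class `dicom`.
#' @return numeric matrix of display intensities in \[0, 255\].
#' @export
dicom_display_matrix <- function(ds) {
  px <- dicom_pixel_matrix(ds)
  slope <- dicom_value(ds, "RescaleSlope")
  intercept <- dicom_value(ds, "RescaleIntercept")
  center <- dicom_value(ds, "WindowCenter")
  width <- dicom_value(ds, "WindowWidth")
  if (is.null(slope)) slope <- 1
  if (is.null(intercept)) intercept <- 0
  hu <- px * slope[1L] + intercept[1L]
  if (is.null(center) || is.null(width)) {
    lo <- min(hu); w <- max(hu) - lo
    if (w == 0) w <- 1
  } else {
    lo <- center[1L] - width[1L] / 2; w <- width[1L]
  }
  round(pmin(pmax((hu - lo) / w, 0), 1) * 255)
}
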