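#' Label masks and class-preserving binary morphology
#'
#' A label mask is the unit of ground truth and prediction in the challenge:
#' an integer matrix with pixel values 0 (background), 1 (ischemic lesion)
#' and 2 (hemorrhagic lesion). Scoring tolerates imprecise lesion boundaries
#' by comparing predictions against an *envelope* of the ground truth: a pair
#' of class-preserving eroded and dilated masks built per class with a 3x3
#' all-ones structuring element, one iteration.
#'
#' @name masks
NULL

#' Construct and validate a label mask
#'
#' @param pixels integer matrix; every value must be 0, 1 or 2.
#' @return the validated integer matrix (invisibly classed as used elsewhere;
#'   label masks are plain matrices throughout the package).
#' @examples
#' m <- label_mask(matrix(c(0, 1, 2, 0), 2, 2))
#' @export
label_mask <- function(pixels) {
  if (!is.matrix(pixels)) stop("label mask must be a matrix", call. = FALSE)
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("label mask must have at least one row and one column", call. = FALSE)
  storage.mode(pixels) <- "integer"
  assert_label_mask(pixels)
  pixels
}

assert_label_mask <- function(m, what = "mask") {
  if (!is.matrix(m)) stop(what, " must be a matrix", call. = FALSE)
  bad <- !(m %in% c(0L, 1L, 2L))
  if (any(bad))
    stop("invalid ", what, ": pixel values outside {0,1,2}: ",
         paste(unique(m[bad])[seq_len(min(5L, length(unique(m[bad]))))], collapse = ", "),
         call. = FALSE)
  invisible(m)
}

assert_binary_mask <- function(m, what = "binary mask") {
  if (!is.matrix(m)) stop(what, " must be a matrix", call. = FALSE)
  if (!all(m %in% c(0L, 1L)))
    stop("invalid ", what, ": pixel values outside {0,1}", call. = FALSE)
  invisible(m)
}

assert_same_dim <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("shape error: dimensions differ (", paste(dim(a), collapse = "x"),
         " vs ", paste(dim(b), collapse = "x"), ")", call. = FALSE)
  invisible(NULL)
}

#' Restrict a label mask to one class
#'
#' Returns the binary view of a single lesion class: 1 exactly where the mask
#' equals `cls`, 0 elsewhere.
#'
#' @param mask label mask (values 0/1/2).
#' @param cls class label, 1 (ischemic) or 2 (hemorrhagic).
#' @return binary matrix of the same dimensions.
#' @export
split_by_class <- function(mask, cls) {
  assert_label_mask(mask)
  if (length(cls) != 1L || !cls %in% c(1L, 2L))
    stop("invalid class: cls must be 1 or 2", call. = FALSE)
  out <- matrix(0L, nrow(mask), ncol(mask))
  out[mask == as.integer(cls)] <- 1L
  out
}

# Shift a matrix by (dr, dc) filling vacated cells with `fill`.
shift_mat <- function(m, dr, dc, fill = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  sr <- max(1L, 1L + dr):min(nr, nr + dr)
  sc <- max(1L, 1L + dc):min(nc, nc + dc)
  if (length(sr) < 1L || length(sc) < 1L) return(out)
  out[sr, sc] <- m[sr - dr, sc - dc]
  out
}

#' Binary erosion with a 3x3 all-ones kernel, one iteration
#'
#' A pixel survives iff its full 3x3 neighborhood is 1. Pixels outside the
#' grid count as 0 (zero padding), so foreground touching the border is
#' always eroded away.
#'
#' @param mask binary matrix (values 0/1).
#' @return binary matrix of the same dimensions.
#' @export
erode3 <- function(mask) {
  assert_binary_mask(mask)
  acc <- mask
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    acc <- acc & shift_mat(mask, dr, dc, 0L)
  }
  matrix(as.integer(acc), nrow(mask), ncol(mask))
}

#' Binary dilation with a 3x3 all-ones kernel, one iteration
#'
#' A pixel becomes 1 iff any pixel of its 3x3 neighborhood is 1 in the input;
#' zero padding outside the grid.
#'
#' @inheritParams erode3
#' @return binary matrix of the same dimensions.
#' @export
dilate3 <- function(mask) {
  assert_binary_mask(mask)
  acc <- mask
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    acc <- acc | shift_mat(mask, dr, dc, 0L)
  }
  matrix(as.integer(acc), nrow(mask), ncol(mask))
}

#' Merge per-class binary masks back into a label mask
#'
#' Pixels set in `class1` become label 1, pixels set in `class2` become
#' label 2. Where both are set, class 2 (hemorrhagic) wins: the class-2
#' assignment is applied last. This precedence is fixed, not configurable,
#' so scores are reproducible.
#'
#' @param class1,class2 binary matrices of equal dimensions.
#' @return label mask of the same dimensions.
#' @export
merge_class_masks <- function(class1, class2) {
  assert_binary_mask(class1, "class-1 mask")
  assert_binary_mask(class2, "class-2 mask")
  assert_same_dim(class1, class2)
  out <- matrix(0L, nrow(class1), ncol(class1))
  out[class1 == 1L] <- 1L
  out[class2 == 1L] <- 2L  # class 2 overwrites on overlap
  out
}

#' Build the eroded/dilated tolerance envelope of a ground-truth mask
#'
#' The ground truth is split into its two class-restricted binary views; each
#' is eroded and dilated with the 3x3 kernel (one iteration); the per-class
#' results are merged back so pixel classes are preserved. The pair bounds
#' the region within which a prediction is treated as fully correct by
#' [relaxed_iou()].
#'
#' @param gt ground-truth label mask.
#' @return list with components `eroded` and `dilated`, both label masks of
#'   the same dimensions as `gt`, satisfying
#'   `support(eroded) subset of support(gt) subset of support(dilated)`.
#' @export
build_envelope <- function(gt) {
  assert_label_mask(gt, "ground truth")
  m1 <- split_by_class(gt, 1L)
  m2 <- split_by_class(gt, 2L)
  list(
    eroded  = merge_class_masks(erode3(m1),  erode3(m2)),
    dilated = merge_class_masks(dilate3(m1), dilate3(m2))
  )
}
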