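#' Four-folder dataset layout and manifests
#'
#' Every image id yields four files in four folders:
#' `DICOM/{imageid}.dcm` (anonymized DICOM, model input),
#' `PNG/{imageid}.png` (window-leveled display rendering, RGBA),
#' `MASK/{imageid}.png` (label mask, literal 0/1/2 values) and
#' `OVERLAY/{imageid}.png` (display image blended with the mask, lesion
#' boundaries in blue/green). A manifest records, per image, the split, the
#' clinical category and the four paths.
#'
#' @name layout
NULL

dataset_folders <- c("DICOM", "PNG", "MASK", "OVERLAY")

#' Valid split and category labels
#'
#' Splits: `training`, `stage1`, `stage2`. Categories: images with no
#' evidence of acute stroke or only chronic ischemic findings
#' (`no_stroke_or_chronic`), hyperacute/acute ischemic findings
#' (`ischemic`), hemorrhagic findings (`hemorrhagic`), and images with both
#' lesion types or differential-diagnosis pathologies
#' (`both_or_differential`).
#'
#' @export
dataset_categories <- function() {
  c("no_stroke_or_chronic", "ischemic", "hemorrhagic", "both_or_differential")
}

#' @rdname dataset_categories
#' @export
dataset_splits <- function() c("training", "stage1", "stage2")

manifest_paths <- function(image_id) {
  list(dicom = file.path("DICOM", paste0(image_id, ".dcm")),
       png = file.path("PNG", paste0(image_id, ".png")),
       mask = file.path("MASK", paste0(image_id, ".png")),
       overlay = file.path("OVERLAY", paste0(image_id, ".png")))
}

#' Build a manifest from per-category image counts
#'
#' Bookkeeping constructor: assigns sequential image ids per category and
#' lays out the four relative file paths for each, without writing files.
#' Useful for composition checks of a planned split.
#'
#' @param split one of [dataset_splits()].
#' @param counts named integer vector; names must be a subset of
#'   [dataset_categories()].
#' @return data frame of class `dataset_manifest` with columns `image_id`,
#'   `split`, `category`, `dicom`, `png`, `mask`, `overlay`.
#' @examples
#' m <- make_manifest("training", c(no_stroke_or_chronic = 4427,
#'                                  ischemic = 1131, hemorrhagic = 1093))
#' nrow(m)  # 6651
#' @export
make_manifest <- function(split, counts) {
  split <- match.arg(split, dataset_splits())
  if (is.null(names(counts)) || !all(names(counts) %in% dataset_categories()))
    stop("counts must be named by dataset categories", call. = FALSE)
  category <- rep(names(counts), times = counts)
  n <- length(category)
  image_id <- sprintf("%s_%05d", split, seq_len(n))
  paths <- lapply(image_id, manifest_paths)
  out <- data.frame(
    image_id = image_id, split = split, category = category,
    dicom = vapply(paths, `[[`, "", "dicom"),
    png = vapply(paths, `[[`, "", "png"),
    mask = vapply(paths, `[[`, "", "mask"),
    overlay = vapply(paths, `[[`, "", "overlay"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("dataset_manifest", "data.frame")
  out
}

#' Per-category counts and total of a manifest
#'
#' @param manifest a `dataset_manifest`.
#' @return list with `total` and named vector `per_category`.
#' @export
manifest_totals <- function(manifest) {
  per <- vapply(dataset_categories(),
                function(k) sum(manifest$category == k), integer(1))
  list(total = nrow(manifest), per_category = per)
}

#' Write the four-folder dataset layout to disk
#'
#' For each entry, writes the anonymized DICOM, the window-leveled display
#' PNG, the literal-valued mask PNG and the overlay PNG, and returns the
#' manifest describing what was written.
#'
#' @param entries list of entries, each a list with `image_id` (unique
#'   string), `dicom` (path to a DICOM file or a `dicom` object), `mask`
#'   (label mask matrix) and optionally `category` (default
#'   `"no_stroke_or_chronic"`).
#' @param root output directory; the four folders are created beneath it.
#' @param split split label recorded in the manifest.
#' @param profile anonymization whitelist applied to every DICOM.
#' @return `dataset_manifest` data frame (paths relative to `root`).
#' @export
write_dataset_layout <- function(entries, root, split = "training",
                                 profile = anonymization_profile()) {
  split <- match.arg(split, dataset_splits())
  ids <- vapply(entries, `[[`, "", "image_id")
  if (anyDuplicated(ids))
    stop("duplicate image ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  for (f in dataset_folders)
    dir.create(file.path(root, f), recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(entries, function(e) {
    ds <- if (inherits(e$dicom, "dicom")) e$dicom else read_dicom(e$dicom)
    ds <- anonymize_dataset(ds, profile)
    p <- manifest_paths(e$image_id)
    write_dicom(ds, file.path(root, p$dicom))
    disp <- dicom_display_matrix(ds)
    g <- disp / 255
    rgba <- array(c(g, g, g, matrix(1, nrow(g), ncol(g))), c(dim(g), 4L))
    png::writePNG(rgba, file.path(root, p$png))
    write_mask_png(e$mask, file.path(root, p$mask))
    png::writePNG(render_overlay(disp, e$mask), file.path(root, p$overlay))
    data.frame(image_id = e$image_id, split = split,
               category = if (is.null(e$category)) "no_stroke_or_chronic" else e$category,
               dicom = p$dicom, png = p$png, mask = p$mask, overlay = p$overlay,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- make_manifest(split, stats::setNames(integer(0), character(0)))[0, ]
  class(out) <- c("dataset_manifest", "data.frame")
  out
}

#' Validate a dataset layout against its manifest
#'
#' Reports the image total, per-category counts, files listed in the
#' manifest but missing on disk, and images whose mask matrix size differs
#' from the expected one (non-standard matrix sizes were excluded from the
#' original test sets).
#'
#' @param manifest a `dataset_manifest`.
#' @param root directory the manifest paths are relative to; `NULL` skips
#'   all on-disk checks (pure bookkeeping report).
#' @param expected_dim expected mask matrix size, default `c(512, 512)`.
#' @return list with `total`, `per_category`, `missing` (data frame
#'   `image_id`,`file`) and `nonstandard` (character vector of image ids).
#' @export
validate_manifest <- function(manifest, root = NULL,
                              expected_dim = c(512L, 512L)) {
  totals <- manifest_totals(manifest)
  missing <- data.frame(image_id = character(), file = character(),
                        stringsAsFactors = FALSE)
  nonstandard <- character()
  if (!is.null(root)) {
    for (i in seq_len(nrow(manifest))) {
      for (col in c("dicom", "png", "mask", "overlay")) {
        f <- manifest[[col]][i]
        if (!file.exists(file.path(root, f)))
          missing <- rbind(missing, data.frame(image_id = manifest$image_id[i],
                                               file = f, stringsAsFactors = FALSE))
      }
      mf <- file.path(root, manifest$mask[i])
      if (file.exists(mf)) {
        m <- read_mask_png(mf)
        if (!identical(dim(m), as.integer(expected_dim)))
          nonstandard <- c(nonstandard, manifest$image_id[i])
      }
    }
  }
  list(total = totals$total, per_category = totals$per_category,
       missing = missing, nonstandard = nonstandard)
}

#' Read and write manifest CSV files
#'
#' Serialized with header `image_id,split,category`; the four file paths
#' are reconstructed from the image id on read.
#'
#' @param manifest a `dataset_manifest`.
#' @param path CSV path.
#' @return `write_manifest_csv`: `path`, invisibly. `read_manifest_csv`:
#'   a `dataset_manifest`.
#' @export
write_manifest_csv <- function(manifest, path) {
  utils::write.csv(manifest[, c("image_id", "split", "category")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_manifest_csv
#' @export
read_manifest_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("image_id", "split", "category") %in% names(df)))
    stop("manifest CSV must have header image_id,split,category", call. = FALSE)
  paths <- lapply(df$image_id, manifest_paths)
  df$dicom <- vapply(paths, `[[`, "", "dicom")
  df$png <- vapply(paths, `[[`, "", "png")
  df$mask <- vapply(paths, `[[`, "", "mask")
  df$overlay <- vapply(paths, `[[`, "", "overlay")
  class(df) <- c("dataset_manifest", "data.frame")
  df
}
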