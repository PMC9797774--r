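#' Seeded synthetic fixtures
#'
#' Every generator is a pure function of its configuration and seed: the
#' global RNG state is left untouched (`withr::with_seed`, R's default
#' Mersenne-Twister generator, fixed across releases so goldens are stable).
#' Phantoms emulate the *format* of the competition data — elliptical
#' multi-class lesion blobs in a 512x512 (configurable) grid — not CT
#' anatomy or texture.
#'
#' @name synthetic
NULL

derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 1000003) * 1009 + offset) %% 2000000011L
}

#' Generate a lesion phantom label mask
#'
#' Places random rotated elliptical blobs: `n_class1` ischemic (label 1)
#' and `n_class2` hemorrhagic (label 2) lesions with semi-axes drawn
#' uniformly from `radius_range`. Class-2 blobs are drawn last and
#' overwrite on overlap, matching the class precedence used everywhere in
#' the package.
#'
#' @param rows,cols grid size; default 512x512.
#' @param n_class1,n_class2 lesion counts per class.
#' @param radius_range length-2 vector of semi-axis bounds in pixels
#'   (min >= 1).
#' @param min_gap minimum Chebyshev distance, in pixels, between class-1 and
#'   class-2 supports. The default 0 allows adjacent or overlapping lesions
#'   (class 2 overwrites), which is the realistic case; a gap of at least 2
#'   keeps the class-2 dilation out of class-1 territory, so a pixel-perfect
#'   prediction of such a phantom scores IoU exactly 1.
#' @param seed integer seed.
#' @return label mask (integer matrix).
#' @export
gen_phantom <- function(rows = 512L, cols = 512L, n_class1 = 1L, n_class2 = 1L,
                        radius_range = c(8, 16), min_gap = 0L, seed = 1L) {
  stopifnot(rows >= 1, cols >= 1, n_class1 >= 0, n_class2 >= 0, min_gap >= 0)
  if (radius_range[1L] < 1) stop("lesion radii must be >= 1", call. = FALSE)
  margin <- ceiling(radius_range[2L]) + 1L
  if ((n_class1 + n_class2) > 0 &&
      (rows < 2L * margin + 1L || cols < 2L * margin + 1L))
    stop("generation error: lesions of radius ", radius_range[2L],
         " cannot fit inside a ", rows, "x", cols, " grid", call. = FALSE)
  withr::with_seed(seed, {
    m <- matrix(0L, rows, cols)
    for (cls in c(1L, 2L)) {
      n <- if (cls == 1L) n_class1 else n_class2
      for (k in seq_len(n)) {
        placed <- FALSE
        for (attempt in seq_len(100L)) {
          a <- stats::runif(1, radius_range[1L], radius_range[2L])
          b <- stats::runif(1, radius_range[1L], radius_range[2L])
          theta <- stats::runif(1, 0, pi)
          cr <- sample(seq.int(margin + 1L, rows - margin), 1L)
          cc <- sample(seq.int(margin + 1L, cols - margin), 1L)
          r_idx <- seq.int(cr - margin, cr + margin)
          c_idx <- seq.int(cc - margin, cc + margin)
          dr <- outer(r_idx - cr, rep(1, length(c_idx)))
          dc <- outer(rep(1, length(r_idx)), c_idx - cc)
          u <- dr * cos(theta) + dc * sin(theta)
          v <- -dr * sin(theta) + dc * cos(theta)
          inside <- (u / a)^2 + (v / b)^2 <= 1
          if (min_gap > 0L && cls == 2L && any(m == 1L)) {
            other <- which(m == 1L, arr.ind = TRUE)
            cand_r <- r_idx[row(inside)[inside]]
            cand_c <- c_idx[col(inside)[inside]]
            cheb <- pmax(abs(outer(cand_r, other[, 1L], "-")),
                         abs(outer(cand_c, other[, 2L], "-")))
            if (min(cheb) < min_gap) next
          }
          sub <- m[r_idx, c_idx]
          sub[inside] <- cls
          m[r_idx, c_idx] <- sub
          placed <- TRUE
          break
        }
        if (!placed)
          stop("generation error: could not place a class-", cls,
               " lesion honoring min_gap = ", min_gap, call. = FALSE)
      }
    }
    m
  })
}

# 4-connected components of the nonzero support, labeled 1..k by iterative
# minimum-label propagation (vectorized; iteration count bounded by the
# largest component diameter).
label_components <- function(mask) {
  fg <- mask != 0L
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[fg] <- seq_len(sum(fg))
  repeat {
    new <- lab
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      s <- shift_mat(lab, d[1L], d[2L], 0L)
      upd <- fg & s > 0L & s < new
      new[upd] <- s[upd]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  ids <- sort(unique(lab[lab > 0L]))
  lab[lab > 0L] <- match(lab[lab > 0L], ids)
  lab
}

#' Specify a controlled degradation of a ground-truth mask
#'
#' @param dilate_steps,erode_steps per-class 3x3 morphology iterations
#'   applied to the prediction (growth / shrinkage).
#' @param shift integer `(drow, dcol)` translation, zero-filled.
#' @param class_flip_prob per-lesion probability of swapping class 1 and 2.
#' @param drop_lesion_prob per-lesion probability of removal.
#' @param seed integer seed for the random per-lesion decisions.
#' @return list of class `degradation_spec`.
#' @export
degradation_spec <- function(dilate_steps = 0L, erode_steps = 0L,
                             shift = c(0L, 0L), class_flip_prob = 0,
                             drop_lesion_prob = 0, seed = 1L) {
  stopifnot(dilate_steps >= 0, erode_steps >= 0, length(shift) == 2L,
            class_flip_prob >= 0, class_flip_prob <= 1,
            drop_lesion_prob >= 0, drop_lesion_prob <= 1)
  structure(list(dilate_steps = as.integer(dilate_steps),
                 erode_steps = as.integer(erode_steps),
                 shift = as.integer(shift),
                 class_flip_prob = class_flip_prob,
                 drop_lesion_prob = drop_lesion_prob,
                 seed = as.integer(seed)),
            class = "degradation_spec")
}

#' Degrade a ground-truth mask into a synthetic team prediction
#'
#' Applies, in order: per-lesion drops, per-lesion class flips,
#' class-preserving dilation/erosion steps, and the translation. The
#' identity spec returns the input unchanged; a pure one-step dilation or
#' erosion stays inside the scoring envelope and still scores IoU 1.
#'
#' @param gt ground-truth label mask.
#' @param spec a [degradation_spec()].
#' @return degraded label mask of the same dimensions.
#' @export
degrade <- function(gt, spec) {
  assert_label_mask(gt, "ground truth")
  stopifnot(inherits(spec, "degradation_spec"))
  m <- gt
  if (spec$drop_lesion_prob > 0 || spec$class_flip_prob > 0) {
    comp <- label_components(m)
    k <- max(comp)
    if (k > 0L) {
      withr::with_seed(spec$seed, {
        drop <- stats::runif(k) < spec$drop_lesion_prob
        flip <- stats::runif(k) < spec$class_flip_prob
      })
      for (i in seq_len(k)) {
        px <- comp == i
        if (drop[i]) {
          m[px] <- 0L
        } else if (flip[i]) {
          vals <- m[px]
          m[px] <- ifelse(vals == 1L, 2L, ifelse(vals == 2L, 1L, 0L))
        }
      }
    }
  }
  if (spec$dilate_steps > 0L || spec$erode_steps > 0L) {
    m1 <- split_by_class(m, 1L); m2 <- split_by_class(m, 2L)
    for (s in seq_len(spec$dilate_steps)) { m1 <- dilate3(m1); m2 <- dilate3(m2) }
    for (s in seq_len(spec$erode_steps)) { m1 <- erode3(m1); m2 <- erode3(m2) }
    m <- merge_class_masks(m1, m2)
  }
  if (any(spec$shift != 0L)) m <- shift_mat(m, spec$shift[1L], spec$shift[2L], 0L)
  m
}

#' Generate a full multi-team synthetic competition
#'
#' One phantom ground truth per image; one degraded submission per team per
#' image, with team quality controlled by `quality_spread`.
#'
#' @param n_teams,n_images counts.
#' @param quality_spread list of `n_teams` [degradation_spec()]s.
#' @param seed integer master seed; per-image and per-team seeds are derived
#'   from it.
#' @param rows,cols mask size; defaults to the desk-scale 128x128 rather
#'   than the full 512x512.
#' @param ... further arguments passed to [gen_phantom()].
#' @return list with `truths` (list of `n_images` masks, named
#'   `img001`, ...) and `submissions` (list of `n_teams` lists of masks,
#'   named `team01`, ...).
#' @export
gen_competition <- function(n_teams, n_images, quality_spread, seed = 1L,
                            rows = 128L, cols = 128L, ...) {
  if (length(quality_spread) != n_teams)
    stop("quality_spread must have one degradation_spec per team", call. = FALSE)
  image_ids <- sprintf("img%03d", seq_len(n_images))
  team_ids <- sprintf("team%02d", seq_len(n_teams))
  truths <- lapply(seq_len(n_images), function(i)
    gen_phantom(rows = rows, cols = cols, seed = derive_seed(seed, i), ...))
  names(truths) <- image_ids
  submissions <- lapply(seq_len(n_teams), function(t) {
    subs <- lapply(seq_len(n_images), function(i) {
      sp <- quality_spread[[t]]
      sp$seed <- derive_seed(seed, 100000L + t * 1000L + i)
      degrade(truths[[i]], sp)
    })
    names(subs) <- image_ids
    subs
  })
  names(submissions) <- team_ids
  list(truths = truths, submissions = submissions)
}

synthetic_tag_values <- function() {
  list(
    PatientName = "ANON^SYNTHETIC", PatientID = "SYN000001",
    PatientBirthDate = "19600101", PatientSex = "O", PatientAge = "060Y",
    StudyDate = "20200101", StudyTime = "120000", AccessionNumber = "ACC0001",
    Modality = "CT", Manufacturer = "Synthetic Imaging",
    InstitutionName = "Synthetic Hospital", ReferringPhysicianName = "REF^DOC",
    StudyDescription = "Synthetic head CT", StationName = "CT01",
    StudyInstanceUID = "1.2.826.0.1.3680043.8.498.10.1",
    SeriesInstanceUID = "1.2.826.0.1.3680043.8.498.10.2",
    InstanceNumber = "1", KVP = "120"
  )
}

#' Generate a synthetic single-frame CT DICOM file
#'
#' Carries the full anonymization whitelist (CT geometry, 16-bit pixels
#' stored at 12-bit depth, brain window 40/80, rescale intercept -1024),
#' the requested extra identifying tags with canned synthetic values, and
#' seeded random pixel data.
#'
#' @param rows,cols image size.
#' @param extra_tags character vector of additional tag keywords (e.g.
#'   `"PatientName"`, `"StudyDate"`); must exist in the package dictionary.
#' @param seed integer seed for the pixel data.
#' @param path optional output file; when `NULL` the `dicom` object is
#'   returned without touching disk.
#' @return the `dicom` object (invisibly when written to `path`).
#' @export
gen_dicom <- function(rows = 512L, cols = 512L, extra_tags = character(),
                      seed = 1L, path = NULL) {
  stopifnot(rows >= 1, cols >= 1)
  px <- withr::with_seed(seed, sample.int(4096L, rows * cols, replace = TRUE) - 1L)
  els <- list(
    dicom_element("SOPClassUID", "1.2.840.10008.5.1.4.1.1.2"),
    dicom_element("SOPInstanceUID",
                  paste("1.2.826.0.1.3680043.8.498", seed, rows, cols, sep = ".")),
    dicom_element("SliceThickness", "5.0"),
    dicom_element("SamplesPerPixel", 1L),
    dicom_element("PhotometricInterpretation", "MONOCHROME2"),
    dicom_element("Rows", rows),
    dicom_element("Columns", cols),
    dicom_element("PixelSpacing", c("0.45", "0.45")),
    dicom_element("BitsAllocated", 16L),
    dicom_element("BitsStored", 12L),
    dicom_element("HighBit", 11L),
    dicom_element("PixelRepresentation", 0L),
    dicom_element("PixelPaddingValue", 0L),
    dicom_element("WindowCenter", "40"),
    dicom_element("WindowWidth", "80"),
    dicom_element("RescaleIntercept", "-1024"),
    dicom_element("RescaleSlope", "1"),
    dicom_element("RescaleType", "HU"),
    dicom_element("PixelData", uint16_bytes(px))  # raster order, 2 bytes/pixel
  )
  vals <- synthetic_tag_values()
  for (tg in extra_tags) {
    v <- vals[[tg]]
    if (is.null(v)) v <- "SYNTHETIC"
    els[[length(els) + 1L]] <- dicom_element(tg, v)
  }
  ds <- dicom_create(els)
  if (!is.null(path)) {
    write_dicom(ds, path)
    return(invisible(ds))
  }
  ds
}

#' Generate a synthetic case registry with a planted composition
#'
#' Plants, per filter criterion, the requested number of records that
#' satisfy it (diagnosis/anchor event plus confirming imaging event inside
#' the +/- window), plants records whose reports contain a query phrase,
#' and fills the remainder with noise engineered to match nothing: lone
#' diagnosis codes, confirming imaging outside the window, and neutral
#' report text.
#'
#' @param n_cases total number of records.
#' @param criterion_counts integer vector, one count per criterion in
#'   `config$criteria`.
#' @param keyword_count number of keyword-matching records.
#' @param seed integer seed.
#' @param config search configuration; default [default_search_config()].
#' @return list of [case_record()]s with ids `case00001`, ...
#' @export
gen_registry <- function(n_cases, criterion_counts = c(0L, 0L, 0L),
                         keyword_count = 0L, seed = 1L,
                         config = default_search_config()) {
  if (length(criterion_counts) != length(config$criteria))
    stop("criterion_counts must have one entry per criterion", call. = FALSE)
  if (sum(criterion_counts) + keyword_count > n_cases)
    stop("infeasible composition: planted counts exceed n_cases", call. = FALSE)
  base <- as.POSIXct("2019-01-01 00:00:00", tz = "UTC")
  withr::with_seed(seed, {
    records <- vector("list", n_cases)
    idx <- 1L
    mk_id <- function(i) sprintf("case%05d", i)
    for (ci in seq_along(config$criteria)) {
      cr <- config$criteria[[ci]]
      for (k in seq_len(criterion_counts[ci])) {
        t0 <- base + sample.int(700L, 1L) * 86400
        offset <- sample(seq.int(-cr$window_days, cr$window_days), 1L) * 86400
        if (length(cr$required_icd)) {
          a <- coded_event(sample(cr$required_icd, 1L), "icd10", t0)
          b_code <- sample(c(cr$anchor_procedures, cr$companion_procedures), 1L)
        } else {
          a <- coded_event(sample(cr$anchor_procedures, 1L), "procedure", t0)
          b_code <- sample(cr$companion_procedures, 1L)
        }
        b <- coded_event(b_code, "procedure", t0 + offset)
        records[[idx]] <- case_record(mk_id(idx), list(a, b),
                                      "Acute findings consistent with stroke.")
        idx <- idx + 1L
      }
    }
    for (k in seq_len(keyword_count)) {
      phrase <- sample(config$phrases, 1L)
      # vary case and spacing; matching is normalized
      text <- paste("Report:", tolower(phrase), " No further comment.")
      records[[idx]] <- case_record(mk_id(idx), list(), text)
      idx <- idx + 1L
    }
    all_icd <- unique(unlist(lapply(config$criteria, `[[`, "required_icd")))
    all_proc <- unique(unlist(lapply(config$criteria, function(cr)
      c(cr$anchor_procedures, cr$companion_procedures))))
    while (idx <= n_cases) {
      kind <- sample(3L, 1L)
      t0 <- base + sample.int(700L, 1L) * 86400
      events <- if (kind == 1L) {
        # lone diagnosis, no imaging leg
        list(coded_event(sample(all_icd, 1L), "icd10", t0))
      } else if (kind == 2L) {
        # imaging far outside every window
        max_w <- max(vapply(config$criteria, `[[`, 0, "window_days"))
        list(coded_event(sample(all_icd, 1L), "icd10", t0),
             coded_event(sample(all_proc, 1L), "procedure",
                         t0 + (max_w + sample(15:60, 1L)) * 86400))
      } else {
        # codes outside every search set
        list(coded_event("Z00.0", "icd10", t0),
             coded_event("999.999", "procedure", t0))
      }
      records[[idx]] <- case_record(mk_id(idx), events,
                                    "Chronic microvascular changes only.")
      idx <- idx + 1L
    }
    records
  })
}
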