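#' Registry cohort filtering by diagnosis/procedure codes and keywords
#'
#' Candidate stroke cases are pulled from a case registry by combining an
#' ICD-10 diagnosis (or an anchoring interventional procedure) with a
#' confirming imaging procedure recorded within a time window of it
#' (+/- 15 days by default, inclusive), and independently by free-text
#' report phrases. Each case record carries coded events with timestamps
#' plus a free-text radiology report.
#'
#' A filter criterion is read as `A and (B or C)`: the diagnosis/anchor leg
#' must co-occur with at least one of the alternative imaging confirmations
#' inside the window. The alternative grouping `(A and B) or C` would select
#' every case with the companion imaging procedure regardless of diagnosis,
#' which contradicts the screening purpose, so it is not offered.
#'
#' @name cohort
NULL

#' Construct a coded registry event
#'
#' @param code non-empty ICD-10 or procedure code (e.g. `"I63.9"`,
#'   `"803.900"`).
#' @param kind `"icd10"` or `"procedure"`.
#' @param timestamp `POSIXct` (or anything `as.POSIXct` accepts, UTC).
#' @return list of class `coded_event`.
#' @export
coded_event <- function(code, kind, timestamp) {
  kind <- match.arg(kind, c("icd10", "procedure"))
  if (!nzchar(code)) stop("event code must be non-empty", call. = FALSE)
  structure(list(code = code, kind = kind,
                 timestamp = as.POSIXct(timestamp, tz = "UTC")),
            class = "coded_event")
}

#' Construct a case record
#'
#' @param case_id unique identifier.
#' @param events list of [coded_event()]s.
#' @param report_text free-text radiology report (may be empty).
#' @return list of class `case_record`.
#' @export
case_record <- function(case_id, events = list(), report_text = "") {
  structure(list(case_id = as.character(case_id), events = events,
                 report_text = report_text),
            class = "case_record")
}

#' Construct a filter criterion
#'
#' @param required_icd set of ICD-10 codes; empty for procedure-anchored
#'   criteria, where `anchor_procedures` takes the diagnosis role.
#' @param anchor_procedures procedure codes: the confirming imaging leg when
#'   `required_icd` is non-empty, otherwise the anchoring treatment
#'   procedure.
#' @param companion_procedures alternative confirming procedure codes.
#' @param window_days non-negative time window, inclusive at the boundary.
#' @param label optional human-readable name.
#' @return list of class `filter_criterion`.
#' @export
filter_criterion <- function(required_icd = character(),
                             anchor_procedures = character(),
                             companion_procedures = character(),
                             window_days = 15L, label = NULL) {
  if (window_days < 0) stop("window_days must be >= 0", call. = FALSE)
  structure(list(required_icd = required_icd,
                 anchor_procedures = anchor_procedures,
                 companion_procedures = companion_procedures,
                 window_days = as.numeric(window_days),
                 label = label),
            class = "filter_criterion")
}

#' The default registry search configuration
#'
#' The stroke ICD-10 codes (cerebral infarction I63.9; intracerebral
#' hemorrhage I61.3/I61.9/I61.5; intracranial hemorrhage I62.9; subarachnoid
#' hemorrhage I60.9/I60.7), the imaging/treatment procedure codes (head CT
#' 803.900/803.910, diffusion-weighted MRI 804.220, thrombectomy for acute
#' stroke 802.891, endovascular cerebral aneurysm treatment 802.760), the
#' three filter criteria combining them, and the normal-report keyword
#' phrases — all with the +/- 15-day window.
#'
#' @return list with `criteria` (list of [filter_criterion()]) and
#'   `phrases` (character vector).
#' @export
default_search_config <- function() {
  icd <- c("I63.9", "I61.3", "I62.9", "I60.9", "I61.9", "I61.5", "I60.7")
  head_ct <- c("803.900", "803.910")
  diffusion_mri <- "804.220"
  thrombectomy <- "802.891"
  aneurysm_tx <- "802.760"
  list(
    criteria = list(
      filter_criterion(required_icd = icd, anchor_procedures = head_ct,
                       companion_procedures = diffusion_mri,
                       label = "icd10_and_head_ct_or_diffusion_mri"),
      filter_criterion(anchor_procedures = thrombectomy,
                       companion_procedures = c(head_ct, diffusion_mri),
                       label = "thrombectomy_and_head_ct_or_diffusion_mri"),
      filter_criterion(anchor_procedures = aneurysm_tx,
                       companion_procedures = head_ct,
                       label = "aneurysm_treatment_and_head_ct")
    ),
    phrases = c("Normal head CT",
                "Head CT examination within normal limits",
                "No acute cranial CT finding was detected")
  )
}

#' Are two timestamps within a day window of each other?
#'
#' Inclusive at the boundary: exactly `window_days` x 24 h apart counts as
#' inside the window.
#'
#' @param t1,t2 `POSIXct` timestamps.
#' @param window_days non-negative number of days.
#' @return logical.
#' @export
within_window <- function(t1, t2, window_days = 15) {
  abs(as.numeric(difftime(t1, t2, units = "days"))) <= window_days
}

#' Does a case record satisfy a filter criterion?
#'
#' True iff the record has a diagnosis-leg event (an ICD-10 event from
#' `required_icd`, or — when `required_icd` is empty — a procedure event
#' from `anchor_procedures`) and a confirming-leg event (from
#' `anchor_procedures` union `companion_procedures`, or from
#' `companion_procedures` alone in the procedure-anchored form) within
#' `window_days` of it.
#'
#' @param record a [case_record()].
#' @param criterion a [filter_criterion()].
#' @return logical.
#' @export
matches_criterion <- function(record, criterion) {
  stopifnot(inherits(record, "case_record"), inherits(criterion, "filter_criterion"))
  codes <- vapply(record$events, `[[`, "", "code")
  kinds <- vapply(record$events, `[[`, "", "kind")
  times <- lapply(record$events, `[[`, "timestamp")
  if (length(criterion$required_icd)) {
    a_idx <- which(kinds == "icd10" & codes %in% criterion$required_icd)
    b_codes <- c(criterion$anchor_procedures, criterion$companion_procedures)
  } else {
    a_idx <- which(kinds == "procedure" & codes %in% criterion$anchor_procedures)
    b_codes <- criterion$companion_procedures
  }
  b_idx <- which(kinds == "procedure" & codes %in% b_codes)
  for (a in a_idx)
    for (b in b_idx)
      if (a != b && within_window(times[[a]], times[[b]], criterion$window_days))
        return(TRUE)
  FALSE
}

#' Does a report contain any of the query phrases?
#'
#' Case-insensitive substring search after whitespace normalization (runs of
#' whitespace collapse to single spaces on both sides).
#'
#' @param report_text free text.
#' @param phrases character vector of phrases.
#' @return logical.
#' @export
keyword_query <- function(report_text, phrases) {
  norm <- function(s) tolower(gsub("\\s+", " ", trimws(s)))
  if (!length(phrases)) return(FALSE)
  text <- norm(report_text)
  any(vapply(phrases, function(p) grepl(norm(p), text, fixed = TRUE), logical(1)))
}

#' Run the code criteria and keyword queries over a registry
#'
#' @param registry list of [case_record()]s with unique case ids.
#' @param criteria list of [filter_criterion()]s; default the package's
#'   standard search configuration.
#' @param phrases character vector of report phrases; default likewise.
#' @return list with `selected` (per criterion, sorted character vectors of
#'   matching case ids; named by criterion labels where available) and
#'   `keyword_hits` (sorted ids whose report matches any phrase).
#' @export
select_cases <- function(registry,
                         criteria = default_search_config()$criteria,
                         phrases = default_search_config()$phrases) {
  ids <- vapply(registry, `[[`, "", "case_id")
  if (anyDuplicated(ids))
    stop("duplicate case ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  selected <- lapply(criteria, function(cr) {
    hit <- vapply(registry, matches_criterion, logical(1), criterion = cr)
    sort(ids[hit])
  })
  names(selected) <- vapply(seq_along(criteria), function(i) {
    lb <- criteria[[i]]$label
    if (is.null(lb)) paste0("criterion", i) else lb
  }, "")
  kw <- vapply(registry, function(r) keyword_query(r$report_text, phrases), logical(1))
  list(selected = selected, keyword_hits = sort(ids[kw]))
}

#' Read and write registries as CSV
#'
#' Two tables: events as `case_id,code,kind,timestamp` (ISO-8601 UTC) and
#' reports as `case_id,report_text`.
#'
#' @param registry list of [case_record()]s.
#' @param events_path,reports_path CSV paths.
#' @return `write_registry_csv`: invisibly, the two paths.
#'   `read_registry_csv`: list of [case_record()]s.
#' @export
write_registry_csv <- function(registry, events_path, reports_path) {
  ev <- do.call(rbind, lapply(registry, function(r) {
    if (!length(r$events)) return(NULL)
    data.frame(case_id = r$case_id,
               code = vapply(r$events, `[[`, "", "code"),
               kind = vapply(r$events, `[[`, "", "kind"),
               timestamp = vapply(r$events, function(e)
                 format(e$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"), ""),
               stringsAsFactors = FALSE)
  }))
  if (is.null(ev))
    ev <- data.frame(case_id = character(), code = character(),
                     kind = character(), timestamp = character())
  rp <- data.frame(case_id = vapply(registry, `[[`, "", "case_id"),
                   report_text = vapply(registry, `[[`, "", "report_text"),
                   stringsAsFactors = FALSE)
  utils::write.csv(ev, events_path, row.names = FALSE)
  utils::write.csv(rp, reports_path, row.names = FALSE)
  invisible(c(events_path, reports_path))
}

#' @rdname write_registry_csv
#' @export
read_registry_csv <- function(events_path, reports_path) {
  ev <- utils::read.csv(events_path, stringsAsFactors = FALSE,
                        colClasses = "character")
  rp <- utils::read.csv(reports_path, stringsAsFactors = FALSE,
                        colClasses = "character")
  lapply(seq_len(nrow(rp)), function(i) {
    id <- rp$case_id[i]
    rows <- ev[ev$case_id == id, , drop = FALSE]
    events <- lapply(seq_len(nrow(rows)), function(j)
      coded_event(rows$code[j], rows$kind[j],
                  as.POSIXct(rows$timestamp[j], format = "%Y-%m-%dT%H:%M:%SZ",
                             tz = "UTC")))
    case_record(id, events, rp$report_text[i])
  })
}
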