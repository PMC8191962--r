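## Containers and delimited-text I/O for segmental strain recordings.
##
## A strain trace is one segment's longitudinal strain time series, in
## percent (negative = shortening), on a time axis in seconds whose origin
## is the QRS onset. A view recording holds the six traces of one apical
## view plus the aortic-valve-closure time of that view; a patient record
## holds the three views plus the clinician-supplied scalars.

#' Construct a strain trace
#'
#' @param segment_id Segment label, e.g. `"BS"` (see [view_segments()]).
#' @param time Numeric vector, seconds from QRS onset; strictly increasing,
#'   first sample at 0.
#' @param strain Numeric vector, percent (negative during shortening); same
#'   length as `time`, all finite.
#' @return An object of class `strain_trace`.
#' @export
strain_trace <- function(segment_id, time, strain) {
  tr <- structure(list(segment_id = as.character(segment_id),
                       time = as.numeric(time),
                       strain = as.numeric(strain)),
                  class = "strain_trace")
  validate_strain_trace(tr)
}

#' @rdname strain_trace
#' @param tr A `strain_trace`.
#' @export
validate_strain_trace <- function(tr) {
  if (length(tr$time) != length(tr$strain))
    stop("trace '", tr$segment_id, "': time and strain lengths differ")
  if (length(tr$time) < 1L)
    stop("trace '", tr$segment_id, "': empty trace")
  if (abs(tr$time[1]) > 1e-12)
    stop("trace '", tr$segment_id, "': time must start at 0 (QRS onset)")
  if (any(diff(tr$time) <= 0))
    stop("trace '", tr$segment_id, "': time not strictly increasing")
  if (!all(is.finite(tr$strain)))
    stop("trace '", tr$segment_id, "': non-finite strain values")
  tr
}

#' @export
print.strain_trace <- function(x, ...) {
  cat(sprintf("<strain_trace %s: %d samples over %.3f s, range [%.2f, %.2f] %%>\n",
              x$segment_id, length(x$time), max(x$time),
              min(x$strain), max(x$strain)))
  invisible(x)
}

#' Construct a view recording
#'
#' @param view One of `"4ch"`, `"3ch"`, `"2ch"`.
#' @param traces List of exactly six [strain_trace()] objects covering the
#'   view's segment set (any order; stored in canonical order).
#' @param t_avc Aortic-valve-closure time in seconds from QRS onset; must lie
#'   in `(0, max(time)]` of every trace.
#' @return An object of class `view_recording`.
#' @export
view_recording <- function(view, traces, t_avc) {
  view <- match.arg(view, strain_views())
  rec <- structure(list(view = view, traces = traces,
                        t_avc = as.numeric(t_avc)),
                   class = "view_recording")
  validate_view_recording(rec)
}

#' @rdname view_recording
#' @param rec A `view_recording`.
#' @export
validate_view_recording <- function(rec) {
  expected <- view_segments(rec$view)
  ids <- vapply(rec$traces, function(tr) tr$segment_id, character(1))
  missing <- setdiff(expected, ids)
  if (length(missing))
    stop("view ", rec$view, ": missing segment ", paste(missing, collapse = ", "))
  extra <- setdiff(ids, expected)
  if (length(extra))
    stop("view ", rec$view, ": unexpected segment ", paste(extra, collapse = ", "))
  if (anyDuplicated(ids))
    stop("view ", rec$view, ": duplicated segment labels")
  lapply(rec$traces, validate_strain_trace)
  if (!is.finite(rec$t_avc) || rec$t_avc <= 0)
    stop("view ", rec$view, ": t_avc must be > 0")
  tmax <- min(vapply(rec$traces, function(tr) max(tr$time), numeric(1)))
  if (rec$t_avc > tmax + 1e-9)
    stop("view ", rec$view, ": t_avc ", rec$t_avc,
         " beyond the end of the traces (", tmax, ")")
  rec$traces <- rec$traces[match(expected, ids)]
  names(rec$traces) <- expected
  rec
}

#' @export
print.view_recording <- function(x, ...) {
  cat(sprintf("<view_recording %s: 6 segments, t_avc = %.3f s>\n",
              x$view, x$t_avc))
  invisible(x)
}

#' Construct a patient record
#'
#' @param patient_id Identifier string.
#' @param views Named list with elements `"4ch"`, `"3ch"`, `"2ch"`, each a
#'   [view_recording()] of the matching view.
#' @param qrs_duration QRS duration in ms (> 0).
#' @param lvef Left-ventricular ejection fraction in percent, in (0, 100).
#' @param esv_baseline,esv_followup LV end-systolic volumes in mL (optional;
#'   `NA` when unknown).
#' @param response `"responder"`, `"non-responder"` or `"unknown"`. When both
#'   volumes are given the label is derived with [classify_response()].
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(patient_id, views, qrs_duration, lvef,
                           esv_baseline = NA_real_, esv_followup = NA_real_,
                           response = NULL) {
  if (is.null(response)) {
    response <- if (is.finite(esv_baseline) && is.finite(esv_followup))
      classify_response(esv_baseline, esv_followup) else "unknown"
  }
  p <- structure(list(patient_id = as.character(patient_id),
                      views = views,
                      qrs_duration = as.numeric(qrs_duration),
                      lvef = as.numeric(lvef),
                      esv_baseline = as.numeric(esv_baseline),
                      esv_followup = as.numeric(esv_followup),
                      response = response),
                 class = "patient_record")
  validate_patient_record(p)
}

#' @rdname patient_record
#' @param p A `patient_record`.
#' @export
validate_patient_record <- function(p) {
  for (v in strain_views()) {
    if (is.null(p$views[[v]]))
      stop("patient ", p$patient_id, ": missing view ", v)
    if (p$views[[v]]$view != v)
      stop("patient ", p$patient_id, ": view slot ", v, " holds a ",
           p$views[[v]]$view, " recording")
    validate_view_recording(p$views[[v]])
  }
  if (!is.finite(p$qrs_duration) || p$qrs_duration <= 0)
    stop("patient ", p$patient_id, ": qrs_duration must be > 0")
  if (!is.finite(p$lvef) || p$lvef <= 0 || p$lvef >= 100)
    stop("patient ", p$patient_id, ": lvef must be in (0, 100)")
  if (!p$response %in% c("responder", "non-responder", "unknown"))
    stop("patient ", p$patient_id, ": invalid response label '", p$response, "'")
  p
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record %s: 3 views, QRS %.0f ms, LVEF %.0f%%, %s>\n",
              x$patient_id, x$qrs_duration, x$lvef, x$response))
  invisible(x)
}

#' Read one view waveform file
#'
#' The dialect is UTF-8 comma-delimited text: header lines `# key: value`
#' for keys `view`, `t_qrs_s`, `t_avc_s`, `sampling_hz`, then a column header
#' `time_s,<seg1>,...,<seg6>` and numeric rows. `t_avc_s` is measured from
#' the QRS onset. The time axis is re-zeroed at the declared `t_qrs_s` on
#' load, so downstream formulas can take t = 0 as the QRS onset.
#'
#' @param path Path to the file.
#' @param view Expected view id; defaults to the `view` header value.
#' @return A validated [view_recording()].
#' @export
read_view_file <- function(path, view = NULL) {
  if (!file.exists(path)) stop("view file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr_idx <- grep("^#", lines)
  meta <- list()
  for (ln in lines[hdr_idx]) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_0-9]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- trimws(m[3])
  }
  for (key in c("view", "t_qrs_s", "t_avc_s"))
    if (is.null(meta[[key]]))
      stop("view file ", path, ": missing header field '", key, "'")
  file_view <- meta$view
  if (is.null(view)) view <- file_view
  if (!identical(view, file_view))
    stop("view file ", path, ": declares view '", file_view,
         "' but '", view, "' was expected")
  t_qrs <- as.numeric(meta$t_qrs_s)
  t_avc <- as.numeric(meta$t_avc_s)
  if (!is.finite(t_qrs)) stop("view file ", path, ": bad t_qrs_s")
  if (!is.finite(t_avc)) stop("view file ", path, ": bad t_avc_s")
  body <- utils::read.csv(textConnection(lines[setdiff(seq_along(lines), hdr_idx)]),
                          check.names = FALSE)
  if (!"time_s" %in% names(body))
    stop("view file ", path, ": missing column 'time_s'")
  segs <- view_segments(view)
  missing <- setdiff(segs, names(body))
  if (length(missing))
    stop("view file ", path, ": missing segment ", paste(missing, collapse = ", "))
  time <- body$time_s - t_qrs
  if (abs(time[1]) > 1e-9)
    stop("view file ", path, ": first sample (", body$time_s[1],
         ") does not coincide with declared t_qrs_s (", t_qrs, ")")
  time[1] <- 0
  traces <- lapply(segs, function(sg) strain_trace(sg, time, body[[sg]]))
  view_recording(view, traces, t_avc)
}

#' Write one view waveform file
#'
#' Inverse of [read_view_file()]: the written file re-reads to the same
#' recording to 1e-9 on all numeric fields. Times are written with the
#' in-memory convention (QRS onset at 0, so `t_qrs_s: 0`).
#'
#' @param rec A validated [view_recording()].
#' @param path Output path.
#' @param sampling_hz Original sampling rate recorded as metadata (Hz).
#' @return `path`, invisibly.
#' @export
write_view_file <- function(rec, path, sampling_hz = NA) {
  rec <- validate_view_recording(rec)
  segs <- view_segments(rec$view)
  if (is.na(sampling_hz)) {
    dt <- diff(rec$traces[[1]]$time)
    sampling_hz <- round(1 / stats::median(dt), 6)
  }
  hdr <- c(paste0("# view: ", rec$view),
           "# t_qrs_s: 0",
           paste0("# t_avc_s: ", format(rec$t_avc, digits = 15)),
           paste0("# sampling_hz: ", format(sampling_hz, digits = 15)))
  mat <- cbind(time_s = rec$traces[[1]]$time,
               do.call(cbind, lapply(rec$traces, function(tr) tr$strain)))
  colnames(mat) <- c("time_s", segs)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(colnames(mat), collapse = ","), con)
  writeLines(apply(format(mat, digits = 15, trim = TRUE, scientific = FALSE),
                   1, paste, collapse = ","), con)
  invisible(path)
}

#' Load a cohort from a manifest file
#'
#' The manifest is comma-delimited with columns `patient_id`, `file_4ch`,
#' `file_3ch`, `file_2ch`, `qrs_ms`, `lvef_pct`, `esv_baseline_ml`,
#' `esv_followup_ml` (the two volumes may be empty). View-file paths are
#' resolved relative to the manifest's directory. Patients whose files fail
#' validation are skipped with a message naming the reason — mirroring the
#' clinical practice of withdrawing recordings with unusable strain signals
#' — rather than aborting the whole run.
#'
#' @param manifest Path to the manifest file.
#' @return List of validated [patient_record()]s; the character vector of
#'   skip messages is attached as attribute `"skipped"`.
#' @export
load_cohort <- function(manifest) {
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  tab <- utils::read.csv(manifest, comment.char = "#", check.names = FALSE,
                         colClasses = c(patient_id = "character"))
  need <- c("patient_id", "file_4ch", "file_3ch", "file_2ch",
            "qrs_ms", "lvef_pct")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("manifest ", manifest, ": missing column ",
         paste(missing, collapse = ", "))
  if (nrow(tab) == 0L) {
    warning("manifest ", manifest, " lists no patients")
    return(structure(list(), skipped = character(0)))
  }
  base <- dirname(manifest)
  resolve <- function(f) ifelse(grepl("^(/|[A-Za-z]:)", f), f, file.path(base, f))
  records <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    rec <- tryCatch({
      views <- list(
        "4ch" = read_view_file(resolve(row$file_4ch), "4ch"),
        "3ch" = read_view_file(resolve(row$file_3ch), "3ch"),
        "2ch" = read_view_file(resolve(row$file_2ch), "2ch"))
      esv0 <- if ("esv_baseline_ml" %in% names(row)) as.numeric(row$esv_baseline_ml) else NA_real_
      esv1 <- if ("esv_followup_ml" %in% names(row)) as.numeric(row$esv_followup_ml) else NA_real_
      patient_record(row$patient_id, views, row$qrs_ms, row$lvef_pct,
                     esv0, esv1)
    }, error = function(e) {
      msg <- paste0(row$patient_id, ": ", conditionMessage(e))
      message("skipping patient ", msg)
      skipped <<- c(skipped, msg)
      NULL
    })
    if (!is.null(rec)) records[[length(records) + 1L]] <- rec
  }
  structure(records, skipped = skipped)
}

#' Write / read the per-patient feature table
#'
#' Comma-delimited, one row per patient: `patient_id`, `response`, then the
#' 158 feature columns in canonical order. Leading `# key: value` comment
#' lines (e.g. seed, config hash) are preserved on read as attribute
#' `"header"`.
#'
#' @param features Data frame as returned by [extract_cohort_features()].
#' @param path Output path.
#' @param header Optional named character vector written as `# key: value`
#'   comment lines.
#' @return `path` invisibly (write); the data frame (read).
#' @export
write_feature_table <- function(features, path, header = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header))
    writeLines(paste0("# ", names(header), ": ", header), con)
  utils::write.csv(features, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  tab <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                         colClasses = c(patient_id = "character"))
  attr(tab, "header") <- hdr
  tab
}
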