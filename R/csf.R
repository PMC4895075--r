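# Cloudwave Signal Format: a self-descriptive JSON container for
# channel-oriented signal segments. One document per ".csf" file, holding
# study metadata, channel metadata, and a fixed number of segments (2 by
# default). Attribute-value structure; unknown attributes encountered on
# read are preserved and re-emitted so documents stay compatible across
# format versions.

CSF_FORMAT_VERSION <- "1.0"

.CSF_TOP_KEYS <- c("format_version", "study", "channels", "segment_count", "segments")
.CSF_SEGMENT_KEYS <- c("sequence_number", "start_time", "end_time",
                       "absolute_start", "partial", "annotations", "data")

#' Assemble a signal segment
#'
#' Bundles one epoch's calibrated channel series with its computed metadata:
#' sequence number, start/end offsets in seconds, the absolute wall-clock
#' start derived from the recording's header, the partial flag, and the
#' clinical annotations whose intervals overlap the epoch.
#'
#' @param series List of `channel_series` from [build_channel_series()].
#' @param plan_entry The epoch's row from [plan_epochs()].
#' @param annotations Full annotation table; the overlapping subset is
#'   selected here with [annotations_in_interval()].
#' @param header The recording's [edf_header()] (for the absolute start).
#' @return A list of class `signal_segment`.
#' @export
build_signal_segment <- function(series, plan_entry, annotations, header) {
  if (is.null(annotations)) annotations <- empty_annotations()
  overlapping <- annotations_in_interval(annotations,
                                         plan_entry$start_time, plan_entry$end_time)
  data <- lapply(series, `[[`, "values")
  names(data) <- vapply(series, `[[`, character(1), "label")
  structure(list(
    sequence_number = plan_entry$segment_index,
    start_time = plan_entry$start_time,
    end_time = plan_entry$end_time,
    absolute_start = edf_start_datetime(header) + plan_entry$start_time,
    is_partial = plan_entry$is_partial,
    annotations = overlapping,
    data = data,
    extra = list()
  ), class = "signal_segment")
}

#' Assemble a CSF document
#'
#' @param study Named list of study metadata (recording id, start date/time,
#'   record duration, signal count, source file name).
#' @param channels Channel-metadata data.frame: the [edf_channel_table()]
#'   projection plus `sampling_rate` and the de-duplicated `label`.
#' @param segments List of [build_signal_segment()] results, ordered by
#'   sequence number.
#' @param format_version CSF format version string.
#' @return A list of class `csf_document`.
#' @export
csf_document <- function(study, channels, segments, format_version = CSF_FORMAT_VERSION) {
  seqs <- vapply(segments, `[[`, numeric(1), "sequence_number")
  if (is.unsorted(seqs, strictly = TRUE))
    usage_error("segments must be strictly ordered by sequence_number")
  structure(list(
    format_version = format_version,
    study = study,
    channels = channels,
    segments = segments,
    extra = list()
  ), class = "csf_document")
}

#' @export
print.csf_document <- function(x, ...) {
  cat(sprintf("<csf_document v%s> %d segment(s), %d channel(s), recording '%s'\n",
              x$format_version, length(x$segments), nrow(x$channels),
              x$study$recording_id %||% "?"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pack ordered segments into CSF documents
#'
#' Groups consecutive segments into documents of `segments_per_file` each
#' (2 by default); only the last document may be smaller. Document count is
#' `ceiling(n_segments / segments_per_file)`.
#'
#' @param segments List of `signal_segment`s ordered by sequence number.
#' @param segments_per_file Segments per document (>= 1).
#' @param study,channels Shared metadata passed to every [csf_document()].
#' @return List of `csf_document`s.
#' @export
pack_segments <- function(segments, segments_per_file = 2L, study = list(),
                          channels = NULL) {
  segments_per_file <- as.integer(segments_per_file)
  if (segments_per_file < 1L) usage_error("segments_per_file must be >= 1")
  seqs <- vapply(segments, `[[`, numeric(1), "sequence_number")
  if (anyDuplicated(seqs) || is.unsorted(seqs, strictly = TRUE))
    usage_error("segments must be ordered with no duplicate sequence numbers")
  if (!length(segments)) return(list())
  grp <- (seq_along(segments) - 1L) %/% segments_per_file
  lapply(unname(split(segments, grp)), function(chunk)
    csf_document(study = study, channels = channels, segments = chunk))
}

# ---- serialization ----------------------------------------------------------

annotations_to_json <- function(ann) {
  if (!nrow(ann)) return(list())
  lapply(seq_len(nrow(ann)), function(i) {
    a <- list(onset = ann$onset[i], duration = ann$duration[i], text = ann$text[i])
    if (!is.na(ann$ontology_term[i])) a$ontology_term <- ann$ontology_term[i]
    a
  })
}

annotations_from_json <- function(lst) {
  if (!length(lst)) return(empty_annotations())
  rows <- lapply(seq_along(lst), function(i) {
    a <- lst[[i]]
    data.frame(onset = as.numeric(a$onset), duration = as.numeric(a$duration),
               text = as.character(a$text),
               ontology_term = as.character(a$ontology_term %||% NA_character_),
               source_line = i, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

segment_to_json <- function(seg) {
  abs_start <- if (inherits(seg$absolute_start, "POSIXt"))
    format(seg$absolute_start, "%Y-%m-%dT%H:%M:%OS3") else as.character(seg$absolute_start)
  c(list(
    sequence_number = seg$sequence_number,
    start_time = seg$start_time,
    end_time = seg$end_time,
    absolute_start = abs_start,
    partial = isTRUE(seg$is_partial),
    annotations = annotations_to_json(seg$annotations),
    data = lapply(seg$data, as.numeric)
  ), seg$extra %||% list())
}

#' Write a CSF document to a JSON file
#'
#' Metadata serializes exactly; signal values serialize at `precision`
#' significant digits (default 17, enough for exact double round-trip).
#' Unknown attributes that came in through [read_csf()] are written back.
#'
#' @param doc A [csf_document()].
#' @param sink Output path (conventionally ".csf").
#' @param precision Significant digits for numeric values.
#' @return Invisibly, `sink`.
#' @export
write_csf <- function(doc, sink, precision = 17L) {
  stopifnot(inherits(doc, "csf_document"))
  body <- c(list(
    format_version = doc$format_version,
    study = doc$study,
    channels = if (is.null(doc$channels)) list() else doc$channels,
    segment_count = length(doc$segments),
    segments = lapply(doc$segments, segment_to_json)
  ), doc$extra %||% list())
  json <- jsonlite::toJSON(body, auto_unbox = TRUE, digits = I(precision),
                           na = "null", null = "null", dataframe = "rows",
                           POSIXt = "ISO8601", pretty = FALSE)
  writeLines(json, sink, useBytes = TRUE)
  invisible(sink)
}

segment_from_json <- function(s) {
  known <- .CSF_SEGMENT_KEYS
  structure(list(
    sequence_number = as.numeric(s$sequence_number),
    start_time = as.numeric(s$start_time),
    end_time = as.numeric(s$end_time),
    absolute_start = as.character(s$absolute_start %||% NA_character_),
    is_partial = isTRUE(s$partial),
    annotations = annotations_from_json(s$annotations),
    data = lapply(s$data, function(v) vapply(v, as.numeric, numeric(1))),
    extra = s[setdiff(names(s), known)]
  ), class = "signal_segment")
}

#' Read a CSF document from a JSON file
#'
#' The inverse of [write_csf()]. Top-level or per-segment attributes this
#' version does not know are kept in `extra` fields and survive a rewrite.
#'
#' @param src Path to a ".csf" file.
#' @return A [csf_document()].
#' @export
read_csf <- function(src) {
  parsed <- jsonlite::fromJSON(src, simplifyVector = FALSE)
  for (key in c("format_version", "segments"))
    if (is.null(parsed[[key]]))
      stop_edf("csf_validation_error", sprintf("CSF document missing required key '%s'", key),
               json_path = paste0("$.", key))
  channels <- if (length(parsed$channels)) {
    as.data.frame(do.call(rbind, lapply(parsed$channels, function(ch)
      lapply(ch, function(v) if (is.null(v)) NA else v))), stringsAsFactors = FALSE) -> df
    df[] <- lapply(df, unlist, use.names = FALSE)
    df
  } else NULL
  doc <- structure(list(
    format_version = as.character(parsed$format_version),
    study = parsed$study,
    channels = channels,
    segments = lapply(parsed$segments, segment_from_json),
    extra = parsed[setdiff(names(parsed), .CSF_TOP_KEYS)]
  ), class = "csf_document")
  doc
}

# ---- validation -------------------------------------------------------------

finding <- function(severity, file, path, message) {
  data.frame(severity = severity, file = file, json_path = path,
             message = message, stringsAsFactors = FALSE)
}

empty_report <- function() finding(character(0), character(0), character(0), character(0))

validate_one_csf <- function(path) {
  out <- empty_report()
  parsed <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                     error = function(e) e)
  if (inherits(parsed, "error"))
    return(finding("error", path, "$", paste("not well-formed JSON:", conditionMessage(parsed))))
  for (key in c("format_version", "study", "channels", "segment_count", "segments"))
    if (is.null(parsed[[key]]))
      out <- rbind(out, finding("error", path, paste0("$.", key),
                                sprintf("missing required key '%s'", key)))
  if (!is.null(parsed$segment_count) && !is.null(parsed$segments) &&
      parsed$segment_count != length(parsed$segments))
    out <- rbind(out, finding("error", path, "$.segment_count",
                              sprintf("segment_count is %s but %d segments present",
                                      parsed$segment_count, length(parsed$segments))))
  rates <- NULL
  if (length(parsed$channels)) {
    labs <- vapply(parsed$channels, function(ch) as.character(ch$label %||% NA), character(1))
    rates <- stats::setNames(
      vapply(parsed$channels, function(ch) as.numeric(ch$sampling_rate %||% NA), numeric(1)),
      labs)
  }
  prev_seq <- -Inf
  for (i in seq_along(parsed$segments)) {
    s <- parsed$segments[[i]]
    jp <- sprintf("$.segments[%d]", i - 1L)
    for (key in c("sequence_number", "start_time", "end_time", "data")) {
      if (is.null(s[[key]])) {
        out <- rbind(out, finding("error", path, paste0(jp, ".", key),
                                  sprintf("missing required key '%s'", key)))
      }
    }
    if (is.null(s$start_time) || is.null(s$end_time)) next
    dur <- as.numeric(s$end_time) - as.numeric(s$start_time)
    if (!(dur > 0))
      out <- rbind(out, finding("error", path, paste0(jp, ".end_time"),
                                "end_time must exceed start_time"))
    if (!is.null(s$sequence_number)) {
      if (as.numeric(s$sequence_number) <= prev_seq)
        out <- rbind(out, finding("error", path, paste0(jp, ".sequence_number"),
                                  "sequence numbers must increase within a document"))
      prev_seq <- as.numeric(s$sequence_number)
    }
    if (!isTRUE(s$partial) && !is.null(rates) && dur > 0) {
      for (lab in names(s$data)) {
        expect_n <- rates[[lab]] * dur
        if (!is.null(expect_n) && is.finite(expect_n) &&
            length(s$data[[lab]]) != round(expect_n))
          out <- rbind(out, finding("error", path,
                                    sprintf("%s.data['%s']", jp, lab),
                                    sprintf("%d samples but sampling_rate x duration = %g",
                                            length(s$data[[lab]]), expect_n)))
      }
    }
  }
  out
}

#' Validate CSF documents
#'
#' Checks JSON well-formedness, required attributes, per-segment invariants
#' (positive duration; for non-partial segments, per-channel sample counts
#' equal to sampling rate times duration), and -- for a directory -- sequence
#' continuity across all documents of the run (a missing or duplicated
#' sequence number raises a warning finding). Findings are returned with
#' severities, never thrown.
#'
#' @param src A ".csf" file or a directory containing them.
#' @return A data.frame report with columns `severity`, `file`, `json_path`,
#'   `message` (zero rows means fully valid).
#' @export
validate_csf <- function(src) {
  if (length(src) == 1L && dir.exists(src)) {
    files <- sort(list.files(src, pattern = "\\.csf$", full.names = TRUE),
                  method = "radix")
    out <- do.call(rbind, c(list(empty_report()), lapply(files, validate_one_csf)))
    seqs <- unlist(lapply(files, function(f) {
      p <- tryCatch(jsonlite::fromJSON(f, simplifyVector = FALSE), error = function(e) NULL)
      vapply(p$segments %||% list(), function(s) as.numeric(s$sequence_number %||% NA), numeric(1))
    }))
    seqs <- seqs[is.finite(seqs)]
    if (length(seqs)) {
      expected <- seq(0, max(seqs))
      missing <- setdiff(expected, seqs)
      if (length(missing))
        out <- rbind(out, finding("warning", src, "$",
                                  sprintf("sequence continuity gap: missing sequence_number(s) %s",
                                          paste(missing, collapse = ", "))))
      if (anyDuplicated(seqs))
        out <- rbind(out, finding("warning", src, "$",
                                  sprintf("duplicate sequence_number(s) across documents: %s",
                                          paste(unique(seqs[duplicated(seqs)]), collapse = ", "))))
    }
    return(out)
  }
  validate_one_csf(src)
}

# ---- indexing ---------------------------------------------------------------

#' Build a segment index over CSF documents
#'
#' One entry per document: file name, first and last sequence number, and the
#' time span covered, enabling time-range lookups without opening every file.
#'
#' @param src Directory of ".csf" files or a character vector of paths.
#' @return A data.frame of class `csf_index` with columns `file`,
#'   `first_sequence`, `last_sequence`, `min_start`, `max_end`.
#' @export
build_csf_index <- function(src) {
  files <- if (length(src) == 1L && dir.exists(src))
    sort(list.files(src, pattern = "\\.csf$", full.names = TRUE), method = "radix")
  else src
  rows <- lapply(files, function(f) {
    doc <- read_csf(f)
    if (!length(doc$segments)) return(NULL)
    seqs <- vapply(doc$segments, `[[`, numeric(1), "sequence_number")
    data.frame(file = f,
               first_sequence = min(seqs), last_sequence = max(seqs),
               min_start = min(vapply(doc$segments, `[[`, numeric(1), "start_time")),
               max_end = max(vapply(doc$segments, `[[`, numeric(1), "end_time")),
               stringsAsFactors = FALSE)
  })
  idx <- do.call(rbind, c(list(data.frame(file = character(0), first_sequence = numeric(0),
                                          last_sequence = numeric(0), min_start = numeric(0),
                                          max_end = numeric(0), stringsAsFactors = FALSE)),
                          rows))
  class(idx) <- c("csf_index", "data.frame")
  idx
}

#' Persist / load a CSF index sidecar
#'
#' @param index A [build_csf_index()] result.
#' @param path JSON sidecar path.
#' @return `write_csf_index` returns `path` invisibly; `read_csf_index`
#'   returns the index.
#' @export
write_csf_index <- function(index, path) {
  jsonlite::write_json(as.data.frame(index), path, dataframe = "rows",
                       auto_unbox = FALSE, digits = I(17))
  invisible(path)
}

#' @rdname write_csf_index
#' @export
read_csf_index <- function(path) {
  idx <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (!nrow(idx)) idx <- data.frame(file = character(0), first_sequence = numeric(0),
                                    last_sequence = numeric(0), min_start = numeric(0),
                                    max_end = numeric(0), stringsAsFactors = FALSE)
  class(idx) <- c("csf_index", "data.frame")
  idx
}

#' Locate segments covering a time range
#'
#' Uses the index to shortlist documents whose span intersects the half-open
#' query window, then scans just those documents for segments whose
#' `[start_time, end_time)` intersects `[query_start, query_end)`.
#'
#' @param index A [build_csf_index()] result.
#' @param query_start,query_end Query window in seconds; start < end.
#' @return A data.frame of `file`, `sequence_number` in sequence order.
#' @export
locate_segments <- function(index, query_start, query_end) {
  if (!(query_start < query_end)) usage_error("query_start must be < query_end")
  hit_none <- data.frame(file = character(0), sequence_number = numeric(0),
                         stringsAsFactors = FALSE)
  if (!nrow(index)) return(hit_none)
  cand <- index[index$min_start < query_end & index$max_end > query_start, , drop = FALSE]
  rows <- lapply(cand$file, function(f) {
    doc <- read_csf(f)
    hits <- Filter(function(s) s$start_time < query_end && s$end_time > query_start,
                   doc$segments)
    if (!length(hits)) return(NULL)
    data.frame(file = f,
               sequence_number = vapply(hits, `[[`, numeric(1), "sequence_number"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(list(hit_none), rows))
  out <- out[order(out$sequence_number), , drop = FALSE]
  rownames(out) <- NULL
  out
}
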