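# Clinical-annotation sidecars: plain-text files of timestamped events
# (seizures, spikes, ...) paired with an EDF by base name. The default
# dialect is tab-separated "onset_seconds<TAB>duration_seconds<TAB>text" with
# "#" comment lines; sites with other conventions can register their own
# line parser.

.annotation_dialects <- new.env(parent = emptyenv())

#' Register a sidecar annotation dialect
#'
#' A dialect is a function that receives one non-empty, non-comment line and
#' returns either `list(onset =, duration =, text =)` or `NULL` when the line
#' is malformed.
#'
#' @param name Dialect name used in [parse_annotations()].
#' @param parse_line The line-parsing function.
#' @export
register_annotation_dialect <- function(name, parse_line) {
  stopifnot(is.character(name), length(name) == 1L, is.function(parse_line))
  assign(name, parse_line, envir = .annotation_dialects)
  invisible(name)
}

parse_tsv_line <- function(line) {
  parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(parts) < 3L) return(NULL)
  onset <- suppressWarnings(as.numeric(parts[1]))
  duration <- suppressWarnings(as.numeric(parts[2]))
  if (is.na(onset) || is.na(duration)) return(NULL)
  list(onset = onset, duration = duration,
       text = paste(parts[-(1:2)], collapse = "\t"))
}

empty_annotations <- function() {
  data.frame(onset = numeric(0), duration = numeric(0), text = character(0),
             ontology_term = character(0), source_line = integer(0),
             stringsAsFactors = FALSE)
}

#' Parse a clinical-annotation sidecar file
#'
#' Each non-empty, non-comment line yields one timestamped event with an
#' onset in seconds from recording start, a duration in seconds (0 marks an
#' instantaneous event such as a spike), and free text. Events are returned
#' sorted by onset with ties broken by line number. Malformed lines -- bad
#' syntax, negative onset or duration -- are never silently dropped: they are
#' collected with reasons in the `rejects` attribute.
#'
#' @param src Path to the sidecar file, or a character vector of lines.
#' @param dialect Name of a registered dialect (default `"tsv"`).
#' @return A data.frame with columns `onset`, `duration`, `text`,
#'   `ontology_term` (NA until [apply_term_mapping()]), `source_line`; the
#'   `rejects` attribute is a data.frame of `source_line`, `line`, `reason`.
#' @export
parse_annotations <- function(src, dialect = "tsv") {
  parse_line <- get0(dialect, envir = .annotation_dialects)
  if (is.null(parse_line))
    usage_error(sprintf("unknown annotation dialect '%s'", dialect))
  lines <- if (length(src) == 1L && file.exists(src)) {
    readLines(src, encoding = "UTF-8", warn = FALSE)
  } else {
    as.character(src)
  }

  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  rows <- list(); rejects <- list()
  for (i in which(keep)) {
    p <- parse_line(lines[i])
    if (is.null(p)) {
      rejects[[length(rejects) + 1L]] <-
        data.frame(source_line = i, line = lines[i],
                   reason = "unparseable line", stringsAsFactors = FALSE)
    } else if (p$onset < 0 || p$duration < 0) {
      rejects[[length(rejects) + 1L]] <-
        data.frame(source_line = i, line = lines[i],
                   reason = "negative onset or duration", stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <-
        data.frame(onset = p$onset, duration = p$duration, text = p$text,
                   ontology_term = NA_character_, source_line = i,
                   stringsAsFactors = FALSE)
    }
  }
  ann <- if (length(rows)) do.call(rbind, rows) else empty_annotations()
  ann <- ann[order(ann$onset, ann$source_line), , drop = FALSE]
  rownames(ann) <- NULL
  attr(ann, "rejects") <- if (length(rejects)) do.call(rbind, rejects) else
    data.frame(source_line = integer(0), line = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  ann
}

#' Normalize annotation text for ontology lookup
#'
#' Lowercases, collapses internal whitespace to single spaces, and strips
#' leading/trailing punctuation, so "  Seizure." and "seizure" match the same
#' controlled term.
#'
#' @param x Character vector.
#' @return Normalized character vector.
#' @export
normalize_annotation_text <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("\\s+", " ", x)
  gsub("^[[:punct:]]+|[[:punct:]]+$", "", x)
}

#' Load a term-to-ontology mapping table
#'
#' Reads a two-column delimited file (annotation text, ontology term
#' identifier such as an EpSO CURIE). Keys are normalized with
#' [normalize_annotation_text()]; duplicate normalized keys are an error.
#'
#' @param src Path to a delimited file, or a named character vector
#'   (`text -> term`).
#' @param ontology_name Label for the vocabulary (e.g. "EpSO").
#' @param sep Field separator for file input (default tab).
#' @return A list of class `term_mapping` with `entries` and `ontology_name`.
#' @export
read_term_mapping <- function(src, ontology_name = "EpSO", sep = "\t") {
  if (is.character(src) && !is.null(names(src))) {
    keys <- normalize_annotation_text(names(src)); terms <- unname(src)
  } else {
    tab <- utils::read.table(src, sep = sep, header = FALSE, quote = "",
                             comment.char = "#", stringsAsFactors = FALSE,
                             col.names = c("text", "term"))
    keys <- normalize_annotation_text(tab$text); terms <- tab$term
  }
  if (anyDuplicated(keys))
    usage_error(sprintf("duplicate normalized mapping key: '%s'",
                        keys[duplicated(keys)][1]))
  structure(list(entries = stats::setNames(terms, keys),
                 ontology_name = ontology_name),
            class = "term_mapping")
}

#' Attach ontology terms to annotations
#'
#' Looks each annotation's normalized text up in the mapping and fills
#' `ontology_term` on match. Unmatched annotations are not an error: they
#' keep `NA` and are counted in the `match_summary` attribute
#' (matched, unmatched, and the distinct unmatched texts).
#'
#' @param annotations Data frame from [parse_annotations()].
#' @param mapping A [read_term_mapping()] object.
#' @return The annotations, order preserved, with `ontology_term` populated.
#' @export
apply_term_mapping <- function(annotations, mapping) {
  stopifnot(inherits(mapping, "term_mapping"))
  keys <- normalize_annotation_text(annotations$text)
  hit <- keys %in% names(mapping$entries)
  out <- annotations
  out$ontology_term[hit] <- unname(mapping$entries[keys[hit]])
  attr(out, "match_summary") <- list(
    ontology = mapping$ontology_name,
    matched = sum(hit),
    unmatched = sum(!hit),
    unmatched_texts = sort(unique(annotations$text[!hit]))
  )
  out
}

#' Select annotations overlapping a time window
#'
#' An event occupies the closed interval `[onset, onset + duration]`; a
#' window is the half-open interval `[start, end)`. An event belongs to every
#' window its interval intersects, so an event spanning a window boundary is
#' duplicated into all windows it touches, and a zero-duration event sitting
#' exactly on a window start belongs to that window (and to none earlier).
#'
#' @param annotations Data frame from [parse_annotations()].
#' @param start,end Window bounds in seconds; `start < end` required.
#' @return The overlapping subset, input order preserved.
#' @export
annotations_in_interval <- function(annotations, start, end) {
  if (!(start < end)) usage_error("interval start must be < end")
  keep <- annotations$onset < end & (annotations$onset + annotations$duration) >= start
  out <- annotations[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

register_annotation_dialect("tsv", parse_tsv_line)
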