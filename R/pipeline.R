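# Directory-level orchestration: discover EDF/annotation pairs, then per
# file run reader -> partitioner -> processor -> CSF generator. Files are
# independent work units, so parallelism is per file and a failing file is
# recorded in the report without aborting the run. The two stages mirror the
# classic two-map decomposition: a metadata/parsing stage ("reader") that is
# useful on its own, and a generation stage ("generator") that does the
# partitioning, calibration, and CSF output.

#' Pair EDF files with their annotation sidecars
#'
#' Scans a directory for ".edf" files (case-insensitive) and joins each with
#' a ".txt" sidecar sharing its base name. Recordings without a sidecar are
#' processed with zero annotations; ".txt" files without a matching EDF are
#' listed in the `orphans` attribute, reported but never processed.
#'
#' @param input_dir Directory to scan.
#' @return A data.frame with `edf_path`, `annotation_path` (NA when absent);
#'   attribute `orphans` holds unmatched ".txt" paths.
#' @export
discover_inputs <- function(input_dir) {
  if (!dir.exists(input_dir))
    stop_edf("edf2csf_io_error", sprintf("cannot read input directory '%s'", input_dir))
  all <- list.files(input_dir, full.names = TRUE)
  ext <- tolower(tools::file_ext(all))
  edfs <- sort(all[ext == "edf"], method = "radix")
  txts <- all[ext == "txt"]
  base_of <- function(p) tools::file_path_sans_ext(basename(p))
  txt_by_base <- stats::setNames(txts, tolower(base_of(txts)))
  matched <- unname(txt_by_base[tolower(base_of(edfs))])
  out <- data.frame(edf_path = edfs,
                    annotation_path = ifelse(is.na(matched), NA_character_, matched),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "orphans") <- sort(unname(txts[!txts %in% out$annotation_path]), method = "radix")
  out
}

#' Pipeline configuration
#'
#' @param input_dir,output_dir Directories for EDF input and CSF output.
#' @param epoch_duration_seconds Epoch length; default 30 s.
#' @param segments_per_file Segments per CSF document; default 2.
#' @param workers Parallel workers (>= 1); files are the unit of parallelism.
#' @param term_mapping_path Optional two-column text file mapping annotation
#'   text to ontology terms.
#' @param emit_raw_digital Also store raw digital integers per channel.
#' @param serialization_precision Significant digits for CSF numeric output
#'   (default 17: exact double round-trip).
#' @param stage `"full"` runs everything; `"read_only"` stops after parsing
#'   and metadata extraction (no CSF is written) for callers that only need
#'   the reader stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, output_dir,
                            epoch_duration_seconds = 30,
                            segments_per_file = 2L,
                            workers = 1L,
                            term_mapping_path = NULL,
                            emit_raw_digital = FALSE,
                            serialization_precision = 17L,
                            stage = c("full", "read_only")) {
  stage <- match.arg(stage)
  workers <- as.integer(workers)
  if (workers < 1L) config_error("workers must be >= 1")
  if (epoch_duration_seconds <= 0) config_error("epoch_duration_seconds must be > 0")
  if (as.integer(segments_per_file) < 1L) config_error("segments_per_file must be >= 1")
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 epoch_duration_seconds = epoch_duration_seconds,
                 segments_per_file = as.integer(segments_per_file),
                 workers = workers, term_mapping_path = term_mapping_path,
                 emit_raw_digital = isTRUE(emit_raw_digital),
                 serialization_precision = as.integer(serialization_precision),
                 stage = stage),
            class = "pipeline_config")
}

# Process one EDF/sidecar pair. Returns a per-file report row; any error is
# caught by the caller so one bad file never takes down the run.
process_one_file <- function(edf_path, annotation_path, config, mapping) {
  t0 <- proc.time()[["elapsed"]]
  parsed <- read_edf_header(edf_path)
  header <- parsed$header; channels <- parsed$channels

  annotations <- if (!is.na(annotation_path)) parse_annotations(annotation_path)
                 else empty_annotations()
  match_summary <- NULL
  if (!is.null(mapping)) {
    annotations <- apply_term_mapping(annotations, mapping)
    match_summary <- attr(annotations, "match_summary")
  }
  t_reader <- proc.time()[["elapsed"]] - t0

  base <- tools::file_path_sans_ext(basename(edf_path))
  row <- list(file = basename(edf_path), status = "ok", reason = NA_character_,
              n_segments = 0L, n_documents = 0L,
              n_annotations = nrow(annotations),
              annotations_matched = if (is.null(match_summary)) NA_integer_
                                    else match_summary$matched,
              out_of_range_samples = 0L,
              reader_seconds = t_reader, generator_seconds = 0)

  if (config$stage == "read_only") return(row)

  t1 <- proc.time()[["elapsed"]]
  plan <- plan_epochs(header, config$epoch_duration_seconds)
  study <- list(recording_id = header$recording_id,
                patient_id = header$patient_id,
                start_date = header$start_date,
                start_time = header$start_time,
                record_duration = header$record_duration,
                n_signals = header$n_signals,
                n_data_records = header$n_data_records,
                source_file = basename(edf_path))
  chan_meta <- as.data.frame(channels)
  chan_meta$label <- disambiguate_labels(chan_meta$label)
  chan_meta$sampling_rate <- sampling_rate(channels, header)

  oor_total <- 0L
  segments <- lapply(seq_len(nrow(plan)), function(i) {
    entry <- plan[i, , drop = FALSE]
    seg <- extract_segment(edf_path, header, channels, entry)
    oor_total <<- oor_total + sum(seg$block$out_of_range)
    series <- build_channel_series(seg$block, channels, header,
                                   keep_digital = config$emit_raw_digital)
    s <- build_signal_segment(series, entry, annotations, header)
    if (config$emit_raw_digital) {
      s$extra$digital <- lapply(series, `[[`, "digital")
      names(s$extra$digital) <- vapply(series, `[[`, character(1), "label")
    }
    s
  })

  docs <- pack_segments(segments, config$segments_per_file,
                        study = study, channels = chan_meta)
  paths <- character(length(docs))
  for (i in seq_along(docs)) {
    paths[i] <- file.path(config$output_dir, sprintf("%s_%04d.csf", base, i - 1L))
    write_csf(docs[[i]], paths[i], precision = config$serialization_precision)
  }
  idx <- build_csf_index(paths)
  idx$file <- basename(idx$file)
  write_csf_index(idx, file.path(config$output_dir, paste0(base, ".index.json")))

  row$n_segments <- nrow(plan)
  row$n_documents <- length(docs)
  row$out_of_range_samples <- oor_total
  row$generator_seconds <- proc.time()[["elapsed"]] - t1
  row
}

#' Run the EDF-to-CSF pipeline over a directory
#'
#' Discovers input pairs, then processes each file independently: parse the
#' EDF header and sidecar annotations (reader stage), and -- unless
#' `stage = "read_only"` -- plan epochs, extract and calibrate each segment,
#' and write packed CSF documents plus a per-recording index sidecar
#' (generator stage). Files are isolated: a corrupt file becomes a `failed`
#' row in the report and the run continues. Output is a pure function of the
#' inputs and the configuration, so worker count and processing order never
#' change the bytes written.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_report`: data.frame with one row per discovered EDF
#'   (`file`, `status`, `reason`, `n_segments`, `n_documents`,
#'   `n_annotations`, `annotations_matched`, `out_of_range_samples`,
#'   `reader_seconds`, `generator_seconds`); attributes `orphans` and
#'   `exit_status` (0 all ok, 2 some failed).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  inputs <- discover_inputs(config$input_dir)
  if (config$stage == "full") {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    if (!dir.exists(config$output_dir) || file.access(config$output_dir, 2L) != 0L)
      stop_edf("edf2csf_io_error",
               sprintf("output directory '%s' is not writable", config$output_dir))
  }
  mapping <- if (!is.null(config$term_mapping_path))
    read_term_mapping(config$term_mapping_path) else NULL

  work <- function(i) {
    tryCatch(
      process_one_file(inputs$edf_path[i], inputs$annotation_path[i], config, mapping),
      error = function(e) list(
        file = basename(inputs$edf_path[i]), status = "failed",
        reason = conditionMessage(e), n_segments = 0L, n_documents = 0L,
        n_annotations = NA_integer_, annotations_matched = NA_integer_,
        out_of_range_samples = NA_integer_,
        reader_seconds = NA_real_, generator_seconds = NA_real_)
    )
  }

  rows <- if (config$workers > 1L && nrow(inputs) > 1L &&
              .Platform$OS.type == "unix") {
    parallel::mclapply(seq_len(nrow(inputs)), work, mc.cores = config$workers)
  } else {
    lapply(seq_len(nrow(inputs)), work)
  }

  report <- if (length(rows)) do.call(rbind, lapply(rows, as.data.frame)) else
    data.frame(file = character(0), status = character(0), reason = character(0),
               n_segments = integer(0), n_documents = integer(0),
               n_annotations = integer(0), annotations_matched = integer(0),
               out_of_range_samples = integer(0),
               reader_seconds = numeric(0), generator_seconds = numeric(0),
               stringsAsFactors = FALSE)
  rownames(report) <- NULL
  attr(report, "orphans") <- attr(inputs, "orphans")
  attr(report, "exit_status") <- if (any(report$status == "failed")) 2L else 0L
  class(report) <- c("pipeline_report", "data.frame")
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d file(s): %d ok, %d failed\n",
              nrow(x), sum(x$status == "ok"), sum(x$status == "failed")))
  print.data.frame(x, ...)
  orph <- attr(x, "orphans")
  if (length(orph))
    cat("orphan annotation file(s):", paste(basename(orph), collapse = ", "), "\n")
  invisible(x)
}
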