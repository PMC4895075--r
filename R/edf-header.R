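#' Construct an EDF study header
#'
#' The EDF main header carries study-specific metadata: patient and recording
#' identifiers, the recording start date and time, the number of data records
#' in the file, the duration in seconds of one data record, and the number of
#' signals (channels). `header_bytes` is always `256 * (1 + n_signals)` and is
#' recomputed here rather than taken on trust.
#'
#' @param patient_id,recording_id Free-text identification fields (at most 80
#'   ASCII characters each).
#' @param start_date Recording start date (`Date` or "dd.mm.yy" string).
#' @param start_time Recording start time of day, "hh.mm.ss".
#' @param n_data_records Number of data records; `-1` is allowed on read and
#'   means unknown.
#' @param record_duration Duration of one data record in seconds (> 0).
#' @param n_signals Number of signals (>= 1).
#' @param version EDF version field; `"0"` for plain EDF.
#' @return An object of class `edf_header`.
#' @seealso [edf_channel_table()], [read_edf_header()], [write_edf()]
#' @export
edf_header <- function(patient_id = "X", recording_id = "X",
                       start_date = Sys.Date(), start_time = "00.00.00",
                       n_data_records = 0L, record_duration = 1,
                       n_signals = 1L, version = "0") {
  if (inherits(start_date, "Date")) start_date <- format(start_date, "%d.%m.%y")
  h <- structure(list(
    version = as.character(version),
    patient_id = as.character(patient_id),
    recording_id = as.character(recording_id),
    start_date = as.character(start_date),
    start_time = as.character(start_time),
    header_bytes = 256L * (1L + as.integer(n_signals)),
    n_data_records = as.integer(n_data_records),
    record_duration = as.numeric(record_duration),
    n_signals = as.integer(n_signals)
  ), class = "edf_header")
  validate_edf_header(h)
}

validate_edf_header <- function(h) {
  if (h$n_signals < 1L) format_error("n_signals must be >= 1")
  if (!is.finite(h$record_duration) || h$record_duration <= 0)
    format_error("record_duration must be a positive number")
  if (h$header_bytes != 256L * (1L + h$n_signals))
    format_error(sprintf("header_bytes is %d but must be 256*(1+n_signals) = %d",
                         h$header_bytes, 256L * (1L + h$n_signals)))
  if (h$n_data_records < -1L)
    format_error("n_data_records must be >= 0, or -1 for unknown")
  if (!grepl("^\\d{2}\\.\\d{2}\\.\\d{2}$", h$start_date))
    format_error(sprintf("start_date '%s' is not in dd.mm.yy form", h$start_date))
  if (!grepl("^\\d{2}\\.\\d{2}\\.\\d{2}$", h$start_time))
    format_error(sprintf("start_time '%s' is not in hh.mm.ss form", h$start_time))
  h
}

#' @export
print.edf_header <- function(x, ...) {
  cat("<edf_header>\n")
  cat(sprintf("  recording '%s', patient '%s'\n", x$recording_id, x$patient_id))
  cat(sprintf("  start %s %s\n", x$start_date, x$start_time))
  cat(sprintf("  %d signal(s), %s data record(s) of %g s\n",
              x$n_signals,
              if (x$n_data_records < 0) "unknown" else as.character(x$n_data_records),
              x$record_duration))
  invisible(x)
}

#' Construct a per-channel metadata table
#'
#' One row per signal, mirroring the channel-specific fields of the EDF
#' subheader: label, transducer type, physical dimension (unit label such as
#' "uV"), the physical and digital calibration extrema, prefiltering note,
#' and the number of samples stored per data record. All arguments are
#' recycled to a common length.
#'
#' @param label Channel labels.
#' @param transducer Transducer descriptions.
#' @param physical_dimension Unit labels (e.g. "uV", "mV", "%").
#' @param physical_min,physical_max Physical calibration range; must differ.
#' @param digital_min,digital_max Digital calibration range (signed 16-bit);
#'   `digital_min < digital_max` is required.
#' @param prefiltering Prefiltering descriptions.
#' @param samples_per_record Samples stored per data record per channel.
#' @return A `data.frame` of class `edf_channel_table`.
#' @export
edf_channel_table <- function(label, transducer = "", physical_dimension = "uV",
                              physical_min = -100, physical_max = 100,
                              digital_min = -32768L, digital_max = 32767L,
                              prefiltering = "", samples_per_record = 1L) {
  ch <- data.frame(
    label = as.character(label),
    transducer = as.character(transducer),
    physical_dimension = as.character(physical_dimension),
    physical_min = as.numeric(physical_min),
    physical_max = as.numeric(physical_max),
    digital_min = as.integer(digital_min),
    digital_max = as.integer(digital_max),
    prefiltering = as.character(prefiltering),
    samples_per_record = as.integer(samples_per_record),
    stringsAsFactors = FALSE
  )
  class(ch) <- c("edf_channel_table", "data.frame")
  validate_edf_channels(ch)
}

validate_edf_channels <- function(ch) {
  bad <- which(ch$digital_min >= ch$digital_max)
  if (length(bad))
    calibration_error(sprintf(
      "channel '%s' (index %d): digital_min (%d) must be < digital_max (%d)",
      ch$label[bad[1]], bad[1], ch$digital_min[bad[1]], ch$digital_max[bad[1]]),
      channel = bad[1])
  bad <- which(ch$physical_min == ch$physical_max)
  if (length(bad))
    calibration_error(sprintf(
      "channel '%s' (index %d): physical_min equals physical_max (%g)",
      ch$label[bad[1]], bad[1], ch$physical_min[bad[1]]), channel = bad[1])
  bad <- which(ch$samples_per_record < 1L)
  if (length(bad))
    format_error(sprintf("channel '%s' (index %d): samples_per_record must be >= 1",
                         ch$label[bad[1]], bad[1]))
  ch
}

#' Per-channel sampling rate in Hz
#'
#' @param channels An [edf_channel_table()].
#' @param header The matching [edf_header()] (supplies the record duration).
#' @return Numeric vector of rates, `samples_per_record / record_duration`.
#' @export
sampling_rate <- function(channels, header) {
  channels$samples_per_record / header$record_duration
}

#' Recording start as a timestamp
#'
#' Interprets the two-digit EDF year with the conventional clipping rule:
#' 85--99 map to the 1900s, 00--84 to the 2000s. The header clock is taken as
#' local time without a zone; a fixed UTC representation is used internally so
#' arithmetic is daylight-saving-proof.
#'
#' @param header An [edf_header()].
#' @return A `POSIXct` timestamp.
#' @export
edf_start_datetime <- function(header) {
  dp <- as.integer(strsplit(header$start_date, ".", fixed = TRUE)[[1]])
  tp <- as.integer(strsplit(header$start_time, ".", fixed = TRUE)[[1]])
  year <- if (dp[3] >= 85L) 1900L + dp[3] else 2000L + dp[3]
  ISOdatetime(year, dp[2], dp[1], tp[1], tp[2], tp[3], tz = "UTC")
}
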