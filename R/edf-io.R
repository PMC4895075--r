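# EDF binary layout constants. The main header is 256 bytes of fixed-width
# ASCII fields; each signal adds 256 bytes of subheader, stored field-major
# (all labels, then all transducers, ...). Sample payload is record-major,
# channel-blocked signed 16-bit little-endian.

.EDF_MAIN_FIELDS <- data.frame(
  name  = c("version", "patient_id", "recording_id", "start_date", "start_time",
            "header_bytes", "reserved", "n_data_records", "record_duration",
            "n_signals"),
  width = c(8L, 80L, 80L, 8L, 8L, 8L, 44L, 8L, 8L, 4L),
  stringsAsFactors = FALSE
)

.EDF_CHANNEL_FIELDS <- data.frame(
  name  = c("label", "transducer", "physical_dimension", "physical_min",
            "physical_max", "digital_min", "digital_max", "prefiltering",
            "samples_per_record", "reserved"),
  width = c(16L, 80L, 8L, 8L, 8L, 8L, 8L, 80L, 8L, 32L),
  stringsAsFactors = FALSE
)

# ---- source plumbing --------------------------------------------------------

# Accepts a file path or a raw vector; returns a seekable binary connection
# plus the total size when knowable.
open_edf_source <- function(src) {
  if (is.raw(src)) {
    list(con = rawConnection(src, "rb"), size = length(src))
  } else if (is.character(src) && length(src) == 1L) {
    if (!file.exists(src)) stop_edf("edf2csf_io_error", sprintf("no such file: '%s'", src))
    list(con = file(src, "rb"), size = file.size(src))
  } else {
    usage_error("byte source must be a file path or a raw vector")
  }
}

ascii_field <- function(bytes, offset, width, name) {
  if (length(bytes) < offset + width)
    truncation_error(sprintf("header truncated before field '%s'", name),
                     field = name)
  slice <- bytes[(offset + 1L):(offset + width)]
  if (any(slice > as.raw(0x7e)) || any(slice < as.raw(0x20)))
    format_error(sprintf("non-ASCII byte in header field '%s' at byte offset %d",
                         name, offset + which(slice > as.raw(0x7e) | slice < as.raw(0x20))[1] - 1L),
                 field = name)
  sub(" +$", "", rawToChar(slice))
}

numeric_field <- function(s, offset, name, integer = FALSE) {
  t <- trimws(s)
  ok <- grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", t)
  if (!nzchar(t) || !ok)
    format_error(sprintf("non-numeric content '%s' in field '%s' at byte offset %d",
                         t, name, offset), field = name, offset = offset)
  v <- as.numeric(t)
  if (integer) as.integer(v) else v
}

# ---- read -------------------------------------------------------------------

#' Read the header of an EDF file
#'
#' Parses the 256-byte main header and the per-signal subheaders into an
#' [edf_header()] and an [edf_channel_table()]. Fixed-width ASCII fields are
#' right-trimmed; numeric fields are validated and a malformed one is reported
#' with its byte offset. A stored record count of -1 (unknown) is resolved
#' from the payload length when the source size is known.
#'
#' @param src File path or raw vector holding an EDF byte stream.
#' @return A list with elements `header` and `channels`.
#' @export
read_edf_header <- function(src) {
  s <- open_edf_source(src)
  on.exit(close(s$con))

  main <- readBin(s$con, "raw", n = 256L)
  off <- cumsum(c(0L, .EDF_MAIN_FIELDS$width))
  raw_fields <- list()
  for (i in seq_len(nrow(.EDF_MAIN_FIELDS)))
    raw_fields[[.EDF_MAIN_FIELDS$name[i]]] <-
      ascii_field(main, off[i], .EDF_MAIN_FIELDS$width[i], .EDF_MAIN_FIELDS$name[i])

  n_signals <- numeric_field(raw_fields$n_signals, off[10], "n_signals", integer = TRUE)
  if (n_signals < 1L) format_error("n_signals must be >= 1")
  header_bytes <- numeric_field(raw_fields$header_bytes, off[6], "header_bytes", integer = TRUE)
  if (header_bytes != 256L * (1L + n_signals))
    format_error(sprintf("header_bytes field is %d but 256*(1+n_signals) = %d",
                         header_bytes, 256L * (1L + n_signals)))

  sub <- readBin(s$con, "raw", n = 256L * n_signals)
  if (length(sub) < 256L * n_signals)
    truncation_error(sprintf(
      "signal subheader truncated: need %d bytes after main header, got %d (field '%s' incomplete)",
      256L * n_signals, length(sub),
      .EDF_CHANNEL_FIELDS$name[findInterval(length(sub), cumsum(.EDF_CHANNEL_FIELDS$width * n_signals)) + 1L]),
      field = "signal subheader")

  cols <- list()
  coff <- 0L
  for (i in seq_len(nrow(.EDF_CHANNEL_FIELDS))) {
    nm <- .EDF_CHANNEL_FIELDS$name[i]; w <- .EDF_CHANNEL_FIELDS$width[i]
    vals <- character(n_signals)
    for (ch in seq_len(n_signals)) {
      vals[ch] <- ascii_field(sub, coff, w, sprintf("%s[%d]", nm, ch))
      coff <- coff + w
    }
    cols[[nm]] <- vals
  }

  abs_off <- function(i, ch) 256L + { # byte offset of channel field, for error reports
    prior <- if (i > 1L) sum(.EDF_CHANNEL_FIELDS$width[seq_len(i - 1L)] * n_signals) else 0L
    prior + (ch - 1L) * .EDF_CHANNEL_FIELDS$width[i]
  }
  num_col <- function(i, integer) {
    nm <- .EDF_CHANNEL_FIELDS$name[i]
    vapply(seq_len(n_signals), function(ch)
      numeric_field(cols[[nm]][ch], abs_off(i, ch), sprintf("%s[%d]", nm, ch),
                    integer = FALSE),
      numeric(1)) -> v
    if (integer) as.integer(v) else v
  }

  channels <- data.frame(
    label = cols$label,
    transducer = cols$transducer,
    physical_dimension = cols$physical_dimension,
    physical_min = num_col(4L, FALSE),
    physical_max = num_col(5L, FALSE),
    digital_min = as.integer(num_col(6L, FALSE)),
    digital_max = as.integer(num_col(7L, FALSE)),
    prefiltering = cols$prefiltering,
    samples_per_record = as.integer(num_col(9L, FALSE)),
    stringsAsFactors = FALSE
  )
  class(channels) <- c("edf_channel_table", "data.frame")
  channels <- validate_edf_channels(channels)

  n_data_records <- numeric_field(raw_fields$n_data_records, off[8], "n_data_records", integer = TRUE)
  record_bytes <- 2L * sum(channels$samples_per_record)
  if (n_data_records == -1L && !is.null(s$size) && is.finite(s$size)) {
    payload <- s$size - header_bytes
    if (payload %% record_bytes != 0)
      format_error(sprintf(
        "cannot infer record count: payload of %d bytes is not a whole number of %d-byte records",
        payload, record_bytes))
    n_data_records <- as.integer(payload / record_bytes)
  }

  header <- structure(list(
    version = raw_fields$version,
    patient_id = raw_fields$patient_id,
    recording_id = raw_fields$recording_id,
    start_date = raw_fields$start_date,
    start_time = raw_fields$start_time,
    header_bytes = header_bytes,
    n_data_records = n_data_records,
    record_duration = numeric_field(raw_fields$record_duration, off[9], "record_duration"),
    n_signals = n_signals
  ), class = "edf_header")
  header <- validate_edf_header(header)

  list(header = header, channels = channels)
}

# ---- record blocks ----------------------------------------------------------

#' Construct a block of raw EDF data records
#'
#' Holds decoded signed 16-bit samples for a contiguous range of data records
#' in on-disk order: within each record, channel 1's samples, then channel
#' 2's, and so on.
#'
#' @param samples Integer vector of decoded samples in on-disk order.
#' @param samples_per_record Integer vector, one entry per channel.
#' @param first_record_index 0-based index of the first record in the block.
#' @param out_of_range Optional per-channel tally of samples outside the
#'   channel's digital calibration range.
#' @return An object of class `edf_record_block`.
#' @export
edf_record_block <- function(samples, samples_per_record, first_record_index = 0L,
                             out_of_range = NULL) {
  samples <- as.integer(samples)
  spr <- as.integer(samples_per_record)
  per_rec <- sum(spr)
  if (per_rec < 1L) usage_error("samples_per_record must sum to >= 1")
  if (length(samples) %% per_rec != 0L)
    format_error(sprintf("sample count %d is not a multiple of %d samples per record",
                         length(samples), per_rec))
  n_records <- length(samples) %/% per_rec
  structure(list(
    first_record_index = as.integer(first_record_index),
    n_records = n_records,
    samples = samples,
    samples_per_record = spr,
    out_of_range = if (is.null(out_of_range)) integer(length(spr)) else as.integer(out_of_range)
  ), class = "edf_record_block")
}

#' @export
print.edf_record_block <- function(x, ...) {
  cat(sprintf("<edf_record_block> records %d..%d (%d records, %d channels, %d samples)\n",
              x$first_record_index, x$first_record_index + x$n_records - 1L,
              x$n_records, length(x$samples_per_record), length(x$samples)))
  invisible(x)
}

#' Read a range of EDF data records
#'
#' Decodes `count` data records starting at 0-based record `first`, seeking
#' directly to the requested range so arbitrarily large files can be read in
#' slices. Samples outside a channel's digital calibration range are retained
#' unmodified but tallied per channel in the returned block's `out_of_range`.
#'
#' @param src File path or raw vector holding an EDF byte stream.
#' @param header Parsed [edf_header()].
#' @param channels Parsed [edf_channel_table()].
#' @param first 0-based index of the first record to read.
#' @param count Number of records to read; defaults to the rest of the file.
#' @return An [edf_record_block()].
#' @export
read_edf_records <- function(src, header, channels, first = 0L,
                             count = header$n_data_records - first) {
  first <- as.integer(first); count <- as.integer(count)
  if (count < 0L) usage_error("count must be >= 0")
  if (first < 0L) usage_error("first must be >= 0")
  if (header$n_data_records >= 0L && first + count > header$n_data_records)
    usage_error(sprintf("record range [%d, %d) exceeds the file's %d data records",
                        first, first + count, header$n_data_records))
  spr <- channels$samples_per_record
  per_rec <- sum(spr)
  if (count == 0L)
    return(edf_record_block(integer(0), spr, first_record_index = first))

  s <- open_edf_source(src)
  on.exit(close(s$con))
  seek(s$con, where = header$header_bytes + first * 2 * per_rec, origin = "start")
  vals <- readBin(s$con, "integer", n = count * per_rec, size = 2L,
                  signed = TRUE, endian = "little")
  if (length(vals) < count * per_rec) {
    complete <- length(vals) %/% per_rec
    truncation_error(sprintf(
      "payload truncated: requested records [%d, %d) but last complete record is %d",
      first, first + count, first + complete - 1L),
      last_complete_record = first + complete - 1L)
  }

  ch_of_sample <- rep.int(seq_along(spr), spr)        # one record's channel map
  idx <- rep.int(ch_of_sample, count)                 # recycled across records
  oor <- vals < channels$digital_min[idx] | vals > channels$digital_max[idx]
  tally <- if (any(oor)) tabulate(idx[oor], nbins = length(spr)) else integer(length(spr))

  edf_record_block(vals, spr, first_record_index = first, out_of_range = tally)
}

# ---- write ------------------------------------------------------------------

pad_field <- function(value, width, name) {
  s <- as.character(value)
  raw_s <- charToRaw(s)
  if (any(raw_s > as.raw(0x7e)) || any(raw_s < as.raw(0x20)))
    format_error(sprintf("field '%s' contains non-ASCII characters", name), field = name)
  if (nchar(s) > width)
    format_error(sprintf("field '%s' value '%s' exceeds its fixed width of %d characters",
                         name, s, width), field = name)
  sprintf(paste0("%-", width, "s"), s)
}

# Canonical ASCII rendering of a numeric header value: integers bare, other
# values with just enough digits to parse back exactly, never wider than the
# field. Values with no exact representation in the field are rejected rather
# than silently rounded.
num_field_string <- function(x, width, name) {
  if (is.integer(x) || (is.finite(x) && x == round(x) && abs(x) < 1e15)) {
    s <- sprintf("%.0f", x)
    if (nchar(s) <= width) return(s)
    format_error(sprintf("numeric field '%s' value %s does not fit in %d characters",
                         name, s, width), field = name)
  }
  for (digits in 1:15) {
    s <- formatC(x, digits = digits, format = "g", flag = "", width = 0)
    s <- trimws(s)
    if (nchar(s) <= width && as.numeric(s) == x) return(s)
  }
  format_error(sprintf("numeric field '%s' value %.17g has no exact representation in %d characters",
                       name, x, width), field = name)
}

#' Write an EDF file
#'
#' Serializes a header, channel table, and record block to the EDF binary
#' layout: space-padded fixed-width ASCII header fields followed by signed
#' 16-bit little-endian samples in record-major, channel-blocked order. A
#' field too wide for its slot or a sample outside the signed 16-bit range is
#' an error, never silently altered, so a written file reads back exactly.
#'
#' @param header An [edf_header()]; its `n_data_records` must equal the
#'   block's record count.
#' @param channels An [edf_channel_table()] with `header$n_signals` rows.
#' @param records An [edf_record_block()] holding the full payload.
#' @param sink Output file path.
#' @return Invisibly, the number of bytes written.
#' @export
write_edf <- function(header, channels, records, sink) {
  validate_edf_header(header)
  validate_edf_channels(channels)
  if (nrow(channels) != header$n_signals)
    usage_error(sprintf("header declares %d signals but channel table has %d rows",
                        header$n_signals, nrow(channels)))
  if (header$n_data_records != records$n_records)
    usage_error(sprintf("header declares %d data records but block holds %d",
                        header$n_data_records, records$n_records))
  if (!identical(as.integer(channels$samples_per_record),
                 as.integer(records$samples_per_record)))
    usage_error("samples_per_record in channel table and record block disagree")
  if (length(records$samples) &&
      (min(records$samples) < -32768L || max(records$samples) > 32767L))
    stop_edf("edf_range_error",
             "sample outside the signed 16-bit range [-32768, 32767]")

  main <- paste0(
    pad_field(header$version, 8L, "version"),
    pad_field(header$patient_id, 80L, "patient_id"),
    pad_field(header$recording_id, 80L, "recording_id"),
    pad_field(header$start_date, 8L, "start_date"),
    pad_field(header$start_time, 8L, "start_time"),
    pad_field(header$header_bytes, 8L, "header_bytes"),
    strrep(" ", 44L),
    pad_field(header$n_data_records, 8L, "n_data_records"),
    pad_field(num_field_string(header$record_duration, 8L, "record_duration"),
              8L, "record_duration"),
    pad_field(header$n_signals, 4L, "n_signals")
  )

  sub_parts <- character(0)
  for (i in seq_len(nrow(.EDF_CHANNEL_FIELDS))) {
    nm <- .EDF_CHANNEL_FIELDS$name[i]; w <- .EDF_CHANNEL_FIELDS$width[i]
    vals <- if (nm == "reserved") {
      rep(strrep(" ", w), nrow(channels))
    } else if (nm %in% c("physical_min", "physical_max")) {
      vapply(seq_len(nrow(channels)), function(ch)
        pad_field(num_field_string(channels[[nm]][ch], w, sprintf("%s[%d]", nm, ch)),
                  w, nm), character(1))
    } else {
      vapply(seq_len(nrow(channels)), function(ch)
        pad_field(channels[[nm]][ch], w, sprintf("%s[%d]", nm, ch)), character(1))
    }
    sub_parts <- c(sub_parts, vals)
  }

  con <- file(sink, "wb")
  on.exit(close(con))
  hdr_raw <- charToRaw(paste0(main, paste0(sub_parts, collapse = "")))
  stopifnot(length(hdr_raw) == header$header_bytes)
  writeBin(hdr_raw, con)
  if (length(records$samples))
    writeBin(records$samples, con, size = 2L, endian = "little")
  invisible(header$header_bytes + 2L * length(records$samples))
}
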