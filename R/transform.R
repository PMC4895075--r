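# Channel-oriented reorganization and digital->physical calibration.
#
# An EDF data record interleaves channels (channel 1's block, then channel
# 2's, ...). Visualization and montage composition need the opposite layout:
# each channel's samples contiguous across the whole segment. The gather is
# a pure permutation -- no sample is dropped, duplicated, or altered.
#
# Calibration is the standard EDF affine map fixed by the channel's digital
# and physical extrema: digital_min maps to physical_min, digital_max to
# physical_max, linearly in between (and beyond: out-of-range samples are
# converted, not clipped).

#' Reorganize a raw record block into channel-oriented sequences
#'
#' For each channel, concatenates that channel's per-record blocks in record
#' order, yielding one contiguous integer sequence per channel and thereby
#' direct single-channel access (the layout montage composition needs).
#'
#' @param block An [edf_record_block()].
#' @param channels The matching [edf_channel_table()].
#' @return A named list (by channel label, de-duplicated with
#'   [disambiguate_labels()]) of integer vectors.
#' @export
to_channel_oriented <- function(block, channels) {
  spr <- channels$samples_per_record
  if (!identical(as.integer(spr), as.integer(block$samples_per_record)))
    format_error("record block sample layout does not match the channel table")
  per_rec <- sum(spr)
  if (length(block$samples) != block$n_records * per_rec)
    format_error(sprintf(
      "corrupt block: %d samples but %d records x %d per record expected",
      length(block$samples), block$n_records, per_rec))

  ch_of_sample <- rep.int(seq_len(nrow(channels)), spr)
  idx <- rep.int(ch_of_sample, block$n_records)
  out <- split(block$samples, factor(idx, levels = seq_len(nrow(channels))))
  names(out) <- disambiguate_labels(channels$label)
  out
}

#' De-duplicate channel labels
#'
#' EDF permits duplicate channel labels but JSON object keys must be unique;
#' repeats are suffixed `.2`, `.3`, ... in order of appearance.
#'
#' @param labels Character vector of channel labels.
#' @return Character vector of unique labels.
#' @export
disambiguate_labels <- function(labels) {
  out <- labels
  for (lab in unique(labels[duplicated(labels)])) {
    at <- which(labels == lab)
    out[at[-1]] <- paste0(lab, ".", seq_along(at[-1]) + 1L)
  }
  out
}

#' Calibration parameters of a channel
#'
#' Builds the affine digital-to-physical map from one channel's extrema:
#' `gain = (physical_max - physical_min) / (digital_max - digital_min)` and
#' an offset such that `physical = offset + gain * digital`, which pins
#' `digital_min` to `physical_min` and `digital_max` to `physical_max`.
#'
#' @param channel One row of an [edf_channel_table()].
#' @return A list of class `calibration_params` with `physical_min`,
#'   `physical_max`, `digital_min`, `digital_max`, `gain`, `offset`.
#' @export
calibration_params <- function(channel) {
  if (nrow(channel) != 1L) usage_error("channel must be a single channel row")
  if (channel$digital_min >= channel$digital_max)
    calibration_error(sprintf("channel '%s': digital_min must be < digital_max",
                              channel$label))
  if (channel$physical_min == channel$physical_max)
    calibration_error(sprintf("channel '%s': physical range is degenerate",
                              channel$label))
  gain <- (channel$physical_max - channel$physical_min) /
    (channel$digital_max - channel$digital_min)
  structure(list(
    physical_min = channel$physical_min, physical_max = channel$physical_max,
    digital_min = channel$digital_min, digital_max = channel$digital_max,
    gain = gain,
    offset = channel$physical_min - gain * channel$digital_min
  ), class = "calibration_params")
}

#' Convert digital sample values to physical units
#'
#' `physical_min + gain * (d - digital_min)`, applied elementwise. Values
#' outside the digital calibration range convert linearly too (reported
#' upstream, never clipped), so the map is invertible everywhere.
#'
#' Internally the affine map is evaluated in the endpoint-exact interpolation
#' form `(1 - t) * physical_min + t * physical_max` with
#' `t = (d - digital_min) / (digital_max - digital_min)`, which guarantees
#' that `digital_min` yields exactly `physical_min`, `digital_max` exactly
#' `physical_max`, and an integral midpoint exactly the physical midpoint --
#' identities the naive `min + gain * (d - dmin)` form misses by an ulp for
#' a few percent of calibrations.
#'
#' @param d Integer (or numeric) digital values.
#' @param cal A [calibration_params()] object.
#' @return Numeric vector in the channel's physical units.
#' @export
digital_to_physical <- function(d, cal) {
  t <- (as.numeric(d) - cal$digital_min) / (cal$digital_max - cal$digital_min)
  (1 - t) * cal$physical_min + t * cal$physical_max
}

#' Invert the calibration map back to digital integers
#'
#' Rounds `(p - offset) / gain` to the nearest integer. For values produced
#' by [digital_to_physical()] from in-range integers this recovers the
#' source integers exactly.
#'
#' @param p Physical values.
#' @param cal A [calibration_params()] object.
#' @return Integer vector of digital values.
#' @export
physical_to_digital <- function(p, cal) {
  as.integer(round((as.numeric(p) - cal$offset) / cal$gain))
}

#' Build calibrated channel series from a raw segment
#'
#' Composes the layout gather and the calibration map: each channel of the
#' block becomes a `channel_series` carrying its label, physical unit,
#' sampling rate, and physical-valued samples (optionally also the raw
#' digital integers).
#'
#' @param block An [edf_record_block()].
#' @param channels The matching [edf_channel_table()].
#' @param header The matching [edf_header()] (supplies sampling rates).
#' @param keep_digital Also retain the raw integers in each series?
#' @return A list of `channel_series` objects, one per channel, each a list
#'   with `label`, `unit`, `sampling_rate`, `values`, `n_samples`,
#'   `out_of_range`, and optionally `digital`.
#' @export
build_channel_series <- function(block, channels, header, keep_digital = FALSE) {
  gathered <- to_channel_oriented(block, channels)
  rates <- sampling_rate(channels, header)
  lapply(seq_len(nrow(channels)), function(i) {
    cal <- calibration_params(channels[i, , drop = FALSE])
    vals <- digital_to_physical(gathered[[i]], cal)
    series <- list(
      label = names(gathered)[i],
      unit = channels$physical_dimension[i],
      sampling_rate = rates[i],
      values = vals,
      n_samples = length(vals),
      out_of_range = block$out_of_range[i]
    )
    if (keep_digital) series$digital <- gathered[[i]]
    structure(series, class = "channel_series")
  })
}
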