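# Epoch planning: splits the record axis of a recording into fixed-duration
# logical segments. Epochs must be whole numbers of EDF data records so that
# no record (and no sample) is ever split.

#' Plan fixed-duration epochs over a recording
#'
#' Computes the record ranges of consecutive epochs of `epoch_duration`
#' seconds (30 s by default). The epoch duration must be a positive integer
#' multiple of the header's record duration. When the recording length is not
#' a multiple of the epoch, the trailing remainder is emitted as a final
#' epoch flagged `is_partial` with its true, shorter duration -- every data
#' record lands in exactly one epoch.
#'
#' @param header An [edf_header()] with a known (`>= 0`) record count.
#' @param epoch_duration Epoch length in seconds; default 30.
#' @return An `epoch_plan`: a data.frame with one row per epoch and columns
#'   `segment_index` (0-based), `first_record`, `n_records`, `start_time`,
#'   `end_time` (seconds from recording start), `is_partial`; attributes
#'   `epoch_duration` and `records_per_epoch`.
#' @export
plan_epochs <- function(header, epoch_duration = 30) {
  rd <- header$record_duration
  ratio <- epoch_duration / rd
  if (!is.finite(ratio) || epoch_duration <= 0 ||
      abs(ratio - round(ratio)) > 1e-9 || round(ratio) < 1)
    config_error(sprintf(
      "epoch_duration (%g s) must be a positive integer multiple of the record duration (%g s)",
      epoch_duration, rd))
  if (header$n_data_records < 0L)
    usage_error("cannot plan epochs: number of data records is unknown")

  rpe <- as.integer(round(ratio))
  n <- header$n_data_records
  n_full <- n %/% rpe
  rem <- n %% rpe

  first <- seq_len(n_full + (rem > 0L)) - 1L
  first_record <- first * rpe
  n_records <- rep(rpe, length(first))
  if (rem > 0L) n_records[length(n_records)] <- rem

  plan <- data.frame(
    segment_index = first,
    first_record = first_record,
    n_records = n_records,
    start_time = first_record * rd,
    end_time = (first_record + n_records) * rd,
    is_partial = c(rep(FALSE, n_full), if (rem > 0L) TRUE),
    stringsAsFactors = FALSE
  )
  attr(plan, "epoch_duration") <- epoch_duration
  attr(plan, "records_per_epoch") <- rpe
  class(plan) <- c("epoch_plan", "data.frame")
  plan
}

#' Extract one planned epoch's raw records
#'
#' Reads only the record range of a single plan entry (lazy slice, never the
#' whole file) and returns the raw sample-oriented block together with the
#' per-channel sample counts of the epoch.
#'
#' @param src File path or raw vector holding the EDF byte stream.
#' @param header,channels Parsed header and channel table for `src`.
#' @param plan_entry One row of a [plan_epochs()] result.
#' @return A list with `block` (an [edf_record_block()]), `entry` (the plan
#'   row), and `channel_samples` (integer vector, samples per channel).
#' @export
extract_segment <- function(src, header, channels, plan_entry) {
  if (nrow(plan_entry) != 1L) usage_error("plan_entry must be a single plan row")
  if (plan_entry$n_records < 1L)
    usage_error(sprintf("segment %d has no data records", plan_entry$segment_index))
  block <- tryCatch(
    read_edf_records(src, header, channels,
                     first = plan_entry$first_record, count = plan_entry$n_records),
    edf_truncation_error = function(e)
      truncation_error(sprintf("segment %d: %s", plan_entry$segment_index,
                               conditionMessage(e)),
                       segment_index = plan_entry$segment_index)
  )
  list(block = block,
       entry = plan_entry,
       channel_samples = plan_entry$n_records * channels$samples_per_record)
}
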