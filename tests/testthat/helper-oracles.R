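# Independent brute-force oracles and small fixture builders. Deliberately
# naive: these re-derive expected values by first principles (manual byte
# arithmetic, per-pair scans, index loops) so they share no code path with
# the implementation they check.

# Manual two-byte little-endian two's-complement decode of an EDF payload.
brute_decode_payload <- function(path, header_bytes) {
  bytes <- readBin(path, "raw", n = file.size(path))
  payload <- as.integer(bytes[(header_bytes + 1L):length(bytes)])
  lo <- payload[seq(1L, length(payload), by = 2L)]
  hi <- payload[seq(2L, length(payload), by = 2L)]
  v <- lo + 256L * hi
  ifelse(v >= 32768L, v - 65536L, v)
}

# Gather a channel's samples from an interleaved stream by explicit index
# arithmetic, one record and one sample at a time.
brute_gather <- function(samples, spr, channel) {
  per_rec <- sum(spr)
  n_records <- length(samples) %/% per_rec
  before <- if (channel > 1L) sum(spr[seq_len(channel - 1L)]) else 0L
  out <- integer(0)
  for (r in seq_len(n_records)) {
    base <- (r - 1L) * per_rec + before
    for (k in seq_len(spr[channel])) out <- c(out, samples[base + k])
  }
  out
}

# Per-pair event/window overlap: event [onset, onset+duration] (closed) vs
# window [start, end) (half-open).
brute_overlaps <- function(onset, duration, start, end) {
  onset < end && (onset + duration) >= start
}

# A small deterministic recording written through the public writer.
make_tiny_edf <- function(path, n_channels = 2L, n_records = 5L,
                          spr = rep(4L, n_channels), samples = NULL,
                          record_duration = 1) {
  channels <- edf_channel_table(
    label = sprintf("C%d", seq_len(n_channels)),
    physical_min = -100, physical_max = 100,
    digital_min = -2048L, digital_max = 2047L,
    samples_per_record = spr)
  header <- edf_header(n_data_records = n_records,
                       record_duration = record_duration,
                       n_signals = n_channels)
  if (is.null(samples))
    samples <- seq_len(n_records * sum(spr)) %% 1000L - 500L
  block <- edf_record_block(samples, spr)
  write_edf(header, channels, block, path)
  list(header = header, channels = channels, block = block, path = path)
}

# Random valid header + channels + payload for round-trip properties.
random_edf_parts <- function() {
  n_ch <- sample.int(4L, 1L)
  n_rec <- sample.int(20L, 1L)
  spr <- sample.int(8L, n_ch, replace = TRUE)
  channels <- edf_channel_table(
    label = sprintf("CH%d", seq_len(n_ch)),
    transducer = sample(c("AgAgCl electrode", ""), n_ch, replace = TRUE),
    physical_dimension = sample(c("uV", "mV", "%"), n_ch, replace = TRUE),
    physical_min = sample(seq(-500, -25, by = 25), n_ch, replace = TRUE),
    physical_max = sample(seq(25, 500, by = 25), n_ch, replace = TRUE),
    digital_min = sample(c(-32768L, -2048L, -512L, 0L), n_ch, replace = TRUE),
    digital_max = sample(c(511L, 1023L, 2047L, 32767L), n_ch, replace = TRUE),
    samples_per_record = spr)
  header <- edf_header(
    patient_id = "P 01", recording_id = "rec X",
    start_date = sprintf("%02d.%02d.%02d", sample(28, 1), sample(12, 1), sample(0:99, 1)),
    start_time = sprintf("%02d.%02d.%02d", sample(0:23, 1), sample(0:59, 1), sample(0:59, 1)),
    n_data_records = n_rec, record_duration = sample(c(0.5, 1, 2), 1),
    n_signals = n_ch)
  samples <- sample(-32768:32767, n_rec * sum(spr), replace = TRUE)
  list(header = header, channels = channels,
       block = edf_record_block(samples, spr))
}
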