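# Synthetic EDF recordings with known ground truth. The generator emulates
# an epilepsy-monitoring-unit export: multiple modalities at heterogeneous
# sampling rates (e.g. 256 Hz EEG, 512 Hz ECG, 1 Hz SpO2), per-channel
# calibration ranges, and a sidecar of timestamped clinical events. Every
# sample is the channel's waveform evaluated in physical units, inverse-
# calibrated, and rounded -- so the exact digital payload, the pre-rounding
# physical values, and the events are all known in advance.

#' Describe one synthetic channel
#'
#' @param label Channel label (e.g. "EEG Fp1").
#' @param unit Physical dimension label (e.g. "uV").
#' @param physical_range Length-2 numeric, the calibration physical extrema.
#' @param digital_range Length-2 integer within signed 16-bit.
#' @param sampling_rate Samples per second; `sampling_rate * record_duration`
#'   must be a positive integer.
#' @param waveform A waveform descriptor: `list(type = "constant", value =)`,
#'   `list(type = "sine", freq =, amplitude =, phase = 0, baseline = 0)`, or
#'   `list(type = "noise")` (uniform over the physical range, driven by the
#'   spec's seed).
#' @return A list describing the channel.
#' @export
synth_channel <- function(label, unit = "uV", physical_range = c(-100, 100),
                          digital_range = c(-32768L, 32767L),
                          sampling_rate = 256,
                          waveform = list(type = "constant", value = 0)) {
  stopifnot(length(physical_range) == 2L, length(digital_range) == 2L)
  list(label = label, unit = unit,
       physical_range = as.numeric(physical_range),
       digital_range = as.integer(digital_range),
       sampling_rate = as.numeric(sampling_rate),
       waveform = waveform)
}

#' Describe a synthetic recording
#'
#' @param duration Total recording length in seconds; must be a multiple of
#'   `record_duration`.
#' @param record_duration EDF data-record duration in seconds.
#' @param channels List of [synth_channel()] descriptors.
#' @param events Data frame (or list of lists) of clinical events with
#'   `onset`, `duration`, `text`.
#' @param seed Integer seed; fixed seed gives byte-identical output files.
#' @param recording_id,patient_id,start_date,start_time Header fields.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(duration, record_duration = 1, channels, events = NULL,
                       seed = 1L, recording_id = "synthetic EMU recording",
                       patient_id = "synthetic", start_date = "06.06.16",
                       start_time = "10.00.00") {
  n_records <- duration / record_duration
  if (abs(n_records - round(n_records)) > 1e-9)
    usage_error("duration must be a whole number of data records")
  for (ch in channels) {
    spr <- ch$sampling_rate * record_duration
    if (abs(spr - round(spr)) > 1e-9 || round(spr) < 1)
      usage_error(sprintf(
        "channel '%s': sampling_rate x record_duration (%g) must be a positive integer",
        ch$label, spr))
  }
  if (is.null(events))
    events <- data.frame(onset = numeric(0), duration = numeric(0),
                         text = character(0), stringsAsFactors = FALSE)
  structure(list(duration = duration, record_duration = record_duration,
                 channels = channels, events = as.data.frame(events),
                 seed = as.integer(seed), recording_id = recording_id,
                 patient_id = patient_id, start_date = start_date,
                 start_time = start_time),
            class = "synth_spec")
}

eval_waveform <- function(wf, t, physical_range) {
  switch(wf$type,
    constant = rep(as.numeric(wf$value), length(t)),
    sine = (wf$baseline %||% 0) +
      wf$amplitude * sin(2 * pi * wf$freq * t + (wf$phase %||% 0)),
    noise = stats::runif(length(t), physical_range[1], physical_range[2]),
    usage_error(sprintf("unknown waveform type '%s'", wf$type))
  )
}

#' The default synthetic fixture
#'
#' A 300-second recording with 1-second data records and three modalities at
#' heterogeneous rates -- 256 Hz EEG (10 Hz sine, a typical alpha-band
#' oscillation, +/-100 uV calibration), 512 Hz ECG (1.2 Hz sine, ~72 bpm,
#' +/-5 mV), and 1 Hz SpO2 (constant 97%) -- plus two clinical events: an
#' instantaneous spike at 45 s and a 30-s seizure starting at 120 s that
#' spans an epoch boundary.
#'
#' @param seed Integer seed for the generator.
#' @return A [synth_spec()].
#' @export
emu_small_spec <- function(seed = 1L) {
  synth_spec(
    duration = 300, record_duration = 1,
    channels = list(
      synth_channel("EEG Fp1", "uV", c(-100, 100), c(-2048L, 2047L), 256,
                    list(type = "sine", freq = 10, amplitude = 50)),
      synth_channel("ECG", "mV", c(-5, 5), c(-32768L, 32767L), 512,
                    list(type = "sine", freq = 1.2, amplitude = 2)),
      synth_channel("SpO2", "%", c(0, 100), c(0L, 1023L), 1,
                    list(type = "constant", value = 97))
    ),
    events = data.frame(onset = c(45, 120), duration = c(0, 30),
                        text = c("Spike", "Seizure"), stringsAsFactors = FALSE),
    seed = seed
  )
}

#' Generate a synthetic EDF recording with ground truth
#'
#' Evaluates each channel's waveform at its sample instants in physical
#' units, maps through the inverse calibration, rounds to digital integers,
#' and writes a real EDF file via [write_edf()] plus a tab-separated
#' annotation sidecar. The returned ground truth carries the exact digital
#' samples, the pre-rounding physical samples, and the events, so any later
#' stage can be checked against what was actually put in. A fixed seed gives
#' byte-identical files.
#'
#' @param spec A [synth_spec()].
#' @param out_dir Output directory (created if needed).
#' @param basename File base name; produces `<basename>.edf` and, when the
#'   spec has events, `<basename>.txt`.
#' @return A list with `edf_path`, `annotation_path` (NA when no events),
#'   `header`, `channels`, and `ground_truth` (per-channel `digital` and
#'   `physical` vectors, the `events` table, and the `seed`).
#' @export
generate_synth_edf <- function(spec, out_dir, basename = "synthetic") {
  stopifnot(inherits(spec, "synth_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  n_records <- as.integer(round(spec$duration / spec$record_duration))
  spr <- vapply(spec$channels, function(ch)
    as.integer(round(ch$sampling_rate * spec$record_duration)), integer(1))

  channels <- edf_channel_table(
    label = vapply(spec$channels, `[[`, character(1), "label"),
    physical_dimension = vapply(spec$channels, `[[`, character(1), "unit"),
    physical_min = vapply(spec$channels, function(ch) ch$physical_range[1], numeric(1)),
    physical_max = vapply(spec$channels, function(ch) ch$physical_range[2], numeric(1)),
    digital_min = vapply(spec$channels, function(ch) ch$digital_range[1], integer(1)),
    digital_max = vapply(spec$channels, function(ch) ch$digital_range[2], integer(1)),
    samples_per_record = spr
  )
  header <- edf_header(
    patient_id = spec$patient_id, recording_id = spec$recording_id,
    start_date = spec$start_date, start_time = spec$start_time,
    n_data_records = n_records, record_duration = spec$record_duration,
    n_signals = length(spec$channels)
  )

  physical <- vector("list", length(spec$channels))
  digital <- vector("list", length(spec$channels))
  for (i in seq_along(spec$channels)) {
    ch <- spec$channels[[i]]
    n <- n_records * spr[i]
    t <- (seq_len(n) - 1L) / ch$sampling_rate
    p <- eval_waveform(ch$waveform, t, ch$physical_range)
    lo <- min(ch$physical_range); hi <- max(ch$physical_range)
    if (any(p < lo - 1e-9) || any(p > hi + 1e-9))
      usage_error(sprintf(
        "channel '%s': waveform leaves the physical range [%g, %g]", ch$label, lo, hi))
    cal <- calibration_params(channels[i, , drop = FALSE])
    d <- physical_to_digital(p, cal)
    d <- pmin(pmax(d, channels$digital_min[i]), channels$digital_max[i])
    physical[[i]] <- p
    digital[[i]] <- d
  }
  names(physical) <- names(digital) <- disambiguate_labels(channels$label)

  # interleave into on-disk record-major, channel-blocked order
  samples <- integer(n_records * sum(spr))
  pos <- 0L
  offs <- integer(length(spr))   # per-channel cursor
  for (r in seq_len(n_records)) {
    for (i in seq_along(spr)) {
      samples[(pos + 1L):(pos + spr[i])] <- digital[[i]][(offs[i] + 1L):(offs[i] + spr[i])]
      pos <- pos + spr[i]
      offs[i] <- offs[i] + spr[i]
    }
  }
  block <- edf_record_block(samples, spr)

  edf_path <- file.path(out_dir, paste0(basename, ".edf"))
  write_edf(header, channels, block, edf_path)

  annotation_path <- NA_character_
  if (nrow(spec$events)) {
    annotation_path <- file.path(out_dir, paste0(basename, ".txt"))
    lines <- c("# onset_seconds<TAB>duration_seconds<TAB>text",
               sprintf("%s\t%s\t%s",
                       format(spec$events$onset, trim = TRUE, scientific = FALSE),
                       format(spec$events$duration, trim = TRUE, scientific = FALSE),
                       spec$events$text))
    writeLines(lines, annotation_path, useBytes = TRUE)
  }

  list(edf_path = edf_path, annotation_path = annotation_path,
       header = header, channels = channels,
       ground_truth = list(digital = digital, physical = physical,
                           events = spec$events, seed = spec$seed))
}

#' Draw a randomized but valid synthetic recording spec
#'
#' Convenience for property-style checks: small random channel counts,
#' heterogeneous rates, random calibrations with `digital_min < digital_max`
#' and a non-degenerate physical range, random waveforms, and a few random
#' events inside the recording.
#'
#' @param max_channels,max_records Upper bounds on the drawn shape.
#' @return A [synth_spec()] (the spec's own `seed` is drawn too).
#' @export
random_synth_spec <- function(max_channels = 4L, max_records = 40L) {
  n_ch <- sample.int(max_channels, 1L)
  n_rec <- sample.int(max_records, 1L)
  chans <- lapply(seq_len(n_ch), function(i) {
    rate <- sample(c(1, 2, 4, 8, 16, 32), 1L)
    dmin <- sample(seq(-2048L, 0L, by = 64L), 1L)
    dmax <- dmin + sample(c(255L, 511L, 1023L, 4095L), 1L)
    pmin <- sample(seq(-500, -50, by = 25), 1L)
    pmax <- sample(seq(50, 500, by = 25), 1L)
    wf <- switch(sample(3L, 1L),
                 list(type = "constant", value = stats::runif(1, pmin, pmax)),
                 list(type = "sine", freq = stats::runif(1, 0.2, rate / 4),
                      amplitude = stats::runif(1, 1, min(-pmin, pmax) * 0.9)),
                 list(type = "noise"))
    synth_channel(sprintf("CH%02d", i), "uV", c(pmin, pmax), c(dmin, dmax), rate, wf)
  })
  n_ev <- sample.int(4L, 1L) - 1L
  events <- if (n_ev > 0L) {
    onset <- sort(round(stats::runif(n_ev, 0, n_rec * 0.9), 3))
    data.frame(onset = onset,
               duration = round(stats::runif(n_ev, 0, n_rec * 0.1), 3),
               text = sample(c("Seizure", "Spike", "Artifact"), n_ev, replace = TRUE),
               stringsAsFactors = FALSE)
  } else NULL
  synth_spec(duration = n_rec, record_duration = 1, channels = chans,
             events = events, seed = sample.int(.Machine$integer.max, 1L))
}
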