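---
title: "From EDF recordings to Cloudwave Signal Format: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From EDF recordings to Cloudwave Signal Format: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(edf2csf)
```

## The problem

Clinical electrophysiology units record multi-modal signals -- scalp and
intracranial EEG, ECG, oxygen saturation -- continuously for days, and store
them as European Data Format (EDF) files. EDF is a *sample-oriented* format:
each fixed-duration *data record* holds a contiguous block of samples from
channel 1, then channel 2, and so on. That layout is convenient for
acquisition hardware but awkward for everything downstream. Visualization,
montage composition, and connectivity analyses all want *channel-oriented*
access: one channel's samples contiguous over a time window. EDF files are
also monolithic (megabytes to gigabytes), while retrieval workloads ask for
short windows around clinical events.

`edf2csf` converts a directory of EDF recordings, with optional plain-text
clinical-annotation sidecars, into collections of small, self-descriptive
Cloudwave Signal Format (CSF) JSON documents. Each document carries study
metadata, channel metadata, and a fixed number of fixed-duration signal
*segments* (epochs) whose samples are calibrated to physical units and laid
out per channel, with the overlapping clinical annotations attached to each
segment.

## The processing model

Processing is organized as two conceptually separate stages per recording,
and recordings are independent work units:

1. **Reader** -- parse the EDF header (study- and channel-specific metadata),
   and parse and ontology-map the annotation sidecar. This stage is useful
   on its own (`stage = "read_only"`), e.g. for cataloguing a data store
   without paying for conversion.
2. **Generator** -- plan epochs, extract each epoch's record range, gather
   the interleaved samples into per-channel arrays, apply the calibration
   map, attach overlapping annotations, and pack consecutive segments into
   CSF documents plus an index sidecar.

Because a recording's output depends only on its bytes and the
configuration, the pipeline is deterministic: worker count and processing
order never change the bytes written, and rerunning into a clean directory
reproduces them exactly. A failure in one file (truncation, malformed
header) is recorded in the run report and the remaining files still convert.

## Partitioning into epochs

Epochs are planned on the record axis. The epoch duration (default **30
seconds**, the conventional review-epoch length in clinical EEG and sleep
scoring) must be a positive integer multiple of the EDF record duration;
otherwise `plan_epochs()` refuses with a configuration error stating both
values. The alternative -- splitting data records -- would require
fractional-sample bookkeeping for channels whose rates do not divide evenly,
and no consumer of 1-second records asking for 30-second epochs needs it.

A recording whose length is not a multiple of the epoch yields a trailing
segment flagged `partial` with its true, shorter duration. Partial epochs
are emitted rather than dropped so that per-channel sample totals are
conserved end-to-end; consumers that want only full epochs can filter on
the flag.

Segment indices are 0-based; segment times are offsets in seconds from the
recording start. The absolute wall-clock start of each segment is derived
from the EDF header date and time at CSF-generation time and serialized as
ISO-8601 local time without a zone (the header itself carries no zone).
Two-digit header years follow the standard clipping rule: 85--99 are 1900s,
00--84 are 2000s.

## Calibration

EDF stores signed 16-bit integers ("digital" values) plus, per channel, the
extrema of both the digital and the physical scale. The conversion is the
affine map that pins `digital_min` to `physical_min` and `digital_max` to
`physical_max`:

$$p(d) = p_{\min} + \frac{p_{\max} - p_{\min}}{d_{\max} - d_{\min}} \,(d - d_{\min})$$

Two numerical decisions matter here.

* **Endpoint-exact evaluation.** The map is evaluated as
  $(1-t)\,p_{\min} + t\,p_{\max}$ with $t = (d - d_{\min})/(d_{\max} -
  d_{\min})$. This form returns *exactly* $p_{\min}$, $p_{\max}$, and (for
  an even digital span) the physical midpoint, because $t$ is exactly 0, 1,
  or 0.5 there and scaling by those constants is exact in binary floating
  point. The naive `min + gain*(d - dmin)` form misses these identities by
  one ulp on a few percent of calibrations (measured over 200,000 random
  draws).
* **Out-of-range samples convert, they are not clipped.** EDF files in the
  wild contain samples outside the declared digital range (amplifier
  railing, header sloppiness). Clipping would silently destroy data, so the
  map is applied linearly everywhere and each channel's out-of-range count
  is tallied in the record block and surfaced in the run report.

The map is invertible: rounding the inverse recovers the source integers
exactly for all in-range values, which the test suite exercises over
thousands of random calibrations. Physical values are held at full double
precision in memory; CSF serialization uses 17 significant digits by
default, the precision at which decimal text round-trips IEEE doubles
bit-exactly (configurable downward for smaller files when exactness is not
required).

## Channel-oriented layout

The gather from record-interleaved to channel-contiguous order is a pure
permutation: for channel $c$ the output is the concatenation, in record
order, of each record's channel-$c$ block. No resampling, filtering, or
re-referencing happens here -- the package's job ends at giving montage
builders and analysis code contiguous per-channel arrays. Duplicate channel
labels (legal in EDF, illegal as JSON object keys) are de-duplicated by
suffixing `.2`, `.3`, ... in order of appearance.

## Annotations

The sidecar dialect is deliberately minimal: one event per line,
`onset<TAB>duration<TAB>text`, `#` comments, onsets and durations in seconds
relative to the recording start. Sites whose units export other shapes can
register a line parser with `register_annotation_dialect()`. Malformed
lines (bad syntax, negative times) are never silently dropped; they are
returned in a rejects table alongside the parsed events.

Ontology mapping is a controlled-vocabulary lookup, nothing more: annotation
text is normalized (lowercased, internal whitespace collapsed, terminal
punctuation stripped) and looked up in a two-column table mapping text to a
term identifier, e.g. from an epilepsy ontology such as EpSO. Unmatched
texts are counted and reported, not erroneous -- clinical free text is messy
and the match rate is itself useful quality information.

Segment membership uses a closed event interval against half-open windows:
an event `[onset, onset + duration]` belongs to every segment
`[start, end)` it intersects. Consequences worth knowing: an event spanning
an epoch boundary is duplicated into every epoch it touches (retrieval by
segment then never misses an event); a zero-duration event sitting exactly
on an epoch start belongs to that epoch and not the previous one; an event
ending exactly on a boundary also appears in the following epoch, whose
first instant it touches.

## CSF documents and indexing

Each document holds `segments_per_file` consecutive segments (default
**2**, i.e. one minute of signal at the default epoch), study metadata,
and per-channel metadata, so it is interpretable without the source EDF.
The JSON schema ships with the package:

```{r}
system.file("extdata", "csf-schema.json", package = "edf2csf")
```

Unknown attributes encountered on read are preserved and re-emitted on
write, so documents produced by future format versions survive a
read-modify-write cycle here. `validate_csf()` checks well-formedness,
required attributes, per-segment invariants (positive duration; for
non-partial segments, per-channel sample counts equal to sampling rate
times duration), and -- across a directory -- sequence continuity; findings
carry severities rather than being thrown, because a validator that stops
at the first fault is useless for triage.

A per-recording index sidecar records each document's sequence-number and
time span, letting `locate_segments()` answer "which files hold seconds
4510--4540" by opening only candidate documents.

## The synthetic-data generator

Real EMU recordings cannot ship with a package, so every stage is exercised
against generated EDF files with known ground truth. The default fixture
(`emu_small_spec()`) models a small multi-modal recording: 300 seconds,
1-second records, 256 Hz EEG carrying a 10 Hz (alpha-band) sine at 50 uV
amplitude on a +/-100 uV calibration, 512 Hz ECG carrying a 1.2 Hz (~72 bpm)
sine on +/-5 mV, and 1 Hz SpO2 constant at 97%, plus an instantaneous spike
at 45 s and a 30-second seizure starting at 120 s -- chosen so one event
sits strictly inside an epoch and the other spans an epoch boundary. These
values are the package's fixed study conditions; tests and the acceptance
script all run against them.

Waveforms are evaluated in physical units and pushed through the *inverse*
calibration with rounding, exactly what an acquisition ADC does; the
generator therefore knows both the exact digital payload and the
pre-quantization physical signal. That yields the pipeline's sharpest
end-to-end check: reconstructed physical values must sit within half a
quantization step (`gain/2`) of the analytic waveform, everywhere.

What the generator does **not** emulate -- and hence what passing tests do
not show -- matters equally: no physiological EEG morphology (no 1/f
spectrum, no artifacts, no seizure dynamics), no EDF dialect quirks from
real exporters (nonstandard padding, vendor header abuse), no EDF+
annotation channels, and no discontinuous recordings. The format layer is
tested bit-exactly, but conclusions about robustness to hostile real-world
headers rest only on the explicit error paths, which are tested with
injected truncations and corrupted fields.

## Problem sizes and degenerate inputs

The test suite and the acceptance script run on deliberately small
problems: the 300-second default fixture (230,700 samples), fifty
randomized recordings of at most 4 channels x 40 records for conservation
checks, 200 randomized shapes for the layout oracle, and 1000 randomized
calibrations for round-trip exactness. These sizes already exercise every
code path -- heterogeneous rates, partial epochs, boundary-spanning events
-- and keep a full check run in tens of seconds on one core; the streaming
record reader (`read_edf_records()` seeks to the requested range) is what
carries the design to gigabyte files.

Degenerate inputs are handled by refusal, not guesswork: zero-record
extraction requests, `digital_min == digital_max` calibrations, epoch
durations that split records, unordered segment packs, and unwritable
output directories all raise classed errors; a stored record count of -1
(legal in EDF, meaning unknown) is resolved from the payload length and
refused if the payload is ragged.

## Known limitations

* Plain EDF only: no EDF+ annotation channels, no BDF (24-bit), no
  discontinuous (EDF+D) recordings.
* The annotation dialect is a package convention; timestamps are assumed
  relative to recording start.
* The ontology mapping is a lookup table; no reasoning over the ontology.
* No signal processing: filtering, re-referencing, and montage arithmetic
  belong to downstream tools; the package only guarantees them cheap
  per-channel access.
* File-level parallelism uses process forking and therefore degrades to
  serial execution on platforms without `fork()`; results are identical
  either way.
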