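# edf2csf

Convert European Data Format (EDF) electrophysiological recordings into
Cloudwave Signal Format (CSF): small, self-descriptive JSON documents of
fixed-duration, channel-oriented, physically calibrated signal segments
with attached clinical annotations.

## Who this is for

Neuroinformatics and clinical-research groups sitting on directories of EDF
exports — EEG, ECG, SpO2 and other polysomnography modalities — who need
them in a form that visualization tools, retrieval services, and
connectivity analyses can consume: per-channel contiguous arrays in
physical units, cut into review-sized epochs, findable by recording time,
and labelled with controlled clinical vocabulary.

## What it computes

EDF stores each *data record* (typically 1 s) as channel 1's samples, then
channel 2's, ..., as signed 16-bit integers. For every recording the
pipeline:

1. **parses** the fixed-width EDF header into study metadata (patient,
   start date/time, record count and duration) and channel metadata
   (label, unit, calibration extrema, samples per record), plus the
   `.txt` annotation sidecar paired by base name;
2. **partitions** the record axis into epochs of fixed duration
   (default 30 s), flagging a trailing remainder as partial rather than
   dropping it;
3. **transforms** each epoch: gathers the interleaved samples into one
   contiguous array per channel and applies the EDF calibration map

   `p(d) = p_min + (p_max − p_min)/(d_max − d_min) · (d − d_min)`

   so that `d_min ↦ p_min` and `d_max ↦ p_max` exactly (out-of-range
   samples convert linearly and are tallied, never clipped);
4. **generates CSF**: packs consecutive segments into JSON documents
   (default 2 per file), each carrying study metadata, channel metadata,
   per-segment times (relative and absolute), the partial flag, the
   clinical annotations whose intervals overlap the segment, and the
   per-channel sample arrays — plus an index sidecar for time-range
   lookup. The JSON schema ships in `inst/extdata/csf-schema.json`.

Files are independent work units: runs parallelize per file, one corrupt
file becomes a reported failure instead of an aborted run, and output
bytes are identical regardless of worker count. A synthetic-EDF generator
with exact ground truth (`emu_small_spec()`, `generate_synth_edf()`) makes
the whole pipeline testable without patient data.

## Worked example

```r
library(edf2csf)

dir <- tempfile("demo")
res <- generate_synth_edf(emu_small_spec(seed = 42), file.path(dir, "edf"), "emu")
# -> emu.edf (300 s: 256 Hz EEG, 512 Hz ECG, 1 Hz SpO2) and emu.txt (2 events)

report <- run_pipeline(pipeline_config(file.path(dir, "edf"), file.path(dir, "csf")))
print(report)
#> <pipeline_report> 1 file(s): 1 ok, 0 failed
#>      file status reason n_segments n_documents n_annotations ...
#> 1 emu.edf     ok   <NA>         10           5             2 ...
```

300 seconds at the default 30-s epoch gives 10 segments; at the default 2
segments per document that is 5 CSF files. Which documents cover the
seizure that starts at 120 s?

```r
idx <- build_csf_index(file.path(dir, "csf"))
locate_segments(idx, 125, 155)
#>           file sequence_number
#> 1 emu_0002.csf               4
#> 2 emu_0002.csf               5
```

Segments 4 (`[120, 150)` s) and 5 both intersect the query window — the
30-s seizure spans the epoch boundary at 150 s, so it is attached to both.
Opening the document shows the calibrated, channel-oriented payload:

```r
doc <- read_csf(file.path(dir, "csf", "emu_0002.csf"))
s <- doc$segments[[1]]
s$annotations
#>   onset duration    text ontology_term source_line
#> 1   120       30 Seizure          <NA>           1
str(s$data, list.len = 3, vec.len = 3)
#> List of 3
#>  $ EEG Fp1: num [1:7680] -0.0244 12.1368 23.5653 33.5775 ...
#>  $ ECG    : num [1:15360] -7.63e-05 2.95e-02 5.88e-02 8.83e-02 ...
#>  $ SpO2   : num [1:30] 97 97 97 97 ...
```

7680 = 256 Hz × 30 s of EEG in microvolts; 30 SpO2 samples at 1 Hz; values
are physical units recovered through each channel's calibration.

A shell entry point wraps the same functions:

```sh
exec/edf2csf convert --input edf/ --output csf/ [--epoch 30] [--segments-per-file 2] \
                     [--workers 4] [--mapping terms.tsv] [--stage read_only|full]
exec/edf2csf validate --input csf/
exec/edf2csf synth --out demo/ --seed 1
```

Exit codes: 0 all files converted, 2 partial success (see the report), 1
startup/usage error.

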