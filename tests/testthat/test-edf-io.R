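test_that("header size and simple fields parse back from a written file", {
  path <- withr::local_tempfile(fileext = ".edf")
  fx <- make_tiny_edf(path, n_channels = 3L, n_records = 300L,
                      spr = c(4L, 2L, 1L))
  parsed <- read_edf_header(path)
  expect_identical(parsed$header$header_bytes, 1024L)   # 256 * (1 + 3)
  expect_identical(parsed$header$n_data_records, 300L)
  expect_identical(parsed$header$record_duration, 1)
  expect_identical(parsed$header$n_signals, 3L)
})

test_that("randomized headers round-trip field-for-field through write/read", {
  set.seed(42)
  for (i in 1:20) {
    parts <- random_edf_parts()
    path <- withr::local_tempfile(fileext = ".edf")
    write_edf(parts$header, parts$channels, parts$block, path)
    parsed <- read_edf_header(path)
    expect_equal(unclass(parsed$header), unclass(parts$header))
    expect_equal(as.data.frame(parsed$channels), as.data.frame(parts$channels))
  }
})

test_that("record decoding honors range, emptiness, and layout arithmetic", {
  path <- withr::local_tempfile(fileext = ".edf")
  spr <- c(3L, 5L)
  n_rec <- 7L
  # channel 1 constant at 100, channel 2 a ramp
  per_rec <- sum(spr)
  samples <- integer(n_rec * per_rec)
  for (r in seq_len(n_rec)) {
    base <- (r - 1L) * per_rec
    samples[base + 1:3] <- 100L
    samples[base + 4:8] <- (r - 1L) * 5L + 1:5
  }
  fx <- make_tiny_edf(path, n_channels = 2L, n_records = n_rec, spr = spr,
                      samples = samples)
  blk <- read_edf_records(path, fx$header, fx$channels)
  expect_identical(length(blk$samples), n_rec * per_rec)
  ch1 <- to_channel_oriented(blk, fx$channels)[["C1"]]
  expect_true(all(ch1 == 100L))

  empty <- read_edf_records(path, fx$header, fx$channels, first = 2L, count = 0L)
  expect_identical(empty$n_records, 0L)
  expect_identical(length(empty$samples), 0L)

  mid <- read_edf_records(path, fx$header, fx$channels, first = 2L, count = 3L)
  expect_identical(length(mid$samples), 3L * per_rec)
  expect_error(read_edf_records(path, fx$header, fx$channels, count = -1L),
               class = "edf2csf_usage_error")
  expect_error(read_edf_records(path, fx$header, fx$channels, first = 5L, count = 4L),
               class = "edf2csf_usage_error")
})

test_that("out-of-range digital samples are kept but tallied per channel", {
  path <- withr::local_tempfile(fileext = ".edf")
  spr <- c(2L, 2L)
  samples <- c(3000L, -3000L, 0L, 0L,   # record 1: ch1 both outside [-2048,2047]
               100L, 200L, 0L, 0L)      # record 2: all in range
  fx <- make_tiny_edf(path, n_channels = 2L, n_records = 2L, spr = spr,
                      samples = samples)
  blk <- read_edf_records(path, fx$header, fx$channels)
  expect_identical(blk$out_of_range, c(2L, 0L))
  expect_identical(blk$samples[1:2], c(3000L, -3000L))  # retained, not clipped
})

test_that("decoded values equal a manual two's-complement byte decoder", {
  set.seed(7)
  for (i in 1:8) {
    parts <- random_edf_parts()
    path <- withr::local_tempfile(fileext = ".edf")
    write_edf(parts$header, parts$channels, parts$block, path)
    blk <- read_edf_records(path, parts$header, parts$channels)
    expect_identical(blk$samples,
                     brute_decode_payload(path, parts$header$header_bytes))
  }
})

test_that("write errors on oversize fields and out-of-range samples", {
  parts <- random_edf_parts()
  path <- withr::local_tempfile(fileext = ".edf")
  bad_header <- parts$header
  bad_header$patient_id <- strrep("x", 81)
  expect_error(write_edf(bad_header, parts$channels, parts$block, path),
               class = "edf_format_error")
  bad_block <- parts$block
  bad_block$samples[1] <- 40000L
  expect_error(write_edf(parts$header, parts$channels, bad_block, path),
               class = "edf_range_error")
})

test_that("file size obeys the EDF size law, including zero records", {
  path <- withr::local_tempfile(fileext = ".edf")
  fx <- make_tiny_edf(path, n_channels = 1L, n_records = 10L, spr = 256L)
  expect_identical(file.size(path), 256 * 2 + 10 * 2 * 256)  # payload 5120

  fx0 <- make_tiny_edf(path, n_channels = 2L, n_records = 0L, spr = c(3L, 4L),
                       samples = integer(0))
  expect_identical(file.size(path), as.numeric(fx0$header$header_bytes))
})

test_that("truncated files produce named, located format errors", {
  path <- withr::local_tempfile(fileext = ".edf")
  fx <- make_tiny_edf(path, n_channels = 2L, n_records = 5L, spr = c(4L, 4L))
  bytes <- readBin(path, "raw", n = file.size(path))

  expect_error(read_edf_header(bytes[1:100]), class = "edf_truncation_error")
  expect_error(read_edf_header(bytes[1:300]), class = "edf_truncation_error")

  # chop the payload mid-record: truncation error reports last complete record
  cut <- fx$header$header_bytes + 2L * 8L * 3L + 5L
  err <- tryCatch(read_edf_records(bytes[1:cut], fx$header, fx$channels),
                  error = identity)
  expect_s3_class(err, "edf_truncation_error")
  expect_identical(err$last_complete_record, 2L)

  # corrupt a numeric field: error carries a byte offset
  bad <- bytes
  bad[237:244] <- charToRaw("notanum ")  # n_data_records field
  err2 <- tryCatch(read_edf_header(bad), error = identity)
  expect_s3_class(err2, "edf_format_error")
  expect_match(conditionMessage(err2), "byte offset")
})

test_that("a degenerate digital calibration range is rejected naming the channel", {
  expect_error(
    edf_channel_table(label = c("OK", "BAD"), digital_min = c(-10L, 5L),
                      digital_max = c(10L, 5L), samples_per_record = 1L),
    class = "edf_calibration_error")
})

test_that("an unknown record count (-1) is inferred from the payload length", {
  path <- withr::local_tempfile(fileext = ".edf")
  fx <- make_tiny_edf(path, n_channels = 2L, n_records = 6L, spr = c(2L, 3L))
  bytes <- readBin(path, "raw", n = file.size(path))
  # overwrite the n_data_records field with -1
  bytes[237:244] <- charToRaw(sprintf("%-8s", "-1"))
  parsed <- read_edf_header(bytes)
  expect_identical(parsed$header$n_data_records, 6L)
  # a ragged payload cannot be resolved
  expect_error(read_edf_header(bytes[seq_len(length(bytes) - 3L)]),
               class = "edf_format_error")
})
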