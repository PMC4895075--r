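# Shared fixture: run the full pipeline on a small synthetic recording once
# per file and reuse the outputs.
local_pipeline_run <- function(env = parent.frame(), duration = 300,
                               seed = 1L, epoch = 30, per_file = 2L) {
  d <- withr::local_tempdir(.local_envir = env)
  out <- file.path(d, "csf")
  res <- generate_synth_edf(emu_small_spec(seed), file.path(d, "in"), "emu")
  cfg <- pipeline_config(file.path(d, "in"), out,
                         epoch_duration_seconds = epoch,
                         segments_per_file = per_file)
  report <- run_pipeline(cfg)
  list(dir = d, out = out, res = res, report = report)
}

test_that("packing groups consecutive segments with only the last short", {
  seg <- function(i) structure(list(sequence_number = i, start_time = i * 30,
                                    end_time = (i + 1) * 30,
                                    absolute_start = NA, is_partial = FALSE,
                                    annotations = NULL,
                                    data = list(), extra = list()),
                               class = "signal_segment")
  segs10 <- lapply(0:9, seg)
  docs <- pack_segments(segs10, 2L)
  expect_length(docs, 5L)
  expect_true(all(vapply(docs, function(d) length(d$segments), integer(1)) == 2L))

  expect_length(pack_segments(list(), 2L), 0L)

  docs7 <- pack_segments(lapply(0:6, seg), 3L)
  expect_identical(vapply(docs7, function(d) length(d$segments), integer(1)),
                   c(3L, 3L, 1L))

  expect_error(pack_segments(rev(segs10), 2L), class = "edf2csf_usage_error")
  expect_error(pack_segments(segs10[c(1, 1, 2)], 2L), class = "edf2csf_usage_error")
})

test_that("write/read round trip preserves metadata exactly and values at
           the configured precision", {
  run <- local_pipeline_run()
  files <- list.files(run$out, pattern = "\\.csf$", full.names = TRUE)
  expect_length(files, 5L)
  for (f in files[c(1, 3, 5)]) {
    doc <- read_csf(f)
    f2 <- withr::local_tempfile(fileext = ".csf")
    write_csf(doc, f2)
    doc2 <- read_csf(f2)
    expect_identical(doc2$study, doc$study)
    expect_identical(doc2$channels, doc$channels)
    expect_identical(length(doc2$segments), length(doc$segments))
    for (i in seq_along(doc$segments)) {
      s1 <- doc$segments[[i]]; s2 <- doc2$segments[[i]]
      expect_identical(s2$sequence_number, s1$sequence_number)
      expect_identical(s2$absolute_start, s1$absolute_start)
      expect_identical(s2$annotations, s1$annotations)
      expect_identical(s2$data, s1$data)   # 17 digits: bit-exact doubles
    }
  }
})

test_that("unknown attributes survive a read/write cycle", {
  run <- local_pipeline_run()
  f <- list.files(run$out, pattern = "\\.csf$", full.names = TRUE)[1]
  parsed <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  parsed$future_extension <- list(answer = 42)
  parsed$segments[[1]]$review_state <- "accepted"
  f2 <- withr::local_tempfile(fileext = ".csf")
  writeLines(jsonlite::toJSON(parsed, auto_unbox = TRUE, digits = I(17)), f2)

  doc <- read_csf(f2)
  f3 <- withr::local_tempfile(fileext = ".csf")
  write_csf(doc, f3)
  back <- jsonlite::fromJSON(f3, simplifyVector = FALSE)
  expect_identical(back$future_extension$answer, 42L)
  expect_identical(back$segments[[1]]$review_state, "accepted")
})

test_that("a zero-segment document is valid and a minimal schema document is
           accepted", {
  doc <- csf_document(study = list(recording_id = "r"), channels = NULL,
                      segments = list())
  f <- withr::local_tempfile(fileext = ".csf")
  write_csf(doc, f)
  parsed <- jsonlite::fromJSON(f)
  expect_identical(parsed$segment_count, 0L)
  expect_identical(nrow(validate_csf(f)), 0L)

  minimal <- '{"format_version":"1.0","study":{},"channels":[],
               "segment_count":1,"segments":[{"sequence_number":0,
               "start_time":0,"end_time":30,"partial":false,
               "annotations":[],"data":{}}]}'
  fm <- withr::local_tempfile(fileext = ".csf")
  writeLines(minimal, fm)
  expect_identical(nrow(validate_csf(fm)), 0L)
})

test_that("validation flags injected faults at their JSON paths and reports
           sequence gaps across a directory", {
  run <- local_pipeline_run()
  expect_identical(nrow(validate_csf(run$out)), 0L)   # pipeline output is clean

  # contradict one segment's sample count
  files <- list.files(run$out, pattern = "\\.csf$", full.names = TRUE)
  parsed <- jsonlite::fromJSON(files[2], simplifyVector = FALSE)
  parsed$segments[[1]]$data[["SpO2"]] <- parsed$segments[[1]]$data[["SpO2"]][1:10]
  writeLines(jsonlite::toJSON(parsed, auto_unbox = TRUE, digits = I(17)), files[2])
  rep1 <- validate_csf(files[2])
  expect_identical(sum(rep1$severity == "error"), 1L)
  expect_match(rep1$json_path[rep1$severity == "error"], "SpO2")

  # remove the document holding sequence numbers 6 and 7: continuity warning
  file.remove(files[4])
  file.remove(files[2])   # also drop the corrupted one to isolate the gap check
  rep2 <- validate_csf(run$out)
  warn <- rep2[rep2$severity == "warning", ]
  expect_identical(nrow(warn), 1L)
  expect_match(warn$message, "missing sequence_number")
  expect_match(warn$message, "2, 3, 6, 7")

  bad_json <- withr::local_tempfile(fileext = ".csf")
  writeLines("{not json", bad_json)
  expect_match(validate_csf(bad_json)$message, "not well-formed")
})

test_that("the index locates exactly the segments overlapping a time query", {
  run <- local_pipeline_run()
  idx <- build_csf_index(run$out)
  expect_identical(nrow(idx), 5L)

  hit <- locate_segments(idx, 31, 32)
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$sequence_number, 1)

  all_hits <- locate_segments(idx, 0, 300)
  expect_identical(all_hits$sequence_number, as.numeric(0:9))

  expect_identical(nrow(locate_segments(idx[0, ], 0, 10)), 0L)
  expect_error(locate_segments(idx, 10, 10), class = "edf2csf_usage_error")

  # random queries against a brute-force scan of all documents
  docs <- lapply(idx$file, read_csf)
  set.seed(41)
  for (i in 1:20) {
    a <- runif(1, -10, 310); b <- a + runif(1, 0.5, 80)
    got <- locate_segments(idx, a, b)
    want <- sort(unlist(lapply(docs, function(doc)
      Filter(function(s) s$start_time < b && s$end_time > a, doc$segments) |>
        vapply(`[[`, numeric(1), "sequence_number"))))
    expect_identical(got$sequence_number, as.numeric(want))
  }

  # sidecar persistence
  f <- withr::local_tempfile(fileext = ".json")
  write_csf_index(idx, f)
  idx2 <- read_csf_index(f)
  expect_equal(as.data.frame(idx2), as.data.frame(idx))
})

test_that("every annotation in range appears in exactly the segments its
           interval overlaps", {
  run <- local_pipeline_run()
  files <- list.files(run$out, pattern = "\\.csf$", full.names = TRUE)
  ann_by_seg <- list()
  for (f in files) {
    doc <- read_csf(f)
    for (s in doc$segments)
      ann_by_seg[[as.character(s$sequence_number)]] <- s
  }
  events <- run$res$ground_truth$events
  for (k in names(ann_by_seg)) {
    s <- ann_by_seg[[k]]
    want <- vapply(seq_len(nrow(events)), function(j)
      brute_overlaps(events$onset[j], events$duration[j], s$start_time, s$end_time),
      logical(1))
    expect_setequal(s$annotations$text, events$text[want])
  }
  # the 30-s seizure at 120 s spans segments 4 and 5; the spike at 45 s sits
  # in segment 1 only
  has_seizure <- vapply(ann_by_seg, function(s) "Seizure" %in% s$annotations$text,
                        logical(1))
  expect_setequal(names(which(has_seizure)), c("4", "5"))
  has_spike <- vapply(ann_by_seg, function(s) "Spike" %in% s$annotations$text,
                      logical(1))
  expect_setequal(names(which(has_spike)), "1")
})
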