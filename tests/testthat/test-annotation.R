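test_that("the default tab-separated dialect parses events and collects rejects", {
  lines <- c("# header comment",
             "",
             "45.0\t30.0\tSeizure",
             "12.5\t0\tSpike",
             "oops\t1\tbad onset",
             "-3\t1\tnegative onset",
             "80\t-1\tnegative duration")
  ann <- parse_annotations(lines)
  expect_identical(nrow(ann), 2L)
  # sorted by onset, not input order
  expect_identical(ann$text, c("Spike", "Seizure"))
  expect_identical(ann$onset, c(12.5, 45.0))
  expect_identical(ann$duration, c(0, 30))
  rej <- attr(ann, "rejects")
  expect_identical(nrow(rej), 3L)
  expect_setequal(rej$reason, c("unparseable line", "negative onset or duration"))

  expect_identical(nrow(parse_annotations(character(0))), 0L)
})

test_that("sidecars written by the generator parse back to the ground truth", {
  set.seed(11)
  d <- withr::local_tempdir()
  events <- data.frame(onset = sort(round(runif(12, 0, 250), 3)),
                       duration = round(runif(12, 0, 40), 3),
                       text = sample(c("Seizure", "Spike", "Eyes closed"), 12, TRUE),
                       stringsAsFactors = FALSE)
  spec <- synth_spec(duration = 300, channels = list(synth_channel("C1", sampling_rate = 4)),
                     events = events, seed = 5L)
  res <- generate_synth_edf(spec, d)
  ann <- parse_annotations(res$annotation_path)
  expect_equal(ann$onset, events$onset)
  expect_equal(ann$duration, events$duration)
  expect_identical(ann$text, events$text)
  expect_identical(nrow(attr(ann, "rejects")), 0L)
})

test_that("ontology lookup normalizes text and reports the unmatched remainder", {
  ann <- parse_annotations(c("1\t0\t  Seizure. ", "2\t0\tSPIKE", "3\t0\tchewing"))
  mapping <- read_term_mapping(c("seizure" = "EPSO:Seizure", "spike" = "EPSO:Spike"))
  out <- apply_term_mapping(ann, mapping)
  expect_identical(out$ontology_term, c("EPSO:Seizure", "EPSO:Spike", NA))
  ms <- attr(out, "match_summary")
  expect_identical(ms$matched, 2L)
  expect_identical(ms$unmatched_texts, "chewing")

  # empty mapping: nothing matches, input preserved
  none <- apply_term_mapping(ann, read_term_mapping(setNames(character(0), character(0))))
  expect_identical(none$text, ann$text)
  expect_identical(attr(none, "match_summary")$unmatched, 3L)
})

test_that("matched counts equal a brute-force normalized-set intersection", {
  set.seed(23)
  vocab <- c("seizure", "spike", "artifact", "eyes open", "eyes closed", "chewing")
  for (i in 1:20) {
    texts <- sample(c(vocab, toupper(vocab), paste0(" ", vocab, ". ")), 15, TRUE)
    ann <- parse_annotations(sprintf("%d\t0\t%s", seq_along(texts), texts))
    keys <- sample(vocab, sample.int(6, 1))
    mapping <- read_term_mapping(setNames(paste0("T:", keys), keys))
    out <- apply_term_mapping(ann, mapping)
    brute <- sum(normalize_annotation_text(ann$text) %in% keys)
    expect_identical(attr(out, "match_summary")$matched, brute)
  }
})

test_that("interval membership follows closed-event/half-open-window overlap", {
  ann <- parse_annotations(c("45\t0\tSpike", "25\t10\tSeizure"))
  w1 <- annotations_in_interval(ann, 30, 60)
  expect_setequal(w1$text, c("Spike", "Seizure"))   # 30 <= 45 < 60; [25,35] spans
  w0 <- annotations_in_interval(ann, 0, 30)
  expect_identical(w0$text, "Seizure")
  expect_error(annotations_in_interval(ann, 30, 30), class = "edf2csf_usage_error")
})

test_that("membership over random events and windows equals the per-pair oracle", {
  set.seed(31)
  onset <- runif(200, 0, 300)
  duration <- ifelse(runif(200) < 0.3, 0, runif(200, 0, 50))
  ann <- parse_annotations(sprintf("%.6f\t%.6f\tE%d", onset, duration, 1:200))
  for (i in 1:25) {
    a <- runif(1, 0, 290); b <- a + runif(1, 0.5, 60)
    got <- annotations_in_interval(ann, a, b)
    want <- vapply(seq_len(nrow(ann)), function(j)
      brute_overlaps(ann$onset[j], ann$duration[j], a, b), logical(1))
    expect_identical(got$text, ann$text[want])
  }
})

test_that("tiled windows neither lose nor duplicate zero-duration events", {
  set.seed(37)
  total <- 120
  onset <- runif(50, 0, total - 1e-6)
  ann <- parse_annotations(sprintf("%.6f\t0\tZ%d", onset, 1:50))
  starts <- seq(0, total - 30, by = 30)
  memberships <- unlist(lapply(starts, function(s)
    annotations_in_interval(ann, s, s + 30)$text))
  expect_identical(sort(memberships), sort(ann$text))

  # every event (any duration) inside the recording lands in >= 1 window
  ann2 <- parse_annotations(sprintf("%.6f\t%.6f\tY%d",
                                    runif(30, 0, 110), runif(30, 0, 20), 1:30))
  hit <- Reduce(`|`, lapply(starts, function(s) {
    got <- annotations_in_interval(ann2, s, s + 30)
    ann2$text %in% got$text
  }))
  expect_true(all(hit))
})

test_that("a site-specific dialect can be registered and used", {
  register_annotation_dialect("csv_test", function(line) {
    p <- strsplit(line, ",", fixed = TRUE)[[1]]
    if (length(p) != 3) return(NULL)
    list(onset = as.numeric(p[1]), duration = as.numeric(p[2]), text = p[3])
  })
  ann <- parse_annotations(c("1.5,2,Seizure"), dialect = "csv_test")
  expect_identical(ann$text, "Seizure")
  expect_error(parse_annotations("x", dialect = "nope"),
               class = "edf2csf_usage_error")
})
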