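test_that("matrix format round-trips data bit-exactly and annotations exactly", {
  rec <- make_test_recording()
  path <- file.path(withr::local_tempdir(), "rec.csv")
  write_recording(rec, path)
  back <- read_recording(path, format = "matrix")
  expect_identical(back$data, rec$data)
  expect_equal(back$fs, rec$fs)
  expect_identical(back$channel_names, rec$channel_names)
  expect_equal(back$annotations, rec$annotations)
  expect_identical(back$true_laterality, "left")
})

test_that("channels are reordered to montage order; extras dropped with warning", {
  rec <- make_test_recording()
  path <- file.path(withr::local_tempdir(), "rec.csv")
  shuffled <- rec
  set.seed(9)
  ord <- sample(18)
  shuffled$data <- rec$data[ord, ]
  shuffled$channel_names <- rec$channel_names[ord]
  write_recording(shuffled, path)
  back <- read_recording(path)
  expect_identical(back$channel_names, montage_spec()$full_channels)
  expect_identical(back$data, rec$data)

  extra <- rec
  extra$data <- rbind(rec$data, rnorm(ncol(rec$data)))
  extra$channel_names <- c(rec$channel_names, "ECG")
  write_recording(extra, path)
  expect_warning(back2 <- read_recording(path), "ECG")
  expect_identical(back2$channel_names, montage_spec()$full_channels)
})

test_that("a missing required channel raises a montage error naming it", {
  rec <- make_test_recording()
  path <- file.path(withr::local_tempdir(), "rec.csv")
  drop <- which(rec$channel_names == "T3-T5")
  rec$data <- rec$data[-drop, ]
  rec$channel_names <- rec$channel_names[-drop]
  rec$annotations <- eegfocus:::empty_annotations()
  write_recording(rec, path)
  err <- expect_error(read_recording(path), class = "montage_error")
  expect_match(conditionMessage(err), "T3-T5")
})

test_that("annotations convert seconds to half-open sample intervals", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "ann.csv")
  write.csv(data.frame(start_s = 10.0, end_s = 25.0, label = "ictal"),
            path, row.names = FALSE)
  ann <- read_annotations(path, fs = 500)
  expect_equal(ann$start, 5000L)
  expect_equal(ann$end, 12500L)

  write.csv(data.frame(start_s = numeric(0), end_s = numeric(0),
                       label = character(0)), path, row.names = FALSE)
  expect_equal(nrow(read_annotations(path, fs = 500)), 0L)

  write.csv(data.frame(start_s = 5, end_s = 5, label = "ictal"),
            path, row.names = FALSE)
  expect_error(read_annotations(path, fs = 500), class = "validation_error")

  write.csv(data.frame(start_s = 1, end_s = 2, label = "postictal"),
            path, row.names = FALSE)
  expect_error(read_annotations(path, fs = 500), class = "validation_error")
})

test_that("recording invariants reject overlapping same-label intervals", {
  m <- montage_spec()
  dat <- matrix(0, 18, 1000)
  bad <- data.frame(start = c(0L, 100L), end = c(200L, 300L),
                    label = c("ictal", "ictal"))
  expect_error(
    recording(dat, 500, m$full_channels, annotations = bad),
    class = "validation_error")
  # different labels may overlap
  ok <- data.frame(start = c(0L, 100L), end = c(200L, 300L),
                   label = c("ictal", "interictal"))
  expect_s3_class(recording(dat, 500, m$full_channels, annotations = ok),
                  "eeg_recording")
})

test_that("select_analysis_channels keeps 16 lateral channels and is idempotent", {
  rec <- make_test_recording()
  sel <- select_analysis_channels(rec)
  expect_length(sel$channel_names, 16)
  expect_false(any(c("FZ-CZ", "CZ-PZ") %in% sel$channel_names))
  expect_identical(sel$channel_names, montage_spec()$analysis_channels)
  again <- select_analysis_channels(sel)
  expect_identical(again$data, sel$data)

  drop <- which(sel$channel_names == "P4-O2")
  sel$data <- sel$data[-drop, ]
  sel$channel_names <- sel$channel_names[-drop]
  err <- expect_error(select_analysis_channels(sel), class = "montage_error")
  expect_match(conditionMessage(err), "P4-O2")
})
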