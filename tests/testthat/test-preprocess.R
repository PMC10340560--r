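test_that("measured sine attenuation matches the magnitude-response oracle", {
  cfg <- preprocess_config()
  fs <- 500
  lp <- eegfocus:::design_lowpass(cfg, fs)
  nt <- eegfocus:::design_notch(cfg, fs)
  t <- seq(0, 20, by = 1 / fs)
  measure <- function(f) {
    x <- sin(2 * pi * f * t)
    y <- signal::filtfilt(nt, signal::filtfilt(lp, x))
    mid <- y[2001:8001]  # steady state, away from filtfilt edge transients
    20 * log10(sqrt(mean(mid^2)) / sqrt(0.5))
  }
  for (f in c(5, 30, 100)) {
    predicted <- filter_response_db(lp, f, fs) + filter_response_db(nt, f, fs)
    expect_equal(measure(f), predicted, tolerance = 0.02)
  }
})

test_that("filtering is linear and shape-preserving", {
  rec <- make_test_recording(duration_s = 4)
  f1 <- apply_filters(rec)
  expect_identical(dim(f1$data), dim(rec$data))
  expect_equal(f1$fs, rec$fs)
  scaled <- rec
  scaled$data <- 3.7 * rec$data
  f2 <- apply_filters(scaled)
  expect_equal(f2$data, 3.7 * f1$data, tolerance = 1e-9)
})

test_that("filtering rejects a sampling rate below twice the cutoff", {
  m <- montage_spec()
  rec <- recording(matrix(rnorm(18 * 500), 18, 500), fs = 100,
                   channel_names = m$full_channels)
  expect_error(apply_filters(rec), class = "config_error")
})

test_that("resampling scales length, preserves tones, rescales annotations", {
  m <- montage_spec()
  fs <- 500; n <- 50000
  t <- (0:(n - 1)) / fs
  dat <- matrix(rep(sin(2 * pi * 20 * t), 18), 18, n, byrow = TRUE)
  ann <- data.frame(start = 5000L, end = 25000L, label = "ictal")
  rec <- recording(dat, fs, m$full_channels, annotations = ann)
  out <- resample_to_analysis_rate(rec, preprocess_config())
  expect_equal(out$fs, 256)
  expect_equal(ncol(out$data), 25600)
  expect_equal(out$annotations$start, 2560L)
  expect_equal(out$annotations$end, 12800L)
  # dominant spectral peak still at 20 Hz
  y <- out$data[1, ]
  spec <- Mod(fft(y))[1:(length(y) / 2)]
  f_peak <- (which.max(spec) - 1) * 256 / length(y)
  expect_equal(f_peak, 20, tolerance = 0.1)
  # identity when already at the analysis rate
  rec256 <- recording(out$data, 256, m$full_channels)
  expect_identical(resample_to_analysis_rate(rec256, preprocess_config())$data,
                   rec256$data)
})

test_that("segmentation counts, discards trailing partials, labels by overlap", {
  m <- montage_spec()
  cfg <- preprocess_config()
  mk <- function(n, ann = NULL)
    recording(matrix(0, 18, n), 256, m$full_channels, annotations = ann)
  expect_equal(dim(segment_epochs(mk(40960), cfg)$epochs)[1], 10)
  es1 <- segment_epochs(mk(5000), cfg)
  expect_equal(dim(es1$epochs)[1], 1)      # 904 trailing samples discarded
  expect_warning(segment_epochs(mk(1000), cfg), "shorter")

  # exactly-50% ictal coverage sits on the >= boundary: labeled ictal
  ann <- data.frame(start = 0L, end = 2048L, label = "ictal")
  es2 <- segment_epochs(mk(4096, ann), cfg)
  expect_identical(es2$labels, "ictal")
  ann3 <- data.frame(start = 0L, end = 2047L, label = "ictal")
  es3 <- segment_epochs(mk(4096, ann3), cfg)
  expect_identical(es3$labels, "interictal")
})

test_that("epoch count is floor(n / epoch_len) and labels ignore signal content", {
  m <- montage_spec()
  cfg <- preprocess_config()
  set.seed(4)
  for (n in c(4096, 6000, 12288, 20000)) {
    ann <- data.frame(start = 0L, end = as.integer(n), label = "ictal")
    r1 <- recording(matrix(rnorm(18 * n), 18, n), 256, m$full_channels,
                    annotations = ann)
    r2 <- recording(matrix(0, 18, n), 256, m$full_channels,
                    annotations = ann)
    e1 <- segment_epochs(r1, cfg); e2 <- segment_epochs(r2, cfg)
    expect_equal(dim(e1$epochs)[1], n %/% 4096)
    expect_identical(e1$labels, e2$labels)
  }
})
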