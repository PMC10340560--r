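# Reference coefficients computed once with an independent wavelet
# implementation (PyWavelets, db4, mode = "periodization") and frozen here.
PYWT_X16 <- c(
   0.30471707975443135, -1.0399841062404955,  0.7504511958064572,
   0.9405647163912139,  -1.9510351886538364, -1.302179506862318,
   0.12784040316728537, -0.3162425923435822, -0.016801157504288795,
  -0.85304392757358,     0.8793979748628286,  0.7777919354289483,
   0.06603069756121605,  1.1272412069680329,  0.4675093422520456,
  -0.8592924628832382)
PYWT_A1 <- c(
   0.3125132806998427, -0.9375077098434109,  1.182124422167452,
  -1.981842818924456,  -0.19610105677175577, -0.7589683938034727,
   0.6930583713107481,  1.05242480513123)
PYWT_D1 <- c(
   0.6806641226167731,  0.35161208805190425, -0.6159656289470551,
  -0.7550021606883311,  0.006566186891972333, 0.7767504872904849,
  -0.9944884230442924, -0.9727179439476424)
PYWT_A2 <- c(1.1245043204817096, 0.1736422774151457,
            -0.421138802918335, -1.3255249899129604)
PYWT_D2 <- c(-2.0149184291179463, -0.35228036868148876,
              0.1375905748536345, -1.035449656359291)

dyadic_sets <- c("HF", paste0("D", 1:9), "A9")

test_that("the periodized db4 step reproduces the independent reference", {
  st <- eegfocus:::dwt_step(PYWT_X16)
  expect_equal(as.numeric(st$A), PYWT_A1, tolerance = 1e-12)
  expect_equal(as.numeric(st$D), PYWT_D1, tolerance = 1e-12)
  st2 <- eegfocus:::dwt_step(st$A)
  expect_equal(as.numeric(st2$A), PYWT_A2, tolerance = 1e-12)
  expect_equal(as.numeric(st2$D), PYWT_D2, tolerance = 1e-12)
})

test_that("the nine-level tree conserves energy and zeroes map to zeroes", {
  dec0 <- dwt_tree(rep(0, 4096))
  for (s in names(dec0$sets)) expect_true(all(dec0$sets[[s]] == 0))

  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(4096)
    dec <- dwt_tree(x)
    e <- sum(vapply(dec$sets[dyadic_sets],
                    function(s) sum(s^2), 0))
    expect_equal(e, sum(x^2), tolerance = 1e-8)
  }
  expect_error(dwt_tree(rnorm(4000)), class = "shape_error")
  expect_error(dwt_tree(rnorm(512)), class = "shape_error")
})

test_that("band energies agree with an FFT band-pass oracle for tones", {
  t <- (0:4095) / 256
  x <- sin(2 * pi * 20 * t)
  dec <- dwt_tree(x)
  total <- sum(x^2)
  # 20 Hz lies inside beta (16-24 Hz): most energy lands there
  expect_gt(band_energy(dec, "Beta") / total, 0.70)
  # agreement with the FFT band-pass oracle, up to wavelet filter roll-off
  oracle <- fft_band_energy(x, 16, 24, 256)
  expect_lt(abs(band_energy(dec, "Beta") - oracle) / total, 0.3)
})

test_that("composite bands sum their parts and partition total energy", {
  set.seed(21)
  x <- rnorm(4096)
  dec <- dwt_tree(x)
  delta_parts <- sum(vapply(c("D5", "D6", "D7", "D8", "D9", "A9"),
                            function(b) band_energy(dec, b), 0))
  expect_equal(band_energy(dec, "Delta"), delta_parts, tolerance = 1e-12)
  expect_equal(band_energy(dec, "Beta") + band_energy(dec, "Gamma"),
               band_energy(dec, "D2"), tolerance = 1e-8)
  # the 13-band table partitions the 0-64 Hz range: together with the
  # out-of-band residual it reconstitutes the total energy
  top <- sum(vapply(c("Delta", "Theta", "Alpha", "D2", "D1"),
                    function(b) band_energy(dec, b), 0))
  expect_equal(top + sum(dec$sets$HF^2), sum(x^2), tolerance = 1e-8)
  expect_error(band_energy(dec, "Mu"), class = "lookup_error")
})

test_that("feature extraction has the right shape, scaling and equivariance", {
  m <- montage_spec()
  set.seed(31)
  rec <- recording(matrix(rnorm(16 * 40960), 16, 40960), 256,
                   m$analysis_channels)
  es <- segment_epochs(rec, preprocess_config())
  fm <- extract_features(es, "Beta")
  expect_equal(dim(fm$energy), c(10, 16))
  expect_true(all(fm$energy >= 0))

  # doubling one channel's amplitude quadruples exactly that column
  rec2 <- rec
  rec2$data[5, ] <- 2 * rec$data[5, ]
  fm2 <- extract_features(segment_epochs(rec2, preprocess_config()), "Beta")
  expect_equal(fm2$energy[, 5], 4 * fm$energy[, 5], tolerance = 1e-12)
  expect_equal(fm2$energy[, -5], fm$energy[, -5], tolerance = 1e-12)

  # epoch permutation equivariance
  perm <- c(3, 1, 2, 7, 10, 4, 5, 9, 6, 8)
  esp <- es
  esp$epochs <- es$epochs[perm, , ]
  esp$labels <- es$labels[perm]
  esp$origin <- es$origin[perm, ]
  fmp <- extract_features(esp, "Beta")
  expect_equal(fmp$energy, fm$energy[perm, ], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("feature matrices round-trip through CSV", {
  fm <- make_separable_features(n_per_class = 5)
  path <- file.path(withr::local_tempdir(), "features.csv")
  write_features(fm, path)
  back <- read_features(path)
  expect_equal(back$energy, fm$energy, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(back$labels, fm$labels)
  expect_identical(back$band, "Beta")
})
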