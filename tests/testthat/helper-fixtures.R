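# Fixtures are built in code: nothing binary ships with the package.

# A small deterministic 18-channel recording with one ictal interval.
make_test_recording <- function(fs = 500, duration_s = 12, seed = 1,
                                ictal = duration_s * c(1, 2) / 3) {
  m <- montage_spec()
  set.seed(seed)
  n <- fs * duration_s
  data <- matrix(rnorm(18 * n), 18, n)
  ann <- data.frame(start = as.integer(ictal[1] * fs),
                    end = as.integer(ictal[2] * fs),
                    label = "ictal", stringsAsFactors = FALSE)
  recording(data, fs = fs, channel_names = m$full_channels,
            subject_id = "T01", recording_id = "T01-R01",
            annotations = ann, true_laterality = "left")
}

# Hand-built epoch set over the 16 analysis channels: channel amplitudes
# set per pair so lateralization arithmetic is fully controlled.
# left_amp/right_amp: length-8 amplitude vectors (pair order).
make_vote_epochs <- function(left_amp, right_amp, n_epochs = 1,
                             epoch_len = 512, labels = NULL) {
  m <- montage_spec()
  base <- sin(2 * pi * 10 * (0:(epoch_len - 1)) / 256)
  epochs <- array(0, dim = c(n_epochs, 16, epoch_len))
  for (e in seq_len(n_epochs)) {
    for (p in 1:8) {
      epochs[e, p, ] <- left_amp[p] * base
      epochs[e, p + 8, ] <- right_amp[p] * base
    }
  }
  structure(list(fs = 256, epoch_len = epoch_len, epochs = epochs,
                 labels = labels %||% rep("ictal", n_epochs),
                 channel_names = m$analysis_channels,
                 origin = data.frame(recording_id = rep("V01", n_epochs),
                                     start_sample = (seq_len(n_epochs) - 1) *
                                       epoch_len)),
            class = "epoch_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Well-separated two-class feature matrix for classifier unit tests.
make_separable_features <- function(n_per_class = 60, d = 16, seed = 1,
                                    gap = 6) {
  set.seed(seed)
  E <- rbind(matrix(exp(rnorm(n_per_class * d)), n_per_class, d),
             matrix(exp(rnorm(n_per_class * d) + gap), n_per_class, d))
  labels <- rep(c("interictal", "ictal"), each = n_per_class)
  structure(list(band = "Beta", energy = E,
                 channel_names = paste0("CH", seq_len(d)),
                 labels = labels,
                 origin = data.frame(
                   recording_id = rep("F01", 2 * n_per_class),
                   start_sample = seq_len(2 * n_per_class) * 4096)),
            class = "feature_matrix")
}

# FFT band-limited energy: the independent oracle for wavelet band energies.
fft_band_energy <- function(x, f_lo, f_hi, fs) {
  n <- length(x)
  X <- fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)               # two-sided -> analog frequency
  keep <- f >= f_lo & f < f_hi
  sum(Mod(X[keep])^2) / n
}
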