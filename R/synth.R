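# Synthetic scalp-EEG cohorts with known ictal intervals and focus side.
#
# The generator emulates the statistical structure the pipeline is built
# for: 500 Hz, 18-channel bipolar 10-20 recordings of 1/f background
# activity with 50 Hz power-line contamination, into which seizures are
# inserted as Hann-enveloped narrowband oscillations (beta band by
# default) with Hann-tapered onsets/offsets on the 16 lateral channels,
# with focus-side channels scaled by an asymmetry factor.

#' Synthetic recording configuration
#'
#' @param fs sampling rate in Hz (default 500).
#' @param duration_s recording length in seconds (default 120).
#' @param seizure_windows list of `c(start_s, end_s)` ictal windows
#'   (non-overlapping, within the recording). Default one 40 s seizure.
#' @param focus_side `"left"` or `"right"`.
#' @param asymmetry_factor amplitude multiplier (gamma >= 1) applied to the
#'   ictal oscillation on focus-side channels; default 1.5 (energy ratio
#'   2.25).
#' @param ictal_band_hz `c(low, high)` of the ictal oscillation; default
#'   `c(16, 24)` (rhythmic beta activity).
#' @param ictal_amplitude_uv peak amplitude of the ictal oscillation on the
#'   non-focus side (microvolts). Default 50.
#' @param background_amplitude_uv RMS of the 1/f background (microvolts).
#'   Default 20.
#' @param background_alpha spectral exponent of the 1/f^alpha background.
#'   Default 1.
#' @param powerline_amplitude_uv amplitude of the 50 Hz mains component.
#'   Default 5.
#' @param seed integer seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(fs = 500, duration_s = 120,
                         seizure_windows = list(c(40, 80)),
                         focus_side = c("right", "left"),
                         asymmetry_factor = 1.5,
                         ictal_band_hz = c(16, 24),
                         ictal_amplitude_uv = 50,
                         background_amplitude_uv = 20,
                         background_alpha = 1,
                         powerline_amplitude_uv = 5,
                         seed = 1L) {
  focus_side <- match.arg(focus_side)
  cfg <- list(fs = fs, duration_s = duration_s,
              seizure_windows = seizure_windows, focus_side = focus_side,
              asymmetry_factor = asymmetry_factor,
              ictal_band_hz = ictal_band_hz,
              ictal_amplitude_uv = ictal_amplitude_uv,
              background_amplitude_uv = background_amplitude_uv,
              background_alpha = background_alpha,
              powerline_amplitude_uv = powerline_amplitude_uv,
              seed = as.integer(seed))
  if (cfg$asymmetry_factor < 1)
    stop_eegfocus("asymmetry_factor must be >= 1", "config_error")
  if (length(cfg$seizure_windows)) {
    w <- do.call(rbind, cfg$seizure_windows)
    if (any(w[, 2L] <= w[, 1L]) || any(w[, 1L] < 0) ||
        any(w[, 2L] > duration_s))
      stop_eegfocus("seizure windows must be within the recording and non-empty",
                    "config_error")
    o <- order(w[, 1L])
    if (nrow(w) > 1L && any(w[o, 1L][-1L] < w[o, 2L][-nrow(w)]))
      stop_eegfocus("seizure windows must not overlap", "config_error")
  }
  class(cfg) <- "synth_config"
  cfg
}

# 1/f^alpha noise of length n via FFT spectral shaping, unit RMS.
pink_noise <- function(n, alpha = 1) {
  white <- stats::rnorm(n)
  X <- stats::fft(white)
  f <- c(1, seq_len(n - 1))             # DC bin kept finite
  f <- pmin(f, n - f + 1)               # fold to two-sided frequency index
  X <- X * f^(-alpha / 2)
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Generate one synthetic EEG recording
#'
#' Background on all 18 channels: seeded 1/f^alpha noise at the configured
#' RMS plus a 50 Hz sinusoid with per-channel random phase. Inside each
#' seizure window a sustained sinusoid with Hann-tapered onset and offset
#' ramps, its frequency drawn uniformly from `ictal_band_hz` (shared across
#' channels, random phase per channel), is added to the 16 lateral
#' channels; focus-side channels get the oscillation scaled by
#' `asymmetry_factor`. Seizure windows are annotated
#' ictal, the remainder interictal, and the focus side is stored as
#' ground truth.
#'
#' @param cfg a [synth_config()].
#' @param subject_id,recording_id identifiers for provenance.
#' @param montage a [montage_spec()].
#' @return An `eeg_recording` with annotations and `true_laterality`.
#' @export
generate_recording <- function(cfg = synth_config(), subject_id = "SYN-P01",
                               recording_id = "SYN-P01-R01",
                               montage = montage_spec()) {
  old <- get0(".Random.seed", envir = .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))
  set.seed(cfg$seed)
  n <- round(cfg$duration_s * cfg$fs)
  chans <- montage$full_channels
  t <- (seq_len(n) - 1) / cfg$fs
  data <- matrix(0, length(chans), n)
  for (ch in seq_along(chans)) {
    bg <- cfg$background_amplitude_uv * pink_noise(n, cfg$background_alpha)
    mains <- cfg$powerline_amplitude_uv *
      sin(2 * pi * 50 * t + stats::runif(1, 0, 2 * pi))
    data[ch, ] <- bg + mains
  }
  side_of <- function(name) {
    if (name %in% montage$pairs$left) "left"
    else if (name %in% montage$pairs$right) "right"
    else "midline"
  }
  ann <- empty_annotations()
  for (w in cfg$seizure_windows) {
    i0 <- floor(w[1L] * cfg$fs); i1 <- ceiling(w[2L] * cfg$fs)
    i1 <- min(i1, n)
    idx <- (i0 + 1L):i1
    # Hann-tapered plateau: cosine ramps (<= 5 s or a quarter of the window
    # each) into a sustained discharge, avoiding a hard on/offset while
    # keeping the rhythmic activity at full amplitude between the ramps
    nw <- length(idx)
    ramp <- min(round(5 * cfg$fs), nw %/% 4L)
    env <- rep(1, nw)
    if (ramp > 0L) {
      up <- 0.5 * (1 - cos(pi * (seq_len(ramp) - 1) / ramp))
      env[seq_len(ramp)] <- up
      env[nw + 1L - seq_len(ramp)] <- up
    }
    f_ict <- stats::runif(1, cfg$ictal_band_hz[1L], cfg$ictal_band_hz[2L])
    for (ch in seq_along(chans)) {
      side <- side_of(chans[ch])
      if (side == "midline") next
      amp <- cfg$ictal_amplitude_uv *
        (if (side == cfg$focus_side) cfg$asymmetry_factor else 1)
      phase <- stats::runif(1, 0, 2 * pi)
      data[ch, idx] <- data[ch, idx] +
        amp * env * sin(2 * pi * f_ict * t[idx] + phase)
    }
    ann <- rbind(ann, data.frame(start = as.integer(i0), end = as.integer(i1),
                                 label = "ictal", stringsAsFactors = FALSE))
  }
  recording(data, fs = cfg$fs, channel_names = chans,
            subject_id = subject_id, recording_id = recording_id,
            annotations = if (nrow(ann)) ann else NULL,
            true_laterality = cfg$focus_side)
}

#' Generate a synthetic patient cohort
#'
#' Each patient is assigned a focus side once (shared by all of that
#' patient's recordings); per-recording seeds are derived deterministically
#' from the master seed, so the same master seed always reproduces the same
#' cohort. The left fraction defaults to 28/76, a right-dominant case mix
#' typical of surgical TLE series.
#'
#' @param n_patients number of patients.
#' @param recordings_per_patient recordings per patient; a scalar or a
#'   vector recycled across patients (uneven series like 76 recordings over
#'   26 patients are expressible this way).
#' @param config a [synth_config()] template (its `focus_side` and `seed`
#'   are overridden per patient/recording).
#' @param left_fraction fraction of patients with a left-sided focus.
#' @param seed master seed.
#' @return list of `eeg_recording`, grouped patient-major, with attribute
#'   `"patients"`: a data.frame of `subject_id`, `focus_side`.
#' @export
generate_cohort <- function(n_patients, recordings_per_patient,
                            config = synth_config(), left_fraction = 28 / 76,
                            seed = 1L) {
  if (n_patients < 1L)
    stop_eegfocus("n_patients must be >= 1", "config_error")
  n_left <- round(n_patients * left_fraction)
  old <- get0(".Random.seed", envir = .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))
  set.seed(derive_seed(seed, 0L))
  sides <- sample(c(rep("left", n_left), rep("right", n_patients - n_left)))
  n_per <- rep_len(recordings_per_patient, n_patients)
  recs <- list()
  for (p in seq_len(n_patients)) {
    sid <- sprintf("SYN-P%02d", p)
    for (r in seq_len(n_per[p])) {
      cfg <- config
      cfg$focus_side <- sides[p]
      cfg$seed <- derive_seed(seed, p, r)
      recs[[length(recs) + 1L]] <- generate_recording(
        cfg, subject_id = sid,
        recording_id = sprintf("%s-R%02d", sid, r))
    }
  }
  attr(recs, "patients") <- data.frame(
    subject_id = sprintf("SYN-P%02d", seq_len(n_patients)),
    focus_side = sides, stringsAsFactors = FALSE)
  recs
}
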