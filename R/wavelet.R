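# Periodized orthonormal db4 analysis filters (Daubechies, 4 vanishing
# moments, 8 taps). With periodization the transform is exactly orthogonal,
# so subband energies partition the signal energy (Parseval) -- the property
# the energy features rely on.
DB4_LO <- c(-0.010597401785069032,  0.0328830116668852,
             0.030841381835560764, -0.18703481171909309,
            -0.027983769416859854,  0.6308807679298589,
             0.7148465705529157,    0.2303778133088965)
DB4_HI <- c(-0.2303778133088965,    0.7148465705529157,
            -0.6308807679298589,   -0.027983769416859854,
             0.18703481171909309,   0.030841381835560764,
            -0.0328830116668852,   -0.010597401785069032)

# One periodized analysis step on the rows of X (n_signals x N, N even).
# Convention: c[k] = sum_m f[m] * x[(2k + L/2 - m) mod N], matching the
# standard periodization used across wavelet toolboxes.
dwt_step <- function(X) {
  if (is.vector(X)) X <- matrix(X, nrow = 1L)
  N <- ncol(X)
  if (N %% 2L != 0L)
    stop_eegfocus("signal length must be even for a DWT step", "shape_error")
  L <- length(DB4_LO)
  half <- N %/% 2L
  A <- matrix(0, nrow(X), half)
  D <- matrix(0, nrow(X), half)
  k2 <- 2L * (seq_len(half) - 1L)
  for (m in seq_len(L) - 1L) {
    idx <- ((k2 + L %/% 2L - m) %% N) + 1L
    A <- A + DB4_LO[m + 1L] * X[, idx, drop = FALSE]
    D <- D + DB4_HI[m + 1L] * X[, idx, drop = FALSE]
  }
  list(A = A, D = D)
}

#' Nine-level db4 subband decomposition of an epoch
#'
#' Dyadic discrete wavelet decomposition (db4, periodization boundary) of
#' each channel of one epoch at the 256 Hz analysis rate. The tree is the
#' classical nine-level decomposition of the 0--64 Hz EEG band: because the
#' analysis Nyquist is 128 Hz, one initial split first isolates the
#' 64--128 Hz residual (`HF`, essentially empty after the 64 Hz low-pass),
#' and the nine named levels below it produce the detail sets D1
#' (32--64 Hz) down to D9 (0.125--0.25 Hz) plus the approximation A9
#' (0--0.125 Hz), exactly the named subband ranges of [band_table()].
#'
#' The D2 set (16--32 Hz) is additionally split once more with the same
#' single-level transform into beta (16--24 Hz) and gamma (24--32 Hz).
#' Wavelet-packet frequency ordering reverses on a detail branch: D2 is
#' spectrally inverted, so its low-pass child holds the upper half (gamma)
#' and its high-pass child the lower half (beta).
#'
#' @param x numeric vector (one channel) or matrix (channels x samples);
#'   the sample count must be a power of two >= 1024 (ten dyadic splits).
#' @param fs sampling rate in Hz (default 256; determines the nominal band
#'   edges reported in [band_table()]).
#' @return An object of class `subband_decomposition`: list with `sets`
#'   (named list of coefficient matrices, channels x n_coeffs, for
#'   HF, D1..D9, A9, BETA, GAMMA), `wavelet`, `boundary`, `levels`, `fs`.
#' @examples
#' dec <- dwt_tree(sin(2 * pi * 20 * (0:4095) / 256))
#' band_energy(dec, "Beta")
#' @export
dwt_tree <- function(x, fs = 256) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  N <- ncol(x)
  if (N < 1024L || bitwAnd(N, N - 1L) != 0L)
    stop_eegfocus("epoch length must be a power of two >= 1024", "shape_error")
  sets <- vector("list", 13L)
  names(sets) <- c("HF", paste0("D", 1:9), "A9", "BETA", "GAMMA")
  st <- dwt_step(x)           # split off the out-of-band 64-128 Hz residual
  sets[["HF"]] <- st$D
  cur <- st$A
  for (lev in 1:9) {
    st <- dwt_step(cur)
    sets[[paste0("D", lev)]] <- st$D
    cur <- st$A
  }
  sets[["A9"]] <- cur
  split2 <- dwt_step(sets[["D2"]])
  sets[["BETA"]] <- split2$D   # detail branch inverts: high-pass child = 16-24 Hz
  sets[["GAMMA"]] <- split2$A
  structure(list(sets = sets, wavelet = "db4", boundary = "periodization",
                 levels = 9L, fs = fs),
            class = "subband_decomposition")
}

#' The subband table of the pipeline
#'
#' The 13 named bands over which energy features are computed, with nominal
#' frequency ranges at the 256 Hz analysis rate and the dyadic coefficient
#' sets that constitute each band. Classical EEG bands map onto the tree as
#' Alpha = D3, Theta = D4, Delta = the union of D5..D9 and A9 (0--4 Hz);
#' Beta and Gamma come from the extra single-level split of D2.
#'
#' @return data.frame with columns `band`, `f_low_hz`, `f_high_hz`, and a
#'   list-column `sets` of coefficient-set names.
#' @export
band_table <- function() {
  tab <- data.frame(
    band = c("Delta", "Theta", "Alpha", "Beta", "Gamma",
             "D1", "D2", "D5", "D6", "D7", "D8", "D9", "A9"),
    f_low_hz  = c(0, 4, 8, 16, 24, 32, 16, 2, 1, 0.5, 0.25, 0.125, 0),
    f_high_hz = c(4, 8, 16, 24, 32, 64, 32, 4, 2, 1, 0.5, 0.25, 0.125),
    stringsAsFactors = FALSE)
  tab$sets <- list(
    c("D5", "D6", "D7", "D8", "D9", "A9"),  # Delta
    "D4", "D3", "BETA", "GAMMA",
    "D1", "D2", "D5", "D6", "D7", "D8", "D9", "A9")
  tab
}

band_sets <- function(band) {
  tab <- band_table()
  i <- match(band, tab$band)
  if (is.na(i))
    stop_eegfocus(sprintf("unknown band '%s'; known bands: %s", band,
                          paste(tab$band, collapse = ", ")),
                  "lookup_error")
  tab$sets[[i]]
}

#' Per-channel band energy of a decomposition
#'
#' Energy of a named band: the sum of squared wavelet coefficients over the
#' band's coefficient set(s). Composite bands (Delta) sum their constituent
#' sets. By orthogonality this equals the energy of the corresponding
#' band-limited component of the signal.
#'
#' @param dec a [dwt_tree()] result.
#' @param band a band name from [band_table()].
#' @return numeric vector, one energy per channel (microvolts^2 x samples).
#' @export
band_energy <- function(dec, band) {
  sets <- band_sets(band)
  e <- 0
  for (s in sets) e <- e + rowSums(dec$sets[[s]]^2)
  e
}

#' Band-energy feature matrix for a set of epochs
#'
#' Decomposes every epoch of every channel and assembles the classifier
#' input: one row per epoch, one column per channel, each value the chosen
#' band's energy in that channel. Labels and provenance are carried through.
#'
#' @param epochs an `epoch_set` (see [segment_epochs()]).
#' @param band a band name from [band_table()] (default `"Beta"`, the most
#'   discriminative band for rhythmic seizure activity).
#' @return An object of class `feature_matrix`: list with `band`, `energy`
#'   (n_epochs x n_channels), `channel_names`, `labels`, `origin`.
#' @export
extract_features <- function(epochs, band = "Beta") {
  band_sets(band)  # fail fast on unknown band
  n_ep <- dim(epochs$epochs)[1L]
  n_ch <- dim(epochs$epochs)[2L]
  energy <- matrix(0, n_ep, n_ch, dimnames = list(NULL, epochs$channel_names))
  for (e in seq_len(n_ep)) {
    dec <- dwt_tree(epochs$epochs[e, , , drop = TRUE], fs = epochs$fs)
    energy[e, ] <- band_energy(dec, band)
  }
  structure(list(band = band, energy = energy,
                 channel_names = epochs$channel_names,
                 labels = epochs$labels, origin = epochs$origin),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature matrix: %d epochs x %d channels, band %s (%d ictal)\n",
              nrow(x$energy), ncol(x$energy), x$band,
              sum(x$labels == "ictal")))
  invisible(x)
}

#' Write / read a feature matrix as CSV
#'
#' Columns are channel energies plus `label`, `recording_id`,
#' `start_sample`; the band name travels in a `# band:` comment line.
#'
#' @param fm a `feature_matrix`.
#' @param path CSV path.
#' @return `path` (write) or a `feature_matrix` (read).
#' @export
write_features <- function(fm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# band: %s", fm$band), con)
  tab <- as.data.frame(fm$energy)
  tab$label <- fm$labels
  tab$recording_id <- fm$origin$recording_id
  tab$start_sample <- fm$origin$start_sample
  utils::write.csv(tab, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  first <- readLines(path, n = 1L)
  band <- sub("^# band:\\s*", "", first)
  tab <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  meta <- c("label", "recording_id", "start_sample")
  chans <- setdiff(names(tab), meta)
  structure(list(band = band,
                 energy = as.matrix(tab[, chans, drop = FALSE]),
                 channel_names = chans, labels = tab$label,
                 origin = data.frame(recording_id = tab$recording_id,
                                     start_sample = tab$start_sample,
                                     stringsAsFactors = FALSE)),
            class = "feature_matrix")
}
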