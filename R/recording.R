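#' Construct a multichannel EEG recording
#'
#' The central container for one EEG record: a channels-by-samples matrix in
#' microvolts, its sampling rate, bipolar channel names, optional labeled
#' ictal/interictal intervals, and the optional expert focus side.
#'
#' Annotation intervals are half-open `[start, end)` in 0-based sample
#' coordinates. Same-label intervals must not overlap.
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param fs sampling rate in Hz (positive).
#' @param channel_names character vector, one unique name per row of `data`.
#' @param subject_id,recording_id identifier strings.
#' @param annotations `NULL` or data.frame with columns `start`, `end`
#'   (0-based samples, half-open) and `label` (`"ictal"`/`"interictal"`).
#' @param true_laterality `"left"`, `"right"` or `"unknown"`.
#' @return An object of class `eeg_recording`.
#' @export
recording <- function(data, fs, channel_names,
                      subject_id = "S", recording_id = "R",
                      annotations = NULL,
                      true_laterality = c("unknown", "left", "right")) {
  true_laterality <- match.arg(true_laterality)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  dimnames(data) <- NULL
  rec <- structure(
    list(subject_id = subject_id, recording_id = recording_id,
         fs = fs, channel_names = as.character(channel_names),
         data = data,
         annotations = annotations %||% empty_annotations(),
         true_laterality = true_laterality),
    class = "eeg_recording")
  validate_recording(rec)
}

empty_annotations <- function() {
  data.frame(start = integer(0), end = integer(0), label = character(0),
             stringsAsFactors = FALSE)
}

validate_recording <- function(rec) {
  if (!is.numeric(rec$fs) || length(rec$fs) != 1L || rec$fs <= 0)
    stop_eegfocus("fs must be a positive scalar", "validation_error")
  if (nrow(rec$data) != length(rec$channel_names))
    stop_eegfocus("channel_names length must match data rows", "validation_error")
  if (anyDuplicated(normalize_channel_name(rec$channel_names)))
    stop_eegfocus("channel names must be unique", "validation_error")
  validate_annotations(rec$annotations, ncol(rec$data))
  invisible(rec)
}

validate_annotations <- function(ann, n_samples) {
  if (!all(c("start", "end", "label") %in% names(ann)))
    stop_eegfocus("annotations need columns start, end, label", "validation_error")
  if (nrow(ann) == 0L) return(invisible(ann))
  if (!all(ann$label %in% c("ictal", "interictal")))
    stop_eegfocus(sprintf("unknown annotation label(s): %s",
                          paste(setdiff(ann$label, c("ictal", "interictal")),
                                collapse = ", ")),
                  "validation_error")
  if (any(ann$end <= ann$start))
    stop_eegfocus("annotation intervals must satisfy end > start",
                  "validation_error")
  if (any(ann$start < 0) || any(ann$end > n_samples))
    stop_eegfocus("annotation intervals must lie within [0, n_samples)",
                  "validation_error")
  for (lab in unique(ann$label)) {
    a <- ann[ann$label == lab, , drop = FALSE]
    a <- a[order(a$start), , drop = FALSE]
    if (nrow(a) > 1L && any(a$start[-1L] < a$end[-nrow(a)]))
      stop_eegfocus(sprintf("overlapping '%s' annotation intervals", lab),
                    "validation_error")
  }
  invisible(ann)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording %s/%s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$recording_id, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  if (nrow(x$annotations))
    cat(sprintf("  %d annotation(s): %s\n", nrow(x$annotations),
                paste(table(x$annotations$label), names(table(x$annotations$label)),
                      collapse = ", ")))
  cat("  true laterality:", x$true_laterality, "\n")
  invisible(x)
}

#' Read an EEG recording from disk
#'
#' Two on-disk layouts are supported. `format = "matrix"` is a plain-text
#' layout: a CSV whose header row holds channel names and whose columns hold
#' samples, with a `<path>.meta` sidecar of `key: value` lines (`fs`,
#' `subject_id`, `recording_id`, `true_laterality`) and an optional
#' `<path>.annotations.csv` (see [read_annotations()]). `format = "edf"`
#' reads a 16-bit EDF file.
#'
#' Channels are matched against [montage_spec()] case-insensitively and
#' tolerating "-"/"_" separators, re-ordered to montage order; unknown extra
#' channels are dropped with a warning. Recordings holding only the 16
#' lateral channels are accepted and returned in canonical analysis order.
#'
#' @param path file path.
#' @param format `"matrix"` or `"edf"`.
#' @param montage a [montage_spec()].
#' @return An `eeg_recording`.
#' @seealso [write_recording()], [select_analysis_channels()]
#' @export
read_recording <- function(path, format = c("matrix", "edf"),
                           montage = montage_spec()) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop_eegfocus(sprintf("cannot read '%s': no such file", path), "io_error")
  raw <- switch(format,
    matrix = read_recording_matrix(path),
    edf    = read_recording_edf(path))
  conform_to_montage(raw, montage)
}

# Re-order channels to montage order, dropping unknown extras.
# Accepts either the full 18-channel set or the 16 lateral channels.
conform_to_montage <- function(rec, montage) {
  have <- normalize_channel_name(rec$channel_names)
  target <- if (all(normalize_channel_name(montage$full_channels) %in% have))
    montage$full_channels else montage$analysis_channels
  idx <- match_channels(target, rec$channel_names)
  extra <- setdiff(seq_along(rec$channel_names), idx)
  if (length(extra))
    warning(sprintf("dropping %d channel(s) not in the montage: %s",
                    length(extra),
                    paste(rec$channel_names[extra], collapse = ", ")))
  rec$data <- rec$data[idx, , drop = FALSE]
  rec$channel_names <- target
  validate_recording(rec)
  rec
}

read_recording_matrix <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  meta_path <- paste0(path, ".meta")
  if (!file.exists(meta_path))
    stop_eegfocus(sprintf("missing metadata sidecar '%s'", meta_path), "io_error")
  meta <- read_keyvalue(meta_path)
  fs <- as.numeric(meta[["fs"]] %||% NA)
  if (!is.finite(fs))
    stop_eegfocus("metadata sidecar must define a numeric 'fs'", "io_error")
  rec <- recording(
    data = t(as.matrix(tab)), fs = fs,
    channel_names = colnames(tab),
    subject_id = meta[["subject_id"]] %||% "S",
    recording_id = meta[["recording_id"]] %||% "R",
    true_laterality = meta[["true_laterality"]] %||% "unknown")
  ann_path <- paste0(path, ".annotations.csv")
  if (file.exists(ann_path))
    rec <- set_annotations(rec, read_annotations(ann_path, fs))
  rec
}

read_keyvalue <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, ":", fixed = TRUE)
  vals <- lapply(kv, function(p) trimws(paste(p[-1L], collapse = ":")))
  names(vals) <- vapply(kv, function(p) trimws(p[[1L]]), "")
  vals
}

#' Write an EEG recording to disk
#'
#' Inverse of [read_recording()]. The matrix format writes the sample CSV,
#' the `.meta` sidecar, and (when annotations are present) the
#' `.annotations.csv` sidecar in seconds.
#'
#' @param rec an `eeg_recording`.
#' @param path output file path.
#' @param format `"matrix"` or `"edf"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("matrix", "edf")) {
  format <- match.arg(format)
  if (format == "edf") return(write_recording_edf(rec, path))
  # %.17g keeps doubles bit-exact through the text round-trip
  txt <- matrix(sprintf("%.17g", t(rec$data)), ncol = nrow(rec$data))
  tab <- as.data.frame(txt, stringsAsFactors = FALSE)
  colnames(tab) <- rec$channel_names
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  writeLines(c(
    sprintf("fs: %.10g", rec$fs),
    sprintf("subject_id: %s", rec$subject_id),
    sprintf("recording_id: %s", rec$recording_id),
    sprintf("true_laterality: %s", rec$true_laterality)
  ), paste0(path, ".meta"))
  if (nrow(rec$annotations))
    write_annotations(rec$annotations, paste0(path, ".annotations.csv"), rec$fs)
  invisible(path)
}

#' Read labeled ictal/interictal intervals
#'
#' Reads a CSV with columns `start_s`, `end_s`, `label` (times in seconds)
#' and converts to 0-based half-open sample intervals: `floor(start_s * fs)`
#' to `ceiling(end_s * fs)`.
#'
#' @param path annotation CSV path.
#' @param fs sampling rate in Hz used for the conversion.
#' @return data.frame with columns `start`, `end` (samples), `label`.
#' @export
read_annotations <- function(path, fs) {
  if (!file.exists(path))
    stop_eegfocus(sprintf("cannot read '%s': no such file", path), "io_error")
  tab <- utils::read.csv(path)
  if (nrow(tab) == 0L) return(empty_annotations())
  if (!all(c("start_s", "end_s", "label") %in% names(tab)))
    stop_eegfocus("annotation file needs columns start_s, end_s, label",
                  "validation_error")
  ann <- data.frame(start = as.integer(floor(tab$start_s * fs)),
                    end = as.integer(ceiling(tab$end_s * fs)),
                    label = as.character(tab$label),
                    stringsAsFactors = FALSE)
  if (any(ann$end <= ann$start))
    stop_eegfocus("annotation intervals must satisfy end_s > start_s",
                  "validation_error")
  if (!all(ann$label %in% c("ictal", "interictal")))
    stop_eegfocus("annotation labels must be 'ictal' or 'interictal'",
                  "validation_error")
  ann
}

write_annotations <- function(ann, path, fs) {
  utils::write.csv(
    data.frame(start_s = ann$start / fs, end_s = ann$end / fs,
               label = ann$label),
    path, row.names = FALSE)
  invisible(path)
}

# Attach annotations to a recording, validating against its length.
set_annotations <- function(rec, ann) {
  rec$annotations <- ann
  validate_recording(rec)
  rec
}

#' Restrict a recording to the 16 lateral analysis channels
#'
#' Drops the midline derivations and re-orders the remaining channels to the
#' canonical pair-major order (left members of pairs 1..8, then right
#' members), so that channels `i` and `i + 8` form a symmetric pair.
#' Idempotent.
#'
#' @param rec an `eeg_recording` containing all 16 analysis channels.
#' @param montage a [montage_spec()].
#' @return The restricted `eeg_recording`.
#' @export
select_analysis_channels <- function(rec, montage = montage_spec()) {
  idx <- match_channels(montage$analysis_channels, rec$channel_names)
  rec$data <- rec$data[idx, , drop = FALSE]
  rec$channel_names <- montage$analysis_channels
  rec
}
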