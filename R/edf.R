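# Minimal EDF (European Data Format) support: continuous 16-bit records,
# one sampling rate shared by all signals. Covers what a scalp-EEG pipeline
# needs; EDF+ event/annotation channels are out of scope (interval labels
# travel in the annotation CSV instead).

edf_field <- function(con, width) {
  trimws(rawToChar(readBin(con, "raw", n = width)))
}

read_recording_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- edf_field(con, 8)
  if (version != "0")
    stop_eegfocus(sprintf("'%s' is not an EDF file (version field '%s')",
                          path, version), "io_error")
  patient_id <- edf_field(con, 80)
  recording_id <- edf_field(con, 80)
  edf_field(con, 8); edf_field(con, 8)      # start date, time: unused
  edf_field(con, 8)                         # header byte count
  edf_field(con, 44)                        # reserved
  n_records <- as.integer(edf_field(con, 8))
  record_dur <- as.numeric(edf_field(con, 8))
  ns <- as.integer(edf_field(con, 4))
  if (!is.finite(ns) || ns < 1L)
    stop_eegfocus("EDF header declares no signals", "io_error")

  labels   <- vapply(seq_len(ns), function(i) edf_field(con, 16), "")
  for (i in seq_len(ns)) edf_field(con, 80)                 # transducer
  for (i in seq_len(ns)) edf_field(con, 8)                  # phys dimension
  pmin <- vapply(seq_len(ns), function(i) as.numeric(edf_field(con, 8)), 0)
  pmax <- vapply(seq_len(ns), function(i) as.numeric(edf_field(con, 8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(edf_field(con, 8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(edf_field(con, 8)), 0)
  for (i in seq_len(ns)) edf_field(con, 80)                 # prefiltering
  spr  <- vapply(seq_len(ns), function(i) as.integer(edf_field(con, 8)), 0L)
  for (i in seq_len(ns)) edf_field(con, 32)                 # reserved

  if (length(unique(spr)) != 1L)
    stop_eegfocus("EDF with per-signal sampling rates is not supported",
                  "io_error")
  fs <- spr[1L] / record_dur
  gain <- (pmax - pmin) / (dmax - dmin)

  data <- matrix(0, nrow = ns, ncol = n_records * spr[1L])
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[s], size = 2,
                     signed = TRUE, endian = "little")
      cols <- ((r - 1L) * spr[s] + 1L):(r * spr[s])
      data[s, cols] <- pmin[s] + (dig - dmin[s]) * gain[s]
    }
  }
  recording(data, fs = fs, channel_names = labels,
            subject_id = if (nzchar(patient_id)) patient_id else "S",
            recording_id = if (nzchar(recording_id)) recording_id else "R")
}

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

write_recording_edf <- function(rec, path) {
  ns <- nrow(rec$data)
  n <- ncol(rec$data)
  # single data record spanning the whole recording keeps every sample
  record_dur <- n / rec$fs
  pmin <- apply(rec$data, 1, min); pmax <- apply(rec$data, 1, max)
  flat <- pmax - pmin < .Machine$double.eps
  pmin[flat] <- pmin[flat] - 1; pmax[flat] <- pmax[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256L + 256L * ns
  put <- function(x, w) writeBin(charToRaw(edf_pad(x, w)), con)
  put("0", 8)
  put(rec$subject_id, 80); put(rec$recording_id, 80)
  put("01.01.00", 8); put("00.00.00", 8)
  put(hdr_bytes, 8); put("", 44)
  put(1L, 8)
  put(format(record_dur, digits = 7), 8)
  put(ns, 4)
  for (l in rec$channel_names) put(l, 16)
  for (i in seq_len(ns)) put("", 80)
  for (i in seq_len(ns)) put("uV", 8)
  for (p in pmin) put(format(p, digits = 7), 8)
  for (p in pmax) put(format(p, digits = 7), 8)
  for (i in seq_len(ns)) put(dmin, 8)
  for (i in seq_len(ns)) put(dmax, 8)
  for (i in seq_len(ns)) put("", 80)
  for (i in seq_len(ns)) put(n, 8)
  for (i in seq_len(ns)) put("", 32)
  for (s in seq_len(ns)) {
    dig <- round(dmin + (rec$data[s, ] - pmin[s]) * (dmax - dmin) /
                   (pmax[s] - pmin[s]))
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}
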