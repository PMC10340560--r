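`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize a bipolar channel label
#'
#' EDF label conventions vary; "Fp1-F7", "FP1_F7" and " fp1-f7 " all denote
#' the same derivation. Normalization upper-cases, trims, and maps "_" to "-".
#'
#' @param x character vector of channel labels.
#' @return normalized labels (upper case, "-" separator).
#' @export
normalize_channel_name <- function(x) {
  x <- toupper(trimws(as.character(x)))
  gsub("_", "-", x, fixed = TRUE)
}

# 32-bit FNV-1a over a character string; returns hex digest.
# Used for config fingerprinting in run reports (stdlib-only, deterministic).
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(enc2utf8(paste(s, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte (b < 256); keep h in doubles throughout
    h <- h - (h %% 256) + bitwXor(h %% 256, b %% 256)
    # h * 16777619 mod 2^32 without 32-bit overflow: split h into 16-bit halves
    lo <- h %% 65536; hi <- (h - lo) / 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  lo <- as.integer(h %% 65536)
  sprintf("%04x%04x", as.integer((h - lo) / 65536), lo)
}

# Deterministic sub-seed derivation: mixes a master seed with integer tags
# (e.g. patient index, recording index) into a seed in [0, 2^31 - 1].
derive_seed <- function(master, ...) {
  tags <- c(master, ...)
  h <- 0
  for (t in tags) {
    h <- (h * 1000003 + (as.numeric(t) %% 2147483647)) %% 2147483647
    h <- (h * 69069 + 1234567) %% 2147483647
  }
  as.integer(h)
}

stop_eegfocus <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "eegfocus_error")))
}
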