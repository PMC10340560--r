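#' The bipolar 10-20 montage used throughout the package
#'
#' Defines the 18 bipolar derivations of the standard longitudinal
#' ("double banana") 10-20 montage, the 8 symmetric left/right channel
#' pairs used for lateralization, and the canonical 16-channel analysis
#' order. The two midline derivations (FZ-CZ, CZ-PZ) have no contralateral
#' partner and are excluded from the analysis set.
#'
#' The canonical analysis order is pair-major: the left member of pair 1
#' through pair 8, then the right members in the same pair order, so that
#' channel `i` and channel `i + 8` always form a symmetric pair.
#'
#' @return An object of class `montage_spec`: a list with elements
#'   `full_channels` (18 names), `analysis_channels` (16 names, pair-major),
#'   and `pairs` (data.frame with columns `left`, `right`, 8 rows).
#' @examples
#' m <- montage_spec()
#' m$pairs
#' @export
montage_spec <- function() {
  pairs <- data.frame(
    left  = c("FP1-F7", "F7-T3", "T3-T5", "T5-O1",
              "FP1-F3", "F3-C3", "C3-P3", "P3-O1"),
    right = c("FP2-F8", "F8-T4", "T4-T6", "T6-O2",
              "FP2-F4", "F4-C4", "C4-P4", "P4-O2"),
    stringsAsFactors = FALSE
  )
  full <- c("FP1-F7", "F7-T3", "T3-T5", "T5-O1",
            "FP2-F8", "F8-T4", "T4-T6", "T6-O2",
            "FP1-F3", "F3-C3", "C3-P3", "P3-O1",
            "FP2-F4", "F4-C4", "C4-P4", "P4-O2",
            "FZ-CZ", "CZ-PZ")
  spec <- list(
    full_channels = full,
    analysis_channels = c(pairs$left, pairs$right),
    pairs = pairs
  )
  class(spec) <- "montage_spec"
  validate_montage_spec(spec)
  spec
}

validate_montage_spec <- function(spec) {
  stopifnot(nrow(spec$pairs) == 8L)
  flat <- c(spec$pairs$left, spec$pairs$right)
  if (anyDuplicated(flat))
    stop_eegfocus("symmetric pair members must be unique", "montage_error")
  if (!identical(spec$analysis_channels, flat))
    stop_eegfocus("analysis_channels must equal the flattened pair list",
                  "montage_error")
  if (!all(flat %in% spec$full_channels))
    stop_eegfocus("all pair members must be full-montage channels",
                  "montage_error")
  invisible(spec)
}

#' @export
print.montage_spec <- function(x, ...) {
  cat("Bipolar 10-20 montage:", length(x$full_channels), "channels,",
      nrow(x$pairs), "symmetric pairs,",
      length(x$analysis_channels), "analysis channels\n")
  invisible(x)
}

# Resolve the indices of `wanted` channels within `available` labels,
# tolerant to case and "-"/"_" separators. Missing channels -> montage_error.
match_channels <- function(wanted, available, context = "recording") {
  idx <- match(normalize_channel_name(wanted), normalize_channel_name(available))
  if (anyNA(idx)) {
    missing <- wanted[is.na(idx)]
    stop_eegfocus(
      sprintf("%s is missing required channel(s): %s",
              context, paste(missing, collapse = ", ")),
      "montage_error")
  }
  idx
}
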