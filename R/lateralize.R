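# Focus lateralization from hemispheric energy asymmetry.
#
# Seizure activity raises signal energy on the focus side, so for each of
# the eight symmetric bipolar channel pairs the ratio of left to right
# energy over the detected ictal samples carries a left/right vote; votes
# are summed per recording and recordings are majority-voted per patient.

#' Energy asymmetry score of a symmetric channel pair
#'
#' `A = sum(xleft^2) / sum(xright^2)`: the ratio of left-channel to
#' right-channel energy over the same ictal samples. `A > 1` indicates a
#' left-side energy excess. Scale-invariant under common gain and maps to
#' `1/A` when the sides are swapped.
#'
#' @param xleft,xright numeric vectors of equal length (microvolts).
#' @return The positive scalar score.
#' @export
asymmetry_score <- function(xleft, xright) {
  if (length(xleft) != length(xright))
    stop_eegfocus("pair segments must have equal length", "validation_error")
  er <- sum(xright^2)
  if (er == 0)
    stop_eegfocus("zero right-channel energy: degenerate pair",
                  "degenerate_input_error")
  sum(xleft^2) / er
}

#' Left/right vote of one channel pair
#'
#' `+1` when the asymmetry score exceeds 1 (left-side excess), `-1`
#' otherwise. The boundary `A = 1` falls to `-1`, consistent with the
#' right-sided "else" branch of the recording rule.
#'
#' @param A positive asymmetry score.
#' @return `+1` or `-1`.
#' @export
pair_vote <- function(A) {
  if (A <= 0) stop_eegfocus("asymmetry score must be positive",
                            "validation_error")
  if (A > 1) 1L else -1L
}

#' Lateralize one recording from its ictal epochs
#'
#' For each of the eight symmetric pairs, per-channel energies are pooled
#' (summed) over all ictal epochs, the asymmetry score of the pooled
#' energies is computed, and the pair votes +1 (left) or -1 (right). The
#' recording is called left when the vote sum is strictly positive, right
#' otherwise. A degenerate pair (zero right-side energy) is excluded from
#' the sum rather than allowed to dominate.
#'
#' An alternative `pooling = "per_epoch"` mode votes each pair within every
#' ictal epoch and averages the votes before thresholding at 0.
#'
#' @param epochs an `epoch_set` over the 16 analysis channels in canonical
#'   pair-major order (channel `i` pairs with channel `i + 8`).
#' @param montage a [montage_spec()].
#' @param labels per-epoch labels to use as the ictal mask; defaults to the
#'   epoch set's own (gold) labels, but detected labels from
#'   [predict_epochs()] can be passed instead.
#' @param pooling `"pooled"` (default) or `"per_epoch"`.
#' @return An object of class `laterality_decision`: list with `pairs`
#'   (data.frame: left, right, asymmetry, vote), `vote_sum`, `side`,
#'   `n_ictal_epochs`, `recording_id`.
#' @export
recording_laterality <- function(epochs, montage = montage_spec(),
                                 labels = epochs$labels,
                                 pooling = c("pooled", "per_epoch")) {
  pooling <- match.arg(pooling)
  if (length(labels) != dim(epochs$epochs)[1L])
    stop_eegfocus("labels length must match epoch count", "validation_error")
  ict <- which(labels == "ictal")
  if (!length(ict))
    stop_eegfocus("no ictal epochs: cannot lateralize this recording",
                  "lateralization_error")
  li <- match_channels(montage$pairs$left, epochs$channel_names, "epoch set")
  ri <- match_channels(montage$pairs$right, epochs$channel_names, "epoch set")

  # per-epoch, per-channel energies of the ictal epochs
  eL <- sapply(seq_len(8L), function(p)
    vapply(ict, function(e) sum(epochs$epochs[e, li[p], ]^2), 0))
  eR <- sapply(seq_len(8L), function(p)
    vapply(ict, function(e) sum(epochs$epochs[e, ri[p], ]^2), 0))
  eL <- matrix(eL, nrow = length(ict)); eR <- matrix(eR, nrow = length(ict))

  if (pooling == "pooled") {
    sL <- colSums(eL); sR <- colSums(eR)
    A <- ifelse(sR > 0, sL / sR, NA_real_)
    vote <- ifelse(is.na(A), NA_integer_, ifelse(A > 1, 1L, -1L))
  } else {
    v <- ifelse(eR > 0, ifelse(eL / eR > 1, 1, -1), NA)
    mv <- colMeans(v, na.rm = TRUE)
    A <- ifelse(colSums(eR) > 0, colSums(eL) / colSums(eR), NA_real_)
    vote <- ifelse(is.nan(mv), NA_integer_, ifelse(mv > 0, 1L, -1L))
  }
  if (anyNA(vote))
    warning(sprintf("excluding %d degenerate pair(s) with zero right-side energy",
                    sum(is.na(vote))))
  vote_sum <- sum(vote, na.rm = TRUE)
  structure(list(
    pairs = data.frame(left = montage$pairs$left, right = montage$pairs$right,
                       asymmetry = A, vote = vote, stringsAsFactors = FALSE),
    vote_sum = vote_sum,
    side = if (vote_sum > 0) "left" else "right",
    n_ictal_epochs = length(ict),
    recording_id = epochs$origin$recording_id[1L] %||% "R"),
    class = "laterality_decision")
}

#' @export
print.laterality_decision <- function(x, ...) {
  cat(sprintf("recording %s: side %s (vote sum %+d over %d pairs, %d ictal epochs)\n",
              x$recording_id, x$side, x$vote_sum,
              sum(!is.na(x$pairs$vote)), x$n_ictal_epochs))
  invisible(x)
}

#' Patient-level lateralization by majority over recordings
#'
#' The patient is called left when strictly more recordings are left than
#' right; ties and right-majorities are called right ("otherwise" branch).
#'
#' @param decisions list of `laterality_decision` objects (or a character
#'   vector of sides).
#' @return An object of class `patient_decision`: list with
#'   `recording_sides`, `n_left`, `n_right`, `side`.
#' @export
patient_laterality <- function(decisions) {
  if (!length(decisions))
    stop_eegfocus("no recording decisions supplied", "lateralization_error")
  sides <- if (is.character(decisions)) decisions
           else vapply(decisions, function(d) d$side, "")
  if (!all(sides %in% c("left", "right")))
    stop_eegfocus("recording sides must be 'left' or 'right'",
                  "validation_error")
  n_left <- sum(sides == "left"); n_right <- sum(sides == "right")
  structure(list(recording_sides = sides, n_left = n_left,
                 n_right = n_right,
                 side = if (n_left > n_right) "left" else "right"),
            class = "patient_decision")
}

#' @export
print.patient_decision <- function(x, ...) {
  cat(sprintf("patient side: %s (%d left vs %d right recordings)\n",
              x$side, x$n_left, x$n_right))
  invisible(x)
}

#' Evaluate lateralization predictions
#'
#' [evaluate()] with `left` as the positive class, the convention under
#' which sensitivity is the left-focus detection rate.
#'
#' @param pred,gold character vectors of sides (`"left"`/`"right"`).
#' @return A `metrics_report`.
#' @export
evaluate_lateralization <- function(pred, gold) {
  if (!all(gold %in% c("left", "right")))
    stop_eegfocus("gold sides must be 'left' or 'right'", "validation_error")
  evaluate(pred, gold, positive = "left")
}
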