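#' Split specification for train/validation/test partitions
#'
#' Label-stratified random partition at fixed fractions. The default
#' 0.70/0.15/0.15 reflects epoch counts of roughly 70/15/15 used when
#' tuning on a held-out validation set and reporting on a disjoint test set.
#'
#' @param train,validation,test fractions summing to 1.
#' @param seed integer RNG seed for the shuffle.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(train = 0.70, validation = 0.15, test = 0.15,
                       seed = 1L) {
  if (abs(train + validation + test - 1) > 1e-9)
    stop_eegfocus("split fractions must sum to 1", "config_error")
  structure(list(train = train, validation = validation, test = test,
                 seed = as.integer(seed)),
            class = "split_spec")
}

subset_features <- function(fm, idx) {
  structure(list(band = fm$band,
                 energy = fm$energy[idx, , drop = FALSE],
                 channel_names = fm$channel_names,
                 labels = fm$labels[idx],
                 origin = fm$origin[idx, , drop = FALSE]),
            class = "feature_matrix")
}

#' Stratified train/validation/test split
#'
#' Shuffles epochs within each class (seeded) and allocates them to the
#' three partitions at the spec fractions. Partitions are disjoint; class
#' balancing, if any, is applied afterwards to the training partition only
#' so that duplicated seizure epochs can never leak into validation or
#' test.
#'
#' @param fm a `feature_matrix`.
#' @param spec a [split_spec()].
#' @return list with elements `train`, `validation`, `test`
#'   (feature matrices).
#' @export
split_dataset <- function(fm, spec = split_spec()) {
  n <- nrow(fm$energy)
  classes <- unique(fm$labels)
  counts <- table(fm$labels)
  if (n < 3L || any(counts < 3L))
    stop_eegfocus("need at least 3 epochs per class to split", "split_error")
  old <- get0(".Random.seed", envir = .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))
  set.seed(spec$seed)
  take <- list(train = integer(0), validation = integer(0), test = integer(0))
  for (cl in classes) {
    idx <- sample(which(fm$labels == cl))
    k <- length(idx)
    n_tr <- round(spec$train * k)
    n_va <- round(spec$validation * k)
    n_va <- min(n_va, k - n_tr)
    take$train <- c(take$train, idx[seq_len(n_tr)])
    take$validation <- c(take$validation, idx[n_tr + seq_len(n_va)])
    take$test <- c(take$test, idx[setdiff(seq_len(k), seq_len(n_tr + n_va))])
  }
  lapply(take, function(i) subset_features(fm, sort(i)))
}

#' Balance classes by duplicating seizure epochs
#'
#' Whole-row duplication of the minority ictal class: each ictal epoch is
#' repeated `k = max(1, round(n_interictal / n_ictal))` times, bringing the
#' interictal:ictal ratio into [1/2, 2]. Interictal rows and all feature
#' values are untouched. Intended for the training partition only.
#'
#' @param fm a `feature_matrix` containing both classes.
#' @return The balanced `feature_matrix`.
#' @export
balance_by_duplication <- function(fm) {
  n_ict <- sum(fm$labels == "ictal")
  n_int <- sum(fm$labels == "interictal")
  if (n_ict == 0L || n_int == 0L)
    stop_eegfocus("both classes must be present to balance", "balancing_error")
  k <- max(1L, as.integer(round(n_int / n_ict)))
  if (k == 1L) return(fm)
  idx <- c(which(fm$labels == "interictal"),
           rep(which(fm$labels == "ictal"), times = k))
  subset_features(fm, idx)
}

#' Confusion-matrix metrics for a binary classification
#'
#' Computes the confusion counts and the accuracy / sensitivity /
#' specificity trio, with a configurable positive class (`"ictal"` for
#' epoch classification, `"left"` for lateralization).
#'
#' @param pred,gold character vectors of equal length.
#' @param positive the positive-class label.
#' @return An object of class `metrics_report`: list with `TP`, `FP`, `TN`,
#'   `FN`, `accuracy`, `sensitivity`, `specificity`, `positive`.
#' @export
evaluate <- function(pred, gold, positive = "ictal") {
  if (length(pred) != length(gold))
    stop_eegfocus("pred and gold must have equal length", "validation_error")
  tp <- sum(pred == positive & gold == positive)
  fp <- sum(pred == positive & gold != positive)
  tn <- sum(pred != positive & gold != positive)
  fn <- sum(pred != positive & gold == positive)
  structure(list(
    TP = tp, FP = fp, TN = tn, FN = fn,
    accuracy = (tp + tn) / length(gold),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    positive = positive),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "accuracy %.4f | sensitivity %.4f | specificity %.4f (positive = %s; TP %d FP %d TN %d FN %d)\n",
    x$accuracy, x$sensitivity, x$specificity, x$positive,
    x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}
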