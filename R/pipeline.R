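# End-to-end orchestration: preprocess -> subband energy features ->
# LSTM epoch classification -> asymmetry-score lateralization, plus the
# band-sweep experiment harness.

#' Pipeline configuration
#'
#' Bundles the stage configurations, the analysis band, the channel mode,
#' lateralization options and the master seed. All randomness in a run
#' (cohort generation, splitting, network initialization, batch shuffling)
#' is derived deterministically from `seed`.
#'
#' @param preprocess a [preprocess_config()].
#' @param lstm an [lstm_config()].
#' @param split a [split_spec()].
#' @param band analysis band from [band_table()] (default `"Beta"`).
#' @param channels 16 (lateral analysis channels) or 18 (full montage).
#' @param ictal_source `"gold"` to lateralize from expert-annotated ictal
#'   epochs, `"predicted"` to use the classifier's detections.
#' @param pooling lateralization pooling mode (see
#'   [recording_laterality()]).
#' @param synth `NULL`, or a list with `n_patients`,
#'   `recordings_per_patient`, optional `config` ([synth_config()]) and
#'   `left_fraction`, describing a synthetic cohort to generate.
#' @param input_dir `NULL`, or a directory of matrix-format recordings
#'   (`*.csv` with `.meta` / `.annotations.csv` sidecars).
#' @param seed master seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(preprocess = preprocess_config(),
                            lstm = lstm_config(),
                            split = split_spec(),
                            band = "Beta",
                            channels = 16,
                            ictal_source = c("gold", "predicted"),
                            pooling = c("pooled", "per_epoch"),
                            synth = NULL,
                            input_dir = NULL,
                            seed = 1L) {
  band_sets(band)  # validate before any compute
  if (!channels %in% c(16, 18))
    stop_eegfocus("channels must be 16 or 18", "config_error")
  cfg <- list(preprocess = preprocess, lstm = lstm, split = split,
              band = band, channels = channels,
              ictal_source = match.arg(ictal_source),
              pooling = match.arg(pooling),
              synth = synth, input_dir = input_dir,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Nested keys `preprocess`, `lstm`, `split` map onto the corresponding
#' constructor arguments; scalar keys map onto [pipeline_config()]
#' arguments.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$preprocess)) args$preprocess <- do.call(preprocess_config, y$preprocess)
  if (!is.null(y$lstm)) args$lstm <- do.call(lstm_config, y$lstm)
  if (!is.null(y$split)) args$split <- do.call(split_spec, y$split)
  if (!is.null(y$synth)) {
    s <- y$synth
    if (!is.null(s$config)) s$config <- do.call(synth_config, s$config)
    args$synth <- s
  }
  for (k in c("band", "channels", "ictal_source", "pooling", "input_dir", "seed"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  do.call(pipeline_config, args)
}

#' Fingerprint of a pipeline configuration
#'
#' Deterministic 32-bit digest of the full (nested) configuration; any
#' field change changes the hash.
#'
#' @param cfg a `pipeline_config`.
#' @return 8-character hex string.
#' @export
config_hash <- function(cfg) {
  fnv1a32(as.character(jsonlite::toJSON(unclass_deep(cfg), digits = NA,
                                        auto_unbox = TRUE, null = "null")))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

load_cohort <- function(cfg) {
  if (!is.null(cfg$synth)) {
    s <- cfg$synth
    return(generate_cohort(
      n_patients = s$n_patients,
      recordings_per_patient = s$recordings_per_patient,
      config = s$config %||% synth_config(),
      left_fraction = s$left_fraction %||% (28 / 76),
      seed = derive_seed(cfg$seed, 101L)))
  }
  if (!is.null(cfg$input_dir)) {
    paths <- list.files(cfg$input_dir, pattern = "\\.csv$", full.names = TRUE)
    paths <- paths[!grepl("\\.annotations\\.csv$", paths)]
    if (!length(paths))
      stop_eegfocus(sprintf("no recordings found under '%s'", cfg$input_dir),
                    "io_error")
    return(lapply(sort(paths), read_recording, format = "matrix"))
  }
  stop_eegfocus("pipeline_config needs either 'synth' or 'input_dir'",
                "config_error")
}

#' Run the full detection + lateralization pipeline
#'
#' Executes every stage in order on a cohort of recordings: filtering,
#' resampling, channel selection, epoch segmentation, band-energy feature
#' extraction, stratified splitting, train-only class balancing, LSTM
#' training, epoch classification on the held-out test split, and per-
#' recording / per-patient lateralization (against expert or detected
#' ictal epochs). Returns a run report with both metric sets, every
#' recording decision, the seeds used, and the configuration hash.
#'
#' @param cfg a [pipeline_config()].
#' @param recordings optional list of `eeg_recording` to use instead of
#'   `cfg$synth` / `cfg$input_dir`.
#' @return An object of class `pipeline_report` (a nested list; see
#'   [write_report()]).
#' @export
run_pipeline <- function(cfg, recordings = NULL) {
  recordings <- recordings %||% load_cohort(cfg)
  montage <- montage_spec()

  epoch_sets <- lapply(recordings, preprocess_recording,
                       cfg = cfg$preprocess, channels = cfg$channels,
                       montage = montage)
  all_epochs <- bind_epoch_sets(epoch_sets)
  features <- extract_features(all_epochs, band = cfg$band)

  split_cfg <- cfg$split
  split_cfg$seed <- derive_seed(cfg$seed, 102L)
  splits <- split_dataset(features, split_cfg)
  train <- balance_by_duplication(splits$train)

  lstm_cfg <- cfg$lstm
  lstm_cfg$input_size <- ncol(features$energy)
  lstm_cfg$seed <- derive_seed(cfg$seed, 103L)
  model <- train_classifier(train, splits$validation, lstm_cfg)

  pred_test <- predict_epochs(model, splits$test)
  epoch_metrics <- evaluate(pred_test$labels, splits$test$labels,
                            positive = "ictal")

  decisions <- list()
  gold_sides <- character(0)
  subjects <- character(0)
  for (k in seq_along(recordings)) {
    es <- epoch_sets[[k]]
    if (dim(es$epochs)[1L] == 0L) next
    labels <- if (cfg$ictal_source == "gold") es$labels
      else predict_epochs(model, extract_features(es, band = cfg$band))$labels
    if (!any(labels == "ictal")) next
    dec <- recording_laterality(es, montage, labels = labels,
                                pooling = cfg$pooling)
    decisions[[length(decisions) + 1L]] <- dec
    gold_sides <- c(gold_sides, recordings[[k]]$true_laterality)
    subjects <- c(subjects, recordings[[k]]$subject_id)
  }

  lat_report <- NULL
  if (length(decisions) && all(gold_sides %in% c("left", "right"))) {
    pred_sides <- vapply(decisions, function(d) d$side, "")
    rec_metrics <- evaluate_lateralization(pred_sides, gold_sides)
    pat_pred <- pat_gold <- character(0)
    for (s in unique(subjects)) {
      sel <- subjects == s
      pat_pred <- c(pat_pred, patient_laterality(pred_sides[sel])$side)
      pat_gold <- c(pat_gold, gold_sides[sel][1L])
    }
    lat_report <- list(
      recording_metrics = unclass(rec_metrics),
      patient_metrics = unclass(evaluate_lateralization(pat_pred, pat_gold)),
      n_recordings = length(decisions),
      n_patients = length(unique(subjects)))
  }

  report <- list(
    config_hash = config_hash(cfg),
    seed = cfg$seed,
    band = cfg$band,
    channels = cfg$channels,
    n_recordings = length(recordings),
    n_epochs = dim(all_epochs$epochs)[1L],
    n_ictal_epochs = sum(all_epochs$labels == "ictal"),
    epoch_metrics = unclass(epoch_metrics),
    best_val_accuracy = model$val_accuracy,
    lateralization = lat_report,
    decisions = lapply(decisions, function(d)
      list(recording_id = d$recording_id, side = d$side,
           vote_sum = d$vote_sum,
           asymmetry = as.numeric(d$pairs$asymmetry),
           votes = as.integer(d$pairs$vote))))
  class(report) <- c("pipeline_report", class(report))
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("pipeline run (band %s, %d channels, seed %d, config %s)\n",
              x$band, x$channels, x$seed, x$config_hash))
  cat(sprintf("  %d recordings -> %d epochs (%d ictal)\n",
              x$n_recordings, x$n_epochs, x$n_ictal_epochs))
  cat(sprintf("  epoch classification: accuracy %.4f sens %.4f spec %.4f\n",
              x$epoch_metrics$accuracy, x$epoch_metrics$sensitivity,
              x$epoch_metrics$specificity))
  if (!is.null(x$lateralization))
    cat(sprintf("  lateralization: recordings %.4f (n=%d), patients %.4f (n=%d)\n",
                x$lateralization$recording_metrics$accuracy,
                x$lateralization$n_recordings,
                x$lateralization$patient_metrics$accuracy,
                x$lateralization$n_patients))
  invisible(x)
}

#' Write a run report as JSON
#'
#' Deterministic serialization: identical reports produce byte-identical
#' files.
#'
#' @param report a `pipeline_report` (or any list).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass_deep(report), path, digits = NA,
                       auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(path)
}

#' Per-band classification sweep
#'
#' Trains and evaluates one classifier per band on shared epochs, shared
#' split and shared seed, reporting validation, test and training accuracy
#' per band -- the experiment design used to select the operating band.
#'
#' @param cfg a [pipeline_config()].
#' @param bands character vector of band names (default: all 13 of
#'   [band_table()]).
#' @param recordings optional in-memory cohort (see [run_pipeline()]).
#' @return data.frame with columns `band`, `validation_accuracy`,
#'   `test_accuracy`, `training_accuracy`.
#' @export
band_sweep <- function(cfg, bands = band_table()$band, recordings = NULL) {
  if (!length(bands))
    stop_eegfocus("need at least one band to sweep", "config_error")
  for (b in bands) band_sets(b)
  recordings <- recordings %||% load_cohort(cfg)
  montage <- montage_spec()
  epoch_sets <- lapply(recordings, preprocess_recording,
                       cfg = cfg$preprocess, channels = cfg$channels,
                       montage = montage)
  all_epochs <- bind_epoch_sets(epoch_sets)

  out <- data.frame(band = character(0), validation_accuracy = numeric(0),
                    test_accuracy = numeric(0), training_accuracy = numeric(0))
  for (b in bands) {
    features <- extract_features(all_epochs, band = b)
    split_cfg <- cfg$split
    split_cfg$seed <- derive_seed(cfg$seed, 102L)
    splits <- split_dataset(features, split_cfg)
    train <- balance_by_duplication(splits$train)
    lstm_cfg <- cfg$lstm
    lstm_cfg$input_size <- ncol(features$energy)
    lstm_cfg$seed <- derive_seed(cfg$seed, 103L)
    model <- train_classifier(train, splits$validation, lstm_cfg)
    acc <- function(fm) {
      p <- predict_epochs(model, fm)
      mean(p$labels == fm$labels)
    }
    out <- rbind(out, data.frame(
      band = b,
      validation_accuracy = acc(splits$validation),
      test_accuracy = acc(splits$test),
      training_accuracy = acc(splits$train)))
  }
  out
}
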