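# Pipeline configuration, the cross-validated evaluation protocol, and
# plain-text artifact formats (feature tables, model bundles, reports).

#' Pipeline configuration
#'
#' One object pins every knob of the pipeline so a run is reproducible from
#' `(config, seed)` alone; the effective config is embedded in feature
#' tables, model bundles and evaluation reports.
#'
#' @param filter A [filter_spec()].
#' @param stft An [stft_config()].
#' @param channels Channel-name subset (`NULL` = all channels, in stored
#'   order). Subsets are configuration by name, never by position.
#' @param backend Deep backend name or `list(name=, ...)`, see
#'   [get_backend()].
#' @param k_per_class Vocabulary words per class (default 8, the cluster
#'   size the evaluation sweep selects).
#' @param classifier `"knn_weighted"`, `"svm_rbf"` or `"svm_cubic"`.
#' @param classifier_params Overrides for [train_classifier()].
#' @param vocab_mode `"per_class"` or `"global"` k-means.
#' @param normalize_counts L1-normalize bag-of-words counts (default).
#' @param n_folds Cross-validation folds (default 5).
#' @param holdout_fraction Training fraction of the secondary holdout mode.
#' @param seed Master seed for fold shuffling, k-means and classifiers.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(filter = filter_spec(), stft = stft_config(),
                            channels = NULL, backend = "mock",
                            k_per_class = 8L,
                            classifier = "knn_weighted",
                            classifier_params = list(),
                            vocab_mode = "per_class",
                            normalize_counts = TRUE, n_folds = 5L,
                            holdout_fraction = 0.7, seed = 1L) {
  structure(list(filter = filter, stft = stft, channels = channels,
                 backend = backend, k_per_class = as.integer(k_per_class),
                 classifier = classifier, classifier_params = classifier_params,
                 vocab_mode = vocab_mode,
                 normalize_counts = isTRUE(normalize_counts),
                 n_folds = as.integer(n_folds),
                 holdout_fraction = holdout_fraction,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

config_to_list <- function(config) {
  x <- unclass(config)
  x$filter <- unclass(x$filter)
  x$stft <- unclass(x$stft)
  x$package_version <- as.character(utils::packageVersion("bohdf"))
  x
}

#' Load a pipeline config from a JSON file
#'
#' Unknown keys are rejected; `filter` and `stft` sub-objects take the same
#' fields as [filter_spec()] and [stft_config()].
#'
#' @param path JSON file path.
#' @param overrides Named list applied on top of the file (CLI flags).
#' @return A [pipeline_config()].
#' @export
load_config <- function(path, overrides = list()) {
  raw <- if (is.null(path)) list() else
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  raw <- utils::modifyList(raw, overrides)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (!is.null(raw$filter)) raw$filter <- do.call(filter_spec, as.list(raw$filter))
  if (!is.null(raw$stft)) {
    st <- as.list(raw$stft)
    if (!is.null(st$band) && length(st$band) == 0) st$band <- NULL
    raw$stft <- do.call(stft_config, st)
  }
  do.call(pipeline_config, raw)
}

# ---- feature tables -------------------------------------------------------

#' Write / read a raw feature table as CSV
#'
#' One row per (trial, channel): `trial_id, channel, label, f1..fD`.
#' Doubles are printed with full precision, so a rerun from identical
#' inputs produces a byte-identical file.
#'
#' @param features List of `raw_feature`.
#' @param path CSV path.
#' @return `path` invisibly; for the reader, the list of `raw_feature`.
#' @export
write_feature_table <- function(features, path) {
  d <- length(features[[1]]$values)
  hdr <- paste(c("trial_id", "channel", "label", paste0("f", seq_len(d))),
               collapse = ",")
  rows <- vapply(features, function(f) {
    paste(c(f$trial_id, f$channel,
            if (is.na(f$label)) "" else f$label,
            fmt_dbl(f$values)), collapse = ",")
  }, character(1))
  con <- file(path, open = "wb")
  writeLines(c(hdr, rows), con, sep = "\n")
  close(con)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  fcols <- grep("^f[0-9]+$", names(df))
  lapply(seq_len(nrow(df)), function(i) {
    structure(list(values = as.numeric(df[i, fcols]),
                   trial_id = as.character(df$trial_id[i]),
                   channel = as.character(df$channel[i]),
                   label = if (is.na(df$label[i])) NA_integer_ else
                     as.integer(df$label[i])),
              class = "raw_feature")
  })
}

# ---- model bundle ---------------------------------------------------------

#' Save / load a trained vocabulary + classifier bundle
#'
#' The bundle is a versioned JSON document (R-type-preserving
#' serialization) embedding the effective pipeline config.
#'
#' @param vocab A `bohdf_vocabulary`.
#' @param classifier A `bohdf_classifier`.
#' @param config The [pipeline_config()] used for training.
#' @param path Output path (JSON).
#' @return `path` invisibly; the loader returns the
#'   `list(vocab, classifier, config)` bundle.
#' @export
save_model_bundle <- function(vocab, classifier, config, path) {
  payload <- list(format = "bohdf-bundle", version = 1L,
                  config = config_to_list(config),
                  vocab = vocab, classifier = classifier)
  writeLines(jsonlite::serializeJSON(payload, digits = NA), path)
  invisible(path)
}

#' @rdname save_model_bundle
#' @export
load_model_bundle <- function(path) {
  payload <- jsonlite::unserializeJSON(paste(readLines(path), collapse = "\n"))
  if (!identical(payload$format, "bohdf-bundle")) {
    stop(sprintf("'%s' is not a bohdf model bundle", path))
  }
  payload
}

# ---- evaluation -----------------------------------------------------------

# deterministic stratified fold assignment: per class, seeded shuffle then
# round-robin
stratified_folds <- function(labels, n_folds, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      if (length(idx) < n_folds) {
        stop(sprintf("class %d has %d trials, fewer than n_folds = %d",
                     cl, length(idx), n_folds))
      }
      idx <- sample(idx)
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

#' Evaluate the pipeline on a labeled dataset
#'
#' Canonical protocol: stratified k-fold cross-validation in which the
#' standardizer, vocabulary and classifier are rebuilt inside every fold
#' from that fold's training trials only — test trials never influence the
#' vocabulary. `mode = "holdout"` instead performs a single stratified
#' 70/30 split.
#'
#' @param trials Labeled list of [eeg_trial()] (>= 2 classes).
#' @param config A [pipeline_config()].
#' @param mode `"cv"` (default) or `"holdout"`.
#' @param features Optional precomputed [extract_raw_features()] output for
#'   these trials (feature extraction is per-trial and unsupervised, so
#'   reusing it across folds leaks nothing).
#' @param verbose Log fold progress.
#' @return A `bohdf_report`: per-fold and mean accuracy, pooled confusion
#'   matrix (rows = truth), and the effective config.
#' @export
evaluate_pipeline <- function(trials, config = pipeline_config(),
                              mode = c("cv", "holdout"), features = NULL,
                              verbose = FALSE) {
  mode <- match.arg(mode)
  labels <- vapply(trials, function(t) as.integer(t$label), integer(1))
  if (anyNA(labels)) stop("evaluation needs fully labeled trials")
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("evaluation needs at least 2 classes")
  if (is.null(features)) features <- extract_raw_features(trials, config,
                                                          verbose = verbose)
  ids <- vapply(trials, function(t) t$trial_id, character(1))
  feat_ids <- vapply(features, function(f) f$trial_id, character(1))
  splits <- if (mode == "cv") {
    fold <- stratified_folds(labels, config$n_folds, config$seed)
    lapply(seq_len(config$n_folds), function(f) list(train = ids[fold != f],
                                                     test = ids[fold == f]))
  } else {
    tr_ids <- with_seed(config$seed, unlist(lapply(classes, function(cl) {
      idx <- sample(which(labels == cl))
      idx[seq_len(max(1, round(config$holdout_fraction * length(idx))))]
    })))
    list(list(train = ids[tr_ids], test = ids[-tr_ids]))
  }
  conf <- matrix(0L, length(classes), length(classes),
                 dimnames = list(truth = classes, predicted = classes))
  fold_acc <- numeric(length(splits))
  for (f in seq_along(splits)) {
    sp <- splits[[f]]
    train_feats <- features[feat_ids %in% sp$train]
    vocab <- build_vocabulary(train_feats, k_per_class = config$k_per_class,
                              seed = config$seed + f,
                              mode = config$vocab_mode)
    enc_train <- encode_dataset(train_feats, vocab,
                                normalize = config$normalize_counts)
    enc_test <- encode_dataset(features[feat_ids %in% sp$test], vocab,
                               normalize = config$normalize_counts)
    params <- utils::modifyList(list(seed = config$seed + f),
                                config$classifier_params)
    clf <- train_classifier(enc_train, kind = config$classifier,
                            params = params)
    pred <- predict(clf, enc_test)
    truth <- vapply(enc_test, function(e) as.integer(e$label), integer(1))
    fold_acc[f] <- mean(pred == truth)
    for (i in seq_along(pred)) {
      conf[as.character(truth[i]), as.character(pred[i])] <-
        conf[as.character(truth[i]), as.character(pred[i])] + 1L
    }
    if (verbose) message(sprintf("fold %d/%d: accuracy %.3f", f,
                                 length(splits), fold_acc[f]))
  }
  structure(list(mode = mode, fold_accuracy = fold_acc,
                 mean_accuracy = mean(fold_acc), confusion = conf,
                 n_trials = length(trials), classes = classes,
                 folds = splits, config = config_to_list(config)),
            class = "bohdf_report")
}

#' @export
print.bohdf_report <- function(x, ...) {
  cat(sprintf("<bohdf_report> %s over %d trials (%d classes)\n", x$mode,
              x$n_trials, length(x$classes)))
  cat(sprintf("  fold accuracies: %s\n",
              paste(sprintf("%.3f", x$fold_accuracy), collapse = " ")))
  cat(sprintf("  mean accuracy:   %.4f\n", x$mean_accuracy))
  cat("  confusion (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report A `bohdf_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  x <- unclass(report)
  x$confusion <- list(classes = report$classes,
                      matrix = unname(as.matrix(report$confusion)))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
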