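# Bag-of-hybrid-deep-features model: feature fusion, per-class k-means
# vocabulary, trial encoding, and classification.

#' Fuse deep and texture features into one raw feature vector
#'
#' Concatenation, deep features first then the 600 texture features; with
#' the default 1000-dim deep backend the raw vector has length 1600.
#'
#' @param deep Numeric deep feature vector ([extract_deep()]).
#' @param texture Numeric length-600 texture descriptor ([omtlbp_describe()]).
#' @param trial_id,channel,label Metadata carried through to the vocabulary
#'   and encoding stages.
#' @return A `raw_feature` list with `values`, `trial_id`, `channel`, `label`.
#' @export
fuse_features <- function(deep, texture, trial_id = "t00", channel = "ch1",
                          label = NA_integer_) {
  if (length(texture) != 600L) stop("texture descriptor must have length 600")
  structure(list(values = c(as.numeric(deep), as.numeric(texture)),
                 trial_id = trial_id, channel = channel,
                 label = if (is.na(label)) NA_integer_ else as.integer(label)),
            class = "raw_feature")
}

features_matrix <- function(features) {
  do.call(rbind, lapply(features, function(f) f$values))
}

features_labels <- function(features) {
  vapply(features, function(f) as.integer(f$label), integer(1))
}

#' Extract raw per-channel features for a set of trials
#'
#' Runs the full per-trial feature path: band-pass filter, per-channel STFT
#' spectrogram, rendered image, texture descriptor (grayscale plane) and
#' deep features (RGB plane), fused into one raw vector per channel.
#'
#' @param trials List of [eeg_trial()].
#' @param config A [pipeline_config()].
#' @param verbose Log per-trial progress.
#' @return List of `raw_feature`, `length(trials) * n_channels` long.
#' @export
extract_raw_features <- function(trials, config = pipeline_config(),
                                 verbose = FALSE) {
  backend <- get_backend(config$backend)
  out <- list()
  for (tr in trials) {
    if (!is.null(config$channels)) tr <- select_channels(tr, config$channels)
    filt <- bandpass_filter(tr, config$filter)
    for (i in seq_len(n_channels(filt))) {
      sp <- compute_stft(filt$samples[i, ], filt$fs, config$stft)
      img <- render_image(sp)
      tex <- omtlbp_describe(img$gray, normalize = TRUE)
      dp <- extract_deep(img, backend)
      out[[length(out) + 1L]] <- fuse_features(
        dp, tex, trial_id = tr$trial_id, channel = filt$channel_names[i],
        label = tr$label)
    }
    if (verbose) message(sprintf("features: %s (%d channels)", tr$trial_id,
                                 n_channels(filt)))
  }
  out
}

#' Build the per-class k-means vocabulary
#'
#' Raw feature vectors are standardized per dimension (z-score fitted on
#' the training vectors only), then k-means is run independently within
#' each class; the concatenated centroids are the vocabulary words. A
#' `mode = "global"` switch pools all classes into one k-means instead.
#'
#' @param features List of `raw_feature` (labeled training vectors only).
#' @param k_per_class Clusters per class (words per class), default 8.
#' @param seed Integer seed for the k-means initializations.
#' @param mode `"per_class"` (default) or `"global"`.
#' @return A `bohdf_vocabulary`: `words` (standardized centroid matrix),
#'   `word_class`, `center`/`scale` of the fitted standardizer, `classes`.
#' @export
build_vocabulary <- function(features, k_per_class = 8L, seed = 1L,
                             mode = c("per_class", "global")) {
  mode <- match.arg(mode)
  X <- features_matrix(features)
  y <- features_labels(features)
  if (anyNA(y)) stop("vocabulary building needs labeled features")
  classes <- sort(unique(y))
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale == 0] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")
  if (mode == "global") {
    k <- k_per_class * length(classes)
    km <- kmeans_lloyd(Xs, k, seed = seed)
    words <- km$centers
    word_class <- rep(NA_integer_, k)
  } else {
    words <- NULL; word_class <- integer(0)
    for (cl in classes) {
      Xc <- Xs[y == cl, , drop = FALSE]
      if (nrow(Xc) < k_per_class) {
        stop(sprintf("class %d has only %d vectors, fewer than k_per_class = %d",
                     cl, nrow(Xc), k_per_class))
      }
      km <- kmeans_lloyd(Xc, k_per_class, seed = seed + as.integer(cl))
      words <- rbind(words, km$centers)
      word_class <- c(word_class, rep(as.integer(cl), k_per_class))
    }
  }
  structure(list(words = words, word_class = word_class,
                 k_per_class = as.integer(k_per_class), mode = mode,
                 center = center, scale = scale, classes = classes),
            class = "bohdf_vocabulary")
}

#' Encode one trial as a bag-of-words histogram
#'
#' Each channel's raw vector is standardized with the vocabulary's scaler
#' and assigned to its nearest word (Euclidean distance, ties to the lowest
#' word index); the word counts over channels form the trial's encoded
#' vector.
#'
#' @param channel_features List of `raw_feature` belonging to one trial.
#' @param vocab A `bohdf_vocabulary`.
#' @param normalize L1-normalize the counts (default); unnormalized they
#'   sum to the number of channels.
#' @return A `bohdf_vector` with `counts`, `label`, `trial_id`.
#' @export
encode_trial <- function(channel_features, vocab, normalize = TRUE) {
  stopifnot(inherits(vocab, "bohdf_vocabulary"), length(channel_features) > 0)
  X <- features_matrix(channel_features)
  if (ncol(X) != ncol(vocab$words)) {
    stop(sprintf("feature dimension %d does not match vocabulary dimension %d",
                 ncol(X), ncol(vocab$words)))
  }
  Xs <- sweep(sweep(X, 2, vocab$center), 2, vocab$scale, "/")
  d2 <- sqdist(Xs, vocab$words)
  nearest <- max.col(-d2, ties.method = "first")
  counts <- tabulate(nearest, nbins = nrow(vocab$words))
  if (normalize) counts <- counts / sum(counts)
  lab <- channel_features[[1]]$label
  structure(list(counts = counts, label = lab,
                 trial_id = channel_features[[1]]$trial_id),
            class = "bohdf_vector")
}

encode_dataset <- function(features, vocab, normalize = TRUE) {
  ids <- vapply(features, function(f) f$trial_id, character(1))
  lapply(split(features, factor(ids, levels = unique(ids))),
         encode_trial, vocab = vocab, normalize = normalize)
}

#' Train a classifier on encoded bag-of-words vectors
#'
#' @param encoded List of `bohdf_vector` (labeled).
#' @param kind `"knn_weighted"` (default; inverse-distance-weighted K
#'   nearest neighbors, K = 10), `"svm_rbf"` or `"svm_cubic"`.
#' @param params Optional overrides: `k` (KNN neighbors), `C` (SVM cost),
#'   `seed`.
#' @return A `bohdf_classifier` model usable with [predict()].
#' @export
train_classifier <- function(encoded, kind = c("knn_weighted", "svm_rbf", "svm_cubic"),
                             params = list()) {
  kind <- match.arg(kind)
  if (length(encoded) == 0) stop("empty training set")
  X <- do.call(rbind, lapply(encoded, function(e) e$counts))
  y <- vapply(encoded, function(e) as.integer(e$label), integer(1))
  if (anyNA(y)) stop("training needs labeled encoded vectors")
  if (length(unique(y)) < 2) {
    stop("training needs at least 2 classes; got a single class")
  }
  model <- switch(kind,
    knn_weighted = list(X = X, y = y, k = params$k %||% 10L),
    svm_rbf   = svm_train(X, y, "rbf", C = params$C %||% 1,
                          seed = params$seed %||% 1L),
    svm_cubic = svm_train(X, y, "cubic", C = params$C %||% 1,
                          seed = params$seed %||% 1L))
  structure(list(kind = kind, model = model, params = params,
                 classes = sort(unique(y))),
            class = "bohdf_classifier")
}

#' Predict class labels for encoded trials
#'
#' KNN votes are weighted by inverse distance; an exact-match neighbor
#' (zero distance) dominates the vote. All ties break toward the lowest
#' class index.
#'
#' @param object A `bohdf_classifier`.
#' @param newdata List of `bohdf_vector` or a numeric matrix of counts.
#' @param ... Unused.
#' @return Integer vector of predicted class labels.
#' @export
predict.bohdf_classifier <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else
    do.call(rbind, lapply(newdata, function(e) e$counts))
  if (object$kind == "knn_weighted") {
    m <- object$model
    k <- min(m$k, nrow(m$X))
    d2 <- sqdist(X, m$X)
    vapply(seq_len(nrow(X)), function(i) {
      ord <- order(d2[i, ])[seq_len(k)]
      d <- sqrt(d2[i, ord])
      lab <- m$y[ord]
      if (any(d < 1e-12)) {               # exact matches dominate
        lab <- lab[d < 1e-12]
        w <- rep(1, length(lab))
      } else {
        w <- 1 / d
      }
      votes <- tapply(w, factor(lab, levels = object$classes), sum,
                      default = 0)
      object$classes[which.max(votes)]    # which.max: lowest index on ties
    }, integer(1))
  } else {
    as.integer(svm_predict(object$model, X))
  }
}
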