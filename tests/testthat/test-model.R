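# planted Gaussian clouds: k tight, well-separated clusters
make_clouds <- function(k, n_per, d = 5, sep = 50, sd = 0.1, seed = 1) {
  set.seed(seed)
  means <- matrix(rnorm(k * d), k) * sep
  X <- do.call(rbind, lapply(seq_len(k), function(j) {
    sweep(matrix(rnorm(n_per * d, sd = sd), n_per), 2, means[j, ], "+")
  }))
  list(X = X, means = means, labels = rep(seq_len(k), each = n_per))
}

test_that("k-means with k = 1 returns the mean; objective never increases", {
  set.seed(2)
  X <- matrix(rnorm(40 * 3), 40)
  km <- kmeans_lloyd(X, 1, seed = 5)
  expect_equal(km$centers[1, ], colMeans(X), tolerance = 1e-12,
               ignore_attr = TRUE)
  for (kk in c(2, 4, 7)) {
    km <- kmeans_lloyd(X, kk, seed = kk)
    expect_true(all(diff(km$objective) <= 1e-9))
  }
})

test_that("k-means recovers planted well-separated clouds", {
  cl <- make_clouds(4, 25)
  km <- kmeans_lloyd(cl$X, 4, seed = 3)
  # match each recovered center to its nearest true mean
  for (j in 1:4) {
    d <- sqrt(rowSums(sweep(cl$means, 2, km$centers[j, ])^2))
    expect_lt(min(d), 1e-1)   # sd 0.1, n 25 -> mean within ~0.1/sqrt(25) per dim
  }
  # final assignment satisfies the nearest-centroid argmin
  d2 <- bohdf:::sqdist(cl$X, km$centers)
  expect_equal(km$assignment, apply(d2, 1, which.min))
  expect_identical(kmeans_lloyd(cl$X, 4, seed = 3)$centers, km$centers)
})

test_that("k-means agrees with the reference implementation on easy data", {
  cl <- make_clouds(3, 30, seed = 9)
  km <- kmeans_lloyd(cl$X, 3, seed = 1)
  ref <- stats::kmeans(cl$X, 3, nstart = 5)
  ours <- km$centers[order(km$centers[, 1]), ]
  theirs <- ref$centers[order(ref$centers[, 1]), ]
  expect_equal(ours, theirs, tolerance = 1e-6, ignore_attr = TRUE)
})

fake_features <- function(X, labels, trial_ids = NULL, channels = NULL) {
  lapply(seq_len(nrow(X)), function(i) {
    structure(list(values = X[i, ],
                   trial_id = if (is.null(trial_ids)) sprintf("t%03d", i)
                   else trial_ids[i],
                   channel = if (is.null(channels)) "ch1" else channels[i],
                   label = as.integer(labels[i])),
              class = "raw_feature")
  })
}

test_that("vocabulary: one class with k = 1 is the standardized class mean", {
  set.seed(11)
  X <- matrix(rnorm(20 * 6), 20)
  v <- build_vocabulary(fake_features(X, rep(0, 20)), k_per_class = 1)
  expect_equal(nrow(v$words), 1)
  # unstandardize: word * scale + center == raw mean
  expect_equal(v$words[1, ] * v$scale + v$center, colMeans(X),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("vocabulary recovers per-class planted clouds within 1e-3", {
  cl0 <- make_clouds(2, 40, d = 4, seed = 21)
  cl1 <- make_clouds(2, 40, d = 4, seed = 22)
  X <- rbind(cl0$X, cl1$X)
  y <- c(rep(0, 80), rep(1, 80))
  v <- build_vocabulary(fake_features(X, y), k_per_class = 2, seed = 7)
  expect_equal(nrow(v$words), 4)
  expect_equal(v$word_class, c(0L, 0L, 1L, 1L))
  true_means <- rbind(cl0$means, cl1$means)
  recovered <- sweep(sweep(v$words, 2, v$scale, "*"), 2, v$center, "+")
  for (j in 1:4) {
    d <- sqrt(rowSums(sweep(true_means, 2, recovered[j, ])^2))
    expect_lt(min(d), 1e-3 * max(1, sqrt(sum(true_means^2))))
  }
  expect_identical(build_vocabulary(fake_features(X, y), 2, seed = 7)$words,
                   v$words)
})

test_that("vocabulary errors when a class has too few vectors", {
  set.seed(3)
  X <- matrix(rnorm(10 * 4), 10)
  expect_error(build_vocabulary(fake_features(X, c(rep(0, 7), rep(1, 3))),
                                k_per_class = 4),
               "class 1")
})

test_that("trial encoding assigns to nearest words and conserves counts", {
  cl <- make_clouds(3, 30, d = 6, seed = 5)
  v <- build_vocabulary(fake_features(cl$X, cl$labels - 1), k_per_class = 1,
                        seed = 2)
  # channels of one trial placed exactly on word 3's centroid
  w3 <- v$words[3, ] * v$scale + v$center
  enc <- encode_trial(fake_features(matrix(rep(w3, 5), 5, byrow = TRUE),
                                    rep(2, 5)), v, normalize = FALSE)
  expect_equal(enc$counts, c(0, 0, 5))
  # conservation over 32 channels
  set.seed(6)
  X32 <- matrix(rnorm(32 * 6), 32)
  enc32 <- encode_trial(fake_features(X32, rep(0, 32),
                                      trial_ids = rep("t1", 32)),
                        v, normalize = FALSE)
  expect_equal(sum(enc32$counts), 32)
  # brute-force nearest-centroid oracle: encode one vector at a time
  Xs <- sweep(sweep(X32, 2, v$center), 2, v$scale, "/")
  for (i in 1:32) {
    e1 <- encode_trial(fake_features(X32[i, , drop = FALSE], 0), v,
                       normalize = FALSE)
    d <- apply(v$words, 1, function(w) sum((Xs[i, ] - w)^2))
    expect_equal(which(e1$counts == 1), which.min(d))
  }
  expect_error(encode_trial(fake_features(matrix(0, 2, 3), c(0, 0)), v),
               "dimension")
})

test_that("KNN: a training point is its own 1-nearest neighbor", {
  set.seed(8)
  enc <- lapply(1:20, function(i) {
    structure(list(counts = runif(6), label = (i - 1) %% 2,
                   trial_id = sprintf("t%d", i)), class = "bohdf_vector")
  })
  clf <- train_classifier(enc, "knn_weighted", params = list(k = 1))
  pred <- predict(clf, enc)
  expect_equal(pred, vapply(enc, function(e) as.integer(e$label), integer(1)))
})

test_that("SVM reaches 100% training accuracy on separable clouds", {
  cl <- make_clouds(3, 15, d = 4, sep = 20, sd = 0.2, seed = 13)
  enc <- lapply(seq_len(nrow(cl$X)), function(i) {
    structure(list(counts = cl$X[i, ], label = cl$labels[i] - 1,
                   trial_id = sprintf("t%d", i)), class = "bohdf_vector")
  })
  for (kind in c("svm_rbf", "svm_cubic")) {
    clf <- train_classifier(enc, kind, params = list(seed = 3))
    expect_equal(predict(clf, enc),
                 vapply(enc, function(e) as.integer(e$label), integer(1)),
                 label = kind)
  }
})

test_that("classifier contracts: empty and single-class input error", {
  expect_error(train_classifier(list(), "knn_weighted"), "empty")
  enc <- lapply(1:5, function(i) {
    structure(list(counts = runif(3), label = 0L, trial_id = sprintf("t%d", i)),
              class = "bohdf_vector")
  })
  expect_error(train_classifier(enc, "knn_weighted"), "single class")
})
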