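# Minimal kernel SVM (no SVM package ships in this environment).
#
# Binary soft-margin SVM trained with simplified SMO on the kernel matrix;
# multiclass via one-vs-one majority vote. Adequate for the moderate-size
# bag-of-features vectors this pipeline produces; not a general-purpose SVM.

svm_kernel <- function(X1, X2, kernel, gamma) {
  G <- X1 %*% t(X2)
  if (kernel == "rbf") {
    d2 <- outer(rowSums(X1^2), rep(1, nrow(X2))) +
      outer(rep(1, nrow(X1)), rowSums(X2^2)) - 2 * G
    exp(-gamma * pmax(d2, 0))
  } else {                      # cubic polynomial
    (gamma * G + 1)^3
  }
}

# Simplified SMO for one binary problem. y in {-1, +1}.
smo_binary <- function(K, y, C = 1, tol = 1e-3, max_passes = 20L, max_iter = 2000L) {
  n <- length(y)
  alpha <- numeric(n)
  b <- 0
  passes <- 0L; iter <- 0L
  fx <- function(i) sum(alpha * y * K[, i]) + b
  while (passes < max_passes && iter < max_iter) {
    iter <- iter + 1L
    changed <- 0L
    for (i in seq_len(n)) {
      Ei <- fx(i) - y[i]
      if ((y[i] * Ei < -tol && alpha[i] < C) || (y[i] * Ei > tol && alpha[i] > 0)) {
        j <- sample.int(n - 1L, 1L)
        if (j >= i) j <- j + 1L
        Ej <- fx(j) - y[j]
        ai_old <- alpha[i]; aj_old <- alpha[j]
        if (y[i] != y[j]) {
          L <- max(0, alpha[j] - alpha[i]); H <- min(C, C + alpha[j] - alpha[i])
        } else {
          L <- max(0, alpha[i] + alpha[j] - C); H <- min(C, alpha[i] + alpha[j])
        }
        if (L >= H) next
        eta <- 2 * K[i, j] - K[i, i] - K[j, j]
        if (eta >= 0) next
        aj <- aj_old - y[j] * (Ei - Ej) / eta
        aj <- min(max(aj, L), H)
        if (abs(aj - aj_old) < 1e-5) next
        ai <- ai_old + y[i] * y[j] * (aj_old - aj)
        alpha[i] <- ai; alpha[j] <- aj
        b1 <- b - Ei - y[i] * (ai - ai_old) * K[i, i] - y[j] * (aj - aj_old) * K[i, j]
        b2 <- b - Ej - y[i] * (ai - ai_old) * K[i, j] - y[j] * (aj - aj_old) * K[j, j]
        b <- if (ai > 0 && ai < C) b1 else if (aj > 0 && aj < C) b2 else (b1 + b2) / 2
        changed <- changed + 1L
      }
    }
    passes <- if (changed == 0L) passes + 1L else 0L
  }
  list(alpha = alpha, b = b)
}

svm_train <- function(X, y, kernel = c("rbf", "cubic"), C = 1, seed = 1L) {
  kernel <- match.arg(kernel)
  # standardize features: kernel scales assume O(1) inputs
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  X <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  classes <- sort(unique(y))
  gamma <- if (kernel == "rbf") {
    v <- mean(apply(X, 2, stats::var))
    1 / (ncol(X) * max(v, 1e-12))
  } else 1 / ncol(X)
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  models <- with_seed(seed, lapply(pairs, function(pr) {
    sel <- y %in% pr
    Xi <- X[sel, , drop = FALSE]
    yi <- ifelse(y[sel] == pr[2], 1, -1)
    K <- svm_kernel(Xi, Xi, kernel, gamma)
    fit <- smo_binary(K, yi)
    list(pair = pr, X = Xi, y = yi, alpha = fit$alpha, b = fit$b)
  }))
  list(kernel = kernel, gamma = gamma, C = C, classes = classes,
       center = ctr, scale = scl, models = models)
}

svm_predict <- function(model, X) {
  X <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  votes <- matrix(0L, nrow(X), length(model$classes))
  colnames(votes) <- model$classes
  for (m in model$models) {
    K <- svm_kernel(X, m$X, model$kernel, model$gamma)
    f <- K %*% (m$alpha * m$y) + m$b
    pred <- ifelse(f >= 0, m$pair[2], m$pair[1])
    for (cl in m$pair) {
      votes[, as.character(cl)] <- votes[, as.character(cl)] + (pred == cl)
    }
  }
  model$classes[max.col(votes, ties.method = "first")]  # tie: lowest class
}
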