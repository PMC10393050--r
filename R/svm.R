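# SVM classification of lock-in feature vectors, with hyperparameters
# chosen by Bayesian optimization: a Gaussian-process surrogate (squared-
# exponential kernel) over {kernel type, log10 cost, log10 gamma} maximizing
# expected improvement of the mean stratified 5-fold cross-validation
# accuracy. The SVM itself is fit with e1071.

# Deterministic stratified fold assignment: samples of each class are
# permuted under the seed and dealt round-robin into k folds.
stratified_folds <- function(labels, k, seed) {
  labels <- as.factor(labels)
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < k) {
        stop_invalid("stratification error: class '", cl, "' has fewer than ",
                     k, " samples")
      }
      fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Stratified train/test split at the sample (video) level
#'
#' Preserves per-class proportions to within one sample; deterministic for a
#' fixed seed.
#'
#' @param labels Class label per sample.
#' @param train_fraction Fraction assigned to training, in (0, 1).
#' @param seed Integer seed.
#' @return Logical vector, `TRUE` for training samples.
#' @export
stratified_split <- function(labels, train_fraction = 0.7, seed = 1) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop_invalid("`train_fraction` must be in (0, 1)")
  }
  labels <- as.factor(labels)
  train <- logical(length(labels))
  with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      n_tr <- round(train_fraction * length(idx))
      n_tr <- max(1L, min(length(idx) - 1L, n_tr))
      train[sample(idx, n_tr)] <- TRUE
    }
  })
  train
}

fit_svm_raw <- function(x, y, kernel, cost, gamma) {
  if (kernel == "linear") {
    e1071::svm(x, y, type = "C-classification", kernel = "linear",
               cost = cost, scale = FALSE)
  } else {
    e1071::svm(x, y, type = "C-classification", kernel = "radial",
               cost = cost, gamma = gamma, scale = FALSE)
  }
}

cv_accuracy <- function(x, y, fold, kernel, cost, gamma) {
  accs <- vapply(sort(unique(fold)), function(f) {
    tr <- fold != f
    model <- fit_svm_raw(x[tr, , drop = FALSE], y[tr], kernel, cost, gamma)
    mean(predict(model, x[!tr, , drop = FALSE]) == y[!tr])
  }, numeric(1))
  mean(accs)
}

# GP posterior (squared-exponential, fixed hyperparameters) on unit-cube
# inputs; returns mean and sd at candidate points.
gp_posterior <- function(X, y, Xstar, lengthscale = 0.3, noise = 1e-4) {
  sf2 <- max(stats::var(y), 1e-6)
  sqdist <- function(A, B) {
    outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  }
  K <- sf2 * exp(-0.5 * sqdist(X, X) / lengthscale^2) +
    diag(noise * sf2 + 1e-10, nrow(X))
  Ks <- sf2 * exp(-0.5 * sqdist(Xstar, X) / lengthscale^2)
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), y - mean(y)))
  mu <- mean(y) + Ks %*% alpha
  v <- forwardsolve(t(L), t(Ks))
  s2 <- pmax(sf2 - colSums(v^2), 1e-12)
  list(mean = as.numeric(mu), sd = sqrt(s2))
}

expected_improvement <- function(mu, sd, best) {
  z <- (mu - best) / sd
  (mu - best) * stats::pnorm(z) + sd * stats::dnorm(z)
}

decode_point <- function(p) {
  list(kernel = if (p[1] < 0.5) "linear" else "radial",
       cost = 10^(-2 + 5 * p[2]),
       gamma = 10^(-4 + 5 * p[3]))
}

#' Train an SVM with Bayesian hyperparameter optimization
#'
#' Searches kernel in {linear, radial}, cost in [1e-2, 1e3] and kernel width
#' gamma in [1e-4, 1e1] (both log-scaled), maximizing mean stratified 5-fold
#' cross-validation accuracy with a Gaussian-process surrogate and
#' expected-improvement acquisition. The best configuration is refit on the
#' full training set. Fully deterministic for a fixed seed.
#'
#' @param features Numeric matrix, rows = samples.
#' @param labels Class label per row; >= 2 classes with >= 5 samples each.
#' @param opt_budget Total number of hyperparameter evaluations
#'   (default 20; the first third is a seeded space-filling design).
#' @param seed Integer seed.
#' @param n_folds Cross-validation folds (default 5).
#' @return A `speckle_svm`: list with `model` (the refit e1071 fit),
#'   `best` (kernel, cost, gamma), `cv_accuracy` of the best point,
#'   `search` (data frame of all evaluations), `classes`, and `seed`.
#' @export
train_svm <- function(features, labels, opt_budget = 20, seed = 1,
                      n_folds = 5) {
  features <- as.matrix(features)
  labels <- as.factor(as.character(labels))
  if (nlevels(labels) < 2) stop_invalid("need >= 2 classes")
  if (nrow(features) != length(labels)) {
    stop_invalid("`features` rows must match `labels` length")
  }
  if (opt_budget < 4) stop_invalid("`opt_budget` must be >= 4")
  fold <- stratified_folds(labels, n_folds, derive_seed(seed, 11))
  n_init <- max(4L, ceiling(opt_budget / 3))
  X <- matrix(NA_real_, 0, 3)
  evals <- data.frame()
  eval_point <- function(p) {
    cfg <- decode_point(p)
    acc <- cv_accuracy(features, labels, fold, cfg$kernel, cfg$cost, cfg$gamma)
    evals <<- rbind(evals, data.frame(kernel = cfg$kernel, cost = cfg$cost,
                                      gamma = cfg$gamma, cv_accuracy = acc))
    X <<- rbind(X, p)
    acc
  }
  with_seed(derive_seed(seed, 12), {
    # space-filling start: alternate kernels, jittered stratified grid
    init <- cbind(rep(c(0, 1), length.out = n_init),
                  (seq_len(n_init) - stats::runif(n_init)) / n_init,
                  ((seq_len(n_init) * 7L) %% n_init + stats::runif(n_init)) / n_init)
    for (i in seq_len(n_init)) eval_point(init[i, ])
    while (nrow(evals) < opt_budget) {
      cand <- cbind(stats::runif(256), stats::runif(256), stats::runif(256))
      cand[, 1] <- as.numeric(cand[, 1] >= 0.5)
      post <- gp_posterior(X, evals$cv_accuracy, cand)
      ei <- expected_improvement(post$mean, post$sd, max(evals$cv_accuracy))
      eval_point(cand[which.max(ei), ])
    }
  })
  best_i <- which.max(evals$cv_accuracy)
  best <- evals[best_i, ]
  model <- fit_svm_raw(features, labels, as.character(best$kernel),
                       best$cost, best$gamma)
  structure(list(model = model,
                 best = list(kernel = as.character(best$kernel),
                             cost = best$cost, gamma = best$gamma),
                 cv_accuracy = best$cv_accuracy,
                 search = evals,
                 classes = levels(labels),
                 seed = seed),
            class = "speckle_svm")
}

#' Predict glucose classes with a trained SVM
#'
#' @param object A `speckle_svm` from [train_svm()].
#' @param newdata Feature matrix with the training column count.
#' @param ... Unused.
#' @return Character vector of predicted class labels (empty input gives an
#'   empty output).
#' @export
predict.speckle_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0) return(character(0))
  if (ncol(newdata) != ncol(object$model$SV)) {
    stop_invalid("feature count does not match the training shape")
  }
  as.character(predict(object$model, newdata))
}
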