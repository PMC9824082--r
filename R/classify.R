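# Classifier bank: linear SVM, random forest, k-NN and multinomial
# logistic regression, with stratified K-fold model selection.

#' Classifier specification
#'
#' Defaults follow the study settings: linear kernel for the SVM, 100
#' trees for the random forest, k = 1 for k-NN, and a quasi-Newton
#' (BFGS-family) optimizer for the multinomial logistic regression.
#'
#' @param family `"svm"`, `"rf"`, `"knn"` or `"lr"`.
#' @param cost SVM regularization strength (default 1).
#' @param ntree random-forest tree count (default 100).
#' @param k neighbor count for k-NN (default 1).
#' @param maxit optimizer iteration cap for LR (default 300).
#' @param seed RNG seed used where training is stochastic.
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("svm", "rf", "knn", "lr"),
                            cost = 1, ntree = 100L, k = 1L, maxit = 300L,
                            seed = 1L) {
  family <- match.arg(family)
  stopifnot(cost > 0, ntree > 0, k > 0, maxit > 0)
  structure(list(family = family, cost = cost, ntree = as.integer(ntree),
                 k = as.integer(k), maxit = as.integer(maxit),
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  extra <- switch(x$family,
                  svm = paste0("linear kernel, cost ", x$cost),
                  rf = paste0(x$ntree, " trees"),
                  knn = paste0("k = ", x$k),
                  lr = "quasi-Newton optimizer")
  cat("<classifier_spec>", x$family, "(", extra, ")\n")
  invisible(x)
}

#' Train a classifier on a feature matrix
#'
#' @param spec a [classifier_spec()].
#' @param features a [feature_matrix()] with >= 2 classes.
#' @return an object of class `har_model`.
#' @export
har_train <- function(spec, features) {
  X <- features$X
  y <- factor(features$labels)
  if (nlevels(y) < 2) stop("training requires at least 2 classes")
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  fit <- switch(spec$family,
    svm = with_seed(spec$seed,
      e1071::svm(X, y, kernel = "linear", cost = spec$cost, scale = FALSE,
                 probability = FALSE)),
    rf = with_seed(spec$seed, randomForest::randomForest(X, y, ntree = spec$ntree)),
    knn = list(X = X, y = y, k = spec$k),
    lr = with_seed(spec$seed,
      nnet::multinom(y ~ ., data.frame(y = y, X), trace = FALSE,
                     maxit = spec$maxit, MaxNWts = 1e6)))
  structure(list(spec = spec, fit = fit, classes = levels(y),
                 dim = ncol(X)),
            class = "har_model")
}

#' Predict activity labels
#'
#' @param model a `har_model` from [har_train()].
#' @param features a [feature_matrix()] with matching dimension.
#' @param type `"class"` for labels, `"prob"` for per-class scores
#'   (available for LR and RF; rows sum to 1).
#' @return character vector of labels, or a score matrix.
#' @export
har_predict <- function(model, features, type = c("class", "prob")) {
  type <- match.arg(type)
  X <- if (inherits(features, "feature_matrix")) features$X else as.matrix(features)
  if (ncol(X) != model$dim)
    stop("feature dimension ", ncol(X), " does not match training (", model$dim, ")")
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  spec <- model$spec
  if (type == "prob") {
    if (spec$family == "lr") {
      p <- stats::predict(model$fit, data.frame(X), type = "probs")
      if (is.null(dim(p))) p <- cbind(1 - p, p, deparse.level = 0)
      colnames(p) <- model$classes
      return(p)
    }
    if (spec$family == "rf") return(stats::predict(model$fit, X, type = "prob"))
    stop("per-class scores are not provided for family '", spec$family, "'")
  }
  out <- switch(spec$family,
    svm = stats::predict(model$fit, X),
    rf = stats::predict(model$fit, X),
    knn = class::knn(model$fit$X, X, model$fit$y, k = model$fit$k),
    lr = stats::predict(model$fit, data.frame(X)))
  as.character(out)
}

#' Select a classifier specification by stratified K-fold CV
#'
#' @param specs list of [classifier_spec()] candidates.
#' @param features a [feature_matrix()] with at least K samples.
#' @param K number of folds (default 10).
#' @param seed seed for the fold assignment.
#' @return list with `best` (the winning spec), `table` (per-spec mean and
#'   sd of validation accuracy) and `fold_accuracy` (spec x fold matrix).
#' @export
cv_select <- function(specs, features, K = 10L, seed = 1L) {
  Z <- nrow(features$X)
  if (Z < K) stop("need at least K = ", K, " samples for ", K, "-fold CV")
  fold <- stratified_folds(features$labels, K, seed)
  acc <- matrix(NA_real_, length(specs), K)
  for (si in seq_along(specs)) {
    for (kk in seq_len(K)) {
      tr <- fold != kk
      ftr <- feature_matrix(features$X[tr, , drop = FALSE], features$labels[tr])
      fva <- feature_matrix(features$X[!tr, , drop = FALSE], features$labels[!tr])
      m <- har_train(specs[[si]], ftr)
      acc[si, kk] <- accuracy_of(har_predict(m, fva), fva$labels)
    }
  }
  mean_acc <- rowMeans(acc)
  tab <- data.frame(
    family = vapply(specs, `[[`, character(1), "family"),
    mean_accuracy = mean_acc,
    sd_accuracy = apply(acc, 1, stats::sd))
  list(best = specs[[which.max(mean_acc)]], table = tab, fold_accuracy = acc)
}
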