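# Pairwise-interpolation augmentation and the experiment harness:
# repeated stratified 75/25 holdout, noise-reduction A/B comparison,
# cross-layout transfer, and sensor-subset selection. All fitted
# components (denoiser, subspace extractors, classifiers) see training
# data only.

#' Pairwise-interpolation augmentation
#'
#' For every (subject, activity) group of exactly 10 repeats, generates 10
#' new maps as element-wise means of same-group pairs in the fixed order
#' (map1,map2), (map2,map3), ..., (map9,map10), (map2,map4), doubling the
#' sample count. Augmented maps never mix subjects or activities.
#'
#' @param data a [dataset_tensor()] whose (subject, activity) groups each
#'   hold exactly 10 maps, in repeat order.
#' @return a [dataset_tensor()] with the original maps followed by the
#'   generated ones.
#' @export
augment_pairwise <- function(data) {
  subj_key <- vapply(data$subjects, function(s) paste(s, collapse = "+"), character(1))
  key <- paste(subj_key, data$labels, sep = "|")
  pairs_first <- c(1:9, 2); pairs_second <- c(2:10, 4)
  new_maps <- list(); new_lab <- character(0); new_subj <- list(); new_lay <- character(0)
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) != 10L)
      stop("group ", k, " has ", length(idx),
           " repeats; the pairing scheme is defined for exactly 10")
    for (p in seq_len(10)) {
      i <- idx[pairs_first[p]]; j <- idx[pairs_second[p]]
      new_maps[[length(new_maps) + 1L]] <- (data$maps[i, , ] + data$maps[j, , ]) / 2
      new_lab <- c(new_lab, data$labels[i])
      new_subj[[length(new_subj) + 1L]] <- data$subjects[[i]]
      new_lay <- c(new_lay, data$layout[i])
    }
  }
  aug <- array(0, c(length(new_maps), dim(data$maps)[2], dim(data$maps)[3]))
  for (i in seq_along(new_maps)) aug[i, , ] <- new_maps[[i]]
  bind_tensors(data, dataset_tensor(aug, new_lab, subjects = new_subj,
                                    layout = new_lay, sensor_id = data$sensor_id))
}

#' Experiment result container
#'
#' @param train_acc,test_acc per-repeat accuracies.
#' @param confusion confusion matrix summed over repeats (truth in rows).
#' @param config configuration fingerprint list.
#' @return an object of class `experiment_result`.
#' @export
experiment_result <- function(train_acc, test_acc, confusion, config = list()) {
  structure(list(train_acc = train_acc, test_acc = test_acc,
                 mean = mean(test_acc), sd = stats::sd(test_acc),
                 confusion = confusion, config = config),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> test accuracy %.2f%% +/- %.2f%% over %d repeat(s)\n",
              100 * x$mean, 100 * ifelse(is.na(x$sd), 0, x$sd), length(x$test_acc)))
  invisible(x)
}

# Fit the configured extractor on train and transform both sets.
fit_transform <- function(train, test, extractor, k = 45L, ridge = 1e-3) {
  if (extractor %in% c("svd", "fisher")) {
    model <- if (extractor == "svd") svd_fit(train, k = min(k, n_samples(train) - 1L))
             else fisher_fit(train, ridge = ridge)
    list(train = subspace_transform(model, train),
         test = subspace_transform(model, test), model = model)
  } else {
    list(train = extract_features(train, extractor),
         test = extract_features(test, extractor), model = NULL)
  }
}

#' Run a repeated-holdout classification experiment
#'
#' For each repeat: stratified 75/25 split, optional denoiser fit on the
#' training portion and applied to both portions, extractor fit on the
#' training portion, classifier trained and scored on the held-out
#' portion. No fitted component sees test data.
#'
#' @param data a [dataset_tensor()].
#' @param extractor `"svd"`, `"fisher"`, `"dct"` or `"glcm"`.
#' @param classifier a [classifier_spec()].
#' @param denoise logical: run the periodic-noise removal stage.
#' @param denoise_refit `"per_repeat"` (default; the denoiser is refit on
#'   every repeat's training portion) or `"once"` (fit on the first
#'   repeat's training portion and reused, a speed option).
#' @param denoise_control list of arguments passed to [fit_noise_params()]
#'   (e.g. `K`, `i1_grid`, `scorer`), or a prefitted [noise_params()] to
#'   skip the search.
#' @param repeats number of random splits (default 10).
#' @param test_fraction held-out fraction (default 0.25).
#' @param seed base seed; repeat r uses a derived child seed.
#' @param k,ridge extractor settings.
#' @return an [experiment_result()].
#' @export
run_experiment <- function(data, extractor = "svd",
                           classifier = classifier_spec("lr"),
                           denoise = FALSE,
                           denoise_refit = c("per_repeat", "once"),
                           denoise_control = list(),
                           repeats = 10L, test_fraction = 0.25, seed = 1L,
                           k = 45L, ridge = 1e-3) {
  denoise_refit <- match.arg(denoise_refit)
  if (length(unique(data$labels)) < 2) stop("need at least 2 classes")
  train_acc <- numeric(repeats); test_acc <- numeric(repeats)
  classes <- sort(unique(data$labels))
  conf <- matrix(0L, length(classes), length(classes),
                 dimnames = list(classes, classes))
  params <- if (inherits(denoise_control, "noise_params")) denoise_control else NULL
  for (r in seq_len(repeats)) {
    sp <- stratified_split(data$labels, test_fraction, derive_seed(seed, r))
    tr <- subset_tensor(data, sp$train)
    te <- subset_tensor(data, sp$test)
    if (denoise) {
      if (is.null(params) || denoise_refit == "per_repeat") {
        ctrl <- denoise_control
        ctrl$train <- tr
        if (is.null(ctrl$seed)) ctrl$seed <- derive_seed(seed, 500L + r)
        params <- do.call(fit_noise_params, ctrl)$params
      }
      tr <- denoise_dataset(tr, params)
      te <- denoise_dataset(te, params)
    }
    ft <- fit_transform(tr, te, extractor, k = k, ridge = ridge)
    cls <- classifier; cls$seed <- derive_seed(seed, 900L + r)
    model <- har_train(cls, ft$train)
    pred_tr <- har_predict(model, ft$train)
    pred_te <- har_predict(model, ft$test)
    train_acc[r] <- accuracy_of(pred_tr, ft$train$labels)
    test_acc[r] <- accuracy_of(pred_te, ft$test$labels)
    conf <- conf + as.matrix(confusion_matrix(pred_te, ft$test$labels, classes))
  }
  experiment_result(train_acc, test_acc, conf,
                    config = list(extractor = extractor,
                                  classifier = classifier$family,
                                  denoise = denoise,
                                  denoise_refit = denoise_refit,
                                  denoise_params = if (denoise) params else NULL,
                                  repeats = repeats,
                                  test_fraction = test_fraction, seed = seed))
}

#' Noise-reduction A/B comparison
#'
#' Runs the same repeated-holdout experiment twice with identical splits
#' and seeds, once without and once with the periodic-noise removal stage,
#' and reports the paired results and accuracy delta.
#'
#' @inheritParams run_experiment
#' @return list with `off`, `on` ([experiment_result()]s) and
#'   `delta = mean(on) - mean(off)`.
#' @export
ab_noise_test <- function(data, extractor = "svd",
                          classifier = classifier_spec("lr"),
                          denoise_refit = "per_repeat",
                          denoise_control = list(),
                          repeats = 10L, test_fraction = 0.25, seed = 1L,
                          k = 45L, ridge = 1e-3) {
  off <- run_experiment(data, extractor, classifier, denoise = FALSE,
                        repeats = repeats, test_fraction = test_fraction,
                        seed = seed, k = k, ridge = ridge)
  on <- run_experiment(data, extractor, classifier, denoise = TRUE,
                       denoise_refit = denoise_refit,
                       denoise_control = denoise_control,
                       repeats = repeats, test_fraction = test_fraction,
                       seed = seed, k = k, ridge = ridge)
  list(off = off, on = on, delta = on$mean - off$mean)
}

# Strip the layout letter so small/large single-subject codes align
# (AS3 and AL3 both become A3); other codes pass through.
harmonize_layout_labels <- function(labels) sub("^A[SL]", "A", labels)

#' Cross-layout transfer experiment
#'
#' Fits the whole pipeline on one layout's data and scores it on the
#' other's. Single-subject activity codes are harmonized across layouts
#' (AS3 and AL3 both map to A3) before the vocabulary check.
#'
#' @param train_data,test_data [dataset_tensor()]s from the two layouts.
#' @inheritParams run_experiment
#' @return an [experiment_result()] with a single repeat.
#' @export
cross_layout_test <- function(train_data, test_data, extractor = "glcm",
                              classifier = classifier_spec("lr"),
                              denoise = FALSE, denoise_control = list(),
                              seed = 1L, k = 45L, ridge = 1e-3) {
  train_data$labels <- harmonize_layout_labels(train_data$labels)
  test_data$labels <- harmonize_layout_labels(test_data$labels)
  if (!setequal(unique(train_data$labels), unique(test_data$labels)))
    stop("label vocabularies differ between layouts")
  if (denoise) {
    ctrl <- denoise_control
    ctrl$train <- train_data
    if (is.null(ctrl$seed)) ctrl$seed <- seed
    params <- do.call(fit_noise_params, ctrl)$params
    train_data <- denoise_dataset(train_data, params)
    test_data <- denoise_dataset(test_data, params)
  }
  ft <- fit_transform(train_data, test_data, extractor, k = k, ridge = ridge)
  cls <- classifier; cls$seed <- seed
  model <- har_train(cls, ft$train)
  pred_tr <- har_predict(model, ft$train)
  pred_te <- har_predict(model, ft$test)
  classes <- sort(unique(c(train_data$labels, test_data$labels)))
  experiment_result(accuracy_of(pred_tr, ft$train$labels),
                    accuracy_of(pred_te, ft$test$labels),
                    as.matrix(confusion_matrix(pred_te, ft$test$labels, classes)),
                    config = list(extractor = extractor,
                                  classifier = classifier$family,
                                  protocol = "cross_layout"))
}

#' Sensor-subset comparison
#'
#' Evaluates the pipeline on every listed sensor subset. For multi-sensor
#' subsets, features are extracted per sensor (extractors fitted on the
#' training portion of that sensor's maps) and concatenated.
#'
#' @param records list of [activity_record()]s containing all listed
#'   sensors.
#' @param subsets list of character vectors of sensor ids.
#' @inheritParams run_experiment
#' @return named list of [experiment_result()]s, one per subset.
#' @export
sensor_subset_test <- function(records, subsets, extractor = "svd",
                               classifier = classifier_spec("lr"),
                               repeats = 5L, test_fraction = 0.25, seed = 1L,
                               k = 45L, ridge = 1e-3) {
  sensors <- unique(unlist(subsets))
  for (s in sensors) for (i in seq_along(records))
    if (!s %in% names(records[[i]]$streams))
      stop("record ", i, " is missing sensor ", s)
  tensors <- lapply(sensors, function(s) build_dataset(records, s))
  names(tensors) <- sensors
  labels <- tensors[[1]]$labels
  out <- list()
  for (sub in subsets) {
    train_acc <- numeric(repeats); test_acc <- numeric(repeats)
    for (r in seq_len(repeats)) {
      sp <- stratified_split(labels, test_fraction, derive_seed(seed, r))
      ftr <- list(); fte <- list()
      for (s in sub) {
        tr <- subset_tensor(tensors[[s]], sp$train)
        te <- subset_tensor(tensors[[s]], sp$test)
        ft <- fit_transform(tr, te, extractor, k = k, ridge = ridge)
        ftr[[s]] <- ft$train$X; fte[[s]] <- ft$test$X
      }
      f_train <- feature_matrix(do.call(cbind, ftr), labels[sp$train])
      f_test <- feature_matrix(do.call(cbind, fte), labels[sp$test])
      cls <- classifier; cls$seed <- derive_seed(seed, 900L + r)
      model <- har_train(cls, f_train)
      train_acc[r] <- accuracy_of(har_predict(model, f_train), f_train$labels)
      test_acc[r] <- accuracy_of(har_predict(model, f_test), f_test$labels)
    }
    nm <- paste(sub, collapse = "+")
    out[[nm]] <- experiment_result(train_acc, test_acc, NULL,
                                   config = list(sensors = sub,
                                                 extractor = extractor,
                                                 classifier = classifier$family))
  }
  out
}
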