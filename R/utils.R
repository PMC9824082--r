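# Internal helpers shared across modules.

#' Evaluate code with a temporarily seeded RNG
#'
#' Saves and restores the global RNG state so that seeded package internals
#' do not perturb the caller's random stream.
#'
#' @param seed integer seed, or NULL for no seeding.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed and a counter, kept within 32-bit range.
derive_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(counter) * 104729) %% 2147483587L)
}

#' Stratified fold assignment
#'
#' Assigns each sample to one of `K` folds, balancing class membership
#' across folds. Deterministic given `seed`.
#'
#' @param labels vector of class labels.
#' @param K number of folds.
#' @param seed integer seed for the shuffling.
#' @return integer vector of fold ids in 1..K.
#' @export
stratified_folds <- function(labels, K, seed = 1L) {
  labels <- as.character(labels)
  n <- length(labels)
  if (n < K) stop("fewer samples (", n, ") than folds (", K, ")")
  fold <- integer(n)
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(sample.int(K), length(idx))
    }
  })
  fold
}

# Stratified train/test split; the total test size is round(Z * fraction),
# apportioned to classes by largest remainder so e.g. 25% of 480 is exactly
# 120. Returns list(train=idx, test=idx).
stratified_split <- function(labels, test_fraction, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  labels <- as.character(labels)
  classes <- unique(labels)
  n_c <- vapply(classes, function(cl) sum(labels == cl), integer(1))
  quota <- n_c * test_fraction
  take <- pmax(1L, floor(quota))
  short <- round(length(labels) * test_fraction) - sum(take)
  if (short > 0) {
    extra <- order(quota - floor(quota), decreasing = TRUE)[seq_len(short)]
    take[extra] <- take[extra] + 1L
  }
  test <- integer(0)
  with_seed(seed, {
    for (ci in seq_along(classes)) {
      idx <- which(labels == classes[ci])
      test <- c(test, sample(idx, min(take[ci], length(idx) - 1L)))
    }
  })
  list(train = setdiff(seq_along(labels), test), test = sort(test))
}

# Classification accuracy.
accuracy_of <- function(pred, truth) mean(as.character(pred) == as.character(truth))

#' Confusion matrix
#'
#' @param pred predicted labels.
#' @param truth reference labels.
#' @param classes optional fixed class ordering.
#' @return a square integer matrix with truth in rows, prediction in columns.
#' @export
confusion_matrix <- function(pred, truth, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(c(as.character(pred), as.character(truth))))
  table(factor(as.character(truth), levels = classes),
        factor(as.character(pred), levels = classes))
}
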