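# Handcrafted feature extraction from (denoised) spatiotemporal maps:
# SVD subspace projection, Fisher canonical variables, block 2D-DCT zigzag
# coefficients, and patchwise GLCM texture statistics.

#' Feature matrix container
#'
#' @param X numeric matrix, samples in rows.
#' @param labels class label per row.
#' @param extractor short tag naming the extractor.
#' @param model fitted extractor state, if any.
#' @return an object of class `feature_matrix`.
#' @export
feature_matrix <- function(X, labels, extractor = NA_character_, model = NULL) {
  X <- as.matrix(X)
  if (nrow(X) != length(labels)) stop("one label per feature row required")
  if (!all(is.finite(X))) stop("non-finite feature values")
  structure(list(X = X, labels = as.character(labels),
                 extractor = extractor, model = model),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix>", nrow(x$X), "samples x", ncol(x$X),
      "features |", x$extractor, "\n")
  invisible(x)
}

## ---- SVD subspace -----------------------------------------------------

#' Fit an SVD subspace model
#'
#' Mean-centers the flattened maps (Z x 2560) and retains the first `k`
#' right singular vectors, the directions of highest variance. The
#' default k = 45 captures well over 95% of the variance on datasets of
#' this kind.
#'
#' @param train a [dataset_tensor()].
#' @param k subspace dimension (default 45); must satisfy
#'   `k <= min(Z, 2560)`.
#' @return an object of class `subspace_model` with orthonormal `basis`
#'   (2560 x k), `center`, singular values and explained-variance
#'   fractions.
#' @export
svd_fit <- function(train, k = 45L) {
  X <- flatten_maps(train)
  k <- as.integer(k)
  if (k > min(nrow(X), ncol(X)))
    stop("k = ", k, " exceeds min(Z, D) = ", min(nrow(X), ncol(X)))
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  sv <- svd(Xc, nu = 0, nv = k)
  var_frac <- sv$d^2 / sum(sv$d^2)
  structure(list(kind = "svd", basis = sv$v, center = center, k = k,
                 singular_values = sv$d,
                 explained = cumsum(var_frac)[k],
                 var_fractions = var_frac),
            class = "subspace_model")
}

#' @export
print.subspace_model <- function(x, ...) {
  cat("<subspace_model>", x$kind, "-", ncol(x$basis), "components")
  if (x$kind == "svd") cat(sprintf(" (%.1f%% variance)", 100 * x$explained))
  cat("\n")
  invisible(x)
}

#' Project maps onto a fitted subspace
#'
#' Test data are centered with the training mean before projection.
#'
#' @param model a `subspace_model` from [svd_fit()] or [fisher_fit()].
#' @param data a [dataset_tensor()].
#' @return a [feature_matrix()] of dimension Z x k (SVD) or Z x (Q-1)
#'   (Fisher).
#' @export
subspace_transform <- function(model, data) {
  X <- flatten_maps(data)
  if (ncol(X) != nrow(model$basis))
    stop("feature dimension ", ncol(X), " does not match model (",
         nrow(model$basis), ")")
  Z <- sweep(X, 2, model$center) %*% model$basis
  feature_matrix(Z, data$labels, extractor = model$kind, model = model)
}

#' @rdname subspace_transform
#' @export
svd_transform <- function(model, data) {
  stopifnot(model$kind == "svd")
  subspace_transform(model, data)
}

## ---- Fisher canonical variables ---------------------------------------

#' Fit Fisher canonical variables
#'
#' Solves the generalized eigenproblem of between-class versus
#' (within-class + ridge) scatter and keeps up to Q-1 components sorted by
#' eigenvalue, Q the number of classes. With ~2560 variables and tens of
#' samples per class the within-class scatter is severely singular, so it
#' is ridge-regularized (`lambda = ridge * tr(Sw)/r`). The computation is
#' carried out in the orthonormal basis spanning the centered training
#' data, which is exactly equivalent to the full-dimensional problem
#' because both scatter matrices vanish on its orthogonal complement.
#'
#' @param train a [dataset_tensor()] with >= 2 classes and >= 2 samples
#'   per class.
#' @param ridge regularization scale relative to the mean within-class
#'   variance (default 1e-3).
#' @return a `subspace_model` with `basis` (2560 x (Q-1)) and the
#'   generalized eigenvalues.
#' @export
fisher_fit <- function(train, ridge = 1e-3) {
  X <- flatten_maps(train)
  y <- factor(train$labels)
  Q <- nlevels(y)
  if (Q < 2) stop("Fisher canonical variables need at least 2 classes")
  if (any(table(y) < 2)) stop("every class needs at least 2 samples")
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  r <- min(nrow(Xc) - 1L, ncol(Xc))
  sv <- svd(Xc, nu = 0, nv = r)
  keep <- sv$d[seq_len(r)] > max(sv$d) * 1e-10
  B <- sv$v[, keep, drop = FALSE]          # orthonormal data-span basis
  Tm <- Xc %*% B                           # Z x r coordinates
  r <- ncol(B)
  Sb <- matrix(0, r, r); Sw <- matrix(0, r, r)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    m <- colMeans(Tm[idx, , drop = FALSE])
    Sb <- Sb + length(idx) * tcrossprod(m)
    Wc <- sweep(Tm[idx, , drop = FALSE], 2, m)
    Sw <- Sw + crossprod(Wc)
  }
  lambda <- ridge * sum(diag(Sw)) / r
  if (lambda <= 0) lambda <- ridge
  R <- chol(Sw + diag(lambda, r))
  # symmetric whitened problem: M = R^-T Sb R^-1
  A <- forwardsolve(t(R), Sb)
  M <- t(forwardsolve(t(R), t(A)))
  eig <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ncomp <- min(Q - 1L, r)
  W <- backsolve(R, eig$vectors[, seq_len(ncomp), drop = FALSE])
  structure(list(kind = "fisher", basis = B %*% W, center = center,
                 eigenvalues = eig$values[seq_len(ncomp)],
                 ridge = ridge, lambda = lambda, Q = Q),
            class = "subspace_model")
}

#' @rdname subspace_transform
#' @export
fisher_transform <- function(model, data) {
  stopifnot(model$kind == "fisher")
  subspace_transform(model, data)
}

## ---- Block 2D-DCT -----------------------------------------------------

# Orthonormal type-II DCT matrix of order n.
dct_matrix <- function(n = 8L) {
  k <- 0:(n - 1)
  C <- sqrt(2 / n) * cos(pi * outer(k, 2 * k + 1) / (2 * n))
  C[1, ] <- C[1, ] / sqrt(2)
  C
}

# First `m` (row, col) index pairs of the standard JPEG zigzag scan of an
# n x n block, starting at the DC corner.
zigzag_indices <- function(n = 8L, m = 6L) {
  ord <- order(outer(0:(n - 1), 0:(n - 1), "+"),
               outer(0:(n - 1), 0:(n - 1), function(r, c)
                 ifelse((r + c) %% 2 == 0, -r, r)))
  arr <- arrayInd(ord, c(n, n))
  arr[seq_len(m), , drop = FALSE]
}

#' Block 2D-DCT zigzag features
#'
#' Tiles the 40x64 map into 40 non-overlapping 8x8 patches (5 time-blocks x
#' 8 pixel-blocks, row-major patch order), applies the orthonormal type-II
#' 2D DCT to each patch, and keeps the first 6 coefficients of the JPEG
#' zigzag scan (DC first), concatenated in patch order.
#'
#' @param map an [st_map()] or 40x64 matrix.
#' @return numeric feature vector of length 240.
#' @export
dct_features <- function(map) {
  map <- unclass(as.matrix(map))
  if (!all(dim(map) == c(40L, 64L))) stop("map must be 40x64")
  C <- dct_matrix(8L)
  zz <- zigzag_indices(8L, 6L)
  out <- numeric(40L * 6L)
  at <- 1L
  for (pr in 1:5) for (pc in 1:8) {
    patch <- map[(8 * pr - 7):(8 * pr), (8 * pc - 7):(8 * pc)]
    D <- C %*% patch %*% t(C)
    out[at:(at + 5L)] <- D[zz]
    at <- at + 6L
  }
  out
}

## ---- GLCM texture statistics ------------------------------------------

# Quantize a matrix to `levels` gray levels by per-map min-max scaling.
quantize_levels <- function(map, levels = 8L) {
  rng <- range(map)
  if (diff(rng) == 0) return(matrix(1L, nrow(map), ncol(map)))
  q <- floor((map - rng[1]) / diff(rng) * levels) + 1L
  q[q > levels] <- levels
  q
}

# Symmetric normalized co-occurrence matrix of quantized patch `q` at
# offset (dr, dc) in (time, pixel) steps.
glcm_matrix <- function(q, dr, dc, levels) {
  n <- nrow(q); m <- ncol(q)
  rows <- seq_len(n); cols <- seq_len(m)
  r1 <- rows[rows + dr >= 1 & rows + dr <= n]
  c1 <- cols[cols + dc >= 1 & cols + dc <= m]
  a <- as.vector(q[r1, c1])
  b <- as.vector(q[r1 + dr, c1 + dc])
  G <- matrix(0, levels, levels)
  for (i in seq_along(a)) G[a[i], b[i]] <- G[a[i], b[i]] + 1
  G <- G + t(G)                       # symmetric
  G / sum(G)
}

# correlation, contrast, dissimilarity, energy of a normalized GLCM.
glcm_statistics <- function(P) {
  L <- nrow(P)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  contrast <- sum(P * (i - j)^2)
  dissim <- sum(P * abs(i - j))
  energy <- sqrt(sum(P^2))
  mu_i <- sum(i * P); mu_j <- sum(j * P)
  s_i <- sqrt(sum((i - mu_i)^2 * P)); s_j <- sqrt(sum((j - mu_j)^2 * P))
  correlation <- if (s_i * s_j == 0) 0 else
    sum((i - mu_i) * (j - mu_j) * P) / (s_i * s_j)
  c(correlation = correlation, contrast = contrast,
    dissimilarity = dissim, energy = energy)
}

# Offsets (time step, pixel step) for the three angle conventions at
# distance d: 0 deg = along the 64-pixel axis, 90 deg = along the time
# axis, 45 deg = one step along each.
glcm_offset <- function(angle, d) {
  switch(as.character(angle),
         "0" = c(0L, d), "45" = c(d, d), "90" = c(d, 0L),
         stop("unsupported GLCM angle ", angle))
}

#' Patchwise GLCM texture features
#'
#' Quantizes the map to `levels` gray levels (per-map min-max scaling),
#' splits it into five 8x64 time-patches, and computes, for each patch x
#' distance {1, 3} x angle {0, 45, 90} degrees, a symmetric normalized
#' co-occurrence matrix and its correlation, contrast, dissimilarity and
#' energy, concatenated in (patch, distance, angle, statistic) order. A
#' constant map quantizes to a single level; its correlation is defined as
#' 0 by convention.
#'
#' @param map an [st_map()] or 40x64 matrix.
#' @param levels number of gray levels (default 8).
#' @return numeric feature vector of length 120.
#' @export
glcm_features <- function(map, levels = 8L) {
  map <- unclass(as.matrix(map))
  if (!all(dim(map) == c(40L, 64L))) stop("map must be 40x64")
  q <- quantize_levels(map, levels)
  out <- numeric(5L * 2L * 3L * 4L)
  at <- 1L
  for (p in 1:5) {
    patch <- q[(8 * p - 7):(8 * p), ]
    for (d in c(1L, 3L)) for (ang in c(0, 45, 90)) {
      off <- glcm_offset(ang, d)
      G <- glcm_matrix(patch, off[1], off[2], levels)
      out[at:(at + 3L)] <- glcm_statistics(G)
      at <- at + 4L
    }
  }
  out
}

## ---- Dispatcher --------------------------------------------------------

#' Extract features from a dataset with a named extractor
#'
#' Stateless extractors (`"dct"`, `"glcm"`) are applied per map; subspace
#' extractors (`"svd"`, `"fisher"`) must be fitted on training data first
#' (pass `model`, or training data via `fit_on`).
#'
#' @param data a [dataset_tensor()].
#' @param extractor `"svd"`, `"fisher"`, `"dct"` or `"glcm"`.
#' @param model optional fitted `subspace_model`.
#' @param fit_on optional training [dataset_tensor()] to fit on.
#' @param k SVD dimension when fitting.
#' @param ridge Fisher regularization when fitting.
#' @return a [feature_matrix()].
#' @export
extract_features <- function(data, extractor = c("svd", "fisher", "dct", "glcm"),
                             model = NULL, fit_on = NULL, k = 45L, ridge = 1e-3) {
  extractor <- match.arg(extractor)
  if (extractor %in% c("svd", "fisher")) {
    if (is.null(model)) {
      if (is.null(fit_on)) stop(extractor, " features require a fitted model or fit_on data")
      model <- if (extractor == "svd") svd_fit(fit_on, k = k)
               else fisher_fit(fit_on, ridge = ridge)
    }
    return(subspace_transform(model, data))
  }
  f <- if (extractor == "dct") dct_features else glcm_features
  X <- t(vapply(seq_len(n_samples(data)),
                function(i) f(data$maps[i, , ]),
                numeric(if (extractor == "dct") 240L else 120L)))
  feature_matrix(X, data$labels, extractor = extractor)
}
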