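# Supervised periodic-noise removal in the 2D Fourier domain.
#
# Axis-aligned periodic noise in a 40x64 spatiotemporal map (vertical
# stripes from pixels that never change; horizontal stripes from
# near-identical consecutive frames) concentrates as symmetric peak pairs
# on the central horizontal and vertical stripes of the shifted power
# spectrum. The algorithm thresholds the log-power values on each stripe
# with a per-image threshold T = mu + i1*0.5*sigma, suppresses the top
# pairs above it by rescaling their complex magnitude down to the stripe
# mean (phase preserved, both mirror members together so the inverse stays
# real), inverts each direction separately, and averages the two inverse
# transforms. The integer grid index i1 and the pair counts are learned by
# K-fold cross-validation against downstream classification accuracy.
#
# Index conventions: spectra are stored shifted, with the zero-frequency
# (DC) coefficient at row 21, column 33 (1-based) of the 40x64 array. The
# horizontal stripe is row 21 (63 non-DC cells, 31 symmetric pairs), the
# vertical stripe is column 33 (39 non-DC cells, 19 pairs).

DC_ROW <- 21L
DC_COL <- 33L
MAX_PAIRS_H <- 31L  # horizontal stripe: offsets 1..31 about DC (column 1 is unpaired Nyquist)
MAX_PAIRS_V <- 19L  # vertical stripe: offsets 1..19 (row 1 unpaired)

# Swap quadrants so DC moves from [1,1] to [DC_ROW, DC_COL] (even sizes).
fftshift2 <- function(m) {
  M <- nrow(m); N <- ncol(m)
  m[c((M / 2 + 1):M, 1:(M / 2)), c((N / 2 + 1):N, 1:(N / 2))]
}
ifftshift2 <- fftshift2  # self-inverse for even dimensions

#' Centered 2D discrete Fourier transform of a spatiotemporal map
#'
#' @param map a 40x64 [st_map()] or numeric matrix, all finite.
#' @return an object of class `lrir_spectrum` holding the shifted complex
#'   coefficient matrix `F` (DC at row 21, column 33) and the source
#'   dimensions. The DC coefficient equals the sum of all map values.
#' @export
dft2 <- function(map) {
  map <- unclass(as.matrix(map))
  if (!all(is.finite(map))) stop("map must be finite")
  structure(list(F = fftshift2(stats::fft(map)), M = nrow(map), N = ncol(map)),
            class = "lrir_spectrum")
}

#' Inverse of [dft2()]
#'
#' @param spec an `lrir_spectrum`.
#' @return the real-valued map (imaginary residue of the inverse transform
#'   is checked to be numerically negligible and discarded).
#' @export
idft2 <- function(spec) {
  x <- stats::fft(ifftshift2(spec$F), inverse = TRUE) / (spec$M * spec$N)
  Re(x)
}

#' Log power spectrum
#'
#' Elementwise `log(1 + |F|)` of the shifted spectrum; the +1 offset keeps
#' exact-zero coefficients finite.
#'
#' @param spec an `lrir_spectrum`.
#' @return a real matrix of the spectrum's dimensions.
#' @export
power_spectrum <- function(spec) log1p(Mod(spec$F))

#' Mean and standard deviation of the central stripes
#'
#' Computes `mu_h`/`sigma_h` over the central horizontal stripe (row 21
#' excluding DC, 63 cells) and `mu_v`/`sigma_v` over the central vertical
#' stripe (column 33 excluding DC, 39 cells) of a log power spectrum.
#'
#' @param P log power spectrum matrix (40x64).
#' @return list with `mu_h`, `sigma_h`, `mu_v`, `sigma_v`.
#' @export
stripe_stats <- function(P) {
  h <- P[DC_ROW, -DC_COL]
  v <- P[-DC_ROW, DC_COL]
  list(mu_h = mean(h), sigma_h = stats::sd(h),
       mu_v = mean(v), sigma_v = stats::sd(v))
}

#' Symmetric peak pairs on a central stripe
#'
#' Enumerates the pairs of stripe cells mirrored about DC (offsets `d` and
#' `-d`), scores each pair by the mean log power of its two members, and
#' returns those whose score exceeds `T`, sorted by score descending with
#' ties broken toward the pair nearer DC. DC itself is never included.
#'
#' @param P log power spectrum matrix (40x64).
#' @param direction `"horizontal"` (row 21, offsets 1..31) or `"vertical"`
#'   (column 33, offsets 1..19).
#' @param T threshold on the pair score; use `-Inf` to list all pairs.
#' @return data.frame with columns `offset` and `value`, possibly empty.
#' @export
find_peak_pairs <- function(P, direction = c("horizontal", "vertical"), T = -Inf) {
  direction <- match.arg(direction)
  if (is.na(T)) stop("threshold must not be NA")
  if (direction == "horizontal") {
    d <- seq_len(MAX_PAIRS_H)
    val <- (P[DC_ROW, DC_COL + d] + P[DC_ROW, DC_COL - d]) / 2
  } else {
    d <- seq_len(MAX_PAIRS_V)
    val <- (P[DC_ROW + d, DC_COL] + P[DC_ROW - d, DC_COL]) / 2
  }
  keep <- val > T
  out <- data.frame(offset = d[keep], value = val[keep])
  out[order(-out$value, out$offset), , drop = FALSE]
}

# Rescale both members of each listed pair so their log(1+|.|) magnitude
# equals target_log, preserving phase (and hence Hermitian symmetry).
suppress_stripe <- function(F, direction, offsets, target_log) {
  target_mag <- expm1(target_log)
  for (d in offsets) {
    cells <- if (direction == "horizontal")
      list(c(DC_ROW, DC_COL + d), c(DC_ROW, DC_COL - d))
    else
      list(c(DC_ROW + d, DC_COL), c(DC_ROW - d, DC_COL))
    for (cc in cells) {
      z <- F[cc[1], cc[2]]
      F[cc[1], cc[2]] <- if (Mod(z) == 0) complex(real = target_mag)
                         else target_mag * z / Mod(z)
    }
  }
  F
}

#' Suppress selected peak pairs and invert
#'
#' Rescales the top `num_h` pairs of the central horizontal stripe to the
#' horizontal stripe mean (removing vertical periodic noise) and the top
#' `num_v` pairs of the central vertical stripe to the vertical stripe
#' mean (removing horizontal periodic noise), then inverts the modified
#' spectrum. The two stripes are disjoint coefficient sets, so this joint
#' suppression equals merging the fully-suppressed direction-specific
#' inverse images; suppression preserves phase and both mirror members, so
#' the inverse stays real. With `num_h = num_v = 0` the input map is
#' returned unchanged (to numerical precision). DC is never touched, so
#' the map mean is preserved exactly.
#'
#' @param spec an `lrir_spectrum`.
#' @param pairs_h,pairs_v pair tables from [find_peak_pairs()] for the
#'   horizontal and vertical stripes (already sorted).
#' @param stats stripe statistics from [stripe_stats()].
#' @param num_h,num_v how many of the leading pairs to suppress on each
#'   stripe; must not exceed the number of available pairs.
#' @return the denoised map as a plain 40x64 matrix.
#' @export
suppress_and_invert <- function(spec, pairs_h, pairs_v, stats, num_h, num_v) {
  if (num_h > nrow(pairs_h))
    stop("num_h (", num_h, ") exceeds available horizontal pairs (", nrow(pairs_h), ")")
  if (num_v > nrow(pairs_v))
    stop("num_v (", num_v, ") exceeds available vertical pairs (", nrow(pairs_v), ")")
  F <- suppress_stripe(spec$F, "horizontal",
                       utils::head(pairs_h$offset, num_h), stats$mu_h)
  F <- suppress_stripe(F, "vertical",
                       utils::head(pairs_v$offset, num_v), stats$mu_v)
  idft2(structure(list(F = F, M = spec$M, N = spec$N), class = "lrir_spectrum"))
}

#' Fitted noise-removal parameters
#'
#' @param i1_h,i1_v selected threshold grid indices (threshold
#'   `T = mu + i1*0.5*sigma` is recomputed per image at apply time).
#' @param num_h,num_v selected pair counts for the horizontal and vertical
#'   stripes.
#' @param K,i1_grid,num_grid_h,num_grid_v,seed provenance of the search.
#' @return an object of class `noise_params`.
#' @export
noise_params <- function(i1_h, i1_v, num_h, num_v, K = NA_integer_,
                         i1_grid = NULL, num_grid_h = NULL, num_grid_v = NULL,
                         seed = NA_integer_) {
  stopifnot(num_h >= 0, num_h <= MAX_PAIRS_H, num_v >= 0, num_v <= MAX_PAIRS_V)
  structure(list(i1_h = i1_h, i1_v = i1_v,
                 num_h = as.integer(num_h), num_v = as.integer(num_v),
                 K = K, i1_grid = i1_grid, num_grid_h = num_grid_h,
                 num_grid_v = num_grid_v, seed = seed),
            class = "noise_params")
}

#' @export
print.noise_params <- function(x, ...) {
  cat("<noise_params> horizontal stripe: i1* =", x$i1_h, ", Num* =", x$num_h,
      "| vertical stripe: i1* =", x$i1_v, ", Num* =", x$num_v, "\n")
  invisible(x)
}

#' Save / load noise parameters as a JSON sidecar
#' @param params a [noise_params()].
#' @param path JSON file path.
#' @return `path` (write) or a [noise_params()] (read).
#' @export
write_noise_params <- function(params, path) {
  jsonlite::write_json(unclass(params)[c("i1_h", "i1_v", "num_h", "num_v", "K", "seed")],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_noise_params
#' @export
read_noise_params <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  noise_params(p$i1_h, p$i1_v, p$num_h, p$num_v, K = p$K, seed = p$seed)
}

#' Denoise one spatiotemporal map with fitted parameters
#'
#' Stripe statistics and peak pairs are recomputed from the map itself
#' (thresholds are per-image); the learned grid index and pair counts are
#' global. On each stripe the leading `min(Num*, pairs above threshold)`
#' pairs are suppressed.
#'
#' @param map an [st_map()] or 40x64 matrix.
#' @param params a [noise_params()].
#' @return the denoised map (metadata attributes preserved when present).
#' @export
denoise_map <- function(map, params) {
  spec <- dft2(map)
  P <- power_spectrum(spec)
  st <- stripe_stats(P)
  th <- st$mu_h + params$i1_h * 0.5 * st$sigma_h
  tv <- st$mu_v + params$i1_v * 0.5 * st$sigma_v
  ph <- find_peak_pairs(P, "horizontal", th)
  pv <- find_peak_pairs(P, "vertical", tv)
  out <- suppress_and_invert(spec, ph, pv, st,
                             min(params$num_h, nrow(ph)),
                             min(params$num_v, nrow(pv)))
  if (inherits(map, "st_map")) {
    st_map(out, label = attr(map, "label"), subjects = attr(map, "subjects"),
           layout = attr(map, "layout"), sensor_id = attr(map, "sensor_id"))
  } else out
}

#' Denoise every map of a dataset tensor
#'
#' @param data a [dataset_tensor()].
#' @param params fitted [noise_params()].
#' @return a [dataset_tensor()] of identical shape.
#' @export
denoise_dataset <- function(data, params) {
  out <- data$maps
  for (i in seq_len(n_samples(data)))
    out[i, , ] <- denoise_map(data$maps[i, , ], params)
  dataset_tensor(out, data$labels, subjects = data$subjects,
                 layout = data$layout, sensor_id = data$sensor_id)
}

#' CV scorers for the noise-parameter search
#'
#' Both scorers project the flattened (denoised) maps onto the leading SVD
#' subspace fitted on the training fold and classify with a linear model:
#' `scorer_svd_linear` uses linear discriminant analysis (fast; the default
#' for the grid search), `scorer_svd_lr` uses multinomial logistic
#' regression with a quasi-Newton optimizer (the downstream model of the
#' full pipeline).
#'
#' @param Xtr,Xval flattened map matrices (rows = samples).
#' @param ytr,yval class labels.
#' @param k SVD subspace dimension (capped at the training rank).
#' @return list with `train` and `val` accuracies.
#' @export
scorer_svd_linear <- function(Xtr, ytr, Xval, yval, k = 45L) {
  k <- min(k, nrow(Xtr) - 1L, ncol(Xtr))
  ctr <- colMeans(Xtr)
  Xc <- sweep(Xtr, 2, ctr)
  V <- svd(Xc, nu = 0, nv = k)$v
  Ztr <- Xc %*% V
  Zval <- sweep(Xval, 2, ctr) %*% V
  fit <- suppressWarnings(MASS::lda(Ztr, grouping = factor(ytr)))
  list(train = accuracy_of(stats::predict(fit, Ztr)$class, ytr),
       val = accuracy_of(stats::predict(fit, Zval)$class, yval))
}

#' @rdname scorer_svd_linear
#' @export
scorer_svd_lr <- function(Xtr, ytr, Xval, yval, k = 45L) {
  k <- min(k, nrow(Xtr) - 1L, ncol(Xtr))
  ctr <- colMeans(Xtr)
  Xc <- sweep(Xtr, 2, ctr)
  V <- svd(Xc, nu = 0, nv = k)$v
  dtr <- data.frame(y = factor(ytr), Xc %*% V)
  dval <- data.frame(sweep(Xval, 2, ctr) %*% V)
  fit <- nnet::multinom(y ~ ., dtr, trace = FALSE, maxit = 200, MaxNWts = 1e5)
  list(train = accuracy_of(stats::predict(fit, dtr), ytr),
       val = accuracy_of(stats::predict(fit, dval), yval))
}

#' Learn noise-removal parameters by cross-validated grid search
#'
#' Runs the supervised search over the threshold grid (`T = mu +
#' i1*0.5*sigma` per image) and the pair-count candidates, independently
#' for the horizontal and vertical stripes. For each fold and candidate
#' cell the training images are denoised (that direction only), a
#' downstream classifier is fitted on the training fold and scored on the
#' validation fold, and validation accuracies are averaged over folds.
#' A cell `(i1, num)` is feasible only if every image has at least `num`
#' pairs exceeding its own threshold; infeasible cells are masked and
#' ignored. Because pairs above a threshold are a prefix of the
#' value-sorted pair list, the candidate denoising depends only on `num`;
#' `i1` acts through the feasibility mask. Ties in mean validation accuracy
#' resolve toward fewer suppressed pairs, then toward the higher threshold.
#'
#' @param train a [dataset_tensor()] of training maps.
#' @param scorer scoring function, see [scorer_svd_linear()].
#' @param K number of CV folds (default 10).
#' @param i1_grid integer threshold grid (default -2..8).
#' @param num_grid_h,num_grid_v candidate pair counts (defaults 1..31 and
#'   1..19).
#' @param seed seed for the stratified fold assignment.
#' @return list with `params` (a [noise_params()]) and `performance`, the
#'   per-direction K x |i1_grid| x |num_grid| validation and training
#'   accuracy tensors with `NA` marking infeasible cells, plus the
#'   fold-averaged 2D validation arrays.
#' @export
fit_noise_params <- function(train, scorer = scorer_svd_linear, K = 10L,
                             i1_grid = -2:8,
                             num_grid_h = seq_len(MAX_PAIRS_H),
                             num_grid_v = seq_len(MAX_PAIRS_V),
                             seed = 1L) {
  Z <- n_samples(train)
  if (Z < K) stop("need at least K = ", K, " samples")
  tab <- table(train$labels)
  if (any(tab < K))
    warning("some classes have fewer than K samples; stratification is relaxed")
  fold <- stratified_folds(train$labels, K, seed)

  # Per-image spectra, stripe stats and full sorted pair lists.
  specs <- vector("list", Z); Ps <- vector("list", Z); sts <- vector("list", Z)
  pairs <- list(h = vector("list", Z), v = vector("list", Z))
  for (i in seq_len(Z)) {
    specs[[i]] <- dft2(train$maps[i, , ])
    Ps[[i]] <- power_spectrum(specs[[i]])
    sts[[i]] <- stripe_stats(Ps[[i]])
    pairs$h[[i]] <- find_peak_pairs(Ps[[i]], "horizontal", -Inf)
    pairs$v[[i]] <- find_peak_pairs(Ps[[i]], "vertical", -Inf)
  }

  search_direction <- function(dir) {
    num_grid <- if (dir == "h") num_grid_h else num_grid_v
    plist <- pairs[[dir]]
    # pairs above threshold per image x i1 candidate
    n_above <- sapply(i1_grid, function(i1) vapply(seq_len(Z), function(j) {
      s <- sts[[j]]
      T <- if (dir == "h") s$mu_h + i1 * 0.5 * s$sigma_h
           else            s$mu_v + i1 * 0.5 * s$sigma_v
      sum(plist[[j]]$value > T)
    }, numeric(1)))
    n_above <- matrix(n_above, nrow = Z)
    feasible <- vapply(num_grid, function(i2)
      apply(n_above >= i2, 2, all), logical(length(i1_grid)))
    feasible <- matrix(feasible, nrow = length(i1_grid))  # |i1| x |num|

    val_t <- array(NA_real_, c(K, length(i1_grid), length(num_grid)))
    trn_t <- array(NA_real_, c(K, length(i1_grid), length(num_grid)))
    direction <- if (dir == "h") "horizontal" else "vertical"
    for (ni in seq_along(num_grid)) {
      if (!any(feasible[, ni])) next
      i2 <- num_grid[ni]
      Xd <- matrix(0, Z, specs[[1]]$M * specs[[1]]$N)
      for (j in seq_len(Z)) {
        mu <- if (dir == "h") sts[[j]]$mu_h else sts[[j]]$mu_v
        F <- suppress_stripe(specs[[j]]$F, direction,
                             utils::head(plist[[j]]$offset, i2), mu)
        Xd[j, ] <- as.vector(t(idft2(structure(list(F = F, M = specs[[j]]$M,
                                                    N = specs[[j]]$N),
                                               class = "lrir_spectrum"))))
      }
      for (kk in seq_len(K)) {
        tr <- fold != kk; va <- !tr
        sc <- scorer(Xd[tr, , drop = FALSE], train$labels[tr],
                     Xd[va, , drop = FALSE], train$labels[va])
        acc <- c(sc$train, sc$val)
        for (ii in which(feasible[, ni])) {
          trn_t[kk, ii, ni] <- acc[1]
          val_t[kk, ii, ni] <- acc[2]
        }
      }
    }
    mean_val <- apply(val_t, c(2, 3), mean)
    if (all(is.na(mean_val)))
      stop("no feasible (threshold, count) combination on the ", direction,
           " stripe; widen the i1 grid")
    # argmax; ties -> fewer pairs, then higher threshold (larger i1)
    cand <- which(!is.na(mean_val), arr.ind = TRUE)
    o <- order(-mean_val[cand], num_grid[cand[, 2]], -i1_grid[cand[, 1]])
    best <- cand[o[1], ]
    list(i1 = i1_grid[best[1]], num = num_grid[best[2]],
         val_tensor = val_t, train_tensor = trn_t, mean_val = mean_val)
  }

  rh <- search_direction("h")
  rv <- search_direction("v")
  list(params = noise_params(rh$i1, rv$i1, rh$num, rv$num, K = K,
                             i1_grid = i1_grid, num_grid_h = num_grid_h,
                             num_grid_v = num_grid_v, seed = seed),
       performance = list(horizontal = rh[c("val_tensor", "train_tensor", "mean_val")],
                          vertical = rv[c("val_tensor", "train_tensor", "mean_val")]))
}
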