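toy_tensor <- function(X, labels) {
  # wrap a Z x 2560 matrix as a dataset tensor (rows -> 40x64 maps)
  Z <- nrow(X)
  maps <- array(0, c(Z, 40, 64))
  for (i in seq_len(Z)) maps[i, , ] <- matrix(X[i, ], 40, 64, byrow = TRUE)
  dataset_tensor(maps, labels)
}

test_that("SVD recovers exact low-rank structure with an orthonormal basis", {
  set.seed(31)
  B <- qr.Q(qr(matrix(rnorm(2560 * 3), 2560, 3)))
  X <- matrix(rnorm(20 * 3), 20, 3) %*% t(B)
  d <- toy_tensor(X, rep(c("AL1", "AL2"), 10))
  m <- svd_fit(d, k = 3)
  expect_equal(m$explained, 1, tolerance = 1e-9)
  expect_equal(crossprod(m$basis), diag(3), tolerance = 1e-9)
  expect_error(svd_fit(d, k = 25), "exceeds")
})

test_that("projection reproduces the matrix product and centers with the training mean", {
  set.seed(32)
  X <- matrix(rnorm(20 * 2560), 20, 2560)
  d <- toy_tensor(X, rep(c("AL1", "AL2"), 10))
  m <- svd_fit(d, k = 5)
  f <- svd_transform(m, d)
  expect_equal(ncol(f$X), 5L)
  Xc <- sweep(lrirhar:::flatten_maps(d), 2, m$center)
  expect_equal(f$X, Xc %*% m$basis, tolerance = 1e-9)
  # the training mean map projects to the origin
  mean_map <- toy_tensor(matrix(m$center, 1), "AL1")
  expect_lt(max(abs(svd_transform(m, mean_map)$X)), 1e-8)
})

test_that("discarded singular values account exactly for the reconstruction error", {
  set.seed(33)
  X <- matrix(rnorm(20 * 2560), 20, 2560)
  d <- toy_tensor(X, rep(c("AL1", "AL2"), 10))
  k <- 4
  m <- svd_fit(d, k = k)
  Xc <- sweep(lrirhar:::flatten_maps(d), 2, m$center)
  resid <- Xc - (Xc %*% m$basis) %*% t(m$basis)
  expect_equal(sum(resid^2), sum(m$singular_values[-(1:k)]^2), tolerance = 1e-6)
})

test_that("Fisher components number Q-1 and separate well-separated classes", {
  set.seed(34)
  # two spherical Gaussian classes far apart in 2560 dims
  mu <- rnorm(2560) * 0.1
  delta <- rnorm(2560); delta <- 6 * delta / sqrt(sum(delta^2))
  X <- rbind(matrix(rnorm(15 * 2560, 0, 1), 15, 2560) + rep(mu + delta / 2, each = 15),
             matrix(rnorm(15 * 2560, 0, 1), 15, 2560) + rep(mu - delta / 2, each = 15))
  d <- toy_tensor(X, rep(c("AL1", "AL2"), each = 15))
  m <- fisher_fit(d)
  expect_equal(ncol(m$basis), 1L)
  f <- fisher_transform(m, d)
  g1 <- f$X[f$labels == "AL1", 1]; g2 <- f$X[f$labels == "AL2", 1]
  pooled_sd <- sqrt((var(g1) * (length(g1) - 1) + var(g2) * (length(g2) - 1)) /
                      (length(g1) + length(g2) - 2))
  expect_gt(abs(mean(g1) - mean(g2)), 5 * pooled_sd)
  # duplicate samples map to identical features
  dd <- toy_tensor(X[c(1, 1), ], c("AL1", "AL1"))
  ff <- fisher_transform(m, dd)
  expect_equal(ff$X[1, ], ff$X[2, ])
})

test_that("Fisher eigenvalues vanish when class means coincide, and Q classes give Q-1 axes", {
  set.seed(35)
  X <- matrix(rnorm(24 * 2560), 24, 2560)
  d <- toy_tensor(X, rep(c("AL1", "AL2", "AL3"), 8))  # random labels: no signal
  m <- fisher_fit(d)
  expect_equal(ncol(m$basis), 2L)
  # 15 classes (the combined single+double vocabulary size) -> 14 components
  d15 <- small15_maps()
  m15 <- fisher_fit(d15)
  expect_equal(ncol(m15$basis), 14L)
  expect_error(fisher_fit(toy_tensor(X[1:4, ], rep("AL1", 4))), "2 classes")
})

test_that("block DCT features have length 240 and match brute-force basis sums", {
  set.seed(36)
  m <- matrix(rnorm(40 * 64, 20, 3), 40, 64)
  f <- dct_features(m)
  expect_length(f, 240L)
  expect_equal(dct_features(matrix(0, 40, 64)), rep(0, 240))
  # constant patch: orthonormal DC is 8c, higher coefficients vanish
  cm <- matrix(2.5, 40, 64)
  fc <- dct_features(cm)
  expect_equal(unname(fc[seq(1, 240, by = 6)]), rep(8 * 2.5, 40), tolerance = 1e-9)
  expect_lt(max(abs(fc[-seq(1, 240, by = 6)])), 1e-9)
  # brute-force oracle on two arbitrary patches (patch order is row-major:
  # patch (pr, pc) occupies slots (8*(pr-1)+pc-1)*6 + 1..6)
  zig <- list(c(0, 0), c(0, 1), c(1, 0), c(2, 0), c(1, 1), c(0, 2))
  for (patch_id in c(1, 14)) {
    pr <- (patch_id - 1) %/% 8 + 1; pc <- (patch_id - 1) %% 8 + 1
    patch <- m[(8 * pr - 7):(8 * pr), (8 * pc - 7):(8 * pc)]
    for (j in 1:6) {
      expected <- brute_dct_coef(patch, zig[[j]][1], zig[[j]][2])
      expect_equal(f[(patch_id - 1) * 6 + j], expected, tolerance = 1e-9)
    }
  }
  # adding a constant moves only the per-patch DC slots
  f2 <- dct_features(m + 1.7)
  expect_equal(f2[-seq(1, 240, by = 6)], f[-seq(1, 240, by = 6)], tolerance = 1e-9)
  expect_true(all(abs(f2[seq(1, 240, by = 6)] - f[seq(1, 240, by = 6)]) > 1))
})

test_that("GLCM features have length 120 with valid ranges and a degenerate convention", {
  set.seed(37)
  m <- matrix(rnorm(40 * 64, 20, 3), 40, 64)
  f <- glcm_features(m)
  expect_length(f, 120L)
  stat_idx <- function(s) seq(s, 120, by = 4)
  expect_true(all(f[stat_idx(1)] >= -1 & f[stat_idx(1)] <= 1))      # correlation
  expect_true(all(f[stat_idx(2)] >= 0))                             # contrast
  expect_true(all(f[stat_idx(3)] >= 0))                             # dissimilarity
  expect_true(all(f[stat_idx(4)] > 0 & f[stat_idx(4)] <= 1))        # energy
  fc <- glcm_features(matrix(5, 40, 64))
  expect_equal(unname(fc[stat_idx(2)]), rep(0, 30))
  expect_equal(unname(fc[stat_idx(3)]), rep(0, 30))
  expect_equal(unname(fc[stat_idx(4)]), rep(1, 30))
  expect_equal(unname(fc[stat_idx(1)]), rep(0, 30))  # correlation convention
})

test_that("GLCM statistics match exhaustive pair counting", {
  # two-level vertical stripe pattern, distance 1, angle 0
  stripe <- matrix(rep(c(10, 30), length.out = 64), 40, 64, byrow = TRUE)
  q <- lrirhar:::quantize_levels(stripe, 8L)
  patch_q <- q[1:8, ]
  expect_equal(lrirhar:::glcm_statistics(lrirhar:::glcm_matrix(patch_q, 0L, 1L, 8L)),
               brute_glcm_stats(brute_glcm(patch_q, 0L, 1L, 8L)), tolerance = 1e-12)
  # random patch, all configured offsets
  set.seed(38)
  m <- matrix(rnorm(40 * 64, 20, 3), 40, 64)
  qm <- lrirhar:::quantize_levels(m, 8L)
  patch_q <- qm[9:16, ]
  for (d in c(1L, 3L)) for (ang in c(0, 45, 90)) {
    off <- lrirhar:::glcm_offset(ang, d)
    expect_equal(
      lrirhar:::glcm_statistics(lrirhar:::glcm_matrix(patch_q, off[1], off[2], 8L)),
      brute_glcm_stats(brute_glcm(patch_q, off[1], off[2], 8L)),
      tolerance = 1e-12)
  }
  # and the packed vector agrees with direct per-slot computation
  f <- glcm_features(m)
  slot <- function(p, di, ai) (p - 1) * 24 + (di - 1) * 12 + (ai - 1) * 4 + 1:4
  off <- lrirhar:::glcm_offset(45, 3L)
  expect_equal(unname(f[slot(2, 2, 2)]),
               unname(brute_glcm_stats(brute_glcm(qm[9:16, ], off[1], off[2], 8L))),
               tolerance = 1e-12)
})

test_that("extractors are deterministic and expose the documented dimensions", {
  d <- small8()
  expect_equal(dim(extract_features(d, "dct")$X), c(n_samples(d), 240L))
  expect_equal(dim(extract_features(d, "glcm")$X), c(n_samples(d), 120L))
  f1 <- extract_features(d, "svd", fit_on = d, k = 10)
  f2 <- extract_features(d, "svd", fit_on = d, k = 10)
  expect_identical(f1$X, f2$X)
})
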