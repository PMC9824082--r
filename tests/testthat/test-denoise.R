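test_that("the centered transform matches a brute-force basis-sum evaluation", {
  set.seed(21)
  X <- matrix(rnorm(40 * 64, 20, 2), 40, 64)
  spec <- dft2(X)
  expect_equal(spec$F, brute_dft_shifted(X), tolerance = 1e-8)
  # DC anchored at (21, 33) and equal to the map sum
  expect_equal(spec$F[21, 33], complex(real = sum(X)), tolerance = 1e-9)
})

test_that("constant and single-frequency maps produce the expected spectra", {
  spec <- dft2(matrix(3, 40, 64))
  expect_equal(Mod(spec$F[21, 33]), 2560 * 3, tolerance = 1e-9)
  off_dc <- Mod(spec$F); off_dc[21, 33] <- 0
  expect_lt(max(off_dc), 1e-8)
  # pure horizontal-axis cosine: exactly one symmetric pair at offset 8
  X <- outer(rep(1, 40), cos(2 * pi * 8 * (0:63) / 64))
  A <- Mod(dft2(X)$F)
  expect_equal(A[21, 33 + 8], 1280, tolerance = 1e-6)
  expect_equal(A[21, 33 - 8], 1280, tolerance = 1e-6)
  A[21, c(33 - 8, 33 + 8)] <- 0
  expect_lt(max(A), 1e-6)
})

test_that("the inverse transform restores random maps to 1e-9", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(40 * 64, 18, 3), 40, 64)
    expect_equal(idft2(dft2(X)), X, tolerance = 1e-9)
  }
})

test_that("log power spectrum is zero-safe and monotone under scaling", {
  expect_equal(power_spectrum(dft2(matrix(0, 40, 64))), matrix(0, 40, 64))
  P <- power_spectrum(dft2(matrix(2, 40, 64)))
  expect_true(P[21, 33] > 0 && max(P[-21, ]) < 1e-8)
  set.seed(4)
  X <- matrix(rnorm(40 * 64, 10), 40, 64)
  expect_true(all(power_spectrum(dft2(3 * X)) >= power_spectrum(dft2(X)) - 1e-12))
})

test_that("stripe statistics exclude DC and match direct formulas", {
  P <- matrix(1, 40, 64)
  P[21, ] <- c(rep(2, 32), 99, rep(4, 31))  # DC = 99 must be ignored
  P[, 33] <- c(rep(3, 20), 99, rep(5, 19))
  P[21, 33] <- 99
  st <- stripe_stats(P)
  h <- c(rep(2, 32), rep(4, 31)); v <- c(rep(3, 20), rep(5, 19))
  expect_equal(st$mu_h, mean(h)); expect_equal(st$sigma_h, sd(h))
  expect_equal(st$mu_v, mean(v)); expect_equal(st$sigma_v, sd(v))
  P2 <- P; P2[21, 33] <- -50
  expect_equal(stripe_stats(P2), st)
  # constant stripe: sd 0
  P3 <- matrix(7, 40, 64)
  expect_equal(stripe_stats(P3)$sigma_h, 0)
})

test_that("planted peaks are found, ordered, and thresholded", {
  m <- flat_map(20, seed = 8)
  n1 <- inject_periodic_noise(m, noise_injection("vertical", freq_v = 10, amp_v = 4), seed = 1)
  n1 <- inject_periodic_noise(n1, noise_injection("vertical", freq_v = 21, amp_v = 2), seed = 2)
  P <- power_spectrum(dft2(unclass(n1)))
  st <- stripe_stats(P)
  pp <- find_peak_pairs(P, "horizontal", st$mu_h + 2 * st$sigma_h)
  expect_gte(nrow(pp), 2)
  expect_equal(pp$offset[1:2], c(10, 21))  # descending height order
  expect_true(all(diff(pp$value) <= 0))
  # threshold above the stripe maximum: nothing returned
  expect_equal(nrow(find_peak_pairs(P, "horizontal", max(P) + 1)), 0L)
})

test_that("suppression is the identity at zero counts and stays real", {
  set.seed(9)
  X <- matrix(rnorm(40 * 64, 19, 2), 40, 64)
  spec <- dft2(X)
  P <- power_spectrum(spec); st <- stripe_stats(P)
  ph <- find_peak_pairs(P, "horizontal"); pv <- find_peak_pairs(P, "vertical")
  expect_equal(suppress_and_invert(spec, ph, pv, st, 0, 0), X, tolerance = 1e-9)
  # realness under suppression: brute-force inverse has negligible imaginary part
  Fh <- lrirhar:::suppress_stripe(spec$F, "horizontal", ph$offset[1:5], st$mu_h)
  expect_lt(max(abs(Im(brute_idft(Fh)))), 1e-9)
  expect_error(suppress_and_invert(spec, ph, pv, st, 32, 0), "exceeds")
})

test_that("suppressing an injected frequency removes >= 90% of its energy, DC intact", {
  clean <- flat_map(20, seed = 3)
  noisy <- inject_periodic_noise(clean, noise_injection("vertical", freq_v = 12, amp_v = 3),
                                 seed = 5)
  spec <- dft2(unclass(noisy))
  P <- power_spectrum(spec); st <- stripe_stats(P)
  ph <- find_peak_pairs(P, "horizontal", st$mu_h + st$sigma_h)
  expect_equal(ph$offset[1], 12)
  out <- suppress_and_invert(spec, ph, find_peak_pairs(P, "vertical"), st, 1, 0)
  e_before <- Mod(spec$F[21, 33 + 12])^2
  e_after <- Mod(dft2(out)$F[21, 33 + 12])^2
  expect_lt(e_after, 0.1 * e_before)
  expect_equal(mean(out), mean(unclass(noisy)), tolerance = 1e-6)
})

test_that("the parameter search returns the feasible argmax, deterministically", {
  d <- small8()
  nd <- inject_dataset_noise(d, default_noise_injection(), seed = 7)
  fit1 <- fit_noise_params(nd, K = 5, seed = 11)
  fit2 <- fit_noise_params(nd, K = 5, seed = 11)
  expect_identical(fit1$params[c("i1_h", "i1_v", "num_h", "num_v")],
                   fit2$params[c("i1_h", "i1_v", "num_h", "num_v")])
  # argmax contract: the selected cell's fold-mean accuracy tops every feasible cell
  for (dir in c("horizontal", "vertical")) {
    mv <- fit1$performance[[dir]]$mean_val
    sel_num <- if (dir == "horizontal") fit1$params$num_h else fit1$params$num_v
    sel_i1 <- if (dir == "horizontal") fit1$params$i1_h else fit1$params$i1_v
    grid_num <- if (dir == "horizontal") fit1$params$num_grid_h else fit1$params$num_grid_v
    sel <- mv[match(sel_i1, fit1$params$i1_grid), match(sel_num, grid_num)]
    expect_gte(sel, max(mv, na.rm = TRUE) - 1e-12)
  }
  # accuracies live in [0, 1] and infeasible cells are masked, not zero
  expect_true(all(fit1$performance$horizontal$val_tensor >= 0 &
                    fit1$performance$horizontal$val_tensor <= 1, na.rm = TRUE))
})

test_that("degenerate flat datasets leave no feasible cell and error helpfully", {
  maps <- array(20, c(12, 40, 64))
  d <- dataset_tensor(maps, rep(c("AL1", "AL2"), each = 6))
  expect_error(fit_noise_params(d, K = 3, seed = 1), "feasible")
})

test_that("the search recovers a planted stripe frequency", {
  d <- small8()
  sub <- subset_tensor(d, which(d$labels %in% c("AL1", "AL7")))
  hits <- 0
  for (seed in 1:3) {
    nd <- inject_dataset_noise(sub, noise_injection("vertical", freq_v = 10, amp_v = 2.5),
                               seed = seed)
    fit <- fit_noise_params(nd, K = 3, seed = seed)
    if (fit$params$num_h >= 1) {
      P <- power_spectrum(dft2(nd$maps[1, , ]))
      top <- find_peak_pairs(P, "horizontal")$offset[seq_len(fit$params$num_h)]
      if (10 %in% top) hits <- hits + 1
    }
  }
  expect_gte(hits, 2)
})

test_that("dataset denoising reduces error to the clean reference and contracts", {
  d <- small8()
  nd <- inject_dataset_noise(d, default_noise_injection(), seed = 13)
  fit <- fit_noise_params(nd, K = 5, seed = 2)
  dn <- denoise_dataset(nd, fit$params)
  expect_equal(dim(dn$maps), dim(nd$maps))
  clean <- attr(nd, "clean_maps")
  expect_lt(mean((dn$maps - clean)^2), mean((nd$maps - clean)^2))
  # zero-count params leave the data untouched
  p0 <- noise_params(i1_h = 8, i1_v = 8, num_h = 0, num_v = 0)
  expect_equal(denoise_dataset(nd, p0)$maps, nd$maps, tolerance = 1e-9)
  # contraction on the injected-noise subspace: a second pass barely moves
  # the coefficients at the injected frequencies
  inj <- default_noise_injection()
  dn2 <- denoise_dataset(dn, fit$params)
  amp_at <- function(maps) {
    a <- 0
    for (i in seq_len(dim(maps)[1])) {
      F <- dft2(maps[i, , ])$F
      a <- a + sum(Mod(F[21, 33 + inj$freq_v])) + sum(Mod(F[21 + inj$freq_h, 33]))
    }
    a
  }
  delta1 <- abs(amp_at(dn$maps) - amp_at(nd$maps))
  delta2 <- abs(amp_at(dn2$maps) - amp_at(dn$maps))
  expect_lt(delta2, 0.01 * delta1)
})

test_that("fitted parameters survive a JSON round trip", {
  p <- noise_params(2, -1, 5, 3, K = 10, seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_noise_params(p, path)
  back <- read_noise_params(path)
  expect_equal(back[c("i1_h", "i1_v", "num_h", "num_v")],
               p[c("i1_h", "i1_v", "num_h", "num_v")])
})
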