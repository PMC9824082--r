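group_tensor <- function(n_class = 2, n_subj = 2, repeats = 10, seed = 51) {
  set.seed(seed)
  Z <- n_class * n_subj * repeats
  maps <- array(rnorm(Z * 40 * 64, 20), c(Z, 40, 64))
  labels <- character(Z); subjects <- vector("list", Z)
  i <- 0
  for (cl in seq_len(n_class)) for (s in seq_len(n_subj)) for (r in seq_len(repeats)) {
    i <- i + 1
    labels[i] <- paste0("AL", cl); subjects[[i]] <- s
  }
  dataset_tensor(maps, labels, subjects = subjects)
}

test_that("pairwise augmentation doubles each 10-repeat group with the stated pairs", {
  d <- group_tensor()
  aug <- augment_pairwise(d)
  expect_equal(n_samples(aug), 2L * n_samples(d))
  # first generated map of the first group is mean(map1, map2) exactly
  first_new <- n_samples(d) + 1L
  expect_equal(aug$maps[first_new, , ], (d$maps[1, , ] + d$maps[2, , ]) / 2)
  # last pair of a group is (map2, map4)
  expect_equal(aug$maps[first_new + 9L, , ], (d$maps[2, , ] + d$maps[4, , ]) / 2)
  # augmented labels/subjects never mix groups
  expect_equal(aug$labels[first_new + 0:9], rep("AL1", 10))
  expect_equal(unlist(aug$subjects[first_new + 0:9]), rep(1, 10))
  # a group of identical maps yields identical new maps
  d2 <- group_tensor(n_class = 1, n_subj = 1)
  for (i in 2:10) d2$maps[i, , ] <- d2$maps[1, , ]
  aug2 <- augment_pairwise(d2)
  for (i in 11:20) expect_equal(aug2$maps[i, , ], d2$maps[1, , ])
  # groups of any other size are rejected
  expect_error(augment_pairwise(subset_tensor(d, 1:19)), "exactly 10")
})

test_that("repeated holdout uses the configured split sizes and is reproducible", {
  d <- group_tensor(n_class = 2, n_subj = 1, repeats = 10)  # Z = 20
  # trivially separable classes
  d$maps[d$labels == "AL2", , ] <- d$maps[d$labels == "AL2", , ] + 50
  res <- run_experiment(d, "dct", classifier_spec("knn"), repeats = 4,
                        test_fraction = 0.25, seed = 61)
  expect_length(res$test_acc, 4L)
  expect_equal(sum(res$confusion), 4L * 5L)  # 25% of 20 per repeat
  expect_equal(res$mean, 1)
  expect_equal(res$sd, 0)
  res2 <- run_experiment(d, "dct", classifier_spec("knn"), repeats = 4,
                         test_fraction = 0.25, seed = 61)
  expect_identical(res$test_acc, res2$test_acc)
  expect_error(run_experiment(d, "dct", repeats = 2, test_fraction = 1.2), "fraction")
})

test_that("holdout splits are stratified and leak-free", {
  labels <- rep(c("AL1", "AL2", "AL3", "AL4"), each = 12)
  sp <- lrirhar:::stratified_split(labels, 0.25, seed = 3)
  expect_length(sp$test, 12L)
  expect_equal(unname(table(labels[sp$test])), rep(3L, 4), ignore_attr = TRUE)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
})

test_that("the A/B harness pairs identical splits and reports a null effect on clean data", {
  d <- fixture("large240", {
    recs <- build_coventry_like(scene_config(), seed = 19, layouts = "large",
                                include_double = FALSE, sensors = "S1")
    build_dataset(recs, "S1")
  })
  ab <- ab_noise_test(d, extractor = "svd", classifier = classifier_spec("lr"),
                      denoise_refit = "once",
                      denoise_control = list(K = 5),
                      repeats = 3, seed = 67)
  expect_identical(ab$off$config$seed, ab$on$config$seed)
  expect_equal(ab$delta, ab$on$mean - ab$off$mean, tolerance = 1e-12)
  # no injected noise: denoising must not change accuracy by more than 2 points
  expect_lte(abs(ab$delta), 0.02)
})

test_that("cross-layout transfer harmonizes labels and behaves sanely under null transfer", {
  d <- small8()
  # split one homogeneous dataset into pseudo-layouts: transfer should be easy
  sp <- lrirhar:::stratified_split(d$labels, 0.5, seed = 71)
  a <- subset_tensor(d, sp$train); b <- subset_tensor(d, sp$test)
  b$labels <- sub("^AL", "AS", b$labels)  # same activities, other layout's codes
  res <- cross_layout_test(a, b, extractor = "svd", classifier = classifier_spec("lr"),
                           seed = 73, k = 20)
  within <- run_experiment(d, "svd", classifier_spec("lr"), repeats = 3,
                           seed = 73, k = 20)$mean
  expect_gt(res$mean, within - 0.15)
  bad <- subset_tensor(b, which(b$labels != "AS1"))
  expect_error(cross_layout_test(a, bad, seed = 1), "vocabularies")
})

test_that("mixed-layout training generalizes at least as well as cross-layout transfer", {
  small <- fixture("small240", {
    recs <- build_coventry_like(scene_config(), seed = 19, layouts = "small",
                                include_double = FALSE, sensors = "S1")
    build_dataset(recs, "S1")
  })
  large <- fixture("large240", {
    recs <- build_coventry_like(scene_config(), seed = 19, layouts = "large",
                                include_double = FALSE, sensors = "S1")
    build_dataset(recs, "S1")
  })
  s2l <- cross_layout_test(small, large, extractor = "glcm",
                           classifier = classifier_spec("lr"), seed = 77)$mean
  l2s <- cross_layout_test(large, small, extractor = "glcm",
                           classifier = classifier_spec("lr"), seed = 77)$mean
  mixed <- bind_tensors(small, large)
  mixed$labels <- lrirhar:::harmonize_layout_labels(mixed$labels)
  mix <- run_experiment(mixed, "glcm", classifier_spec("lr"), repeats = 5,
                        seed = 77)$mean
  expect_gte(mix, max(s2l, l2s) - 1e-9)
})

test_that("sensor subsets evaluate independently and concatenate features", {
  recs <- fixture("sensor_recs", {
    scene <- scene_config()
    unlist(lapply(1:6, function(rep) lapply(c("I3", "I4", "I8", "I9"), function(a)
      simulate_record(a, scene, subjects = (rep %% 3) + 1,
                      seed = lrirhar:::derive_seed(83, rep * 10 + match(a, c("I3","I4","I8","I9")))))),
      recursive = FALSE)
  })
  out <- sensor_subset_test(recs, list("S1", "S2", c("S1", "S2", "S3")),
                            extractor = "dct", classifier = classifier_spec("lr"),
                            repeats = 3, seed = 87)
  expect_length(out, 3L)
  expect_named(out, c("S1", "S2", "S1+S2+S3"))
  expect_error(sensor_subset_test(recs, list("S9")), "S9")
})

test_that("a side sensor beats the front sensor on depth-axis traversals", {
  # walking away/toward move along the depth axis of the front sensor (S2),
  # which sees them only as size change; the side sensor S1 images the full
  # motion axis. Aggregate over repeated splits.
  recs <- fixture("traversal_recs", {
    scene <- scene_config()
    out <- list()
    i <- 0
    for (subj in 1:3) for (a in c("I3", "I4", "I8", "I9")) for (rep in 1:5) {
      i <- i + 1
      out[[i]] <- simulate_record(a, scene, subjects = subj,
                                  seed = lrirhar:::derive_seed(91, i))
    }
    out
  })
  out <- sensor_subset_test(recs, list("S1", "S2"), extractor = "svd",
                            classifier = classifier_spec("lr"),
                            repeats = 10, seed = 93, k = 20)
  expect_gt(mean(out$S1$test_acc), mean(out$S2$test_acc))
})
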