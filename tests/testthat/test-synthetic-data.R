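test_that("generated tables have the requested shape, labels and determinism", {
  spec <- synthetic_spec(n_per_class = 285, n_features = 30, cov_rank = 5,
                         seed = 11)
  tab <- generate_two_class_table(spec)
  expect_equal(dim(tab$features), c(570L, 30L))
  expect_setequal(unique(tab$labels), c("a", "b"))
  expect_equal(as.vector(table(tab$labels)), c(285L, 285L))
  expect_false(anyNA(tab$features))

  # bit-identical per (spec, seed), different for a different seed
  expect_identical(tab, generate_two_class_table(spec))
  spec2 <- synthetic_spec(n_per_class = 285, n_features = 30, cov_rank = 5,
                          seed = 12)
  expect_false(identical(tab, generate_two_class_table(spec2)))

  # generation does not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(generate_two_class_table(spec))
  expect_identical(rnorm(1), before)
})

test_that("class means are separated by the requested distance", {
  # noise-dominated scale kept small so the sample-mean oracle is sharp
  spec <- synthetic_spec(n_per_class = 50, n_features = 5, separation = 10,
                         cov_rank = 1, cov_sd = 0.5, noise_sd = 0.1,
                         seed = 3)
  tab <- generate_two_class_table(spec)
  d <- colMeans(tab$features[tab$labels == "a", ]) -
    colMeans(tab$features[tab$labels == "b", ])
  se <- sqrt(2 * (spec$cov_sd^2 * spec$cov_rank + spec$noise_sd^2) /
               spec$n_per_class)
  expect_lt(abs(sqrt(sum(d^2)) - 10), 3 * se)

  # zero separation: the two classes share one distribution
  spec0 <- synthetic_spec(n_per_class = 400, n_features = 5, separation = 0,
                          cov_rank = 1, cov_sd = 0.5, noise_sd = 0.5,
                          seed = 4)
  tab0 <- generate_two_class_table(spec0)
  d0 <- colMeans(tab0$features[tab0$labels == "a", ]) -
    colMeans(tab0$features[tab0$labels == "b", ])
  se0 <- sqrt(2 * (spec0$cov_sd^2 + spec0$noise_sd^2) / spec0$n_per_class)
  expect_lt(sqrt(sum(d0^2)), 3 * se0 * sqrt(5))
})

test_that("noise-only configuration recovers the stated variance", {
  spec <- synthetic_spec(n_per_class = 1500, n_features = 8, separation = 0,
                         cov_rank = 1, cov_sd = 0, noise_sd = 0.7, seed = 5)
  v <- apply(generate_two_class_table(spec)$features, 2, var)
  expect_true(all(abs(v - 0.7^2) / 0.7^2 < 0.1))
})

test_that("invalid spec fields are rejected naming the field", {
  expect_error(synthetic_spec(n_per_class = 0), "n_per_class")
  expect_error(synthetic_spec(separation = -1), "separation")
  expect_error(synthetic_spec(noise_sd = 0), "noise_sd")
  expect_error(synthetic_spec(n_features = 4, cov_rank = 9), "cov_rank")
})

test_that("train/test split partitions, stratifies and is deterministic", {
  tab <- generate_two_class_table(synthetic_spec(n_per_class = 285,
                                                 n_features = 6, seed = 6))
  sp <- split_train_test(tab, 0.6, seed = 7)
  expect_equal(n_samples(sp$train), 342L)
  expect_equal(n_samples(sp$test), 228L)

  # conservation: union restores the table, intersection empty
  all_rows <- rbind(sp$train$features, sp$test$features)
  expect_equal(nrow(unique(all_rows)), 570L)
  expect_setequal(
    apply(all_rows, 1, paste, collapse = ","),
    apply(tab$features, 1, paste, collapse = ","))

  # stratification: per-class proportions within one sample
  expect_equal(as.vector(table(sp$train$labels)), c(171L, 171L))

  expect_identical(sp, split_train_test(tab, 0.6, seed = 7))
  expect_false(identical(sp, split_train_test(tab, 0.6, seed = 8)))

  # unstratified variant still partitions
  spu <- split_train_test(tab, 0.6, seed = 7, stratified = FALSE)
  expect_equal(n_samples(spu$train), 342L)

  tiny <- labeled_table(matrix(1:6, 3, 2), c("a", "a", "b"))
  expect_error(split_train_test(tiny, 0.5, seed = 1), "cannot stratify")
  expect_error(split_train_test(tab, 1.2, seed = 1), "train_fraction")
})

test_that("CSV round-trip preserves the table", {
  tab <- generate_two_class_table(synthetic_spec(
    n_per_class = 10, n_features = 3, cov_rank = 2, seed = 9))
  path <- withr::local_tempfile(fileext = ".csv")
  write_labeled_table(tab, path)
  back <- load_table(path)
  expect_equal(back$features, tab$features, tolerance = 1e-12)
  expect_identical(back$labels, tab$labels)
  expect_identical(back$feature_names, tab$feature_names)
})
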