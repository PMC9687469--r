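# build a classifier from explicit ensembles, bypassing the embedding, so
# decision-value identities can be tested against hand-picked states
manual_clf <- function(states_a, states_b, params, tie = NULL) {
  structure(list(states_a = states_a, states_b = states_b,
                 class_a = "b", class_b = "a",
                 tie_class = if (is.null(tie)) "a" else tie,
                 params = params, config = embedding_config()),
            class = "fidelity_classifier")
}

test_that("kernel-sum decision value equals the density-matrix form", {
  set.seed(71)
  tab <- separable_table(n_per_class = 8)
  p <- init_params(4, seed = 3)
  clf <- fidelity_classifier(tab, p)
  rho <- density_matrix(clf$states_a)
  sig <- density_matrix(clf$states_b)
  for (i in 1:20) {
    f <- rnorm(4)
    x <- unclass(embed_sample(f, p))
    expect_equal(decision_value(f, clf),
                 Re(Conj(x) %*% (rho - sig) %*% x)[1], tolerance = 1e-10)
  }
})

test_that("decision values hit their analytic landmarks and bounds", {
  set.seed(72)
  p <- init_params(2, seed = 1)
  s00 <- matrix(c(1, 0, 0, 0) + 0i, 4)
  s01 <- matrix(c(0, 1, 0, 0) + 0i, 4)

  # x embedded exactly on the sole class-A state, orthogonal to B -> f = 1
  zero <- hybrid_params(matrix(0, 2, 2), rep(0, 12))  # embeds any x at |00>
  clf1 <- manual_clf(s00, s01, zero)
  expect_equal(decision_value(c(0.3, -0.2), clf1), 1, tolerance = 1e-12)

  # identical ensembles -> f = 0 everywhere; ties go to the tie class
  states <- random_state_matrix(3)
  clf0 <- manual_clf(states, states, p)
  f <- rnorm(2)
  expect_equal(decision_value(f, clf0), 0, tolerance = 1e-12)
  expect_identical(predict(clf0, f), "a")          # default: negative class
  clf0b <- manual_clf(states, states, p, tie = "b")
  expect_identical(predict(clf0b, f), "b")

  # antisymmetry under swapping the ensembles; |f| <= 1 always
  sa <- random_state_matrix(4); sb <- random_state_matrix(5)
  clf <- manual_clf(sa, sb, p)
  swp <- manual_clf(sb, sa, p)
  for (i in 1:10) {
    f <- rnorm(2)
    expect_equal(decision_value(f, clf), -decision_value(f, swp),
                 tolerance = 1e-12)
    expect_lte(abs(decision_value(f, clf)), 1)
  }

  # sign rule: positive -> class A, negative -> class B
  tab <- separable_table(n_per_class = 10)
  pt <- train_embedding(tab, init_params(4, seed = 1),
                        train_config(steps = 200, seed = 2))$params
  clft <- fidelity_classifier(tab, pt)
  fv <- decision_value(tab, clft)
  pred <- predict(clft, tab)
  expect_identical(pred[fv > 0], rep(clft$class_a, sum(fv > 0)))
  expect_identical(pred[fv < 0], rep(clft$class_b, sum(fv < 0)))
})

test_that("metrics match hand-computed confusion tables", {
  expect_equal(compute_metrics(c("m", "m", "b"), c("m", "m", "b"), "m"),
               list(precision = 1, recall = 1, f1 = 1))

  # TP = 2, FP = 1, FN = 1
  met <- compute_metrics(c("m", "m", "m", "b"), c("m", "m", "b", "m"), "m")
  expect_equal(met$precision, 2 / 3)
  expect_equal(met$recall, 2 / 3)
  expect_equal(met$f1, 2 / 3)

  # f1 is the harmonic mean of precision and recall
  expect_equal(met$f1, 2 * met$precision * met$recall /
                 (met$precision + met$recall), tolerance = 1e-9)

  # no positive predictions: precision 0 with a warning, recall 0
  expect_warning(met0 <- compute_metrics(c("b", "b"), c("m", "b"), "m"),
                 "precision")
  expect_equal(met0$precision, 0)
  expect_equal(met0$recall, 0)
  expect_equal(met0$f1, 0)

  expect_error(compute_metrics("a", c("a", "b"), "a"), "equal length")
})

test_that("gram matrices are symmetric overlaps with unit diagonal", {
  expect_equal(gram_matrix(matrix(c(1, 0, 0, 0) + 0i, 4)),
               matrix(1, 1, 1), tolerance = 1e-15)
  pair <- cbind(c(1, 0, 0, 0), c(0, 1, 0, 0)) + 0i
  expect_equal(gram_matrix(pair), diag(2), tolerance = 1e-15)

  set.seed(73)
  s <- random_state_matrix(3)
  g <- gram_matrix(s)
  expect_lt(max(abs(g - t(g))), 1e-12)
  expect_equal(diag(g), rep(1, 3), tolerance = 1e-12)
  expect_true(all(g >= 0 & g <= 1 + 1e-12))
  for (i in 1:3) for (j in 1:3) {
    expect_equal(g[i, j], state_overlap(s[, i], s[, j]), tolerance = 1e-12)
  }
})

test_that("a trained separable toy shows block structure in Hilbert space", {
  tab <- separable_table(n_per_class = 10)
  fit <- train_embedding(tab, init_params(4, seed = 1),
                         train_config(steps = 300, seed = 5))
  states <- embed_table(tab, fit$params)
  g <- gram_matrix(states)
  same <- outer(tab$labels, tab$labels, `==`)
  expect_gt(mean(g[same & upper.tri(g)]), mean(g[!same & upper.tri(g)]))
})

test_that("evaluate_split assembles the published record layout", {
  tab <- separable_table(n_per_class = 12)
  fit <- train_embedding(tab, init_params(4, seed = 1),
                         train_config(steps = 300, seed = 6))

  # degenerate identity split: train == test, near-perfect metrics
  rec <- evaluate_split(tab, tab, fit$params)
  expect_named(rec, c("n_features_used", "used_pca", "training_cost",
                      "test_cost", "precision", "recall", "f1"))
  expect_equal(rec$training_cost, rec$test_cost, tolerance = 1e-12)
  expect_gt(rec$f1, 0.95)
  expect_equal(rec$n_features_used, 4L)

  # untrained random params on zero-separation data: chance-level F1
  f1s <- vapply(1:5, function(s) {
    spec <- synthetic_spec(n_per_class = 60, n_features = 6, separation = 0,
                           cov_rank = 2, seed = s)
    t0 <- generate_two_class_table(spec)
    sp <- split_train_test(t0, 0.5, seed = s)
    evaluate_split(sp$train, sp$test, init_params(6, seed = s))$f1
  }, numeric(1))
  expect_lt(abs(median(f1s) - 0.5), 0.15)
})
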