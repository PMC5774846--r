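test_that("KNN prediction averages the k nearest training targets", {
  d <- matrix(c(1, 2, 3), nrow = 1)
  expect_equal(knn_predict(d, c(1, 2, 3), k = 3), 2)
  expect_equal(knn_predict(d, c(1, 2, 3), k = 1), 1)
  expect_error(knn_predict(d, c(1, 2, 3), k = 0), "at least 1")
  expect_error(knn_predict(d, c(1, 2, 3), k = 4), "exceeds")

  # ties at the k-th distance resolve by stable training order
  dt <- matrix(c(1, 1, 1, 2), nrow = 1)
  expect_equal(knn_predict(dt, c(10, 20, 30, 40), k = 2), 15)

  # k = training size -> global mean (leave-one-out shrinks by one)
  sq <- as.matrix(dist(matrix(rnorm(12), ncol = 2)))
  y <- rnorm(6)
  expect_equal(knn_predict(sq[1, , drop = FALSE], y, k = 6), mean(y))
  loo <- knn_predict(sq, y, k = 5, loo = TRUE)
  expect_equal(loo[1], mean(y[-1]))
})

test_that("tree ensembles fit signals and are seed-deterministic", {
  set.seed(99)
  x <- matrix(rnorm(500 * 5), ncol = 5)
  y <- x[, 1]
  cfg <- model_config("gbt", "regression",
                      params = list(n_estimators = 1000,
                                    learning_rate = 0.1), seed = 7)
  fit <- fit_predict_trees(x, y, cfg)
  r2 <- 1 - mean((fit$predictions - y)^2) / var(y)
  expect_gt(r2, 0.99)

  # constant target -> constant prediction
  cfit <- fit_predict_trees(x, rep(2.5, 500), cfg)
  expect_equal(unique(round(cfit$predictions, 6)), 2.5)

  # fixed seed determinism across repeated fits
  fit2 <- fit_predict_trees(x, y, cfg)
  expect_identical(fit$predictions, fit2$predictions)
  for (fam in c("rf", "et")) {
    cfgf <- model_config(fam, "regression",
                         params = list(n_estimators = 100), seed = 3)
    p1 <- fit_predict_trees(x[1:200, ], y[1:200], cfgf)$predictions
    p2 <- fit_predict_trees(x[1:200, ], y[1:200], cfgf)$predictions
    expect_identical(p1, p2)
  }
  expect_error(fit_predict_trees(cbind(x[, 1], NA), y, cfg), "non-finite")
})

test_that("duplicated redundant features barely move held-out error", {
  set.seed(42)
  n <- 600
  x <- matrix(rnorm(n * 4), ncol = 4)
  y <- x[, 1] + 0.5 * x[, 2] + rnorm(n, sd = 0.5)
  tr <- 1:300; te <- 301:n
  rmse <- function(p) sqrt(mean((p - y[te])^2))
  xdup <- cbind(x, x)
  base <- dup <- numeric(0)
  for (s in 1:3) {           # mean over repeated runs, as in practice
    cfg <- model_config("gbt", "regression",
                        params = list(n_estimators = 500,
                                      learning_rate = 0.05), seed = s)
    base <- c(base, rmse(fit_predict_trees(x[tr, ], y[tr], cfg,
                                           newx = x[te, ])$predictions))
    dup <- c(dup, rmse(fit_predict_trees(xdup[tr, ], y[tr], cfg,
                                         newx = xdup[te, ])$predictions))
  }
  expect_lt(abs(mean(dup) - mean(base)) / mean(base), 0.10)
})

test_that("voting and consensus averaging are element-wise means", {
  expect_equal(vote_classifiers(list(0.2, 0.4, 0.6)), 0.4)
  expect_equal(vote_classifiers(list(c(0.1, 0.9))), c(0.1, 0.9))
  p <- c(0.3, 0.7)
  expect_equal(vote_classifiers(list(p, p, p)), p)
  expect_error(vote_classifiers(list(c(0.1), c(0.1, 0.2))), "mismatch")

  expect_equal(consensus_average(list(1, 3)), 2)
  expect_equal(consensus_average(list(c(1, 2), c(1, 2))), c(1, 2))
  v <- rnorm(4)
  expect_equal(consensus_average(rep(list(v), 5)), v)
})

test_that("registered configs carry the reference hyperparameters", {
  g <- model_config("gbt", "regression")
  expect_equal(g$params$n_estimators, 20000)
  expect_equal(g$params$max_depth, 8)
  expect_equal(g$params$learning_rate, 0.005)
  expect_equal(g$params$subsample, 0.7)
  expect_equal(g$params$max_features, "sqrt")
  gs <- model_config("gbt", "classification")
  expect_equal(gs$params$n_estimators, 2000)
  expect_equal(gs$params$subsample, 0.5)
  expect_equal(gs$params$learning_rate, 0.01)
  expect_equal(gs$params$class_weight_ratio, 100)
  expect_equal(model_config("rf")$params$n_estimators, 2000)
  expect_equal(model_config("knn")$params$k, 3)
})
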