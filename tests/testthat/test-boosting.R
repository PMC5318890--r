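test_that("single trees match forced geometry and handle constant residuals", {
  X <- matrix(c(0, 1), ncol = 1)
  tr <- fit_tree(X, c(0, 1), depth = 1, min_node = 1)
  expect_equal(tr$var[1], 1)
  expect_equal(tr$threshold[1], 0.5)
  expect_equal(predict_tree(tr, X), c(0, 1))

  # constant residuals: single leaf predicting the constant, zero improvement
  tr0 <- fit_tree(matrix(rnorm(20), 10, 2), rep(3, 10), depth = 5, min_node = 2)
  expect_equal(nrow(tr0), 1)
  expect_true(is.na(tr0$var[1]))
  expect_equal(tr0$pred[1], 3)
  expect_equal(tr0$improvement[1], 0)
})

test_that("tree fitting recovers step functions and matches the exhaustive oracle", {
  # 20-point piecewise-constant target with 3 steps, depth 3
  x <- seq(0.5, 19.5)
  y <- c(rep(0, 5), rep(4, 5), rep(-2, 5), rep(1, 5))
  tr <- fit_tree(matrix(x, ncol = 1), y, depth = 3, min_node = 2)
  thrs <- sort(tr$threshold[!is.na(tr$var)])
  expect_equal(thrs, c(5, 10, 15))
  expect_equal(predict_tree(tr, matrix(x, ncol = 1)), y)

  # exhaustive-search oracle equivalence on small random instances
  set.seed(33)
  for (i in 1:12) {
    n <- sample(10:30, 1)
    p <- sample(1:4, 1)
    X <- matrix(rnorm(n * p), n, p)
    r <- rnorm(n)
    depth <- sample(1:4, 1)
    min_node <- sample(1:3, 1)
    tr <- fit_tree(X, r, depth = depth, min_node = min_node)
    expect_equal(predict_tree(tr, X),
                 oracle_tree_predictions(X, r, depth, min_node),
                 tolerance = 1e-12)
  }
})

test_that("trees never exceed the configured number of splits", {
  set.seed(8)
  X <- matrix(rnorm(200), 100, 2)
  r <- rnorm(100)
  for (depth in c(1, 3, 5)) {
    tr <- fit_tree(X, r, depth = depth, min_node = 5)
    expect_lte(sum(!is.na(tr$var)), depth)
    expect_true(all(tr$improvement >= 0))
  }
})

small_gbm_data <- function(n = 150, seed = 5) {
  set.seed(seed)
  X <- cbind(a = runif(n, 0, 10), b = runif(n, 0, 10), noise = rnorm(n))
  y <- 2 * pmax(X[, "a"] - 5, 0) + 0.3 * X[, "b"] + rnorm(n, 0, 0.3)
  list(X = X, y = y)
}

test_that("boosting fits are seeded, additive and reduce training error", {
  d <- small_gbm_data()
  cfg <- gbm_config(n_trees = 120, interaction_depth = 3, learning_rate = 0.05,
                    cv_folds = 3, seed = 17)
  fit <- fit_gbm(d$X, d$y, cfg)
  fit2 <- fit_gbm(d$X, d$y, cfg)
  expect_equal(predict(fit, d$X), predict(fit2, d$X))
  expect_true(fit$best_iteration >= 1 && fit$best_iteration <= 120)

  # prediction decomposition: adding tree m changes predictions by
  # learning_rate * tree_m(x)
  for (m in c(2, 50, 120)) {
    delta <- predict(fit, d$X, n_trees = m) - predict(fit, d$X, n_trees = m - 1)
    expect_equal(delta, 0.05 * predict_tree(fit$trees[[m]], d$X))
  }
  # zero trees: predictions equal the training-mean initial value
  expect_equal(predict(fit, d$X, n_trees = 0), rep(mean(d$y), nrow(d$X)))

  # bag_fraction 1 on a noiseless additive truth: training MSE non-increasing
  y0 <- 2 * pmax(d$X[, "a"] - 5, 0) + 0.3 * d$X[, "b"]
  fit1 <- fit_gbm(d$X, y0, gbm_config(n_trees = 150, interaction_depth = 3,
                                      learning_rate = 0.1, cv_folds = 3,
                                      bag_fraction = 1, seed = 2))
  expect_true(all(diff(fit1$train_error) <= 1e-12))

  # constant response: predictions stay at the mean, zero training error
  fitc <- fit_gbm(d$X, rep(7, nrow(d$X)),
                  gbm_config(n_trees = 10, cv_folds = 2, seed = 1))
  expect_equal(predict(fitc, d$X, n_trees = 10), rep(7, nrow(d$X)))
  expect_equal(fitc$train_error, rep(0, 10))

  expect_error(fit_gbm(d$X[1:3, ], d$y[1:3], gbm_config(cv_folds = 5)),
               "cv_folds rows")
  expect_error(gbm_config(learning_rate = 0), "learning_rate")
  expect_error(gbm_config(cv_folds = 1), "cv_folds")
  expect_error(gbm_config(bag_fraction = 0), "bag_fraction")
})

test_that("relative influence is normalised and concentrates on true drivers", {
  # noiseless truth depending on one variable only
  set.seed(12)
  X <- cbind(a = runif(80, 0, 1), b = runif(80, 0, 1))
  y <- sin(2 * pi * X[, "a"])
  fit <- fit_gbm(X, y, gbm_config(n_trees = 150, interaction_depth = 2,
                                  learning_rate = 0.1, cv_folds = 3,
                                  bag_fraction = 1, min_node_size = 5,
                                  seed = 4))
  ri <- relative_influence(fit, n_trees = 150)
  expect_equal(sum(ri), 100)
  expect_gt(ri[["a"]], 99)
  expect_true(all(ri >= 0))

  # model with no splits is flagged
  fit0 <- fit_gbm(X, rep(1, 80), gbm_config(n_trees = 5, cv_folds = 2, seed = 1))
  expect_warning(ri0 <- relative_influence(fit0, n_trees = 5), "no splits")
  expect_true(all(ri0 == 0))
})

test_that("partial dependence averages the model over the data distribution", {
  d <- small_gbm_data()
  cfg <- gbm_config(n_trees = 100, interaction_depth = 2, learning_rate = 0.1,
                    cv_folds = 3, bag_fraction = 1, seed = 9)
  fit <- fit_gbm(d$X, d$y, cfg)

  # a variable the truth ignores gives a (nearly) flat profile
  pd_noise <- partial_dependence(fit, "noise")
  expect_lt(diff(range(pd_noise$yhat)), 0.05 * diff(range(d$y)))

  # direct data-average definition, checked against a hand loop
  g <- c(2, 5, 8)
  pd <- partial_dependence(fit, "a", grid = g)
  hand <- vapply(g, function(v) {
    Xi <- d$X; Xi[, "a"] <- v
    mean(predict(fit, Xi))
  }, numeric(1))
  expect_equal(pd$yhat, hand)

  # stumps on a single predictor: PDP equals the model's own prediction
  x1 <- matrix(sort(runif(60, 0, 10)), ncol = 1)
  colnames(x1) <- "a"
  y1 <- as.numeric(x1 > 4) * 3
  stump <- fit_gbm(x1, y1, gbm_config(n_trees = 80, interaction_depth = 1,
                                      learning_rate = 0.2, cv_folds = 3,
                                      bag_fraction = 1, min_node_size = 5,
                                      seed = 3))
  gg <- seq(0.5, 9.5, by = 0.5)
  pd1 <- partial_dependence(stump, "a", grid = gg, n_trees = 80)
  expect_equal(pd1$yhat,
               predict(stump, matrix(gg, ncol = 1, dimnames = list(NULL, "a")),
                       n_trees = 80))

  # two-variable grids and error handling
  pd2 <- partial_dependence(fit, c("a", "b"), grid = list(c(2, 5), c(3, 6)))
  expect_equal(nrow(pd2), 4)
  expect_error(partial_dependence(fit, "zzz"), "not in model")
  expect_error(partial_dependence(fit, "a", grid = c(-5, 2)),
               "outside the observed")
})
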