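test_that("initialisation produces the documented shapes and He variance", {
  model <- init_mlp(mlp_spec(), input_width = 100, seed = 1)
  dims <- lapply(model$weights, dim)
  expect_equal(dims, list(c(100L, 128L), c(128L, 64L), c(64L, 32L),
                          c(32L, 16L), c(16L, 8L), c(8L, 1L)))
  expect_true(all(vapply(model$biases, function(b) all(b == 0), logical(1))))
  # empirical first-layer weight variance ~ 2 / fan_in over 12800 draws
  expect_equal(stats::var(as.numeric(model$weights[[1]])), 2 / 100,
               tolerance = 0.2)
  # per-layer variance within 20% of 2/fan_in at fan_in >= 64
  expect_equal(stats::var(as.numeric(model$weights[[2]])), 2 / 128,
               tolerance = 0.2)
  # seed determinism
  expect_identical(model, init_mlp(mlp_spec(), 100, seed = 1))
  expect_error(mlp_spec(hidden_sizes = c(8, 0)), "positive")
})

test_that("forward pass matches closed-form hand networks", {
  # all-zero weights: sigmoid(0) = 0.5 exactly
  model <- init_mlp(mlp_spec(c(4, 3)), input_width = 2, seed = 1)
  model$weights <- lapply(model$weights, function(w) w * 0)
  expect_equal(mlp_forward(model, matrix(c(1.5, -2), 1)), 0.5)

  # single hidden unit, unit weights, zero biases: sigmoid(relu(x))
  hand <- init_mlp(mlp_spec(1L), input_width = 1, seed = 1)
  hand$weights <- list(matrix(1), matrix(1))
  hand$biases <- list(0, 0)
  expect_equal(mlp_forward(hand, matrix(0)), 0.5)
  expect_equal(mlp_forward(hand, matrix(2)), 1 / (1 + exp(-2)),
               tolerance = 1e-12)
  expect_equal(mlp_forward(hand, matrix(2)), 0.8808, tolerance = 1e-4)
  # relu gates negative inputs to 0.5
  expect_equal(mlp_forward(hand, matrix(-3)), 0.5)

  expect_error(mlp_forward(hand, matrix(0, 1, 2)), "expects")
})

test_that("forward pass with non-negative weights is monotone in each input", {
  model <- init_mlp(mlp_spec(c(6, 4)), input_width = 3, seed = 2)
  model$weights <- lapply(model$weights, abs)
  base <- c(0.3, -0.5, 1.2)
  p0 <- mlp_forward(model, matrix(base, 1))
  for (j in 1:3) {
    for (delta in c(0.1, 1, 5)) {
      x <- base
      x[j] <- x[j] + delta
      expect_gte(mlp_forward(model, matrix(x, 1)), p0)
    }
  }
})

test_that("classification thresholds use >= at the boundary", {
  probs <- c(0.49, 0.5, 0.51)
  expect_equal(as.integer(probs >= 0.5), c(0L, 1L, 1L))
  # all-zero model outputs exactly 0.5, so everything is positive at 0.5
  model <- init_mlp(mlp_spec(2L), input_width = 3, seed = 1)
  model$weights <- lapply(model$weights, function(w) w * 0)
  model$encoder <- NULL
  x <- matrix(rnorm(15), 5)
  expect_equal(predict(model, x, type = "class"), rep(1L, 5))
  # threshold 1 labels everything negative (sigmoid output < 1)
  tbl <- tibble::tibble(a = rnorm(5), b = rnorm(5), c = rnorm(5))
  fit <- train_mlp(tbl, c(0, 1, 0, 1, 0), spec = mlp_spec(2L),
                   control = mlp_control(epochs = 2, val_fraction = 0),
                   seed = 1)
  expect_equal(classify(fit, tbl, threshold = 1)$predicted_label, rep(0L, 5))
})

test_that("training separates a linearly separable toy set perfectly", {
  # 20 points on a line: x > 0 is positive, margin 1
  toy <- tibble::tibble(x = c(seq(-5.5, -1, length.out = 10),
                              seq(1, 5.5, length.out = 10)))
  y <- rep(c(0, 1), each = 10)
  fit <- train_mlp(toy, y, spec = mlp_spec(c(8L, 4L)),
                   control = mlp_control(epochs = 300, batch_size = 4,
                                         val_fraction = 0,
                                         learning_rate = 5e-3),
                   seed = 3)
  acc <- mean(predict(fit, toy, type = "class") == y)
  expect_equal(acc, 1)
})

test_that("training reduces the loss and is seed-reproducible", {
  dev <- make_dev_set(100, 400, seed = 7)
  y <- as.integer(dev$latent_class == "sz")
  ctrl <- mlp_control(epochs = 15, val_fraction = 0)
  fit <- train_mlp(dev, y, control = ctrl, seed = 11)
  h <- fit$history$train_loss
  expect_lt(h[length(h)], h[1])
  # loss is non-increasing up to small optimisation jitter
  expect_lt(max(diff(h)), 0.05)
  fit2 <- train_mlp(dev, y, control = ctrl, seed = 11)
  expect_identical(fit$weights, fit2$weights)
  expect_error(train_mlp(dev, rep(1, nrow(dev))), "single class")
})

test_that("the trained classifier reaches AUC >= 0.8 on the development-set shape", {
  dev <- make_dev_set(223, 1776, seed = 1)
  y <- as.integer(dev$latent_class == "sz")
  fit <- train_mlp(dev, y, seed = 42)
  held <- make_dev_set(223, 1776, seed = 2)
  y_held <- as.integer(held$latent_class == "sz")
  expect_gte(auc_mann_whitney(mlp_forward(fit, held), y_held), 0.8)
})

test_that("zero-separation features give chance-level held-out AUC", {
  ns <- make_dev_set(500, 1500, schema = null_feature_schema(), seed = 3)
  y <- as.integer(ns$latent_class == "sz")
  fit <- train_mlp(ns, y, control = mlp_control(epochs = 30), seed = 6)
  held <- make_dev_set(500, 1500, schema = null_feature_schema(), seed = 4)
  auc <- auc_mann_whitney(mlp_forward(fit, held),
                          as.integer(held$latent_class == "sz"))
  expect_gt(auc, 0.4)
  expect_lt(auc, 0.6)
})

test_that("cross-validation folds are stratified partitions with sane AUCs", {
  dev <- make_dev_set(200, 1800, seed = 13)
  y <- as.integer(dev$latent_class == "sz")
  ctrl <- mlp_control(epochs = 8, val_fraction = 0)
  spec <- mlp_spec(c(16L, 8L))
  cv <- cross_validate(dev, y, k = 10, spec = spec, control = ctrl, seed = 17)
  expect_length(cv$fold_aucs, 10)
  expect_true(all(cv$fold_aucs > 0 & cv$fold_aucs <= 1))
  # folds of 200 +/- stratification rounding checked via pooled counts
  expect_equal(sum(cv$counts), 2000)
  # mean fold AUC close to a single-split AUC at the same settings
  set.seed(18)
  idx <- sample.int(nrow(dev))
  tr <- idx[1:1500]
  te <- idx[1501:2000]
  fit <- train_mlp(dev[tr, ], y[tr], spec = spec, control = ctrl, seed = 17)
  single <- auc_mann_whitney(mlp_forward(fit, dev[te, ]), y[te])
  expect_lt(abs(mean(cv$fold_aucs) - single), 0.05)
})
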