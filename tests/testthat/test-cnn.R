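test_that("the built network matches the layer plan", {
  cfg <- cnn_config(input_shape = c(16, 16, 16), seed = 1)
  expect_message(model <- build_cnn(cfg), "trainable parameters")
  # first conv layer: 2 filters of 3x3x3 over 1 input channel
  expect_identical(dim(model$params[["conv1.W"]]), c(27L, 2L))
  expect_equal(model$config$conv_filters, c(2L, 8L, 16L, 32L, 64L, 128L))
  # softmax head has exactly 2 units
  expect_identical(ncol(model$params[["head.W"]]), 2L)
  # reported parameter count is the brute-force scalar count
  expect_equal(model$param_count,
               sum(vapply(model$params, length, numeric(1))))
  # dense stack parameter count follows the weights-plus-biases formula
  dense_sizes <- c(model$flat_dim, 128, 64, 2)
  dense_scalars <- length(model$params[["dense1.W"]]) +
    length(model$params[["dense1.b"]]) +
    length(model$params[["dense2.W"]]) +
    length(model$params[["dense2.b"]]) +
    length(model$params[["head.W"]]) + length(model$params[["head.b"]])
  expect_equal(parameter_count(dense_sizes)$parameter_count, dense_scalars)
})

test_that("too-small inputs fail the shape plan with a named layer", {
  expect_error(suppressMessages(build_cnn(cnn_config(input_shape = c(4, 4, 4)))),
               "average pooling after conv layer 2")
})

test_that("predicted probabilities are a normalized, deterministic pair", {
  model <- suppressMessages(build_cnn(cnn_config(input_shape = c(16, 16, 16),
                                                 seed = 2)))
  v <- random_volume(c(16, 16, 16), seed = 3)
  p1 <- predict_proba(model, v)
  expect_equal(p1$p_healthy + p1$p_diseased, 1, tolerance = 1e-12)
  expect_true(all(c(p1$p_healthy, p1$p_diseased) >= 0))
  # inference mode has no dropout: repeated calls identical
  expect_identical(p1, predict_proba(model, v))

  # zeroed head gives equal logits, hence (0.5, 0.5)
  zero <- model
  zero$params[["head.W"]][] <- 0
  zero$params[["head.b"]][] <- 0
  p0 <- predict_proba(zero, v)
  expect_equal(c(p0$p_healthy, p0$p_diseased), c(0.5, 0.5))

  expect_error(predict_proba(model, random_volume(c(8, 8, 8))),
               "does not match")
})

test_that("probabilities stay normalized across many random inputs", {
  model <- suppressMessages(build_cnn(cnn_config(input_shape = c(16, 16, 16),
                                                 seed = 4)))
  for (s in 1:5) {
    p <- predict_proba(model, random_volume(c(16, 16, 16), seed = s))
    expect_equal(p$p_healthy + p$p_diseased, 1, tolerance = 1e-9)
  }
})

test_that("training requires both classes and zero epochs is a no-op", {
  cohort <- small_phantom_cohort(n_per_class = 2)
  model <- suppressMessages(build_cnn(cnn_config(input_shape = c(16, 16, 16),
                                                 seed = 5)))
  one_class <- as_cohort(cohort$volumes[1:2], c(0L, 0L))
  expect_error(train_cnn(model, one_class), "both classes")

  fit0 <- train_cnn(model, cohort, epochs = 0)
  expect_identical(fit0$model$params, model$params)
  expect_equal(nrow(fit0$history), 0)
  expect_length(intersect(fit0$train_idx, fit0$val_idx), 0)
})

test_that("training reduces loss, is seeded, and the lr schedule only decays", {
  cohort <- small_phantom_cohort(n_per_class = 4, effect = 0.8, noise = 0.02)
  cfg <- cnn_config(input_shape = c(16, 16, 16), seed = 6,
                    learning_rate = 1e-3)
  model <- suppressMessages(build_cnn(cfg))
  fit <- train_cnn(model, cohort, epochs = 8)
  expect_equal(nrow(fit$history), 8)
  expect_true(all(is.finite(fit$history$loss)))
  expect_lt(fit$history$loss[8], fit$history$loss[1])
  # plateau schedule never increases the rate and respects its floor
  expect_true(all(diff(fit$history$lr) <= 0))
  expect_true(all(fit$history$lr >= cfg$min_lr))

  fit2 <- train_cnn(suppressMessages(build_cnn(cfg)), cohort, epochs = 8)
  expect_identical(fit$history, fit2$history)

  # the held-out report is computable and internally consistent
  rep_ <- holdout_eval(fit, cohort)
  expect_gte(rep_$auc, 0); expect_lte(rep_$auc, 1)
})
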