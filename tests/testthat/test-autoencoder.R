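test_that("initialization produces the symmetric layer plan, reproducibly", {
  p <- ae_init(10, hidden_width = 2, seed = 1)
  expect_equal(p$layer_sizes, c(10L, 4L, 2L, 2L, 2L, 4L, 10L))
  # shape chain: weight k maps n_{k-1} -> n_k
  for (k in seq_along(p$weights)) {
    expect_identical(dim(p$weights[[k]]),
                     c(p$layer_sizes[k + 1L], p$layer_sizes[k]))
    expect_length(p$biases[[k]], p$layer_sizes[k + 1L])
  }
  q <- ae_init(10, hidden_width = 2, seed = 1)
  expect_identical(p$weights, q$weights)
  r <- ae_init(10, hidden_width = 7, seed = 1)
  expect_equal(r$layer_sizes[4L], 7L)
  expect_error(ae_init(0, 2), ">= 1")
})

test_that("encode/decode follow the affine-plus-activation contract", {
  p <- ae_init(6, seed = 2)
  zero <- p
  for (k in seq_along(zero$weights)) zero$weights[[k]][] <- 0
  expect_equal(ae_encode(zero, rnorm(6)), c(0, 0))
  expect_equal(ae_decode(zero, c(1, 1)), rep(0, 6))  # tanh(0) = 0
  expect_length(ae_encode(p, rnorm(6)), 2L)

  # rectifier keeps positives, zeroes negatives through a hand-built layer
  toy <- zero
  toy$weights[[1]][1:2, 1:2] <- diag(2)
  h1 <- pmax(drop(toy$weights[[1]] %*% c(2, -3, 0, 0, 0, 0)), 0)
  expect_equal(h1[1:2], c(2, 0))

  # decoder output bounded by the tanh range (saturates to 1 only in
  # floating point)
  big <- p
  for (k in seq_along(big$weights)) big$weights[[k]] <- big$weights[[k]] * 50
  expect_lte(max(abs(ae_decode(big, c(3, -3)))), 1)
  expect_lt(max(abs(ae_decode(p, c(3, -3)))), 1)

  expect_error(ae_encode(p, rnorm(5)), "does not match")
  expect_error(ae_decode(p, rnorm(3)), "bottleneck")
})

test_that("reconstruct is exactly decode after encode", {
  p <- ae_init(12, seed = 3)
  x <- runif(12, -1, 1)
  expect_identical(ae_reconstruct(p, x), ae_decode(p, ae_encode(p, x)))
})

test_that("loss implements both squared-error conventions", {
  expect_equal(ae_loss(c(1, 2), c(1, 2)), 0)
  expect_equal(ae_loss(c(0, 0), c(1, 1)), 1)            # (1+1)/2
  expect_equal(ae_loss(c(0, 0), c(1, 1), type = "sum"), 2)
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(ae_loss(x, y), ae_loss(y, x))
  expect_gte(ae_loss(x, y), 0)
  expect_error(ae_loss(1:3, 1:4), "mismatch")
})

test_that("backpropagation gradients match finite differences", {
  p <- ae_init(5, hidden_width = 2, seed = 7)
  x <- runif(5, -0.9, 0.9)
  g <- ae_gradient(p, x)
  eps <- 1e-6
  for (k in c(1, 3, 6)) {
    for (idx in seq_len(min(4, length(p$weights[[k]])))) {
      pp <- p; pp$weights[[k]][idx] <- pp$weights[[k]][idx] + eps
      pm <- p; pm$weights[[k]][idx] <- pm$weights[[k]][idx] - eps
      num <- (ae_loss(x, ae_reconstruct(pp, x)) -
                ae_loss(x, ae_reconstruct(pm, x))) / (2 * eps)
      expect_equal(g$weights[[k]][idx], num, tolerance = 1e-5)
    }
    pb <- p; pb$biases[[k]][1] <- pb$biases[[k]][1] + eps
    pb2 <- p; pb2$biases[[k]][1] <- pb2$biases[[k]][1] - eps
    num_b <- (ae_loss(x, ae_reconstruct(pb, x)) -
                ae_loss(x, ae_reconstruct(pb2, x))) / (2 * eps)
    expect_equal(g$biases[[k]][1], num_b, tolerance = 1e-5)
  }
})

test_that("sgd_step applies exactly -v times the gradient", {
  p <- ae_init(3, seed = 1)
  zero_grad <- list(weights = lapply(p$weights, function(w) w * 0),
                    biases = lapply(p$biases, function(b) b * 0))
  expect_identical(sgd_step(p, zero_grad, 0.1)$weights, p$weights)

  g <- zero_grad
  g$weights[[1]][1, 1] <- 2   # as if J = w^2 at w = 1
  p1 <- p
  p1$weights[[1]][1, 1] <- 1
  stepped <- sgd_step(p1, g, 0.1)
  expect_equal(stepped$weights[[1]][1, 1], 0.8)

  # a small step strictly decreases the loss along the gradient
  x <- runif(3, -0.5, 0.5)
  gr <- ae_gradient(p, x)
  p2 <- sgd_step(p, gr, 0.01)
  expect_lt(ae_loss(x, ae_reconstruct(p2, x)), ae_loss(x, ae_reconstruct(p, x)))

  bad <- zero_grad
  bad$weights[[1]] <- matrix(0, 2, 2)
  expect_error(sgd_step(p, bad, 0.1), "shape mismatch")
  expect_error(sgd_step(p, zero_grad, -1), "> 0")
})

test_that("training descends, is deterministic, and validates inputs", {
  spec <- phantom_spec(shape = c(8, 8, 8), noise_sd = 0.02, seed = 5)
  v <- normalize_volume(generate_phantom(spec, 0), c(-1, 1))
  p0 <- ae_init(prod(dim(v)), seed = 2)

  fit0 <- ae_train(p0, list(v), train_config(epochs = 0, seed = 2))
  expect_identical(fit0$params$weights, p0$weights)
  expect_equal(nrow(fit0$history), 0)

  cfg <- train_config(epochs = 200, seed = 2)
  fit1 <- ae_train(p0, list(v), cfg)
  fit2 <- ae_train(p0, list(v), cfg)
  expect_identical(fit1$history$loss, fit2$history$loss)
  expect_lt(fit1$history$loss[200], fit1$history$loss[1])
  expect_true(all(fit1$history$loss >= 0))

  raw <- generate_phantom(spec, 0)   # unnormalized, exceeds (-1, 1)
  expect_error(ae_train(p0, list(raw), cfg), "normalize")
})

test_that("parameter_count equals brute-force enumeration of model scalars", {
  expect_equal(parameter_count(c(3, 2))$parameter_count, 8)
  expect_equal(parameter_count(c(5, 1))$parameter_count, 6)
  expect_error(parameter_count(7), "at least 2")

  # against an instantiated autoencoder
  p <- ae_init(20, hidden_width = 3, seed = 1)
  n_scalars <- sum(lengths(p$weights)) + sum(lengths(p$biases))
  expect_equal(parameter_count(p$layer_sizes)$parameter_count, n_scalars)
  expect_equal(parameter_count(p)$parameter_count, n_scalars)

  # against directly instantiated random dense stacks
  set.seed(99)
  for (rep in 1:5) {
    sizes <- sample(1:9, sample(2:6, 1), replace = TRUE)
    built <- lapply(seq_len(length(sizes) - 1), function(k) {
      list(W = matrix(0, sizes[k + 1], sizes[k]), b = numeric(sizes[k + 1]))
    })
    brute <- sum(vapply(built, function(l) length(l$W) + length(l$b),
                        numeric(1)))
    expect_equal(parameter_count(sizes)$parameter_count, brute)
  }
})

test_that("compare_optimizers is consistent with plain training runs", {
  spec <- phantom_spec(shape = c(8, 8, 8), noise_sd = 0.02, seed = 5)
  v <- normalize_volume(generate_phantom(spec, 0), c(-1, 1))
  cfg <- train_config(epochs = 50, seed = 4)

  tbl1 <- compare_optimizers(list(v), cfg, optimizers = "adam")
  ref <- ae_train(ae_init(prod(dim(v)), seed = 4), list(v), cfg)
  expect_equal(nrow(tbl1), 1)
  expect_equal(tbl1$final_loss, ref$history$loss[50])

  tbl <- compare_optimizers(list(v), cfg)
  expect_equal(tbl$optimizer, c("adam", "sgd_momentum", "rmsprop", "adagrad"))
  expect_true(all(is.finite(tbl$final_loss)))
  expect_true(all(is.finite(tbl$ssim)))

  expect_error(compare_optimizers(list(v), cfg, optimizers = "lbfgs"),
               "unknown optimizer")
})
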