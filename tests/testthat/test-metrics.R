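test_that("mse/mae match hand values and are symmetric", {
  a <- array(0, dim = c(4, 4)); b <- array(0.1, dim = c(4, 4))
  expect_equal(mse(a, a), 0)
  expect_equal(mse(a, b), 0.01)
  expect_equal(mae(a, a), 0)
  expect_equal(mae(a, a + 0.5), 0.5)
  x <- matrix(rnorm(16), 4); y <- matrix(rnorm(16), 4)
  expect_equal(mse(x, y), mse(y, x))
  expect_error(mse(matrix(0, 2, 2), matrix(0, 3, 3)), "shape mismatch")
})

test_that("psnr follows 10*log10(R^2/mse) with Inf at zero error", {
  a <- matrix(0, 4, 4)
  expect_equal(psnr(a, a, 1), Inf)
  expect_equal(psnr(a, a + 0.1, 1), 20)         # mse 0.01, R 1
  expect_equal(psnr(a, a + 1, 1), 0)            # mse = R^2
  expect_error(psnr(a, a, 0), "> 0")
  set.seed(1)
  for (rep in 1:20) {
    x <- matrix(runif(25), 5); y <- matrix(runif(25), 5); R <- runif(1, 0.5, 3)
    expect_equal(psnr(x, y, R), 10 * log10(R^2 / mse(x, y)), tolerance = 1e-9)
  }
})

test_that("mae is bounded by the root of mse (Jensen)", {
  set.seed(7)
  for (rep in 1:30) {
    x <- rnorm(40); y <- rnorm(40)
    expect_lte(mae(x, y), sqrt(mse(x, y)) + 1e-12)
  }
})

test_that("ssim is 1 on identical inputs, symmetric and bounded", {
  set.seed(3)
  a <- matrix(runif(15 * 15), 15)
  b <- matrix(runif(15 * 15), 15)
  expect_equal(ssim(a, a), 1)
  expect_equal(ssim(a, b), ssim(b, a))
  expect_gte(ssim(a, b), -1)
  expect_lte(ssim(a, b), 1)
  v <- array(runif(10^3), dim = c(10, 10, 10))
  expect_equal(ssim(v, v), 1)
  expect_error(ssim(matrix(0, 4, 4), matrix(0, 4, 4), window = 11),
               "window")
})

test_that("ssim of independent-noise images concentrates near zero", {
  vals <- vapply(1:10, function(s) {
    set.seed(s)
    ssim(matrix(rnorm(32 * 32), 32), matrix(rnorm(32 * 32), 32))
  }, numeric(1))
  expect_lt(abs(mean(vals)), 0.1)
  expect_lt(max(abs(vals)), 0.3)
})

test_that("ssim equals the direct formula when one window covers the patch", {
  set.seed(11)
  x <- matrix(runif(64), 8); y <- x + matrix(rnorm(64, sd = 0.2), 8)
  got <- ssim(x, y, data_range = 1, window = 8, gaussian = FALSE)
  expect_equal(got, ssim_single_window(x, y, 1), tolerance = 1e-9)
})

test_that("windowed ssim equals brute-force evaluation on every window", {
  set.seed(13)
  w <- 5
  x <- matrix(runif(12 * 12), 12); y <- x + matrix(rnorm(144, sd = 0.3), 12)
  vals <- c()
  for (i in 1:(12 - w + 1)) for (j in 1:(12 - w + 1)) {
    vals <- c(vals, ssim_single_window(x[i:(i + w - 1), j:(j + w - 1)],
                                       y[i:(i + w - 1), j:(j + w - 1)], 1))
  }
  expect_equal(ssim(x, y, data_range = 1, window = w, gaussian = FALSE),
               mean(vals), tolerance = 1e-9)

  # and in 3D with the uniform window
  xv <- array(runif(8^3), dim = c(8, 8, 8))
  yv <- xv + array(rnorm(8^3, sd = 0.2), dim = c(8, 8, 8))
  vals3 <- c()
  for (i in 1:4) for (j in 1:4) for (k in 1:4) {
    vals3 <- c(vals3, ssim_single_window(
      xv[i:(i + 4), j:(j + 4), k:(k + 4)],
      yv[i:(i + 4), j:(j + 4), k:(k + 4)], 1))
  }
  expect_equal(ssim(xv, yv, data_range = 1, window = 5),
               mean(vals3), tolerance = 1e-9)
})

test_that("metrics are invariant to a common spatial rearrangement", {
  set.seed(17)
  x <- matrix(runif(144), 12); y <- matrix(runif(144), 12)
  perm <- sample(144)
  expect_equal(mse(x, y), mse(x[perm], y[perm]))
  expect_equal(mae(x, y), mae(x[perm], y[perm]))
  # transposing both inputs leaves the square-window SSIM unchanged
  expect_equal(ssim(x, y), ssim(t(x), t(y)), tolerance = 1e-12)
})

test_that("reports collect all four metrics consistently with a group tag", {
  spec <- phantom_spec(shape = c(12, 12, 12), seed = 8)
  v <- normalize_volume(generate_phantom(spec, 0), c(-1, 1))
  r_same <- reconstruction_report(v, v, group = "HC")
  expect_equal(r_same$ssim, 1)
  expect_equal(r_same$psnr, Inf)
  expect_equal(r_same$mse, 0)
  expect_equal(r_same$mae, 0)
  expect_equal(r_same$group, "HC")

  w <- normalize_volume(generate_phantom(spec, 1, 2), c(-1, 1))
  r <- reconstruction_report(v, w, group = "ASD")
  expect_equal(r$mse, mse(v, w))
  expect_equal(r$mae, mae(v, w))
  expect_equal(r$psnr, psnr(v, w, 2))
  expect_equal(r$ssim, ssim(unclass(v), unclass(w), data_range = 2))

  v01 <- normalize_volume(generate_phantom(spec, 0), c(0, 1))
  expect_error(reconstruction_report(v, v01), "ranges")

  reports <- rbind(r_same, r_same, r)
  summ <- summarize_reports(reports)
  hc <- summ[summ$group == "HC", ]
  expect_equal(hc$n, 2)
  expect_equal(hc$mse, 0)
  expect_equal(summ[summ$group == "ASD", ]$ssim, r$ssim)
})
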