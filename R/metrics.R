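as_metric_array <- function(x) {
  if (inherits(x, "mri_volume")) volume_data(x)
  else if (inherits(x, "mri_slice")) slice_data(x)
  else if (is.array(x) || is.matrix(x)) unclass(x)
  else as.numeric(x)
}

check_same_shape <- function(ref, test) {
  dr <- dim(ref) %||% length(ref)
  dt <- dim(test) %||% length(test)
  if (!identical(as.integer(dr), as.integer(dt))) {
    stop(sprintf("shape mismatch: %s vs %s",
                 paste(dr, collapse = "x"), paste(dt, collapse = "x")),
         call. = FALSE)
  }
}

#' Mean squared error
#'
#' @param ref,test arrays, slices or volumes of identical shape.
#' @return Mean over all elements of the squared difference.
#' @export
mse <- function(ref, test) {
  ref <- as_metric_array(ref); test <- as_metric_array(test)
  check_same_shape(ref, test)
  mean((test - ref)^2)
}

#' Mean absolute error
#'
#' @inheritParams mse
#' @return Mean over all elements of the absolute difference.
#' @export
mae <- function(ref, test) {
  ref <- as_metric_array(ref); test <- as_metric_array(test)
  check_same_shape(ref, test)
  mean(abs(test - ref))
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(R^2 / MSE)` in decibels, where `R` is the dynamic range of
#' the data (2 for intensities normalized to (-1, 1), 1 for (0, 1)).
#' Identical inputs give `Inf`.
#'
#' @inheritParams mse
#' @param data_range positive dynamic range R.
#' @return PSNR in dB (possibly `Inf`).
#' @export
psnr <- function(ref, test, data_range = 1) {
  if (data_range <= 0) stop("`data_range` must be > 0", call. = FALSE)
  m <- mse(ref, test)
  if (m == 0) Inf else 10 * log10(data_range^2 / m)
}

# valid-mode separable correlation of `a` with 1D kernel `k` along each axis
sep_filter_valid <- function(a, k) {
  w <- length(k)
  nd <- length(dim(a) %||% 1L)
  if (is.null(dim(a))) a <- array(a, dim = length(a))
  for (ax in seq_len(nd)) {
    n <- dim(a)[1L]
    m <- n - w + 1L
    out <- 0
    for (j in seq_len(w)) {
      idx <- c(list(seq(j, j + m - 1L)),
               rep(list(quote(expr = )), length(dim(a)) - 1L))
      out <- out + k[j] * do.call(`[`, c(list(a), idx, list(drop = FALSE)))
    }
    # rotate axes so each axis takes a turn in first position
    a <- aperm(out, c(seq_along(dim(out))[-1L], 1L))
  }
  a
}

gaussian_kernel_1d <- function(size, sigma) {
  x <- seq_len(size) - (size + 1) / 2
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Structural similarity index
#'
#' Mean over sliding windows of the standard SSIM map
#' `((2*mu_x*mu_y + C1) * (2*sigma_xy + C2)) /
#'  ((mu_x^2 + mu_y^2 + C1) * (sigma_x^2 + sigma_y^2 + C2))`
#' with `C1 = (K1*R)^2`, `C2 = (K2*R)^2`. Local statistics are weighted
#' means over the window (population convention); the map is evaluated at
#' every position where the full window fits (valid mode, no padding).
#'
#' Defaults follow common practice: 2D inputs use an 11x11 Gaussian window
#' with sigma 1.5; 3D inputs use a uniform 7x7x7 window.
#'
#' @inheritParams mse
#' @param data_range positive dynamic range R shared by both inputs.
#' @param window odd window side length; `NULL` picks 11 (2D, Gaussian) or
#'   7 (3D, uniform).
#' @param K1,K2 stabilization constants (defaults 0.01 and 0.03).
#' @param gaussian use Gaussian window weights (default for 2D); uniform
#'   weights otherwise.
#' @param sigma Gaussian window standard deviation (pixels).
#' @return SSIM in `[-1, 1]`; 1 for identical inputs.
#' @export
ssim <- function(ref, test, data_range = 1, window = NULL,
                 K1 = 0.01, K2 = 0.03, gaussian = NULL, sigma = 1.5) {
  ref <- as_metric_array(ref); test <- as_metric_array(test)
  check_same_shape(ref, test)
  if (data_range <= 0) stop("`data_range` must be > 0", call. = FALSE)
  nd <- length(dim(ref) %||% 1L)
  if (is.null(gaussian)) gaussian <- nd <= 2L
  if (is.null(window)) window <- if (nd <= 2L) 11L else 7L
  d <- dim(ref) %||% length(ref)
  if (any(d < window)) {
    stop(sprintf("window %d larger than image extent %s", window,
                 paste(d, collapse = "x")), call. = FALSE)
  }
  k <- if (gaussian) gaussian_kernel_1d(window, sigma) else
    rep(1 / window, window)
  mu_x <- sep_filter_valid(ref, k)
  mu_y <- sep_filter_valid(test, k)
  mu_xx <- sep_filter_valid(ref * ref, k)
  mu_yy <- sep_filter_valid(test * test, k)
  mu_xy <- sep_filter_valid(ref * test, k)
  var_x <- mu_xx - mu_x^2
  var_y <- mu_yy - mu_y^2
  cov_xy <- mu_xy - mu_x * mu_y
  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  map <- ((2 * mu_x * mu_y + C1) * (2 * cov_xy + C2)) /
    ((mu_x^2 + mu_y^2 + C1) * (var_x + var_y + C2))
  mean(map)
}

#' Per-volume reconstruction report
#'
#' Computes all four reconstruction metrics with a consistent data range
#' and returns them as one tibble row, optionally tagged with a group
#' label (e.g. `"ASD"` or `"HC"`) for grouped summaries.
#'
#' The data range defaults to the width of the inputs' normalization
#' interval; both inputs must carry the same interval when present.
#'
#' @param ref,test `mri_volume`s or `mri_slice`s of identical shape.
#' @param group optional group tag.
#' @param data_range dynamic range override; `NULL` uses the normalization
#'   metadata (falling back to the observed range of `ref`).
#' @param ... further arguments passed to [ssim()].
#' @return A one-row tibble: `ssim`, `psnr`, `mae`, `mse`, `group`, `shape`.
#' @export
reconstruction_report <- function(ref, test, group = NA_character_,
                                  data_range = NULL, ...) {
  rr <- attr(ref, "intensity_range")
  rt <- attr(test, "intensity_range")
  if (!is.null(rr) && !is.null(rt) && !isTRUE(all.equal(rr, rt))) {
    stop("inputs carry different normalization ranges; renormalize first",
         call. = FALSE)
  }
  if (is.null(data_range)) {
    data_range <- if (!is.null(rr %||% rt)) diff(rr %||% rt)
                  else max(diff(range(as_metric_array(ref))), 1e-12)
  }
  a <- as_metric_array(ref); b <- as_metric_array(test)
  check_same_shape(a, b)
  tibble::tibble(
    ssim = ssim(a, b, data_range = data_range, ...),
    psnr = psnr(a, b, data_range = data_range),
    mae = mae(a, b),
    mse = mse(a, b),
    group = group,
    shape = paste(dim(a) %||% length(a), collapse = "x"))
}

#' Summarize reconstruction reports by group
#'
#' @param reports tibble of rows from [reconstruction_report()].
#' @return tibble of per-group means of `ssim`, `psnr`, `mae`, `mse` and
#'   the group size `n`.
#' @export
summarize_reports <- function(reports) {
  stopifnot(is.data.frame(reports))
  groups <- unique(reports$group)
  rows <- lapply(groups, function(g) {
    r <- reports[is.na(reports$group) == is.na(g) &
                   (is.na(g) | reports$group == g), , drop = FALSE]
    tibble::tibble(group = g, n = nrow(r),
                   ssim = mean(r$ssim), psnr = mean(r$psnr),
                   mae = mean(r$mae), mse = mean(r$mse))
  })
  do.call(rbind, rows)
}
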