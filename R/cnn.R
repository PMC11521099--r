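#' 3D CNN classifier configuration
#'
#' Layer plan of the volumetric two-class discriminator. The default follows
#' the reference architecture: 3x3x3 convolutions with 2 filters in the
#' first layer and 8 in the next, both stride 2 for downsampling; average
#' pooling 2x2x2 stride 2; then deeper 3x3x3 convolutions with 16, 32, 64
#' and 128 filters at stride 1 (same-padding, preserving spatial
#' resolution). All convolutions are rectifier-activated; batch
#' normalization follows every convolution except the first. Two dense
#' layers of 128 (rectifier) and 64 (tanh) units follow, each with dropout
#' 0.5, and the head is 2 softmax units. Training minimizes binary
#' cross-entropy with Adam (learning rate 1e-05) under a
#' reduce-on-plateau schedule.
#'
#' @param input_shape integer length-3 volume shape (desk-scale default
#'   32^3; 128^3 is supported but slow).
#' @param conv_filters filters per convolutional layer.
#' @param conv_stride stride per convolutional layer.
#' @param batch_norm logical per convolutional layer.
#' @param pool_after index of the conv layer after which 2x2x2 stride-2
#'   average pooling is applied.
#' @param dense_units,dense_activation fully-connected plan.
#' @param dropout dropout rate after each dense layer, in `[0, 1)`.
#' @param learning_rate initial Adam learning rate.
#' @param epsilon Adam numerical-stability constant.
#' @param plateau_factor,plateau_patience,min_lr reduce-on-plateau schedule:
#'   multiply the learning rate by `plateau_factor` after
#'   `plateau_patience` epochs without validation-loss improvement, never
#'   below `min_lr`.
#' @param validation_split held-out fraction for the stratified
#'   train/validation split.
#' @param seed integer seed for initialization, splitting, shuffling and
#'   dropout.
#' @return A `cnn_config`.
#' @export
cnn_config <- function(input_shape = c(32, 32, 32),
                       conv_filters = c(2, 8, 16, 32, 64, 128),
                       conv_stride = c(2, 2, 1, 1, 1, 1),
                       batch_norm = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
                       pool_after = 2L,
                       dense_units = c(128, 64),
                       dense_activation = c("relu", "tanh"),
                       dropout = 0.5,
                       learning_rate = 1e-05, epsilon = 1e-08,
                       plateau_factor = 0.5, plateau_patience = 5,
                       min_lr = 1e-07,
                       validation_split = 0.2, seed = 1) {
  input_shape <- as.integer(input_shape)
  if (length(input_shape) != 3L || any(input_shape < 1L)) {
    stop("`input_shape` must be 3 positive integers", call. = FALSE)
  }
  nl <- length(conv_filters)
  if (length(conv_stride) != nl || length(batch_norm) != nl) {
    stop("`conv_filters`, `conv_stride` and `batch_norm` must have equal length",
         call. = FALSE)
  }
  if (dropout < 0 || dropout >= 1) stop("`dropout` must be in [0, 1)", call. = FALSE)
  if (length(dense_units) != length(dense_activation)) {
    stop("dense plan lengths differ", call. = FALSE)
  }
  structure(list(input_shape = input_shape,
                 conv_filters = as.integer(conv_filters),
                 conv_stride = as.integer(conv_stride),
                 batch_norm = as.logical(batch_norm),
                 pool_after = as.integer(pool_after),
                 dense_units = as.integer(dense_units),
                 dense_activation = dense_activation,
                 dropout = dropout,
                 learning_rate = learning_rate, epsilon = epsilon,
                 plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 min_lr = min_lr,
                 validation_split = validation_split,
                 seed = as.integer(seed)),
            class = "cnn_config")
}

conv_out_extent <- function(n, stride) (n - 1L) %/% stride + 1L  # same-pad k=3

#' Build the 3D CNN
#'
#' Instantiates the layer plan of a [cnn_config()] with seeded He (conv) /
#' Glorot (dense) initialization and reports the trainable-parameter count
#' in the build log.
#'
#' @param config a [cnn_config()].
#' @return A `cnn_model`: named flat parameter list plus architecture
#'   metadata and batch-norm running statistics.
#' @export
build_cnn <- function(config = cnn_config()) {
  stopifnot(inherits(config, "cnn_config"))
  nl <- length(config$conv_filters)
  dims <- config$input_shape
  arch_conv <- vector("list", nl)
  in_ch <- 1L
  for (k in seq_len(nl)) {
    out_dims <- vapply(dims, conv_out_extent, integer(1),
                       stride = config$conv_stride[k])
    arch_conv[[k]] <- list(in_ch = in_ch, out_ch = config$conv_filters[k],
                           stride = config$conv_stride[k],
                           bn = config$batch_norm[k],
                           in_dims = dims, out_dims = out_dims)
    dims <- out_dims
    in_ch <- config$conv_filters[k]
    if (k == config$pool_after) {
      pooled <- dims %/% 2L
      if (any(pooled < 1L)) {
        stop(sprintf(paste0("input %s is too small: average pooling after ",
                            "conv layer %d would reduce extent %s to zero"),
                     paste(config$input_shape, collapse = "x"), k,
                     paste(dims, collapse = "x")), call. = FALSE)
      }
      arch_conv[[k]]$pool <- TRUE
      dims <- pooled
    }
  }
  flat_dim <- prod(dims) * in_ch
  params <- with_private_seed(config$seed, {
    p <- list()
    for (k in seq_len(nl)) {
      a <- arch_conv[[k]]
      fan_in <- 27L * a$in_ch
      p[[paste0("conv", k, ".W")]] <-
        matrix(stats::rnorm(fan_in * a$out_ch, sd = sqrt(2 / fan_in)),
               nrow = fan_in, ncol = a$out_ch)
      p[[paste0("conv", k, ".b")]] <- numeric(a$out_ch)
      if (a$bn) {
        p[[paste0("conv", k, ".gamma")]] <- rep(1, a$out_ch)
        p[[paste0("conv", k, ".beta")]] <- numeric(a$out_ch)
      }
    }
    d_in <- flat_dim
    for (j in seq_along(config$dense_units)) {
      d_out <- config$dense_units[j]
      lim <- sqrt(6 / (d_in + d_out))
      p[[paste0("dense", j, ".W")]] <-
        matrix(stats::runif(d_in * d_out, -lim, lim), nrow = d_in, ncol = d_out)
      p[[paste0("dense", j, ".b")]] <- numeric(d_out)
      d_in <- d_out
    }
    lim <- sqrt(6 / (d_in + 2))
    p[["head.W"]] <- matrix(stats::runif(d_in * 2, -lim, lim),
                            nrow = d_in, ncol = 2L)
    p[["head.b"]] <- numeric(2L)
    p
  })
  running <- list()
  for (k in seq_len(nl)) {
    if (arch_conv[[k]]$bn) {
      running[[paste0("conv", k, ".mean")]] <- numeric(config$conv_filters[k])
      running[[paste0("conv", k, ".var")]] <- rep(1, config$conv_filters[k])
    }
  }
  n_par <- sum(vapply(params, length, numeric(1)))
  model <- structure(list(config = config, arch_conv = arch_conv,
                          final_dims = dims, flat_dim = flat_dim,
                          params = params, running = running,
                          param_count = n_par),
                     class = "cnn_model")
  message(sprintf("built 3D CNN (%s input): %s trainable parameters",
                  paste(config$input_shape, collapse = "x"),
                  format(n_par, big.mark = ",")))
  model
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model> input %s | conv filters %s | dense %s | head 2 softmax\n",
              paste(x$config$input_shape, collapse = "x"),
              paste(x$config$conv_filters, collapse = ","),
              paste(x$config$dense_units, collapse = ",")))
  cat(sprintf("  trainable parameters: %s\n",
              format(x$param_count, big.mark = ",")))
  invisible(x)
}

avgpool2 <- function(a) {
  d <- dim(a)
  a <- (a[seq(1, d[1], 2), , , , drop = FALSE] +
          a[seq(2, d[1], 2), , , , drop = FALSE]) / 2
  a <- (a[, seq(1, d[2], 2), , , drop = FALSE] +
          a[, seq(2, d[2], 2), , , drop = FALSE]) / 2
  (a[, , seq(1, d[3], 2), , drop = FALSE] +
     a[, , seq(2, d[3], 2), , drop = FALSE]) / 2
}

avgpool2_back <- function(g) {
  d <- dim(g)
  g[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2),
    rep(seq_len(d[3]), each = 2), , drop = FALSE] / 8
}

softmax2 <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

cnn_input_vector <- function(model, v) {
  a <- if (inherits(v, "mri_volume")) volume_data(v) else v
  d <- dim(a) %||% length(a)
  if (!identical(as.integer(d), model$config$input_shape)) {
    stop(sprintf("volume shape %s does not match model input %s",
                 paste(d, collapse = "x"),
                 paste(model$config$input_shape, collapse = "x")),
         call. = FALSE)
  }
  as.numeric(a)
}

# full forward pass; `training` enables batch statistics and dropout (which
# consumes the caller's RNG stream); cache retains intermediates for backprop
cnn_forward <- function(model, x, training = FALSE, keep_cache = FALSE) {
  cfg <- model$config
  p <- model$params
  eps <- 1e-5
  cache <- list(conv = vector("list", length(model$arch_conv)), dense = list())
  cur <- x
  for (k in seq_along(model$arch_conv)) {
    a <- model$arch_conv[[k]]
    Xcol <- im2col3d(cur, c(a$in_dims, a$in_ch), a$stride)
    Z <- Xcol %*% p[[paste0("conv", k, ".W")]]
    Z <- Z + rep(p[[paste0("conv", k, ".b")]], each = nrow(Z))
    A <- Z * (Z > 0)
    ck <- list(Xcol = Xcol, relu_mask = Z > 0)
    if (a$bn) {
      gamma <- p[[paste0("conv", k, ".gamma")]]
      beta <- p[[paste0("conv", k, ".beta")]]
      if (training) {
        mu <- colMeans(A)
        va <- colMeans(A * A) - mu^2
        model$running[[paste0("conv", k, ".mean")]] <-
          0.9 * model$running[[paste0("conv", k, ".mean")]] + 0.1 * mu
        model$running[[paste0("conv", k, ".var")]] <-
          0.9 * model$running[[paste0("conv", k, ".var")]] + 0.1 * va
      } else {
        mu <- model$running[[paste0("conv", k, ".mean")]]
        va <- model$running[[paste0("conv", k, ".var")]]
      }
      istd <- 1 / sqrt(va + eps)
      Ahat <- (A - rep(mu, each = nrow(A))) * rep(istd, each = nrow(A))
      A <- Ahat * rep(gamma, each = nrow(A)) + rep(beta, each = nrow(A))
      ck$Ahat <- Ahat; ck$istd <- istd
    }
    if (isTRUE(a$pool)) {
      arr <- array(A, dim = c(a$out_dims, a$out_ch))
      ck$prepool_dims <- dim(arr)
      arr <- avgpool2(arr)
      ck$postpool_dims <- dim(arr)
      cur <- as.numeric(arr)
    } else {
      cur <- as.numeric(A)
    }
    if (keep_cache) cache$conv[[k]] <- ck
  }
  act <- cur
  keep <- 1 - cfg$dropout
  for (j in seq_along(cfg$dense_units)) {
    W <- p[[paste0("dense", j, ".W")]]
    z <- drop(crossprod(W, act)) + p[[paste0("dense", j, ".b")]]
    a_act <- if (cfg$dense_activation[j] == "tanh") tanh(z) else z * (z > 0)
    cj <- list(input = act, z = z, a_act = a_act)
    if (training && cfg$dropout > 0) {
      mask <- stats::runif(length(a_act)) >= cfg$dropout
      act <- a_act * mask / keep
      cj$mask <- mask
    } else {
      act <- a_act
    }
    if (keep_cache) cache$dense[[j]] <- cj
  }
  logits <- drop(crossprod(p[["head.W"]], act)) + p[["head.b"]]
  probs <- softmax2(logits)
  list(probs = probs, head_input = act, cache = if (keep_cache) cache,
       model = model)
}

# backprop of the cross-entropy loss for one sample; returns named gradients
cnn_backward <- function(model, fw, label) {
  cfg <- model$config
  p <- model$params
  grads <- list()
  onehot <- c(1 - label, label)
  dlog <- fw$probs - onehot
  grads[["head.W"]] <- fw$head_input %o% dlog
  grads[["head.b"]] <- dlog
  da <- drop(p[["head.W"]] %*% dlog)
  keep <- 1 - cfg$dropout
  for (j in rev(seq_along(cfg$dense_units))) {
    cj <- fw$cache$dense[[j]]
    if (!is.null(cj$mask)) da <- da * cj$mask / keep
    dz <- if (cfg$dense_activation[j] == "tanh") da * (1 - cj$a_act^2)
          else da * (cj$z > 0)
    grads[[paste0("dense", j, ".W")]] <- cj$input %o% dz
    grads[[paste0("dense", j, ".b")]] <- dz
    da <- drop(p[[paste0("dense", j, ".W")]] %*% dz)
  }
  for (k in rev(seq_along(model$arch_conv))) {
    a <- model$arch_conv[[k]]
    ck <- fw$cache$conv[[k]]
    if (isTRUE(a$pool)) {
      g <- array(da, dim = ck$postpool_dims)
      dA <- matrix(avgpool2_back(g), ncol = a$out_ch)
    } else {
      dA <- matrix(da, ncol = a$out_ch)
    }
    if (a$bn) {
      N <- nrow(dA)
      gamma <- p[[paste0("conv", k, ".gamma")]]
      grads[[paste0("conv", k, ".gamma")]] <- colSums(dA * ck$Ahat)
      grads[[paste0("conv", k, ".beta")]] <- colSums(dA)
      dAhat <- dA * rep(gamma, each = N)
      m1 <- colMeans(dAhat)
      m2 <- colMeans(dAhat * ck$Ahat)
      dA <- rep(ck$istd, each = N) *
        (dAhat - rep(m1, each = N) - ck$Ahat * rep(m2, each = N))
    }
    dZ <- dA * ck$relu_mask
    grads[[paste0("conv", k, ".W")]] <- crossprod(ck$Xcol, dZ)
    grads[[paste0("conv", k, ".b")]] <- colSums(dZ)
    if (k > 1L) {
      dXcol <- dZ %*% t(p[[paste0("conv", k, ".W")]])
      da <- col2im3d(dXcol, c(a$in_dims, a$in_ch), a$stride)
    }
  }
  grads
}

#' Predict class probabilities for one volume
#'
#' Inference-mode forward pass (dropout disabled, batch-norm running
#' statistics), so repeated calls on the same input are identical. The two
#' probabilities sum to one.
#'
#' @param model a `cnn_model`.
#' @param v a `mri_volume` (or 3D array) matching the model input shape.
#' @return A one-row tibble: `p_healthy`, `p_diseased`.
#' @export
predict_proba <- function(model, v) {
  stopifnot(inherits(model, "cnn_model"))
  x <- cnn_input_vector(model, v)
  pr <- cnn_forward(model, x, training = FALSE)$probs
  tibble::tibble(p_healthy = pr[1L], p_diseased = pr[2L])
}

#' Predict class probabilities for a cohort
#'
#' @param model a `cnn_model`.
#' @param cohort a `labeled_cohort`.
#' @return tibble with one row per volume: `label`, `p_healthy`,
#'   `p_diseased`.
#' @export
predict_cohort <- function(model, cohort) {
  stopifnot(inherits(cohort, "labeled_cohort"))
  rows <- lapply(cohort$volumes, function(v) predict_proba(model, v))
  out <- do.call(rbind, rows)
  tibble::tibble(label = cohort$labels, p_healthy = out$p_healthy,
                 p_diseased = out$p_diseased)
}

stratified_split <- function(labels, validation_split) {
  val_idx <- integer(0)
  for (cl in c(0L, 1L)) {
    idx <- which(labels == cl)
    n_val <- max(1L, round(length(idx) * validation_split))
    val_idx <- c(val_idx, sample(idx, n_val))
  }
  list(train = setdiff(seq_along(labels), val_idx), val = sort(val_idx))
}

bce_loss <- function(probs, label) -log(max(probs[label + 1L], 1e-12))

#' Train the 3D CNN classifier
#'
#' Streams volumes one at a time, minimizing binary cross-entropy with
#' Adam; a stratified validation split monitors generalization and drives
#' the reduce-on-plateau learning-rate schedule. Batch-norm layers use
#' per-sample spatial statistics during training and running statistics at
#' inference. Entirely seeded: identical configs and cohorts give identical
#' histories.
#'
#' @param model a `cnn_model` from [build_cnn()].
#' @param cohort a `labeled_cohort` with both classes present; volumes must
#'   match the model input shape.
#' @param epochs number of passes over the training split.
#' @return A `cnn_fit`: list with `model`, `history` tibble (`epoch`,
#'   `loss`, `val_loss`, `lr`), `train_idx`, `val_idx`.
#' @export
train_cnn <- function(model, cohort, epochs = 30) {
  stopifnot(inherits(model, "cnn_model"), inherits(cohort, "labeled_cohort"))
  labels <- cohort$labels
  if (length(unique(labels)) < 2L) {
    stop("cohort must contain both classes", call. = FALSE)
  }
  cfg <- model$config
  xs <- lapply(cohort$volumes, function(v) cnn_input_vector(model, v))
  out <- with_private_seed(cfg$seed + 104729L, {
    split <- stratified_split(labels, cfg$validation_split)
    if (epochs == 0L) {
      empty <- tibble::tibble(epoch = integer(0), loss = numeric(0),
                              val_loss = numeric(0), lr = numeric(0))
      return_value <- list(model = model, history = empty,
                           train_idx = split$train, val_idx = split$val)
      return_value
    } else {
    m_st <- lapply(model$params, function(x) array(0, dim = dim(x) %||% length(x)))
    v_st <- m_st
    t_st <- 0L
    lr <- cfg$learning_rate
    best_val <- Inf
    wait <- 0L
    hist <- vector("list", epochs)
    for (epoch in seq_len(epochs)) {
      ord <- split$train[sample.int(length(split$train))]
      ep_loss <- 0
      for (i in ord) {
        fw <- cnn_forward(model, xs[[i]], training = TRUE, keep_cache = TRUE)
        model <- fw$model                       # batch-norm running stats
        ep_loss <- ep_loss + bce_loss(fw$probs, labels[i])
        g <- cnn_backward(model, fw, labels[i])
        t_st <- t_st + 1L
        for (nm in names(model$params)) {
          gn <- g[[nm]]
          m_st[[nm]] <- 0.9 * m_st[[nm]] + 0.1 * gn
          v_st[[nm]] <- 0.999 * v_st[[nm]] + 0.001 * gn^2
          mhat <- m_st[[nm]] / (1 - 0.9^t_st)
          vhat <- v_st[[nm]] / (1 - 0.999^t_st)
          model$params[[nm]] <- model$params[[nm]] -
            lr * mhat / (sqrt(vhat) + cfg$epsilon)
        }
      }
      val_loss <- mean(vapply(split$val, function(i) {
        bce_loss(cnn_forward(model, xs[[i]], training = FALSE)$probs, labels[i])
      }, numeric(1)))
      hist[[epoch]] <- tibble::tibble(epoch = epoch,
                                      loss = ep_loss / length(ord),
                                      val_loss = val_loss, lr = lr)
      if (val_loss < best_val - 1e-8) {
        best_val <- val_loss
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$plateau_patience) {
          lr <- max(lr * cfg$plateau_factor, cfg$min_lr)
          wait <- 0L
        }
      }
    }
    list(model = model, history = do.call(rbind, hist),
         train_idx = split$train, val_idx = split$val)
    }
  })
  structure(out, class = "cnn_fit")
}

#' @export
print.cnn_fit <- function(x, ...) {
  n <- nrow(x$history)
  cat(sprintf("<cnn_fit> %d epochs | final loss %.4f | final val loss %.4f\n",
              n, if (n) x$history$loss[n] else NA,
              if (n) x$history$val_loss[n] else NA))
  invisible(x)
}

#' Evaluate a fitted classifier on its held-out split
#'
#' Scores the validation volumes of a [train_cnn()] fit and returns the
#' ROC/AUC/accuracy report.
#'
#' @param fit a `cnn_fit`.
#' @param cohort the `labeled_cohort` the fit was trained on.
#' @return A `roc_report` (see [evaluate_classifier()]).
#' @export
holdout_eval <- function(fit, cohort) {
  stopifnot(inherits(fit, "cnn_fit"), inherits(cohort, "labeled_cohort"))
  sub <- as_cohort(cohort$volumes[fit$val_idx], cohort$labels[fit$val_idx])
  preds <- predict_cohort(fit$model, sub)
  evaluate_classifier(preds$label, preds$p_diseased)
}

#' Plot a training history
#'
#' @param object an `ae_fit` or `cnn_fit`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cnn_fit <- function(object, ...) {
  h <- object$history
  df <- rbind(data.frame(epoch = h$epoch, loss = h$loss, set = "training"),
              data.frame(epoch = h$epoch, loss = h$val_loss, set = "validation"))
  ggplot2::ggplot(df, ggplot2::aes(x = epoch, y = loss, colour = set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Epoch", y = "Cross-entropy loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ae_fit <- function(object, ...) {
  ggplot2::ggplot(object$history, ggplot2::aes(x = epoch, y = loss)) +
    ggplot2::geom_line(colour = "#2171b5") +
    ggplot2::labs(x = "Epoch", y = "Reconstruction loss") +
    ggplot2::theme_minimal()
}
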