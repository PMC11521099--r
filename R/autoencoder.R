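#' Fully-connected bottleneck autoencoder
#'
#' The reconstruction model is a symmetric dense autoencoder: the encoder
#' compresses a flattened volume through rectifier-activated layers of 4 and
#' 2 units; an intermediate fully-connected layer of width `hidden_width`
#' sits between encoder and decoder; the decoder mirrors the encoder (2 then
#' 4 units, rectifier) and ends in a tanh output layer of the input
#' dimension, so reconstructions live in (-1, 1). Layer sizes are therefore
#' `[D, 4, 2, H, 2, 4, D]`.
#'
#' Weights are drawn from a seeded uniform fan-in scheme
#' (`U(-1/sqrt(n_in), 1/sqrt(n_in))`); biases start at zero.
#'
#' @param input_dim D, the flattened input length (e.g. 2,097,152 for a
#'   128^3 volume).
#' @param hidden_width H, the width of the intermediate layer between
#'   encoder and decoder (default 2, continuing the bottleneck).
#' @param seed integer seed for weight initialization.
#' @return A `dense_autoencoder`: list with `layer_sizes`, `weights`,
#'   `biases`, `hidden_activation` ("relu") and `output_activation` ("tanh").
#' @export
ae_init <- function(input_dim, hidden_width = 2, seed = 1) {
  if (input_dim < 1 || hidden_width < 1) {
    stop("`input_dim` and `hidden_width` must be >= 1", call. = FALSE)
  }
  sizes <- as.integer(c(input_dim, 4, 2, hidden_width, 2, 4, input_dim))
  n_layers <- length(sizes) - 1L
  params <- with_private_seed(seed, {
    weights <- vector("list", n_layers)
    for (k in seq_len(n_layers)) {
      fan_in <- sizes[k]
      lim <- 1 / sqrt(fan_in)
      weights[[k]] <- matrix(stats::runif(sizes[k + 1L] * fan_in, -lim, lim),
                             nrow = sizes[k + 1L], ncol = fan_in)
    }
    weights
  })
  structure(list(layer_sizes = sizes,
                 weights = params,
                 biases = lapply(sizes[-1L], function(n) numeric(n)),
                 hidden_activation = "relu",
                 output_activation = "tanh"),
            class = "dense_autoencoder")
}

#' @export
print.dense_autoencoder <- function(x, ...) {
  cat(sprintf("<dense_autoencoder> layers %s (%s hidden, %s output)\n",
              paste(x$layer_sizes, collapse = "-"),
              x$hidden_activation, x$output_activation))
  cat(sprintf("  trainable parameters: %s\n",
              format(parameter_count(x$layer_sizes)$parameter_count,
                     big.mark = ",")))
  invisible(x)
}

relu <- function(z) pmax(z, 0)

ae_check_x <- function(p, x, what = "input") {
  x <- as.numeric(x)
  if (length(x) != p$layer_sizes[1L]) {
    stop(sprintf("%s length %d does not match model input dimension %d",
                 what, length(x), p$layer_sizes[1L]), call. = FALSE)
  }
  x
}

# forward pass keeping pre-activations and activations for backprop
ae_forward <- function(p, x) {
  n_layers <- length(p$weights)
  a <- vector("list", n_layers + 1L)
  z <- vector("list", n_layers)
  a[[1L]] <- x
  for (k in seq_len(n_layers)) {
    z[[k]] <- drop(p$weights[[k]] %*% a[[k]]) + p$biases[[k]]
    a[[k + 1L]] <- if (k == n_layers) tanh(z[[k]]) else relu(z[[k]])
  }
  list(a = a, z = z)
}

#' Encode a flattened volume to its bottleneck code
#'
#' Applies the two encoder layers (`h = relu(W x + b)` per layer); the code
#' is the 2-unit bottleneck activation.
#'
#' @param p a `dense_autoencoder`.
#' @param x numeric vector (or `flat_volume`) of length `input_dim`.
#' @return Numeric code vector of length 2.
#' @export
ae_encode <- function(p, x) {
  x <- ae_check_x(p, x)
  for (k in 1:2) x <- relu(drop(p$weights[[k]] %*% x) + p$biases[[k]])
  x
}

#' Decode a bottleneck code to a flattened reconstruction
#'
#' Applies the intermediate layer and the decoder; interior layers use the
#' rectifier, the final layer tanh, so every output component is in (-1, 1).
#'
#' @param p a `dense_autoencoder`.
#' @param h numeric code vector (bottleneck width, 2 by default).
#' @return Numeric vector of length `input_dim`.
#' @export
ae_decode <- function(p, h) {
  h <- as.numeric(h)
  if (length(h) != p$layer_sizes[3L]) {
    stop(sprintf("code length %d does not match bottleneck width %d",
                 length(h), p$layer_sizes[3L]), call. = FALSE)
  }
  n_layers <- length(p$weights)
  for (k in 3:n_layers) {
    z <- drop(p$weights[[k]] %*% h) + p$biases[[k]]
    h <- if (k == n_layers) tanh(z) else relu(z)
  }
  h
}

#' Reconstruct a flattened volume
#'
#' `ae_reconstruct(p, x)` is exactly `ae_decode(p, ae_encode(p, x))`.
#'
#' @inheritParams ae_encode
#' @return Numeric vector of length `input_dim`.
#' @export
ae_reconstruct <- function(p, x) ae_decode(p, ae_encode(p, x))

#' Reconstruct a volume through the autoencoder
#'
#' Flattens, reconstructs and unflattens, preserving shape metadata.
#'
#' @param p a `dense_autoencoder`.
#' @param v a normalized `mri_volume`.
#' @return A reconstructed `mri_volume`.
#' @export
reconstruct_volume <- function(p, v) {
  f <- flatten_volume(v)
  y <- ae_reconstruct(p, as.numeric(f))
  attributes(y) <- attributes(unclass(f))
  unflatten_volume(structure(y, class = "flat_volume"))
}

#' Reconstruction loss
#'
#' Squared-error reconstruction loss between an input `x` and an output `y`.
#' `type = "mean"` (default) averages over components, keeping the loss
#' scale independent of the input dimension; `type = "sum"` is the raw
#' squared L2 norm.
#'
#' @param x,y equal-length numeric vectors.
#' @param type `"mean"` or `"sum"`.
#' @return Non-negative scalar.
#' @export
ae_loss <- function(x, y, type = c("mean", "sum")) {
  type <- match.arg(type)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop(sprintf("length mismatch: %d vs %d", length(x), length(y)),
         call. = FALSE)
  }
  s <- sum((y - x)^2)
  if (type == "mean") s / length(x) else s
}

#' Loss gradient for one sample by backpropagation
#'
#' Exact partial derivatives of the reconstruction loss with respect to
#' every weight and bias, for a single flattened sample (the target is the
#' input itself).
#'
#' @param p a `dense_autoencoder`.
#' @param x numeric input vector of length `input_dim`.
#' @param loss `"mean"` or `"sum"` convention (see [ae_loss()]).
#' @return list with `weights`, `biases` (shapes matching `p`) and the
#'   scalar `loss` at `x`.
#' @export
ae_gradient <- function(p, x, loss = c("mean", "sum")) {
  loss <- match.arg(loss)
  x <- ae_check_x(p, x)
  fw <- ae_forward(p, x)
  n_layers <- length(p$weights)
  y <- fw$a[[n_layers + 1L]]
  dW <- vector("list", n_layers)
  db <- vector("list", n_layers)
  dy <- 2 * (y - x)
  if (loss == "mean") dy <- dy / length(x)
  delta <- dy * (1 - y^2)                       # tanh'
  for (k in n_layers:1) {
    dW[[k]] <- tcrossprod(delta, fw$a[[k]])
    db[[k]] <- delta
    if (k > 1L) {
      delta <- drop(crossprod(p$weights[[k]], delta)) * (fw$z[[k - 1L]] > 0)
    }
  }
  list(weights = dW, biases = db, loss = ae_loss(x, y, loss))
}

#' One plain gradient-descent step
#'
#' Moves every weight and bias by minus the learning rate times its partial
#' derivative: `W <- W - v * dJ/dW`, `b <- b - v * dJ/db`.
#'
#' @param p a `dense_autoencoder`.
#' @param gradient list with `weights` and `biases` matching `p`'s shapes.
#' @param v positive learning rate.
#' @return Updated `dense_autoencoder`.
#' @export
sgd_step <- function(p, gradient, v) {
  if (v <= 0) stop("learning rate must be > 0", call. = FALSE)
  for (k in seq_along(p$weights)) {
    if (!identical(dim(p$weights[[k]]), dim(gradient$weights[[k]]))) {
      stop("gradient shape mismatch at layer ", k, call. = FALSE)
    }
    p$weights[[k]] <- p$weights[[k]] - v * gradient$weights[[k]]
    p$biases[[k]] <- p$biases[[k]] - v * gradient$biases[[k]]
  }
  p
}

#' Training configuration
#'
#' @param optimizer one of `"adam"` (default), `"sgd_momentum"`,
#'   `"rmsprop"`, `"adagrad"`.
#' @param learning_rate positive step size (default 0.001).
#' @param epsilon numerical-stability constant of the adaptive optimizers
#'   (default 1e-08).
#' @param epochs number of full passes over the training samples.
#' @param batch_size samples per gradient update; 1 (the default) streams
#'   one image at a time.
#' @param seed integer seed controlling sample order.
#' @param loss `"mean"` or `"sum"` squared-error convention.
#' @return A `train_config`.
#' @export
train_config <- function(optimizer = c("adam", "sgd_momentum", "rmsprop",
                                       "adagrad"),
                         learning_rate = 0.001, epsilon = 1e-08,
                         epochs = 100, batch_size = 1, seed = 1,
                         loss = c("mean", "sum")) {
  optimizer <- match.arg(optimizer)
  loss <- match.arg(loss)
  if (learning_rate <= 0) stop("`learning_rate` must be > 0", call. = FALSE)
  if (batch_size < 1) stop("`batch_size` must be >= 1", call. = FALSE)
  if (epochs < 0) stop("`epochs` must be >= 0", call. = FALSE)
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 epsilon = epsilon, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), loss = loss),
            class = "train_config")
}

# stateful first-order optimizer over a flat list of parameter arrays;
# returns a closure computing the additive update for a gradient list
make_optimizer <- function(name, lr, eps, shapes) {
  zero <- lapply(shapes, function(s) array(0, dim = s))
  state <- list(m = zero, v = zero, t = 0L)
  function(grads) {
    state$t <<- state$t + 1L
    upd <- vector("list", length(grads))
    for (i in seq_along(grads)) {
      g <- grads[[i]]
      upd[[i]] <- switch(
        name,
        adam = {
          state$m[[i]] <<- 0.9 * state$m[[i]] + 0.1 * g
          state$v[[i]] <<- 0.999 * state$v[[i]] + 0.001 * g^2
          mhat <- state$m[[i]] / (1 - 0.9^state$t)
          vhat <- state$v[[i]] / (1 - 0.999^state$t)
          lr * mhat / (sqrt(vhat) + eps)
        },
        sgd_momentum = {
          state$m[[i]] <<- 0.9 * state$m[[i]] + g
          lr * state$m[[i]]
        },
        rmsprop = {
          state$v[[i]] <<- 0.9 * state$v[[i]] + 0.1 * g^2
          lr * g / (sqrt(state$v[[i]]) + eps)
        },
        adagrad = {
          state$v[[i]] <<- state$v[[i]] + g^2
          lr * g / (sqrt(state$v[[i]]) + eps)
        },
        stop("unknown optimizer: ", name, call. = FALSE))
    }
    upd
  }
}

ae_training_inputs <- function(data) {
  vols <- if (inherits(data, "labeled_cohort")) data$volumes
          else if (inherits(data, "mri_volume")) list(data)
          else if (is.list(data)) data
          else list(data)
  xs <- lapply(vols, function(v) {
    if (inherits(v, "mri_volume")) as.numeric(flatten_volume(v))
    else as.numeric(v)
  })
  rng <- range(unlist(lapply(xs, range)))
  if (rng[1] < -1 || rng[2] > 1) {
    stop(sprintf(paste0("training intensities span [%.3g, %.3g]; normalize ",
                        "volumes into [-1, 1] first (tanh output cannot ",
                        "reach values outside it)"), rng[1], rng[2]),
         call. = FALSE)
  }
  xs
}

#' Train the autoencoder
#'
#' Streams training samples one mini-batch at a time (batch size 1 by
#' default, mirroring generator-style training of large volumes), computes
#' exact backpropagation gradients and applies the configured first-order
#' optimizer. One epoch is one pass over the (possibly single-item) dataset.
#' The recorded per-epoch loss is the mean sample loss evaluated during the
#' pass. Fully deterministic given the config seed.
#'
#' @param p a `dense_autoencoder` whose input dimension matches the data.
#' @param data a `labeled_cohort`, a list of normalized `mri_volume`s, or a
#'   list of flattened numeric vectors; intensities must lie in `[-1, 1]`.
#' @param config a [train_config()].
#' @return An `ae_fit`: list with `params` (trained model), `history`
#'   (tibble of `epoch`, `loss`) and `config`.
#' @export
ae_train <- function(p, data, config = train_config()) {
  stopifnot(inherits(p, "dense_autoencoder"), inherits(config, "train_config"))
  xs <- ae_training_inputs(data)
  if (length(xs) < 1L) stop("need at least one training sample", call. = FALSE)
  n_layers <- length(p$weights)
  shapes <- c(lapply(p$weights, dim), lapply(p$biases, length))
  opt <- make_optimizer(config$optimizer, config$learning_rate,
                        config$epsilon, shapes)
  losses <- numeric(config$epochs)
  if (config$epochs > 0L) {
    for (epoch in seq_len(config$epochs)) {
      ord <- if (length(xs) > 1L) {
        with_private_seed(config$seed + epoch, sample.int(length(xs)))
      } else 1L
      epoch_loss <- 0
      i <- 1L
      while (i <= length(ord)) {
        idx <- ord[seq(i, min(i + config$batch_size - 1L, length(ord)))]
        gW <- NULL; gb <- NULL; bloss <- 0
        for (j in idx) {
          g <- ae_gradient(p, xs[[j]], loss = config$loss)
          bloss <- bloss + g$loss
          if (is.null(gW)) { gW <- g$weights; gb <- g$biases }
          else for (k in seq_len(n_layers)) {
            gW[[k]] <- gW[[k]] + g$weights[[k]]
            gb[[k]] <- gb[[k]] + g$biases[[k]]
          }
        }
        nb <- length(idx)
        if (nb > 1L) for (k in seq_len(n_layers)) {
          gW[[k]] <- gW[[k]] / nb; gb[[k]] <- gb[[k]] / nb
        }
        upd <- opt(c(gW, gb))
        for (k in seq_len(n_layers)) {
          p$weights[[k]] <- p$weights[[k]] - upd[[k]]
          p$biases[[k]] <- p$biases[[k]] - drop(upd[[n_layers + k]])
        }
        epoch_loss <- epoch_loss + bloss
        i <- i + nb
      }
      losses[epoch] <- epoch_loss / length(ord)
    }
  }
  structure(list(params = p,
                 history = tibble::tibble(epoch = seq_len(config$epochs),
                                          loss = losses),
                 config = config),
            class = "ae_fit")
}

#' @export
print.ae_fit <- function(x, ...) {
  cat(sprintf("<ae_fit> %d epochs (%s), final loss %.6g\n",
              nrow(x$history), x$config$optimizer,
              if (nrow(x$history)) x$history$loss[nrow(x$history)] else NA))
  invisible(x)
}

#' Trainable-parameter count of a dense network
#'
#' For layer sizes `n_0 ... n_d` the number of trainable scalars is
#' `sum over layers of (n_{k-1} * n_k + n_k)` — all connection weights plus
#' all bias terms. This is the model-complexity estimate reported for every
#' built network.
#'
#' @param layer_sizes integer vector of at least 2 positive layer widths, or
#'   a `dense_autoencoder`.
#' @return A `complexity_estimate`: list with `layer_sizes` and the exact
#'   integer `parameter_count`.
#' @export
parameter_count <- function(layer_sizes) {
  if (inherits(layer_sizes, "dense_autoencoder")) {
    layer_sizes <- layer_sizes$layer_sizes
  }
  layer_sizes <- as.numeric(layer_sizes)
  if (length(layer_sizes) < 2L) {
    stop("need at least 2 layers", call. = FALSE)
  }
  if (any(layer_sizes < 1)) stop("layer sizes must be positive", call. = FALSE)
  d <- length(layer_sizes)
  u <- sum(layer_sizes[-d] * layer_sizes[-1L] + layer_sizes[-1L])
  structure(list(layer_sizes = layer_sizes, parameter_count = u),
            class = "complexity_estimate")
}

#' @export
print.complexity_estimate <- function(x, ...) {
  cat(sprintf("<complexity_estimate> layers %s: %s trainable parameters\n",
              paste(x$layer_sizes, collapse = "-"),
              format(x$parameter_count, big.mark = ",")))
  invisible(x)
}

#' Compare optimizers on the same training task
#'
#' Trains fresh, identically-initialized models with each requested
#' optimizer on identical data, seed and epoch budget, and reports the
#' final training loss plus the structural similarity between the first
#' training volume and its reconstruction.
#'
#' @param data training data as accepted by [ae_train()].
#' @param base_config a [train_config()]; its `optimizer` field is ignored.
#' @param optimizers character vector from
#'   `c("adam", "sgd_momentum", "rmsprop", "adagrad")`.
#' @param hidden_width interior layer width for the models.
#' @return tibble with one row per optimizer: `optimizer`, `final_loss`,
#'   `ssim`.
#' @export
compare_optimizers <- function(data, base_config = train_config(),
                               optimizers = c("adam", "sgd_momentum",
                                              "rmsprop", "adagrad"),
                               hidden_width = 2) {
  known <- c("adam", "sgd_momentum", "rmsprop", "adagrad")
  bad <- setdiff(optimizers, known)
  if (length(bad)) {
    stop("unknown optimizer(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  xs <- ae_training_inputs(data)
  first_vol <- if (inherits(data, "labeled_cohort")) data$volumes[[1L]]
               else if (is.list(data) && inherits(data[[1L]], "mri_volume")) data[[1L]]
               else if (inherits(data, "mri_volume")) data
               else NULL
  rows <- lapply(optimizers, function(op) {
    cfg <- base_config
    cfg$optimizer <- op
    p0 <- ae_init(length(xs[[1L]]), hidden_width = hidden_width,
                  seed = base_config$seed)
    fit <- ae_train(p0, data, cfg)
    s <- NA_real_
    if (!is.null(first_vol)) {
      rec <- reconstruct_volume(fit$params, first_vol)
      rng <- attr(first_vol, "intensity_range") %||% c(-1, 1)
      s <- ssim(volume_data(first_vol), volume_data(rec),
                data_range = diff(rng))
    }
    tibble::tibble(optimizer = op,
                   final_loss = fit$history$loss[nrow(fit$history)],
                   ssim = s)
  })
  do.call(rbind, rows)
}
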