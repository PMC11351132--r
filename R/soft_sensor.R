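#' Configuration of the feedforward soft-sensor network
#'
#' A 4-80-60-1 fully connected regression network mapping the four probe
#' channels (pH, redox, capacitance, temperature) to ethanol concentration.
#' Hidden layers use ReLU, the output is linear, and training minimizes mean
#' squared error with Adam. The network is a pointwise map: the prediction
#' at a timestep depends only on that timestep's features.
#'
#' @param hidden Hidden layer widths (fixed architecture `c(80, 60)`).
#' @param epochs Training epochs.
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size; `NULL` = full batch.
#' @param seed Integer seed for initialisation and batch shuffling.
#' @return A `ferm_fnn_config` list.
#' @export
fnn_config <- function(hidden = c(80L, 60L), epochs = 200L,
                       learning_rate = 1e-3, batch_size = 256L,
                       seed = 1L) {
  stopifnot(length(hidden) == 2L, all(hidden >= 1L), epochs >= 1L,
            learning_rate > 0)
  structure(list(n_in = 4L, hidden = as.integer(hidden), n_out = 1L,
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = if (is.null(batch_size)) NULL
                              else as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "ferm_fnn_config")
}

#' Train the ethanol soft sensor
#'
#' Fits the feedforward regression network on stacked, normalized
#' (feature, target) rows by minimizing mean squared error. Deterministic
#' given `config$seed` in a single-threaded BLAS.
#'
#' @param features Numeric matrix `(m, 4)` of normalized probe channels.
#' @param targets Numeric matrix `(m, 1)` (or vector) of normalized ethanol.
#' @param config A [fnn_config()].
#' @return A `ferm_soft_sensor`: weights, config and per-epoch training MSE.
#' @export
train_soft_sensor <- function(features, targets, config = fnn_config()) {
  stopifnot(inherits(config, "ferm_fnn_config"))
  x <- as.matrix(features)
  y <- matrix(as.numeric(targets), ncol = 1L)
  if (ncol(x) != config$n_in) stop("features must have ", config$n_in,
                                   " columns")
  if (nrow(x) != nrow(y)) stop("features and targets must align")
  if (anyNA(x) || anyNA(y)) stop("NaN/NA in training data")
  m <- nrow(x)
  bs <- if (is.null(config$batch_size)) m else min(config$batch_size, m)
  widths <- c(config$n_in, config$hidden, config$n_out)

  p <- with_seed(derive_seed(config$seed, "fnn-init"), {
    pp <- list()
    for (i in seq_len(length(widths) - 1L)) {
      pp[[paste0("W", i)]] <- nn_init(widths[i], widths[i + 1L])
      pp[[paste0("b", i)]] <- numeric(widths[i + 1L])
    }
    pp
  })
  opt <- adam_init(p)
  losses <- numeric(config$epochs)

  with_seed(derive_seed(config$seed, "fnn-train"), {
    for (epoch in seq_len(config$epochs)) {
      perm <- if (bs < m) sample.int(m) else seq_len(m)
      ep_sse <- 0
      for (start in seq(1L, m, by = bs)) {
        idx <- perm[start:min(start + bs - 1L, m)]
        xb <- x[idx, , drop = FALSE]; yb <- y[idx, , drop = FALSE]
        z1 <- nn_dense_fwd(xb, p$W1, p$b1); a1 <- nn_relu(z1)
        z2 <- nn_dense_fwd(a1, p$W2, p$b2); a2 <- nn_relu(z2)
        pred <- nn_dense_fwd(a2, p$W3, p$b3)
        err <- pred - yb
        ep_sse <- ep_sse + sum(err^2)
        if (!is.finite(ep_sse)) stop("divergent loss at epoch ", epoch)
        dpred <- 2 * err / nrow(xb)
        bw3 <- nn_dense_bwd(dpred, a2, p$W3)
        dz2 <- nn_relu_bwd(bw3$dx, z2)
        bw2 <- nn_dense_bwd(dz2, a1, p$W2)
        dz1 <- nn_relu_bwd(bw2$dx, z1)
        bw1 <- nn_dense_bwd(dz1, xb, p$W1)
        grads <- list(W1 = bw1$dW, b1 = bw1$db, W2 = bw2$dW, b2 = bw2$db,
                      W3 = bw3$dW, b3 = bw3$db)
        opt <- adam_step(p, grads, opt, config$learning_rate)
      }
      losses[epoch] <- ep_sse / m
    }
  })

  structure(list(params = p, config = config, train_mse = losses),
            class = "ferm_soft_sensor")
}

#' @export
print.ferm_soft_sensor <- function(x, ...) {
  cat(sprintf("<ferm_soft_sensor> 4-%d-%d-1, %d epochs, final MSE %.3g\n",
              x$config$hidden[1], x$config$hidden[2],
              length(x$train_mse), x$train_mse[length(x$train_mse)]))
  invisible(x)
}

#' Predict ethanol concentration from probe channels
#'
#' @param model A trained [train_soft_sensor()].
#' @param features Numeric matrix `(m, 4)` of normalized probe channels.
#' @return Numeric matrix `(m, 1)` of normalized ethanol predictions.
#' @export
predict_ethanol <- function(model, features) {
  stopifnot(inherits(model, "ferm_soft_sensor"))
  x <- as.matrix(features)
  if (ncol(x) != model$config$n_in) {
    stop("features must have ", model$config$n_in, " columns")
  }
  p <- model$params
  a1 <- nn_relu(nn_dense_fwd(x, p$W1, p$b1))
  a2 <- nn_relu(nn_dense_fwd(a1, p$W2, p$b2))
  nn_dense_fwd(a2, p$W3, p$b3)
}
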