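#' Configuration of the convolutional variational autoencoder
#'
#' The encoder passes the `(n_points, 7)` input through five 1-D
#' convolutional layers (ReLU) followed by one dropout layer, flattens the
#' resulting `(n_points, 64)` feature map, and applies two dense layers (512
#' and 64 units) before projecting to a latent mean and log-variance, both of
#' size `latent_dim`. The decoder mirrors the process and ends in a sigmoid,
#' so inputs are expected min-max normalized to `[0, 1]`. With the default
#' 500-point grid the flattened vector has 500 x 64 = 32,000 entries.
#'
#' @param input_shape Integer pair `(n_points, n_channels)`.
#' @param conv_filters Filter counts of the five convolutional layers; the
#'   last must produce the 64-channel feature map.
#' @param kernel_size Odd convolution kernel length (stride is 1, "same"
#'   padding, preserving the time axis).
#' @param dropout_rate Dropout fraction applied after the convolutional
#'   stack during training.
#' @param dense_units Units of the two dense encoder layers.
#' @param latent_dim Latent dimension (default 10).
#' @param epochs Training epochs (default 100, the epoch count at which the
#'   loss curve flattens before becoming irregular).
#' @param batch_size Minibatch size; `NULL` = full batch (the default for a
#'   handful of experiments).
#' @param learning_rate Adam learning rate.
#' @param seed Integer seed controlling initialisation, dropout and the
#'   reparameterization draws.
#' @return A `ferm_vae_config` list.
#' @export
vae_config <- function(input_shape = c(500L, 7L),
                       conv_filters = c(32L, 32L, 48L, 64L, 64L),
                       kernel_size = 5L,
                       dropout_rate = 0.2,
                       dense_units = c(512L, 64L),
                       latent_dim = 10L,
                       epochs = 100L,
                       batch_size = NULL,
                       learning_rate = 1e-3,
                       seed = 1L) {
  stopifnot(length(input_shape) == 2L, all(input_shape >= 1L),
            length(conv_filters) >= 1L, all(conv_filters >= 1L),
            kernel_size %% 2L == 1L,
            dropout_rate >= 0, dropout_rate < 1,
            length(dense_units) == 2L, all(dense_units >= 1L),
            latent_dim >= 1L, epochs >= 1L, learning_rate > 0)
  structure(list(input_shape = as.integer(input_shape),
                 conv_filters = as.integer(conv_filters),
                 kernel_size = as.integer(kernel_size),
                 dropout_rate = dropout_rate,
                 dense_units = as.integer(dense_units),
                 latent_dim = as.integer(latent_dim),
                 epochs = as.integer(epochs),
                 batch_size = if (is.null(batch_size)) NULL
                              else as.integer(batch_size),
                 learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "ferm_vae_config")
}

## Initialise all VAE parameter matrices (He-normal, zero biases).
vae_init_params <- function(config) {
  L <- config$input_shape[1]; C <- config$input_shape[2]
  k <- config$kernel_size
  nf <- config$conv_filters
  du <- config$dense_units
  latent <- config$latent_dim
  flat <- L * nf[length(nf)]

  p <- list()
  chans <- c(C, nf)
  for (i in seq_along(nf)) {
    p[[paste0("enc_conv", i, "_W")]] <- nn_init(k * chans[i], chans[i + 1])
    p[[paste0("enc_conv", i, "_b")]] <- numeric(chans[i + 1])
  }
  p$enc_d1_W <- nn_init(flat, du[1]);   p$enc_d1_b <- numeric(du[1])
  p$enc_d2_W <- nn_init(du[1], du[2]);  p$enc_d2_b <- numeric(du[2])
  ## Small-scale latent heads keep the initial posterior near the prior.
  p$enc_mu_W <- nn_init(du[2], latent) * 0.01; p$enc_mu_b <- numeric(latent)
  p$enc_lv_W <- nn_init(du[2], latent) * 0.01; p$enc_lv_b <- numeric(latent)

  p$dec_d1_W <- nn_init(latent, du[2]); p$dec_d1_b <- numeric(du[2])
  p$dec_d2_W <- nn_init(du[2], du[1]);  p$dec_d2_b <- numeric(du[1])
  p$dec_d3_W <- nn_init(du[1], flat);   p$dec_d3_b <- numeric(flat)
  dchans <- c(rev(nf), C)   # e.g. 64 -> 64 -> 48 -> 32 -> 32 -> 7
  for (i in seq_along(nf)) {
    p[[paste0("dec_conv", i, "_W")]] <- nn_init(k * dchans[i], dchans[i + 1])
    p[[paste0("dec_conv", i, "_b")]] <- numeric(dchans[i + 1])
  }
  p
}

## Encoder forward. x2: sample-major (B*L, C). Returns posterior and caches.
vae_encode_fwd <- function(p, config, x2, B, dropout_mask = NULL) {
  L <- config$input_shape[1]; k <- config$kernel_size
  nf <- config$conv_filters
  cache <- list(conv = vector("list", length(nf)))
  h <- x2
  for (i in seq_along(nf)) {
    cv <- nn_conv_fwd(h, B, L, p[[paste0("enc_conv", i, "_W")]],
                      p[[paste0("enc_conv", i, "_b")]], k)
    cache$conv[[i]] <- list(x = h, M = cv$M, z = cv$z)
    h <- nn_relu(cv$z)
  }
  if (!is.null(dropout_mask)) h <- h * dropout_mask
  cache$post_conv <- h
  hf <- nn_flatten(h, B, L)
  cache$hf <- hf
  z1 <- nn_dense_fwd(hf, p$enc_d1_W, p$enc_d1_b); d1 <- nn_relu(z1)
  z2 <- nn_dense_fwd(d1, p$enc_d2_W, p$enc_d2_b); d2 <- nn_relu(z2)
  cache$z1 <- z1; cache$d1 <- d1; cache$z2 <- z2; cache$d2 <- d2
  mu <- nn_dense_fwd(d2, p$enc_mu_W, p$enc_mu_b)
  logvar <- nn_dense_fwd(d2, p$enc_lv_W, p$enc_lv_b)
  list(mu = mu, logvar = logvar, cache = cache)
}

## Decoder forward. z: (B, latent). Returns xhat (B*L, C) plus caches.
vae_decode_fwd <- function(p, config, z) {
  L <- config$input_shape[1]; k <- config$kernel_size
  nf <- config$conv_filters
  B <- nrow(z)
  cache <- list(z = z)
  g1 <- nn_dense_fwd(z, p$dec_d1_W, p$dec_d1_b);  a1 <- nn_relu(g1)
  g2 <- nn_dense_fwd(a1, p$dec_d2_W, p$dec_d2_b); a2 <- nn_relu(g2)
  g3 <- nn_dense_fwd(a2, p$dec_d3_W, p$dec_d3_b); a3 <- nn_relu(g3)
  cache$g1 <- g1; cache$a1 <- a1; cache$g2 <- g2; cache$a2 <- a2
  cache$g3 <- g3; cache$a3 <- a3
  h <- nn_unflatten(a3, B, L)
  cache$conv <- vector("list", length(nf))
  for (i in seq_along(nf)) {
    cv <- nn_conv_fwd(h, B, L, p[[paste0("dec_conv", i, "_W")]],
                      p[[paste0("dec_conv", i, "_b")]], k)
    cache$conv[[i]] <- list(x = h, M = cv$M, z = cv$z)
    h <- if (i < length(nf)) nn_relu(cv$z) else nn_sigmoid(cv$z)
  }
  list(xhat = h, cache = cache)
}

## Full backward pass; returns gradients for every parameter.
vae_backward <- function(p, config, x2, B, enc, dec, zs, eps,
                         dropout_mask = NULL) {
  L <- config$input_shape[1]; k <- config$kernel_size
  nf <- config$conv_filters
  C <- config$input_shape[2]
  g <- list()

  ## Reconstruction: loss = mean over samples of per-sample SSE.
  dxhat <- 2 * (dec$xhat - x2) / B
  ## Sigmoid output layer.
  nl <- length(nf)
  dz <- dxhat * dec$xhat * (1 - dec$xhat)
  for (i in rev(seq_len(nl))) {
    cv <- dec$cache$conv[[i]]
    cin <- ncol(cv$x)
    bw <- nn_conv_bwd(dz, cv$M, B, L, k, cin, p[[paste0("dec_conv", i, "_W")]])
    g[[paste0("dec_conv", i, "_W")]] <- bw$dW
    g[[paste0("dec_conv", i, "_b")]] <- bw$db
    if (i > 1L) {
      dz <- nn_relu_bwd(bw$dx, dec$cache$conv[[i - 1L]]$z)
    } else {
      dh <- bw$dx
    }
  }
  da3 <- nn_flatten(dh, B, L)
  dg3 <- nn_relu_bwd(da3, dec$cache$g3)
  bw <- nn_dense_bwd(dg3, dec$cache$a2, p$dec_d3_W)
  g$dec_d3_W <- bw$dW; g$dec_d3_b <- bw$db
  dg2 <- nn_relu_bwd(bw$dx, dec$cache$g2)
  bw <- nn_dense_bwd(dg2, dec$cache$a1, p$dec_d2_W)
  g$dec_d2_W <- bw$dW; g$dec_d2_b <- bw$db
  dg1 <- nn_relu_bwd(bw$dx, dec$cache$g1)
  bw <- nn_dense_bwd(dg1, dec$cache$z, p$dec_d1_W)
  g$dec_d1_W <- bw$dW; g$dec_d1_b <- bw$db
  dzs <- bw$dx                                   # gradient w.r.t. sampled z

  ## KL term (mean over batch) + reparameterization path.
  mu <- enc$mu; lv <- enc$logvar
  dmu <- mu / B + dzs
  dlv <- 0.5 * (exp(lv) - 1) / B + dzs * eps * 0.5 * exp(lv / 2)

  bw_mu <- nn_dense_bwd(dmu, enc$cache$d2, p$enc_mu_W)
  g$enc_mu_W <- bw_mu$dW; g$enc_mu_b <- bw_mu$db
  bw_lv <- nn_dense_bwd(dlv, enc$cache$d2, p$enc_lv_W)
  g$enc_lv_W <- bw_lv$dW; g$enc_lv_b <- bw_lv$db
  dd2 <- bw_mu$dx + bw_lv$dx
  dz2 <- nn_relu_bwd(dd2, enc$cache$z2)
  bw <- nn_dense_bwd(dz2, enc$cache$d1, p$enc_d2_W)
  g$enc_d2_W <- bw$dW; g$enc_d2_b <- bw$db
  dz1 <- nn_relu_bwd(bw$dx, enc$cache$z1)
  bw <- nn_dense_bwd(dz1, enc$cache$hf, p$enc_d1_W)
  g$enc_d1_W <- bw$dW; g$enc_d1_b <- bw$db
  dh <- nn_unflatten(bw$dx, B, L)
  if (!is.null(dropout_mask)) dh <- dh * dropout_mask
  for (i in rev(seq_along(nf))) {
    dz <- nn_relu_bwd(dh, enc$cache$conv[[i]]$z)
    cv <- enc$cache$conv[[i]]
    cin <- ncol(cv$x)
    bw <- nn_conv_bwd(dz, cv$M, B, L, k, cin, p[[paste0("enc_conv", i, "_W")]])
    g[[paste0("enc_conv", i, "_W")]] <- bw$dW
    g[[paste0("enc_conv", i, "_b")]] <- bw$db
    dh <- bw$dx
  }
  g
}

#' Kullback-Leibler divergence of a diagonal-Gaussian posterior to the prior
#'
#' Closed form against the standard-normal prior:
#' \deqn{D_{KL} = \tfrac12 \sum_i (\mu_i^2 + e^{logvar_i} - logvar_i - 1)}
#' Always non-negative.
#'
#' @param posterior List with numeric vectors `mu` and `logvar`.
#' @return KL divergence in nats (scalar).
#' @export
kl_divergence <- function(posterior) {
  mu <- as.numeric(posterior$mu); lv <- as.numeric(posterior$logvar)
  if (length(mu) != length(lv)) stop("mu and logvar must have equal length")
  if (any(!is.finite(mu)) || any(!is.finite(lv))) {
    stop("non-finite posterior parameters")
  }
  0.5 * sum(mu^2 + exp(lv) - lv - 1)
}

#' Draw a latent sample by the reparameterization trick
#'
#' `z = mu + exp(logvar/2) * eps` with `eps ~ N(0, I)`; deterministic given
#' the seed.
#'
#' @param posterior List with `mu` and `logvar`.
#' @param seed Integer seed.
#' @return Numeric latent vector.
#' @export
reparameterize <- function(posterior, seed = 1L) {
  mu <- as.numeric(posterior$mu); lv <- as.numeric(posterior$logvar)
  if (length(mu) != length(lv)) stop("mu and logvar must have equal length")
  eps <- with_seed(seed, stats::rnorm(length(mu)))
  mu + exp(lv / 2) * eps
}

#' Negative-ELBO loss of one reconstruction
#'
#' Reconstruction term is the summed squared error (unit-variance Gaussian
#' log-likelihood up to an additive constant), the regularizer is
#' [kl_divergence()]; the total is their sum, so minimizing it maximizes the
#' evidence lower bound.
#'
#' @param x Input series (matrix).
#' @param x_hat Reconstruction of the same shape.
#' @param posterior List with `mu` and `logvar`.
#' @return List with `reconstruction`, `kl` and `total` (nats).
#' @export
elbo_loss <- function(x, x_hat, posterior) {
  if (!identical(dim(x), dim(x_hat)) || length(x) != length(x_hat)) {
    stop("x and x_hat must have identical shape")
  }
  recon <- sum((x - x_hat)^2)
  kl <- kl_divergence(posterior)
  list(reconstruction = recon, kl = kl, total = recon + kl)
}

#' Train the convolutional VAE on a series tensor
#'
#' Minimizes the negative ELBO (summed-squared-error reconstruction + KL to
#' the standard-normal prior) with Adam. Inputs must be normalized to
#' `[0, 1]` (sigmoid decoder); training is full-batch by default and
#' deterministic for a fixed `config$seed` in a single-threaded BLAS.
#'
#' @param tensor Array `(n_sets, n_points, n_channels)` from
#'   [to_vae_tensor()], min-max normalized.
#' @param config A [vae_config()].
#' @return A `ferm_vae` model: parameters, config and the per-epoch loss
#'   history (`epoch`, `reconstruction`, `kl`, `total`).
#' @export
train_vae <- function(tensor, config = vae_config()) {
  stopifnot(inherits(config, "ferm_vae_config"))
  dims <- dim(tensor)
  if (length(dims) != 3L) stop("tensor must be (sets, points, channels)")
  n <- dims[1]
  if (n < 2L) stop("need at least 2 series to train")
  if (!identical(as.integer(dims[2:3]), config$input_shape)) {
    stop("tensor shape (", dims[2], ", ", dims[3],
         ") does not match config input_shape")
  }
  if (min(tensor) < -0.1 || max(tensor) > 1.1) {
    warning("input values outside [-0.1, 1.1]; did you min-max normalize?")
  }
  L <- config$input_shape[1]
  bs <- if (is.null(config$batch_size)) n else min(config$batch_size, n)

  ## Sample-major stack of the whole tensor: rows (b-1)*L + l.
  x_all <- do.call(rbind, lapply(seq_len(n), function(b) tensor[b, , ]))

  p <- with_seed(derive_seed(config$seed, "vae-init"),
                 vae_init_params(config))
  opt <- adam_init(p)
  history <- data.frame(epoch = integer(0), reconstruction = numeric(0),
                        kl = numeric(0), total = numeric(0))

  rng_seed <- derive_seed(config$seed, "vae-train")
  with_seed(rng_seed, {
    for (epoch in seq_len(config$epochs)) {
      perm <- if (bs < n) sample.int(n) else seq_len(n)
      ep_recon <- 0; ep_kl <- 0
      for (start in seq(1L, n, by = bs)) {
        batch <- perm[start:min(start + bs - 1L, n)]
        B <- length(batch)
        rows <- as.vector(vapply(batch, function(b) (b - 1L) * L + seq_len(L),
                                 integer(L)))
        x2 <- x_all[rows, , drop = FALSE]
        dropout_mask <- if (config$dropout_rate > 0) {
          nf_last <- config$conv_filters[length(config$conv_filters)]
          matrix(stats::rbinom(B * L * nf_last, 1L,
                               1 - config$dropout_rate) /
                   (1 - config$dropout_rate), B * L, nf_last)
        } else NULL

        enc <- vae_encode_fwd(p, config, x2, B, dropout_mask)
        eps <- matrix(stats::rnorm(B * config$latent_dim),
                      B, config$latent_dim)
        zs <- enc$mu + exp(enc$logvar / 2) * eps
        dec <- vae_decode_fwd(p, config, zs)

        recon <- sum((dec$xhat - x2)^2)
        kl <- 0.5 * sum(enc$mu^2 + exp(enc$logvar) - enc$logvar - 1)
        if (!is.finite(recon + kl)) {
          stop("NaN/Inf loss at epoch ", epoch)
        }
        ep_recon <- ep_recon + recon; ep_kl <- ep_kl + kl

        grads <- vae_backward(p, config, x2, B, enc, dec, zs, eps,
                              dropout_mask)
        opt <- adam_step(p, grads, opt, config$learning_rate)
      }
      history <- rbind(history,
                       data.frame(epoch = epoch,
                                  reconstruction = ep_recon / n,
                                  kl = ep_kl / n,
                                  total = (ep_recon + ep_kl) / n))
    }
  })

  structure(list(params = p, config = config, history = history),
            class = "ferm_vae")
}

#' @export
print.ferm_vae <- function(x, ...) {
  cat(sprintf(
    "<ferm_vae> input (%d, %d), latent %d, %d epochs, final loss %.3f\n",
    x$config$input_shape[1], x$config$input_shape[2], x$config$latent_dim,
    nrow(x$history), x$history$total[nrow(x$history)]))
  invisible(x)
}

#' Encode one series to its latent posterior
#'
#' Runs the encoder deterministically (dropout disabled) and returns the
#' diagonal-Gaussian posterior q(z|x).
#'
#' @param x One normalized series: matrix `(n_points, n_channels)`.
#' @param model A trained [train_vae()] model.
#' @return List with `mu` and `logvar`, both length `latent_dim`.
#' @export
vae_encode <- function(x, model) {
  stopifnot(inherits(model, "ferm_vae"))
  cfg <- model$config
  x <- as.matrix(x)
  if (!identical(as.integer(dim(x)), cfg$input_shape)) {
    stop("x must have shape (", cfg$input_shape[1], ", ",
         cfg$input_shape[2], ")")
  }
  if (any(!is.finite(x))) stop("x must be finite")
  enc <- vae_encode_fwd(model$params, cfg, x, 1L, dropout_mask = NULL)
  list(mu = as.numeric(enc$mu), logvar = as.numeric(enc$logvar))
}

#' Decode latent vectors to series
#'
#' @param model A trained [train_vae()] model.
#' @param z Matrix `(n, latent_dim)` (or a single latent vector).
#' @return Array `(n, n_points, n_channels)` of normalized series in
#'   `[0, 1]`.
#' @export
vae_decode <- function(model, z) {
  stopifnot(inherits(model, "ferm_vae"))
  cfg <- model$config
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  if (ncol(z) != cfg$latent_dim) stop("z must have ", cfg$latent_dim,
                                      " columns")
  dec <- vae_decode_fwd(model$params, cfg, z)
  L <- cfg$input_shape[1]; C <- cfg$input_shape[2]
  n <- nrow(z)
  out <- array(NA_real_, c(n, L, C), dimnames = list(NULL, NULL,
                                                     FERM_CHANNELS[seq_len(C)]))
  for (b in seq_len(n)) out[b, , ] <- dec$xhat[((b - 1L) * L + 1L):(b * L), ]
  out
}

#' Generate synthetic experiments from the prior
#'
#' Draws `n` latent vectors from the standard-normal prior, decodes them,
#' inverse-normalizes with the supplied normalizer, and tags the series as
#' synthetic. Deterministic given the seed.
#'
#' @param model A trained [train_vae()] model.
#' @param n Number of synthetic experiments (>= 1).
#' @param normalizer The [fit_normalizer()] used to normalize the training
#'   tensor.
#' @param seed Integer seed.
#' @param time Time grid to attach (defaults to an even grid on 0-10 h).
#' @return A [ferm_collection()] with provenance `"synthetic"`.
#' @export
generate_synthetic <- function(model, n, normalizer, seed = 1L,
                               time = NULL) {
  stopifnot(inherits(model, "ferm_vae"))
  if (n < 1L) stop("n must be >= 1")
  cfg <- model$config
  z <- with_seed(derive_seed(seed, "generate"),
                 matrix(stats::rnorm(n * cfg$latent_dim), n, cfg$latent_dim))
  tensor <- vae_decode(model, z)
  if (is.null(time)) time <- seq(0, 10, length.out = cfg$input_shape[1])
  coll <- tensor_to_collection(tensor, time = time,
                               ids = sprintf("syn%03d", seq_len(n)),
                               provenance = rep("synthetic", n))
  invert_normalizer(coll, normalizer)
}
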