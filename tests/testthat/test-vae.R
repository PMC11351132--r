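## Monte-Carlo oracle for the KL divergence to the standard normal:
## E_q[log q(z) - log p(z)] estimated from draws of q.
kl_monte_carlo <- function(mu, logvar, n_draws = 1e4, seed = 1) {
  set.seed(seed)
  d <- length(mu)
  eps <- matrix(rnorm(n_draws * d), n_draws, d)
  z <- sweep(sweep(eps, 2, exp(logvar / 2), "*"), 2, mu, "+")
  logq <- -0.5 * rowSums(sweep((z - rep(mu, each = n_draws))^2, 2,
                               exp(logvar), "/") +
                           rep(logvar, each = n_draws) + log(2 * pi))
  logp <- -0.5 * rowSums(z^2 + log(2 * pi))
  mean(logq - logp)
}

test_that("closed-form KL matches hand values and the Monte-Carlo oracle", {
  expect_equal(kl_divergence(list(mu = rep(0, 10), logvar = rep(0, 10))), 0)
  expect_equal(kl_divergence(list(mu = c(1, rep(0, 9)),
                                  logvar = rep(0, 10))), 0.5)
  lv <- rep(0, 10); lv[1] <- log(4)
  expect_equal(kl_divergence(list(mu = rep(0, 10), logvar = lv)),
               0.5 * (4 - log(4) - 1))
  expect_equal(kl_monte_carlo(rep(0, 10), lv, n_draws = 1e6, seed = 3),
               0.5 * (4 - log(4) - 1), tolerance = 0.01)
  expect_error(kl_divergence(list(mu = c(NA, 1), logvar = c(0, 0))),
               "finite")
})

test_that("KL divergence is non-negative over random posteriors", {
  set.seed(11)
  for (i in 1:200) {
    post <- list(mu = rnorm(10), logvar = runif(10, -3, 3))
    expect_gte(kl_divergence(post), 0)
  }
})

test_that("reparameterization collapses to the mean at zero variance and is seeded", {
  post <- list(mu = 1:10 / 10, logvar = rep(-60, 10))
  expect_equal(reparameterize(post, seed = 4), 1:10 / 10, tolerance = 1e-10)
  post2 <- list(mu = rep(0, 10), logvar = rep(0, 10))
  expect_identical(reparameterize(post2, seed = 9),
                   reparameterize(post2, seed = 9))
  draws <- vapply(1:10000, function(s) reparameterize(post2, seed = s),
                  numeric(10))
  expect_true(all(abs(rowMeans(draws)) < 4 / sqrt(10000)))
})

test_that("negative-ELBO decomposes exactly and matches a hand-summed toy", {
  x <- matrix(c(0.2, 0.4, 0.6, 0.8), 2, 2)
  x_hat <- matrix(c(0.1, 0.4, 0.9, 0.8), 2, 2)
  post <- list(mu = c(1, 0), logvar = c(0, 0))
  loss <- elbo_loss(x, x_hat, post)
  expect_equal(loss$reconstruction, 0.1^2 + 0.3^2)
  expect_equal(loss$kl, kl_divergence(post))
  expect_identical(loss$total, loss$reconstruction + loss$kl)
  zero <- elbo_loss(x, x, list(mu = c(0, 0), logvar = c(0, 0)))
  expect_equal(zero$total, 0)
  expect_error(elbo_loss(x, t(x)[, 1, drop = FALSE], post), "shape")
})

test_that("encoder emits a latent posterior of the configured size, deterministically", {
  fix <- tiny_trained_vae()
  x <- fix$tensor[1, , ]
  post <- vae_encode(x, fix$model)
  expect_length(post$mu, 4L)
  expect_length(post$logvar, 4L)
  expect_true(all(is.finite(c(post$mu, post$logvar))))
  expect_identical(vae_encode(x, fix$model), post)
  expect_error(vae_encode(x[1:10, ], fix$model), "shape")

  ## zeroing the latent heads forces a standard-normal posterior
  zeroed <- fix$model
  zeroed$params$enc_mu_W[] <- 0; zeroed$params$enc_mu_b[] <- 0
  zeroed$params$enc_lv_W[] <- 0; zeroed$params$enc_lv_b[] <- 0
  post0 <- vae_encode(x, zeroed)
  expect_equal(post0$mu, rep(0, 4))
  expect_equal(post0$logvar, rep(0, 4))
})

test_that("default architecture flattens 500 x 64 = 32,000 features", {
  cfg <- vae_config()
  expect_equal(cfg$input_shape[1] *
                 cfg$conv_filters[length(cfg$conv_filters)], 32000L)
  expect_equal(cfg$dense_units, c(512L, 64L))
  expect_equal(cfg$latent_dim, 10L)
})

test_that("training reduces the loss and the decoder output has the input shape", {
  fix <- tiny_trained_vae()
  h <- fix$model$history
  expect_equal(nrow(h), 10L)
  expect_lt(h$total[10], h$total[1])
  expect_true(all(h$kl >= 0))
  expect_equal(h$total, h$reconstruction + h$kl)

  out <- vae_decode(fix$model, rep(0, 4))
  expect_equal(dim(out), c(1L, 60L, 7L))
  expect_true(all(out >= 0 & out <= 1))   # sigmoid-bounded
})

test_that("training warns on un-normalized input and validates shape", {
  tens <- tiny_trained_vae()$tensor
  expect_warning(train_vae(tens * 30, tiny_vae_config(epochs = 1L)),
                 "normalize")
  expect_error(train_vae(tens[, 1:10, ], tiny_vae_config(epochs = 1L)),
               "input_shape")
})

test_that("synthetic generation is seeded, tagged and sized as requested", {
  fix <- tiny_trained_vae()
  syn <- generate_synthetic(fix$model, 5L, fix$normalizer, seed = 21L,
                            time = fix$time)
  expect_length(syn, 5L)
  expect_true(all(vapply(syn$experiments, `[[`, character(1),
                         "provenance") == "synthetic"))
  expect_equal(dim(syn[[1]]$data), c(60L, 7L))
  syn2 <- generate_synthetic(fix$model, 5L, fix$normalizer, seed = 21L,
                             time = fix$time)
  expect_identical(syn2$experiments, syn$experiments)
  expect_error(generate_synthetic(fix$model, 0L, fix$normalizer), "n must")
})
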