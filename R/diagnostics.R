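#' @importFrom ggplot2 .data
NULL

#' Per-channel histogram overlap between two collections
#'
#' For every channel, builds histograms on shared breaks spanning the pooled
#' range of both collections and reports the histogram intersection
#' `sum(pmin(p, q))` of the two normalized bin-proportion vectors: 1 when the
#' binned distributions coincide, 0 when their supports are disjoint. Used
#' to quantify how well the generated data reproduce the original data's
#' variability structure.
#'
#' @param original,synthetic Imputed [ferm_collection()] objects.
#' @param bins Number of bins (default 30).
#' @param file Optional path for a faceted histogram figure (written with
#'   ggplot2 when given).
#' @return Named numeric vector of per-channel overlaps in `[0, 1]`.
#' @export
histogram_report <- function(original, synthetic, bins = 30L, file = NULL) {
  stopifnot(inherits(original, "ferm_collection"),
            inherits(synthetic, "ferm_collection"))
  if (collection_has_missing(original) || collection_has_missing(synthetic)) {
    stop("impute collections before computing histogram overlap")
  }
  pool_o <- do.call(rbind, lapply(original$experiments, `[[`, "data"))
  pool_s <- do.call(rbind, lapply(synthetic$experiments, `[[`, "data"))
  overlaps <- vapply(FERM_CHANNELS, function(ch) {
    a <- pool_o[, ch]; b <- pool_s[, ch]
    if (!length(a) || !length(b)) stop("empty channel: ", ch)
    rng <- range(c(a, b))
    if (diff(rng) == 0) return(1)   # identical constant channels
    breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
    p <- graphics::hist(a, breaks = breaks, plot = FALSE)$counts / length(a)
    q <- graphics::hist(b, breaks = breaks, plot = FALSE)$counts / length(b)
    sum(pmin(p, q))
  }, numeric(1))

  if (!is.null(file)) {
    df <- rbind(
      data.frame(source = "original",
                 channel = rep(FERM_CHANNELS, each = nrow(pool_o)),
                 value = as.vector(pool_o)),
      data.frame(source = "synthetic",
                 channel = rep(FERM_CHANNELS, each = nrow(pool_s)),
                 value = as.vector(pool_s)))
    gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$value,
                                           fill = .data$source)) +
      ggplot2::geom_histogram(bins = bins, alpha = 0.5,
                              position = "identity") +
      ggplot2::facet_wrap(~channel, scales = "free") +
      ggplot2::labs(x = NULL, y = "count")
    ggplot2::ggsave(file, gg, width = 10, height = 6)
  }
  overlaps
}

## Exact (O(n^2)) t-SNE for small point sets: per-point precision found by
## binary search on the target perplexity, gradient descent with momentum
## and early exaggeration on the 2-D embedding.
tsne_exact <- function(X, perplexity = 10, n_iter = 500L, seed = 1L) {
  n <- nrow(X)
  if (perplexity >= n) stop("perplexity must be smaller than the number of points")
  D2 <- as.matrix(stats::dist(X))^2

  P <- matrix(0, n, n)
  target <- log(perplexity)
  for (i in seq_len(n)) {
    beta_lo <- 0; beta_hi <- Inf; beta <- 1
    di <- D2[i, -i]
    for (iter in 1:60) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { beta_hi <- beta; beta <- beta / 2; next }
      p <- w / sw
      h <- -sum(p[p > 0] * log(p[p > 0]))
      if (abs(h - target) < 1e-5) break
      if (h > target) { beta_lo <- beta
        beta <- if (is.finite(beta_hi)) (beta + beta_hi) / 2 else beta * 2
      } else { beta_hi <- beta; beta <- (beta + beta_lo) / 2 }
    }
    P[i, -i] <- w / sum(w)
  }
  P <- (P + t(P)) / (2 * n)
  P[P < 1e-12] <- 1e-12

  Y <- with_seed(seed, matrix(stats::rnorm(n * 2, 0, 1e-4), n, 2))
  inc <- matrix(0, n, 2)
  momentum <- 0.5
  for (iter in seq_len(n_iter)) {
    Pe <- if (iter <= 100L) P * 4 else P
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- num / sum(num)
    Q[Q < 1e-12] <- 1e-12
    W <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    if (iter == 250L) momentum <- 0.8
    inc <- momentum * inc - 200 * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

#' t-SNE overlay of original and synthetic experiments
#'
#' Each experiment is flattened into one long vector (all normalized
#' channels end to end, e.g. 500 x 7 = 3500 values) and all experiments are
#' embedded together into two dimensions, one point per experiment, so the
#' coverage of the original data cloud by the generated data can be judged
#' visually.
#'
#' @param originals,synthetics Imputed [ferm_collection()] objects (>= 3
#'   experiments each).
#' @param perplexity t-SNE perplexity (default 10).
#' @param seed Integer seed (embedding initialisation).
#' @param file Optional path for the scatter figure.
#' @return Data frame with `id`, `group`, `x`, `y` (one row per experiment).
#' @export
tsne_overlay <- function(originals, synthetics, perplexity = 10, seed = 1L,
                         file = NULL) {
  stopifnot(inherits(originals, "ferm_collection"),
            inherits(synthetics, "ferm_collection"))
  if (length(originals) < 3L || length(synthetics) < 3L) {
    stop("need at least 3 experiments per group")
  }
  flatten <- function(coll) {
    t(vapply(coll$experiments, function(e) as.vector(e$data),
             numeric(length(coll$experiments[[1]]$data))))
  }
  X <- rbind(flatten(originals), flatten(synthetics))
  if (anyNA(X)) stop("impute collections before embedding")
  group <- rep(c("original", "synthetic"),
               c(length(originals), length(synthetics)))
  Y <- tsne_exact(X, perplexity = perplexity, seed = seed)
  out <- data.frame(id = c(collection_ids(originals),
                           collection_ids(synthetics)),
                    group = group, x = Y[, 1], y = Y[, 2])
  if (!is.null(file)) {
    gg <- ggplot2::ggplot(out, ggplot2::aes(x = .data$x, y = .data$y,
                                            colour = .data$group,
                                            shape = .data$group)) +
      ggplot2::geom_point(size = 2.5, alpha = 0.8) +
      ggplot2::scale_shape_manual(values = c(original = 17,
                                             synthetic = 19)) +
      ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2")
    ggplot2::ggsave(file, gg, width = 6, height = 5)
  }
  out
}

#' Prediction overlay for one held-out experiment
#'
#' Predicts the ethanol trajectory of a test experiment with a trained soft
#' sensor (in normalized units), returns the measured/predicted curves and
#' the R-squared and RMSE computed by the package's metric functions, and
#' optionally renders the overlay figure (predicted line over measured
#' markers).
#'
#' @param model A trained [train_soft_sensor()].
#' @param test_series A [ferm_experiment()] with an observed ethanol
#'   channel.
#' @param normalizer The [fit_normalizer()] fitted on the model's training
#'   originals.
#' @param file Optional path for the overlay figure.
#' @return List with `r2`, `rmse` and a `data` frame
#'   (`time_h`, `measured`, `predicted`, normalized units).
#' @export
prediction_overlay <- function(model, test_series, normalizer, file = NULL) {
  stopifnot(inherits(test_series, "ferm_experiment"))
  if (anyNA(test_series$data[, FERM_TARGET_CHANNEL])) {
    stop("test experiment has missing ethanol values")
  }
  test_n <- normalize_matrix(test_series$data, normalizer)
  y <- test_n[, FERM_TARGET_CHANNEL]
  y_hat <- as.numeric(predict_ethanol(model, test_n[, FERM_INPUT_CHANNELS,
                                                    drop = FALSE]))
  df <- data.frame(time_h = test_series$time, measured = y,
                   predicted = y_hat)
  if (!is.null(file)) {
    gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_h)) +
      ggplot2::geom_point(ggplot2::aes(y = .data$measured),
                          colour = "steelblue", size = 0.8) +
      ggplot2::geom_line(ggplot2::aes(y = .data$predicted),
                         colour = "darkorange", linewidth = 0.9) +
      ggplot2::labs(x = "time (h)", y = "ethanol (normalized)",
                    title = test_series$id)
    ggplot2::ggsave(file, gg, width = 6, height = 4)
  }
  list(r2 = r_squared(y, y_hat), rmse = rmse(y, y_hat), data = df)
}
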