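#' Random leave-one-experiment-out split
#'
#' Draws one experiment uniformly at random as the test set and returns the
#' complement as training ids, keeping entire time series grouped.
#'
#' @param n_sets Number of experiments.
#' @param seed Integer seed.
#' @return List with integer vectors `train` (length `n_sets - 1`) and
#'   `test` (length 1).
#' @export
split_experiments <- function(n_sets, seed = 1L) {
  if (n_sets < 2L) stop("need at least 2 experiments to split")
  test <- with_seed(seed, sample.int(n_sets, 1L))
  list(train = setdiff(seq_len(n_sets), test), test = test)
}

#' Specify a training-set augmentation regime
#'
#' `Original` trains on the original experiments only; `Augmented10` adds 10
#' synthetic experiments sampled without replacement; `Augmented100` adds
#' the entire synthetic pool.
#'
#' @param name One of `"Original"`, `"Augmented10"`, `"Augmented100"`.
#' @param n_synthetic Number of synthetic sets to add; defaults to 0, 10, or
#'   `NA` (= the whole pool) by regime name.
#' @return A `ferm_regime` list.
#' @export
regime_spec <- function(name = c("Original", "Augmented10", "Augmented100"),
                        n_synthetic = NULL) {
  name <- match.arg(name)
  if (is.null(n_synthetic)) {
    n_synthetic <- switch(name, Original = 0L, Augmented10 = 10L,
                          Augmented100 = NA_integer_)
  }
  structure(list(name = name, n_synthetic = n_synthetic),
            class = "ferm_regime")
}

#' Compose a training collection for a regime
#'
#' Combines the original training experiments with synthetic experiments:
#' none for `Original`, `n_synthetic` sampled without replacement for
#' `Augmented10`, and the full pool for `Augmented100`.
#'
#' @param regime A [regime_spec()].
#' @param original_train [ferm_collection()] of original training sets.
#' @param synthetic_pool [ferm_collection()] of synthetic sets (may be
#'   `NULL` for the Original regime).
#' @param seed Integer seed for the synthetic subsample.
#' @return A [ferm_collection()].
#' @export
compose_regime <- function(regime, original_train, synthetic_pool = NULL,
                           seed = 1L) {
  stopifnot(inherits(regime, "ferm_regime"))
  n_syn <- regime$n_synthetic
  if (!is.na(n_syn) && n_syn == 0L) return(original_train)
  if (is.null(synthetic_pool)) stop("regime needs a synthetic pool")
  pool_n <- length(synthetic_pool)
  if (is.na(n_syn)) n_syn <- pool_n
  if (n_syn > pool_n) {
    stop("synthetic pool (", pool_n, ") smaller than requested ", n_syn)
  }
  pick <- if (n_syn == pool_n) seq_len(pool_n) else {
    with_seed(derive_seed(seed, "compose"), sample.int(pool_n, n_syn))
  }
  ferm_collection(c(original_train$experiments,
                    synthetic_pool$experiments[pick]))
}

#' Repeated leave-one-experiment-out evaluation of one regime
#'
#' Per iteration: draw a random held-out original experiment, compose the
#' regime's training collection, fit a min-max normalizer on the training
#' *originals* only, train the soft sensor on the stacked normalized rows,
#' predict the held-out experiment and record R-squared, adjusted R-squared
#' (N = number of training sets, p = 4), MAE and RMSE in normalized target
#' space.
#'
#' @param originals Imputed [ferm_collection()] of original experiments.
#' @param synthetic_pool [ferm_collection()] of synthetic experiments
#'   (`NULL` for the Original regime).
#' @param regime A [regime_spec()].
#' @param n_iter Number of repeated splits (the study protocol uses 100).
#' @param base_seed Integer seed; iteration sub-seeds are derived from it, so
#'   regimes evaluated with the same `base_seed` see the same split sequence.
#' @param fnn A [fnn_config()] template (its seed is re-derived per
#'   iteration).
#' @return A `ferm_metric_distribution`: per-iteration metrics plus
#'   mean/sd summaries.
#' @export
repeated_evaluation <- function(originals, synthetic_pool = NULL,
                                regime = regime_spec("Original"),
                                n_iter = 100L, base_seed = 1L,
                                fnn = fnn_config()) {
  stopifnot(inherits(originals, "ferm_collection"))
  if (collection_has_missing(originals)) {
    stop("impute originals before evaluation")
  }
  n_iter <- as.integer(n_iter)
  if (n_iter < 1L) stop("n_iter must be >= 1")
  n_sets <- length(originals)
  ids <- collection_ids(originals)

  rows <- vector("list", n_iter)
  for (i in seq_len(n_iter)) {
    it_seed <- derive_seed(base_seed, "iteration", i)
    res <- tryCatch(
      evaluate_one_split(originals, synthetic_pool, regime, it_seed, fnn),
      error = function(e) stop("iteration ", i, ": ", conditionMessage(e))
    )
    rows[[i]] <- data.frame(iteration = i, test_id = ids[res$test],
                            r2 = res$r2, adj_r2 = res$adj_r2,
                            mae = res$mae, rmse = res$rmse)
  }
  metrics <- do.call(rbind, rows)
  summary <- data.frame(
    metric = c("r2", "adj_r2", "mae", "rmse"),
    mean = vapply(metrics[c("r2", "adj_r2", "mae", "rmse")], mean, 0),
    sd = vapply(metrics[c("r2", "adj_r2", "mae", "rmse")], stats::sd, 0),
    row.names = NULL)
  structure(list(regime = regime$name, metrics = metrics, summary = summary,
                 n_iter = n_iter),
            class = "ferm_metric_distribution")
}

evaluate_one_split <- function(originals, synthetic_pool, regime, it_seed,
                               fnn) {
  n_sets <- length(originals)
  split <- split_experiments(n_sets, seed = derive_seed(it_seed, "split"))
  train_orig <- originals[split$train]
  test_series <- originals[[split$test]]

  training <- compose_regime(regime, train_orig, synthetic_pool,
                             seed = derive_seed(it_seed, "regime"))
  normalizer <- fit_normalizer(train_orig, scheme = "minmax")
  training_n <- apply_normalizer(training, normalizer)
  arrays <- to_regression_arrays(training_n)

  fnn$seed <- derive_seed(it_seed, "fnn")
  model <- train_soft_sensor(arrays$features, arrays$targets, fnn)

  test_n <- normalize_matrix(test_series$data, normalizer)
  y <- test_n[, FERM_TARGET_CHANNEL]
  y_hat <- predict_ethanol(model, test_n[, FERM_INPUT_CHANNELS,
                                         drop = FALSE])
  list(test = split$test,
       r2 = r_squared(y, y_hat),
       adj_r2 = adjusted_r_squared(r_squared(y, y_hat),
                                   N = length(training), p = 4L),
       mae = mean_absolute_error(y, y_hat),
       rmse = rmse(y, y_hat))
}

#' @export
print.ferm_metric_distribution <- function(x, ...) {
  cat(sprintf("<ferm_metric_distribution> %s, %d iterations\n",
              x$regime, x$n_iter))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Statistical comparison of augmentation regimes
#'
#' Assembles the per-metric comparison of the three regimes: means, standard
#' deviations, percent change versus the Original baseline, Welch's
#' unequal-variance t-test on the means and Levene's test on the variances,
#' with significance flagged at p < 0.05. Baseline rows carry `NA` in the
#' change columns.
#'
#' @param dist_orig,dist_aug10,dist_aug100 [repeated_evaluation()] results
#'   with equal iteration counts.
#' @return A `ferm_comparison` data.frame with columns `metric`, `regime`,
#'   `mean`, `pct_mean`, `p_welch`, `sd`, `pct_sd`, `p_levene`,
#'   `significant_mean`, `significant_sd`.
#' @export
comparison_table <- function(dist_orig, dist_aug10, dist_aug100) {
  dists <- list(dist_orig, dist_aug10, dist_aug100)
  ok <- vapply(dists, inherits, logical(1), "ferm_metric_distribution")
  if (!all(ok)) stop("inputs must be repeated_evaluation() results")
  n_iters <- vapply(dists, function(d) as.integer(d$n_iter), integer(1))
  if (length(unique(n_iters)) != 1L) stop("mismatched iteration counts")

  rows <- list()
  for (metric in c("r2", "adj_r2", "mae", "rmse")) {
    base <- dist_orig$metrics[[metric]]
    for (d in dists) {
      v <- d$metrics[[metric]]
      is_base <- identical(d$regime, dist_orig$regime)
      wt <- if (is_base) list(p = NA_real_) else welch_t_test(base, v)
      lv <- if (is_base) list(p = NA_real_) else levene_test(base, v)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = metric, regime = d$regime,
        mean = mean(v),
        pct_mean = if (is_base) NA_real_ else percent_change(mean(base),
                                                             mean(v)),
        p_welch = wt$p,
        sd = stats::sd(v),
        pct_sd = if (is_base) NA_real_ else percent_change(stats::sd(base),
                                                           stats::sd(v)),
        p_levene = lv$p)
    }
  }
  out <- do.call(rbind, rows)
  out$significant_mean <- !is.na(out$p_welch) & out$p_welch < 0.05
  out$significant_sd <- !is.na(out$p_levene) & out$p_levene < 0.05
  class(out) <- c("ferm_comparison", "data.frame")
  out
}
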