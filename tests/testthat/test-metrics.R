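test_that("R-squared matches hand evaluations, including negative values", {
  y <- c(0, 1, 2)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 3)), 0)
  expect_equal(r_squared(y, c(0, 0, 0)), -1.5)
  expect_error(r_squared(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("error metrics match hand sums and obey MAE <= RMSE", {
  expect_equal(mean_absolute_error(c(0, 2), c(1, 1)), 1)
  expect_equal(rmse(c(0, 4), c(0, 0)), 2 * sqrt(2))
  expect_equal(rmse(1:5, 1:5), 0)
  set.seed(3)
  for (i in 1:20) {
    y <- rnorm(50); y_hat <- rnorm(50)
    expect_lte(mean_absolute_error(y, y_hat), rmse(y, y_hat))
    expect_equal(rmse(3 * y, 3 * y_hat), 3 * rmse(y, y_hat))
  }
  expect_error(mean_absolute_error(numeric(0), numeric(0)), "empty")
})

test_that("vectorized metrics agree with naive loop implementations", {
  loop_r2 <- function(y, y_hat) {
    ss_res <- 0; ss_tot <- 0; yb <- sum(y) / length(y)
    for (i in seq_along(y)) {
      ss_res <- ss_res + (y[i] - y_hat[i])^2
      ss_tot <- ss_tot + (y[i] - yb)^2
    }
    1 - ss_res / ss_tot
  }
  loop_mae <- function(y, y_hat) {
    s <- 0
    for (i in seq_along(y)) s <- s + abs(y[i] - y_hat[i])
    s / length(y)
  }
  loop_rmse <- function(y, y_hat) {
    s <- 0
    for (i in seq_along(y)) s <- s + (y[i] - y_hat[i])^2
    sqrt(s / length(y))
  }
  set.seed(17)
  for (i in 1:10) {
    y <- rnorm(200); y_hat <- y + rnorm(200, 0, 0.3)
    expect_equal(r_squared(y, y_hat), loop_r2(y, y_hat), tolerance = 1e-12)
    expect_equal(mean_absolute_error(y, y_hat), loop_mae(y, y_hat),
                 tolerance = 1e-12)
    expect_equal(rmse(y, y_hat), loop_rmse(y, y_hat), tolerance = 1e-12)
  }
})

test_that("adjusted R-squared uses the set count and reproduces published rows", {
  expect_lt(abs(adjusted_r_squared(0.6367, N = 10, p = 4) - 0.3461), 1e-4)
  expect_lt(abs(adjusted_r_squared(0.7872, N = 20, p = 4) - 0.7304), 1e-4)
  expect_equal(adjusted_r_squared(1.0, N = 20, p = 4), 1.0)
  expect_error(adjusted_r_squared(0.5, N = 5, p = 4), "exceed")
  set.seed(23)
  for (i in 1:20) {
    r2 <- runif(1, -1, 0.999)
    expect_lt(adjusted_r_squared(r2, N = 20, p = 4), r2)
  }
})

test_that("percent change reproduces the published derived columns", {
  expect_equal(percent_change(0.6367, 0.7872), 23.63, tolerance = 1e-3)
  expect_equal(percent_change(0.09219, 0.06974), -24.35, tolerance = 1e-3)
  expect_equal(percent_change(5, 5), 0)
  ## negative baseline: sign tracks the direction of change
  expect_gt(percent_change(-2.34, 0.76), 0)
  expect_error(percent_change(0, 1), "zero")
})

test_that("Welch test matches the hand formula and the pooled special case", {
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  res <- welch_t_test(a, b)
  ## hand evaluation of the Welch statistic and Satterthwaite df
  se2 <- var(a) / 4 + var(b) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(se2)
  df_hand <- se2^2 / ((var(a) / 4)^2 / 3 + (var(b) / 4)^2 / 3)
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$df, df_hand, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-12)

  ## equal variance, equal n: Welch t equals pooled Student t
  set.seed(31)
  x <- rnorm(12); y <- rnorm(12)
  pooled <- t.test(x, y, var.equal = TRUE)
  expect_equal(welch_t_test(x, y)$t, unname(pooled$statistic),
               tolerance = 1e-10)

  same <- welch_t_test(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})

test_that("Levene test matches a hand-computed one-way F on absolute deviations", {
  a <- c(1, 2, 5, 8); b <- c(3, 3.5, 4, 4.5)
  res <- levene_test(a, b)
  da <- abs(a - mean(a)); db <- abs(b - mean(b))
  d <- c(da, db); g <- mean(d)
  ssb <- 4 * (mean(da) - g)^2 + 4 * (mean(db) - g)^2
  ssw <- sum((da - mean(da))^2) + sum((db - mean(db))^2)
  W_hand <- (ssb / 1) / (ssw / 6)
  expect_equal(res$W, W_hand, tolerance = 1e-10)
  expect_equal(res$p, pf(W_hand, 1, 6, lower.tail = FALSE),
               tolerance = 1e-10)

  expect_equal(levene_test(a, a)$W, 0)
  expect_equal(levene_test(a, a)$p, 1)
  wider <- levene_test(a, a * 10)
  expect_gt(wider$W, 0)
})
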