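#' Generalized coefficient of determination
#'
#' `1 - sum((y - y_hat)^2) / sum((y - mean(y))^2)`. Unlike a squared
#' correlation this may be negative when the predictions are worse than the
#' mean of the observations.
#'
#' @param y Observed values (length >= 2, non-constant).
#' @param y_hat Predicted values, same length.
#' @return R-squared (unitless, <= 1).
#' @export
r_squared <- function(y, y_hat) {
  y <- as.numeric(y); y_hat <- as.numeric(y_hat)
  if (length(y) != length(y_hat)) stop("y and y_hat must have equal length")
  if (length(y) < 2L) stop("need at least 2 observations")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("y is constant; R-squared undefined")
  1 - sum((y - y_hat)^2) / ss_tot
}

#' Adjusted coefficient of determination
#'
#' `1 - (1 - r2) * (N - 1) / (N - p - 1)`. Here `N` counts training *sets*
#' (whole experiments), not individual data points, so the adjustment
#' reflects how many experiments back the model rather than the raw sample
#' size; `p` is the number of predictors (4 probe channels).
#'
#' @param r2 Unadjusted R-squared.
#' @param N Number of data sets.
#' @param p Number of predictors (default 4).
#' @return Adjusted R-squared.
#' @export
adjusted_r_squared <- function(r2, N, p = 4L) {
  if (any(N <= p + 1L)) stop("N must exceed p + 1")
  1 - (1 - r2) * (N - 1) / (N - p - 1)
}

#' Mean absolute error
#'
#' @param y Observed values (non-empty).
#' @param y_hat Predicted values, same length.
#' @return MAE in target units.
#' @export
mean_absolute_error <- function(y, y_hat) {
  y <- as.numeric(y); y_hat <- as.numeric(y_hat)
  if (!length(y)) stop("empty input")
  if (length(y) != length(y_hat)) stop("y and y_hat must have equal length")
  mean(abs(y - y_hat))
}

#' Root mean squared error
#'
#' @param y Observed values (non-empty).
#' @param y_hat Predicted values, same length.
#' @return RMSE in target units.
#' @export
rmse <- function(y, y_hat) {
  y <- as.numeric(y); y_hat <- as.numeric(y_hat)
  if (!length(y)) stop("empty input")
  if (length(y) != length(y_hat)) stop("y and y_hat must have equal length")
  sqrt(mean((y - y_hat)^2))
}

#' Percent change relative to a baseline
#'
#' `100 * (new - baseline) / abs(baseline)`, so the sign always reflects the
#' direction of the change even for negative baselines.
#'
#' @param baseline Baseline value (non-zero).
#' @param new New value.
#' @return Percent change.
#' @export
percent_change <- function(baseline, new) {
  if (any(baseline == 0)) stop("zero baseline")
  100 * (new - baseline) / abs(baseline)
}

#' Welch's unequal-variance t-test
#'
#' Two-sided Welch t-test with Welch-Satterthwaite degrees of freedom.
#'
#' @param a,b Numeric samples (length >= 2 each).
#' @return List with `t`, `df` and two-sided `p`.
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("samples need length >= 2")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = length(a) + length(b) - 2,
                                        p = 1))
    stop("both samples have zero variance")
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}

#' Levene's test of equal variance (mean-centred)
#'
#' One-way ANOVA on the absolute deviations from the group means, i.e. the
#' classic Levene statistic; the p-value comes from the F distribution.
#'
#' @param a,b Numeric samples (length >= 2 each).
#' @return List with `W` (the F statistic) and `p`.
#' @export
levene_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("samples need length >= 2")
  values <- c(a, b)
  group <- factor(rep(c("a", "b"), c(length(a), length(b))))
  dev <- abs(values - stats::ave(values, group))
  if (stats::var(dev) == 0) return(list(W = 0, p = 1))
  lt <- car::leveneTest(values, group, center = mean)
  list(W = lt[["F value"]][1], p = lt[["Pr(>F)"]][1])
}
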