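#' K-nearest-neighbour imputation of missing sensor channels
#'
#' Treats every time-aligned sample (one grid point of one experiment, all 7
#' channels) as an observation and pools samples across experiments. Each
#' missing entry is replaced by the mean of that channel over the `k`
#' complete samples nearest in Euclidean distance computed over the channels
#' observed in the incomplete sample. Observed entries are returned
#' bit-identical; imputation is idempotent.
#'
#' @param collection A [ferm_collection()]; at least one experiment must be
#'   fully observed for every channel.
#' @param k Number of neighbours (default 5).
#' @return The imputed `ferm_collection` (no missing values remain).
#' @export
impute_missing_channels <- function(collection, k = 5L) {
  stopifnot(inherits(collection, "ferm_collection"))
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  pooled <- do.call(rbind, lapply(collection$experiments, `[[`, "data"))
  complete <- stats::complete.cases(pooled)
  if (!any(complete)) stop("no fully observed samples available")
  if (k > sum(complete)) {
    stop("k = ", k, " exceeds the ", sum(complete), " complete samples")
  }
  donors <- pooled[complete, , drop = FALSE]

  impute_row <- function(row) {
    obs <- !is.na(row)
    if (all(obs)) return(row)
    if (!any(obs)) stop("sample with all channels missing cannot be imputed")
    d2 <- colSums((t(donors[, obs, drop = FALSE]) - row[obs])^2)
    nn <- order(d2)[seq_len(k)]
    row[!obs] <- colMeans(donors[nn, !obs, drop = FALSE])
    row
  }

  for (i in seq_along(collection$experiments)) {
    dat <- collection$experiments[[i]]$data
    bad <- which(!stats::complete.cases(dat))
    for (r in bad) dat[r, ] <- impute_row(dat[r, ])
    collection$experiments[[i]]$data <- dat
  }
  collection
}

#' Fit a per-channel normalizer
#'
#' Learns per-channel statistics over all experiments of a fitting
#' collection: `minmax` stores (min, range) and maps onto `[0, 1]`;
#' `zscore` stores (mean, sd). In evaluation runs the normalizer is fitted
#' on training experiments only and reused unchanged for test data.
#'
#' @param collection An imputed [ferm_collection()].
#' @param scheme `"minmax"` (default) or `"zscore"`.
#' @return A `ferm_normalizer` with `center` and `scale` per channel.
#' @export
fit_normalizer <- function(collection, scheme = c("minmax", "zscore")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(collection, "ferm_collection"))
  if (collection_has_missing(collection)) {
    stop("collection must be imputed before fitting a normalizer")
  }
  pooled <- do.call(rbind, lapply(collection$experiments, `[[`, "data"))
  if (scheme == "minmax") {
    center <- apply(pooled, 2, min)
    scale <- apply(pooled, 2, max) - center
  } else {
    center <- colMeans(pooled)
    scale <- apply(pooled, 2, stats::sd)
  }
  flat <- names(which(scale <= 0 | !is.finite(scale)))
  if (length(flat)) stop("constant channel(s): ", paste(flat, collapse = ", "))
  structure(list(scheme = scheme, center = center, scale = scale),
            class = "ferm_normalizer")
}

normalize_matrix <- function(data, normalizer, invert = FALSE) {
  if (!identical(colnames(data), names(normalizer$center))) {
    stop("channel mismatch between data and normalizer")
  }
  if (invert) {
    sweep(sweep(data, 2, normalizer$scale, "*"), 2, normalizer$center, "+")
  } else {
    sweep(sweep(data, 2, normalizer$center, "-"), 2, normalizer$scale, "/")
  }
}

#' Apply or invert a normalizer over a collection
#'
#' Elementwise affine transform per channel; shapes and missing masks are
#' preserved. `apply_normalizer` followed by `invert_normalizer` is the
#' identity to floating-point precision.
#'
#' @param collection A [ferm_collection()].
#' @param normalizer A [fit_normalizer()] result.
#' @return The transformed `ferm_collection`.
#' @export
apply_normalizer <- function(collection, normalizer) {
  stopifnot(inherits(normalizer, "ferm_normalizer"))
  for (i in seq_along(collection$experiments)) {
    collection$experiments[[i]]$data <-
      normalize_matrix(collection$experiments[[i]]$data, normalizer)
  }
  collection
}

#' @rdname apply_normalizer
#' @export
invert_normalizer <- function(collection, normalizer) {
  stopifnot(inherits(normalizer, "ferm_normalizer"))
  for (i in seq_along(collection$experiments)) {
    collection$experiments[[i]]$data <-
      normalize_matrix(collection$experiments[[i]]$data, normalizer,
                       invert = TRUE)
  }
  collection
}

#' Resample an experiment onto an even grid
#'
#' Linear interpolation of every channel onto `n_points` evenly spaced times
#' over the original span; endpoints are preserved exactly. Missing entries
#' interrupt interpolation (a fully missing channel stays fully missing).
#'
#' @param series A [ferm_experiment()].
#' @param n_points Target grid size (>= 2).
#' @return The regridded `ferm_experiment`.
#' @export
regrid <- function(series, n_points) {
  stopifnot(inherits(series, "ferm_experiment"))
  n_points <- as.integer(n_points)
  if (n_points < 2L) stop("n_points must be >= 2")
  new_time <- seq(series$time[1], series$time[length(series$time)],
                  length.out = n_points)
  new_data <- matrix(NA_real_, n_points, ncol(series$data),
                     dimnames = list(NULL, colnames(series$data)))
  for (ch in colnames(series$data)) {
    y <- series$data[, ch]
    obs <- !is.na(y)
    if (sum(obs) >= 2L) {
      new_data[, ch] <- stats::approx(series$time[obs], y[obs],
                                      xout = new_time, rule = 2)$y
    }
  }
  out <- series
  out$time <- new_time
  out$data <- new_data
  out
}

#' Stack a collection into a (sets, points, channels) tensor
#'
#' @param collection An imputed [ferm_collection()] of uniform length.
#' @return A numeric array `(n_sets, n_points, 7)` with channel dimnames; the
#'   collection's ids and provenance are carried as attributes.
#' @export
to_vae_tensor <- function(collection) {
  stopifnot(inherits(collection, "ferm_collection"))
  if (collection_has_missing(collection)) {
    stop("impute the collection before building tensors")
  }
  n_points <- length(collection$experiments[[1]]$time)
  n <- length(collection)
  tensor <- array(NA_real_, dim = c(n, n_points, length(FERM_CHANNELS)),
                  dimnames = list(NULL, NULL, FERM_CHANNELS))
  for (i in seq_len(n)) tensor[i, , ] <- collection$experiments[[i]]$data
  attr(tensor, "ids") <- collection_ids(collection)
  attr(tensor, "time") <- collection$experiments[[1]]$time
  attr(tensor, "provenance") <-
    vapply(collection$experiments, `[[`, character(1), "provenance")
  tensor
}

#' Rebuild a collection from a series tensor
#'
#' Inverse of [to_vae_tensor()].
#'
#' @param tensor Array `(n_sets, n_points, 7)`.
#' @param time Time grid (defaults to the tensor's `time` attribute).
#' @param ids,provenance Optional overrides.
#' @return A [ferm_collection()].
#' @export
tensor_to_collection <- function(tensor, time = attr(tensor, "time"),
                                 ids = attr(tensor, "ids"),
                                 provenance = attr(tensor, "provenance")) {
  n <- dim(tensor)[1]
  if (is.null(time)) time <- seq_len(dim(tensor)[2])
  if (is.null(ids)) ids <- sprintf("set%03d", seq_len(n))
  if (is.null(provenance)) provenance <- rep("original", n)
  experiments <- lapply(seq_len(n), function(i) {
    dat <- tensor[i, , ]
    colnames(dat) <- FERM_CHANNELS
    ferm_experiment(time, dat, id = ids[i], provenance = provenance[i])
  })
  ferm_collection(experiments)
}

#' Flatten a collection into regression arrays
#'
#' Stacks experiments in collection order into a feature matrix over the four
#' probe channels (pH, redox, capacitance, temperature) and an ethanol target
#' column.
#'
#' @param collection An imputed [ferm_collection()] of uniform length.
#' @return List with `features` (`n_sets*n_points x 4`) and `targets`
#'   (`n_sets*n_points x 1`).
#' @export
to_regression_arrays <- function(collection) {
  stopifnot(inherits(collection, "ferm_collection"))
  if (collection_has_missing(collection)) {
    stop("impute the collection before building regression arrays")
  }
  pooled <- do.call(rbind, lapply(collection$experiments, `[[`, "data"))
  list(features = pooled[, FERM_INPUT_CHANNELS, drop = FALSE],
       targets = pooled[, FERM_TARGET_CHANNEL, drop = FALSE])
}
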