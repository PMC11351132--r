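#' @keywords internal
#' @useDynLib fermaug, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

## Canonical channel order. All arrays, CSV files and tensors use this order;
## the first four channels are the soft-sensor inputs, ethanol is the target.
FERM_CHANNELS <- c("pH", "redox", "capacitance", "temperature",
                   "ethanol", "substrate", "cells")
FERM_INPUT_CHANNELS <- FERM_CHANNELS[1:4]
FERM_TARGET_CHANNEL <- "ethanol"

## CSV column names (units encoded in the header, not in memory).
FERM_CSV_HEADER <- c("time_h", "pH", "redox_mV", "capacitance_pFcm",
                     "temperature_C", "ethanol_gL", "substrate_gL", "cells_gL")

#' Channel names used throughout the package
#'
#' Returns the fixed channel order: pH (-), redox potential (mV), capacitance
#' (pF/cm), temperature (degC), ethanol (g/L), substrate (g/L), cells (g/L).
#' The first four are the online probe signals used as soft-sensor inputs.
#'
#' @return Character vector of length 7.
#' @export
ferm_channels <- function() FERM_CHANNELS

#' Construct a fermentation experiment series
#'
#' One fermentation cycle: a strictly increasing time grid plus seven
#' channels. Missing sensor readings are stored as `NA` (the missing mask).
#'
#' @param time Numeric vector of time points in hours, strictly increasing.
#' @param data Numeric matrix `length(time) x 7` with columns
#'   [ferm_channels()]; `NA` marks missing readings.
#' @param id Experiment identifier (string).
#' @param provenance `"original"` or `"synthetic"`.
#' @param faults Character vector describing injected faults (may be empty).
#' @return An object of class `ferm_experiment`.
#' @export
ferm_experiment <- function(time, data, id,
                            provenance = c("original", "synthetic"),
                            faults = character()) {
  provenance <- match.arg(provenance)
  data <- as.matrix(data)
  if (length(time) < 2L) stop("time grid needs at least 2 points")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (nrow(data) != length(time)) stop("data rows must match time grid")
  if (ncol(data) != length(FERM_CHANNELS)) {
    stop("data must have ", length(FERM_CHANNELS), " channels")
  }
  if (is.null(colnames(data))) {
    colnames(data) <- FERM_CHANNELS
  } else if (!identical(colnames(data), FERM_CHANNELS)) {
    if (!setequal(colnames(data), FERM_CHANNELS)) {
      stop("channel names must be: ", paste(FERM_CHANNELS, collapse = ", "))
    }
    data <- data[, FERM_CHANNELS, drop = FALSE]
  }
  if (any(!is.finite(data[!is.na(data)]))) stop("non-finite channel values")
  structure(
    list(id = as.character(id), time = as.numeric(time), data = data,
         provenance = provenance, faults = as.character(faults)),
    class = "ferm_experiment"
  )
}

#' @export
print.ferm_experiment <- function(x, ...) {
  n_miss <- colSums(is.na(x$data))
  cat(sprintf("<ferm_experiment '%s'> %d points over %.2f h [%s]\n",
              x$id, length(x$time), diff(range(x$time)), x$provenance))
  if (any(n_miss > 0)) {
    cat("  missing:", paste0(names(n_miss)[n_miss > 0], " (",
                             n_miss[n_miss > 0], ")", collapse = ", "), "\n")
  }
  if (length(x$faults)) cat("  faults:", paste(x$faults, collapse = "; "), "\n")
  invisible(x)
}

#' @export
as.data.frame.ferm_experiment <- function(x, ...) {
  data.frame(id = x$id, time_h = x$time, x$data,
             provenance = x$provenance, check.names = FALSE)
}

#' Construct a collection of experiment series
#'
#' An ordered list of [ferm_experiment()] objects sharing grid length and
#' channel set, with unique ids.
#'
#' @param experiments List of `ferm_experiment` objects.
#' @return An object of class `ferm_collection`.
#' @export
ferm_collection <- function(experiments) {
  if (!length(experiments)) stop("empty collection")
  ok <- vapply(experiments, inherits, logical(1), "ferm_experiment")
  if (!all(ok)) stop("all elements must be ferm_experiment objects")
  n <- vapply(experiments, function(e) length(e$time), integer(1))
  if (length(unique(n)) != 1L) stop("all experiments must share grid length")
  ids <- vapply(experiments, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("experiment ids must be unique")
  structure(list(experiments = experiments), class = "ferm_collection")
}

#' @export
length.ferm_collection <- function(x) length(x$experiments)

#' @export
`[[.ferm_collection` <- function(x, i) x$experiments[[i]]

#' @export
`[.ferm_collection` <- function(x, i) ferm_collection(x$experiments[i])

#' @export
print.ferm_collection <- function(x, ...) {
  prov <- table(vapply(x$experiments, `[[`, character(1), "provenance"))
  cat(sprintf("<ferm_collection> %d experiments (%s), %d grid points\n",
              length(x), paste(names(prov), prov, sep = ": ", collapse = ", "),
              length(x$experiments[[1]]$time)))
  invisible(x)
}

#' @export
as.data.frame.ferm_collection <- function(x, ...) {
  do.call(rbind, lapply(x$experiments, as.data.frame))
}

collection_ids <- function(collection) {
  vapply(collection$experiments, `[[`, character(1), "id")
}

collection_has_missing <- function(collection) {
  any(vapply(collection$experiments, function(e) anyNA(e$data), logical(1)))
}
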