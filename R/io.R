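#' Write one experiment to CSV
#'
#' One row per grid point with header
#' `time_h,pH,redox_mV,capacitance_pFcm,temperature_C,ethanol_gL,substrate_gL,cells_gL`.
#' Missing readings are written as empty fields; values are preserved to at
#' least 12 significant digits on round trip.
#'
#' @param series A [ferm_experiment()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_experiment_csv <- function(series, path) {
  stopifnot(inherits(series, "ferm_experiment"))
  df <- data.frame(series$time, series$data)
  names(df) <- FERM_CSV_HEADER
  fmt <- lapply(df, function(col) {
    out <- vapply(col, function(v) {
      if (is.na(v)) "" else format(v, digits = 15, scientific = FALSE,
                                   trim = TRUE)
    }, character(1))
    out
  })
  lines <- c(paste(FERM_CSV_HEADER, collapse = ","),
             do.call(paste, c(fmt, sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Read one experiment from CSV
#'
#' Inverse of [write_experiment_csv()]: empty fields become missing values.
#' A file whose redox column is entirely empty parses as a
#' failed-redox-sensor experiment.
#'
#' @param path CSV file path.
#' @param id Experiment id (defaults to the file name without extension).
#' @param provenance `"original"` or `"synthetic"`.
#' @return A [ferm_experiment()].
#' @export
read_experiment_csv <- function(path, id = NULL,
                                provenance = "original") {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  if (!identical(header, FERM_CSV_HEADER)) {
    stop("malformed header in ", path, " (line 1); expected: ",
         paste(FERM_CSV_HEADER, collapse = ","))
  }
  df <- utils::read.csv(path, colClasses = "numeric",
                        na.strings = c("", "NA"))
  bad <- which(!stats::complete.cases(df["time_h"]))
  if (length(bad)) stop("missing time value in ", path, " at line ",
                        bad[1] + 1L)
  data <- as.matrix(df[, -1, drop = FALSE])
  colnames(data) <- FERM_CHANNELS
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  ferm_experiment(df$time_h, data, id = id, provenance = provenance)
}

#' Write a study collection to a directory
#'
#' Writes one CSV per experiment plus a `manifest.csv` recording `id`,
#' `file`, `provenance` and injected `faults`, so original and synthetic
#' series never mix silently.
#'
#' @param collection A [ferm_collection()].
#' @param dir Output directory (created if absent).
#' @return The manifest data frame, invisibly.
#' @export
write_study <- function(collection, dir) {
  stopifnot(inherits(collection, "ferm_collection"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(collection$experiments, function(e) {
    file <- paste0(e$id, ".csv")
    write_experiment_csv(e, file.path(dir, file))
    data.frame(id = e$id, file = file, provenance = e$provenance,
               faults = paste(e$faults, collapse = ";"))
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read a study collection from a directory
#'
#' Reads `manifest.csv` and the experiment CSVs it lists.
#'
#' @param dir Directory written by [write_study()].
#' @return A [ferm_collection()].
#' @export
read_study <- function(dir) {
  manifest_path <- file.path(dir, "manifest.csv")
  if (!file.exists(manifest_path)) stop("no manifest.csv in ", dir)
  manifest <- utils::read.csv(manifest_path, colClasses = "character")
  experiments <- lapply(seq_len(nrow(manifest)), function(i) {
    e <- read_experiment_csv(file.path(dir, manifest$file[i]),
                             id = manifest$id[i],
                             provenance = manifest$provenance[i])
    if (nzchar(manifest$faults[i])) {
      e$faults <- strsplit(manifest$faults[i], ";")[[1]]
    }
    e
  })
  ferm_collection(experiments)
}
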