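# Reading/writing series, and serializing test results.

#' Read a univariate series from a text file
#'
#' Parses one value per line; a single leading non-numeric line is
#' treated as a header and skipped.  Lines with comma- or tab-separated
#' fields are supported via `column`.
#'
#' @param path File path.
#' @param column Which field to take when lines hold several (default 1).
#' @return Numeric vector.
#' @export
read_series <- function(path, column = 1L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty file: ", path, call. = FALSE)
  pick <- function(ln) {
    parts <- strsplit(trimws(ln), "[,\t ]+")[[1]]
    if (length(parts) < column) NA_character_ else parts[column]
  }
  fields <- vapply(lines, pick, character(1), USE.NAMES = FALSE)
  vals <- suppressWarnings(as.numeric(fields))
  start <- 1L
  if (is.na(vals[1L]) && length(vals) > 1L) start <- 2L  # header line
  vals <- vals[start:length(vals)]
  bad <- which(is.na(vals))
  if (length(bad)) {
    stop("cannot parse a number on line ", bad[1L] + start - 1L, " of ",
         path, call. = FALSE)
  }
  if (!all(is.finite(vals))) {
    bad <- which(!is.finite(vals))[1L]
    stop("non-finite value on line ", bad + start - 1L, " of ", path,
         call. = FALSE)
  }
  vals
}

#' Write a series as single-column text
#'
#' Values are printed with 17 significant digits so a read/write round
#' trip is lossless at double precision.
#'
#' @param x Numeric vector.
#' @param path Output path.
#' @export
write_series <- function(x, path) {
  writeLines(formatC(x, digits = 17, format = "g"), path)
  invisible(path)
}

# per-frequency table of a finished test
os_freq_table <- function(test) {
  stopifnot(inherits(test, "os_test"))
  r <- test$report
  data.frame(frequency = r$freq, OS = test$spectrum$values,
             surrogate_mean = test$ensemble$mean,
             surrogate_sd = test$ensemble$sd, z = r$z, p = r$p, q = r$q,
             significant = r$significant)
}

#' Export a finished ordinal-spectrum test
#'
#' Writes a machine-readable JSON report (config echo, verdict,
#' significant bands, per-frequency arrays) and/or a TSV of the
#' per-frequency table.
#'
#' @param test An `"os_test"` from [ordinal_spectrum_test()].
#' @param json,tsv Output paths; `NULL` skips that artifact.
#' @return Invisibly, the list serialized to JSON.
#' @export
write_os_report <- function(test, json = NULL, tsv = NULL) {
  stopifnot(inherits(test, "os_test"))
  tab <- os_freq_table(test)
  rep <- list(
    config = test$config,
    verdict = test$verdict,
    min_q = min(test$report$q),
    bands = test$report$bands[, c("f_lo", "f_hi")],
    frequencies = tab
  )
  if (!is.null(json)) {
    jsonlite::write_json(rep, json, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  }
  if (!is.null(tsv)) {
    utils::write.table(tab, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(rep)
}

#' Export a rank autocovariance as two-column TSV
#'
#' @param cov A `"rank_autocov"`.
#' @param path Output path.
#' @export
write_cov_tsv <- function(cov, path) {
  stopifnot(inherits(cov, "rank_autocov"))
  utils::write.table(
    data.frame(lag = 0:(cov$n_lags - 1L), covariance = cov$cov),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export an ordinal spectrum as two-column TSV
#'
#' @param os An `"ordinal_spectrum"`.
#' @param path Output path.
#' @export
write_spectrum_tsv <- function(os, path) {
  stopifnot(inherits(os, "ordinal_spectrum"))
  utils::write.table(
    data.frame(normalized_frequency = os$freq, OS = os$values),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
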