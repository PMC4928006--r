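#' Read a univariate series from a delimited text file
#'
#' Reads one numeric column from a CSV, TSV, or whitespace-separated text
#' file. A header row is auto-detected (its cell in the target column is not
#' numeric) unless `header` is given explicitly. Non-numeric data rows are
#' rejected with their file row numbers.
#'
#' @param path Path to an existing file.
#' @param format `"auto"` (by extension, default), `"csv"`, `"tsv"`, or
#'   `"txt"` (whitespace).
#' @param column Column index, or name when the file has a header.
#' @param header `NA` to auto-detect, otherwise `TRUE`/`FALSE`.
#' @return A `bstks_series` with `origin = "file"`.
#' @export
read_series <- function(path, format = c("auto", "csv", "tsv", "txt"),
                        column = 1L, header = NA) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "csv") "csv" else if (ext == "tsv") "tsv" else "txt"
  }
  sep <- switch(format, csv = ",", tsv = "\t", txt = "")
  raw <- utils::read.table(path, sep = sep, header = FALSE,
                           colClasses = "character", strip.white = TRUE,
                           stringsAsFactors = FALSE)
  first <- raw[1L, , drop = TRUE]
  if (is.na(header)) {
    probe <- if (is.character(column)) first else first[[as.integer(column)]]
    header <- if (is.character(column)) {
      column %in% unlist(first)
    } else {
      is.na(suppressWarnings(as.numeric(probe)))
    }
  }
  if (header) {
    names(raw) <- unlist(raw[1L, ])
    raw <- raw[-1L, , drop = FALSE]
  }
  if (is.character(column) && !column %in% names(raw)) {
    stop(sprintf("column '%s' not found", column), call. = FALSE)
  }
  col <- if (is.character(column)) raw[[column]] else raw[[as.integer(column)]]
  if (is.null(col) || length(col) == 0L) {
    stop("selected column is empty", call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(col))
  bad <- which(is.na(vals))
  if (length(bad) > 0L) {
    file_rows <- bad + if (header) 1L else 0L
    stop(sprintf("non-numeric value(s) in column at file row(s): %s",
                 paste(utils::head(file_rows, 10L), collapse = ", ")),
         call. = FALSE)
  }
  series(vals, name = basename(path), origin = "file")
}

#' Write a series as a one-column CSV
#'
#' @param x A [series()] or numeric vector.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_series <- function(x, path) {
  z <- series_values(x)
  # 17 significant digits: doubles survive the round trip bit-identically
  writeLines(c("value", sprintf("%.17g", z)), path)
  invisible(path)
}

#' Write a detection result or benchmark summary to disk
#'
#' Detection results (`bstks_result`, `cp_scan`) are written as JSON with a
#' deterministic field order; reported change points are 1-based and mapped
#' back to the original file's row numbering via the series offset. A missing
#' estimate is written as an explicit no-change record. Benchmark summaries
#' are written as tidy CSV, one row per method x condition x metric.
#'
#' @param x A `bstks_result`, `cp_scan`, or `bstks_benchmark`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_result <- function(x, path) {
  UseMethod("write_result")
}

#' @export
write_result.bstks_result <- function(x, path) {
  rec <- list(
    method = "bstks",
    series = x$series_name,
    n = x$n,
    detected = !is.na(x$e_cp),
    e_cp = if (is.na(x$e_cp)) NULL else x$e_cp + x$offset,
    message = if (is.na(x$e_cp)) "no change detected" else NULL,
    significant = x$significant,
    statistic = if (is.na(x$statistic)) NULL else x$statistic,
    thresholds = list(crit_alpha = x$config$crit_alpha,
                      crit_beta = x$config$crit_beta,
                      crit_gamma = x$config$crit_gamma),
    modes = list(criterion1_mode = x$config$criterion1_mode,
                 descent_mode = x$config$descent_mode),
    path = x$path
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @export
write_result.cp_scan <- function(x, path) {
  rec <- list(
    method = x$method,
    detected = !is.na(x$e_cp),
    e_cp = if (is.na(x$e_cp)) NULL else x$e_cp,
    message = if (is.na(x$e_cp)) "no change detected" else NULL,
    statistic = if (is.na(x$statistic)) NULL else x$statistic,
    profile = as.numeric(x$profile),
    splits = x$splits
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @export
write_result.bstks_benchmark <- function(x, path) {
  tidy_block <- function(df, position) {
    metrics <- c("hit_rate", "error", "accuracy", "auc", "mean_time")
    do.call(rbind, lapply(metrics, function(m) {
      data.frame(method = df$method,
                 group = df$group,
                 N = if ("N" %in% names(df)) df$N else NA_integer_,
                 d = df$d,
                 position = position(df),
                 metric = m,
                 value = df[[m]])
    }))
  }
  cond <- tidy_block(x$conditions, function(df) as.character(df$position))
  grp <- tidy_block(x$groups, function(df) "all")
  x$overall$group <- NA_integer_
  ovr <- tidy_block(x$overall, function(df) "grand")
  out <- rbind(cond, grp, ovr)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
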