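#' Construct a time series object
#'
#' A `bstks_series` is a thin container around a numeric vector of samples
#' `z[1..N]` together with provenance metadata: a display name, whether the
#' values came from a file or a generator, and the index-mapping offset
#' recorded when the length is normalised (0 when no shift was applied).
#'
#' @param values Numeric vector of samples; all values must be finite.
#' @param name Free-text label used in printing and output files.
#' @param origin Either `"file"` or `"synthetic"`.
#' @param offset Integer index shift applied during length normalisation;
#'   reported positions are mapped back to original coordinates by adding it.
#' @return An object of class `bstks_series`.
#' @examples
#' s <- series(rnorm(32))
#' length(s$values)
#' @export
series <- function(values, name = "series", origin = c("synthetic", "file"),
                   offset = 0L) {
  origin <- match.arg(origin)
  values <- as.numeric(values)
  if (length(values) == 0L) {
    stop("a series must contain at least one sample", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("all series values must be finite", call. = FALSE)
  }
  structure(
    list(values = values, name = as.character(name)[1L], origin = origin,
         offset = as.integer(offset)),
    class = "bstks_series"
  )
}

#' @export
print.bstks_series <- function(x, ...) {
  cat(sprintf("<bstks_series> '%s': N = %d, origin = %s, offset = %d\n",
              x$name, length(x$values), x$origin, x$offset))
  invisible(x)
}

# Accept either a bstks_series or a bare numeric vector everywhere.
series_values <- function(x) {
  if (inherits(x, "bstks_series")) x$values else as.numeric(x)
}

series_offset <- function(x) {
  if (inherits(x, "bstks_series")) x$offset else 0L
}

is_pow2 <- function(n) {
  n >= 1 && bitwAnd(as.integer(n), as.integer(n) - 1L) == 0L
}

#' Normalise a series to a dyadic length
#'
#' The tree search requires a full set of dyadic levels, so the number of
#' samples must be a power of two (and at least 4). With
#' `policy = "truncate"` the tail is dropped down to the largest power of two
#' not exceeding the input length (with a warning); leading indices are
#' unchanged, so the recorded offset stays 0. With `policy = "error"` a
#' non-dyadic length is an error.
#'
#' @param x A [series()] or numeric vector.
#' @param policy `"truncate"` (default) or `"error"`.
#' @return A `bstks_series` of dyadic length.
#' @examples
#' s <- normalize_length(rnorm(33))   # warns, keeps the first 32 samples
#' length(s$values)
#' @export
normalize_length <- function(x, policy = c("truncate", "error")) {
  policy <- match.arg(policy)
  s <- if (inherits(x, "bstks_series")) x else series(x)
  n <- length(s$values)
  if (n < 4L) {
    stop("series must contain at least 4 samples", call. = FALSE)
  }
  if (is_pow2(n)) {
    return(s)
  }
  if (policy == "error") {
    stop(sprintf("series length %d is not a power of two", n), call. = FALSE)
  }
  n2 <- 2L^floor(log2(n))
  warning(sprintf("series truncated from %d to %d samples (tail dropped)",
                  n, n2), call. = FALSE)
  s$values <- s$values[seq_len(n2)]
  s
}
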