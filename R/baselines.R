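#' Scaled two-sample Kolmogorov-Smirnov statistic
#'
#' `sqrt(mn/(m+n)) * sup_x |F_m(x) - G_n(x)|`, the supremum taken exactly over
#' the pooled sample points (where the e.c.d.f. gap attains its maximum).
#'
#' @param x,y Non-empty numeric samples.
#' @return The scaled statistic (scalar, `>= 0`).
#' @examples
#' two_sample_ks(c(0, 0, 0), c(1, 1, 1, 1, 1))  # sqrt(15/8)
#' @export
two_sample_ks <- function(x, y) {
  m <- length(x)
  n <- length(y)
  if (m == 0L || n == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  v <- sort(unique(c(x, y)))
  gap <- max(abs(findInterval(v, sort(x)) / m - findInterval(v, sort(y)) / n))
  sqrt(m * n / (m + n)) * gap
}

new_cp_scan <- function(method, e_cp, statistic, profile, splits) {
  structure(list(method = method, e_cp = e_cp, statistic = statistic,
                 profile = profile, splits = splits),
            class = "cp_scan")
}

#' @export
print.cp_scan <- function(x, ...) {
  cat(sprintf("<cp_scan> method = %s\n", x$method))
  if (is.na(x$e_cp)) {
    cat("  no estimate (profile undefined)\n")
  } else {
    cat(sprintf("  estimated change point: %d, statistic = %.4f\n",
                x$e_cp, x$statistic))
  }
  invisible(x)
}

#' Exhaustive Kolmogorov-Smirnov scan
#'
#' Computes [two_sample_ks()] between `z[1..m]` and `z[(m+1)..N]` for every
#' split `m = 1..N-1`; the estimate is the argmax (first maximum on ties),
#' reported as the last pre-change sample index.
#'
#' @param x A [series()] or numeric vector, `N >= 4`.
#' @return A `cp_scan` with `e_cp`, `statistic`, the per-split `profile`, and
#'   the `splits` it is indexed by.
#' @export
ks_scan <- function(x) {
  z <- series_values(x)
  N <- length(z)
  if (N < 4L) stop("series too short for a KS scan (N >= 4)", call. = FALSE)
  splits <- seq_len(N - 1L)
  profile <- vapply(splits, function(m) {
    two_sample_ks(z[1:m], z[(m + 1):N])
  }, numeric(1))
  i <- which.max(profile)
  new_cp_scan("ks", splits[i], profile[i], profile, splits)
}

#' Welch-t scan
#'
#' Computes the Welch two-sample t statistic
#' `t = (mean_L - mean_R) / sqrt(S1^2/m + S2^2/n)` for every split
#' `m = 2..N-2` (each side needs at least two samples for a variance);
#' the estimate is the argmax of `|t|`. Splits where both segment variances
#' are zero yield `NA` in the profile and are excluded from the argmax; when
#' the whole profile is undefined no estimate is returned.
#'
#' @param x A [series()] or numeric vector, `N >= 8` (shorter series leave
#'   too few valid splits to be informative).
#' @return A `cp_scan`; the profile holds `|t|` values.
#' @export
t_scan <- function(x) {
  z <- series_values(x)
  N <- length(z)
  if (N < 8L) stop("series too short for a t scan (N >= 8)", call. = FALSE)
  splits <- seq(2L, N - 2L)
  profile <- vapply(splits, function(m) {
    zl <- z[1:m]
    zr <- z[(m + 1):N]
    v1 <- stats::var(zl)
    v2 <- stats::var(zr)
    se2 <- v1 / m + v2 / (N - m)
    if (se2 == 0) NA_real_ else abs(mean(zl) - mean(zr)) / sqrt(se2)
  }, numeric(1))
  if (all(is.na(profile))) {
    return(new_cp_scan("t", NA_integer_, NA_real_, profile, splits))
  }
  i <- which.max(profile)  # which.max skips NAs; first maximum on ties
  new_cp_scan("t", splits[i], profile[i], profile, splits)
}

#' Singular-spectrum-analysis window configuration
#'
#' Defaults: window `m = max(8, N/8 rounded down to even)`, lag `M = m/2`,
#' `K = m - M + 1` lagged vectors per window, base interval = the first `m`
#' samples, and subspace dimension `l` chosen at fit time as the smallest
#' count of leading singular directions capturing at least `energy_frac` of
#' the base trajectory matrix's squared singular-value energy.
#'
#' @param N Series length.
#' @param m Even window width, `4 <= m <= N/2`.
#' @param l Subspace dimension (`1..M`), or `NULL` to use the energy rule.
#' @param energy_frac Variance fraction for the automatic choice of `l`.
#' @return An object of class `ssa_config` with `m`, `M`, `K`, `l`,
#'   `energy_frac`.
#' @export
ssa_config <- function(N, m = NULL, l = NULL, energy_frac = 0.9) {
  if (is.null(m)) m <- max(8L, 2L * (as.integer(N) %/% 16L))
  m <- as.integer(m)
  if (m %% 2L != 0L || m < 4L || m > N / 2) {
    stop("SSA window m must be even with 4 <= m <= N/2", call. = FALSE)
  }
  M <- m %/% 2L
  if (!is.null(l)) {
    l <- as.integer(l)
    if (l < 1L || l > M) stop("subspace dimension l must be in 1..M",
                              call. = FALSE)
  }
  structure(list(m = m, M = M, K = m - M + 1L, l = l,
                 energy_frac = energy_frac),
            class = "ssa_config")
}

#' Lagged (Hankel) trajectory matrix of a window
#'
#' The `M x K` matrix of the interval `[n+1, n+m]` with entry
#' `(i, h) = z[n + i + h - 1]`; anti-diagonals are constant.
#'
#' @param x A [series()] or numeric vector.
#' @param n 0-based window start; requires `n + m <= N`.
#' @param config An [ssa_config()].
#' @return Numeric matrix of dimension `M x K`.
#' @examples
#' ssa_trajectory(1:6, 0, ssa_config(24, m = 4))  # rbind(1:3, 2:4)
#' @export
ssa_trajectory <- function(x, n, config) {
  z <- series_values(x)
  if (n < 0 || n + config$m > length(z)) {
    stop("window overruns the series", call. = FALSE)
  }
  outer(seq_len(config$M), seq_len(config$K),
        function(i, h) z[n + i + h - 1])
}

#' Sequential SSA change detection
#'
#' Describes the base interval (the first `m` samples) by the subspace
#' spanned by the top `l` left singular vectors of its trajectory matrix,
#' then slides a test window along the series: for each start
#' `n = 0..N-m-M`, the detection statistic is the mean squared distance of
#' the test window's lagged vectors to the base subspace,
#' `D_n = ||X_n - P X_n||_F^2 / (M K)` with `P` the subspace projector.
#' A structural change makes the lagged vectors leave the base subspace and
#' the profile rise; after the window has fully crossed the change the
#' profile plateaus, so the change is localised by the *onset* of the rise
#' rather than the argmax over the plateau. The estimate maps the first
#' window start at which the profile reaches half its maximum to a sample
#' index as `e_cp = n_onset + m`, clamped to `1..N-1` (a declared
#' convention; the profile-to-index mapping is not prescribed by the
#' detection statistic itself).
#'
#' @param x A [series()] or numeric vector with `N >= 4 m`.
#' @param config An [ssa_config()]; defaults to `ssa_config(N)`.
#' @return A `cp_scan`; `splits` holds the 0-based window starts, and the
#'   resolved subspace dimension is attached as attribute `"l"` of the
#'   profile.
#' @export
ssa_detect <- function(x, config = NULL) {
  z <- series_values(x)
  N <- length(z)
  if (is.null(config)) config <- ssa_config(N)
  m <- config$m
  M <- config$M
  if (N < 4L * m) {
    stop("series too short for the SSA window (needs N >= 4m)", call. = FALSE)
  }
  base <- ssa_trajectory(z, 0L, config)
  sv <- svd(base)
  l <- config$l
  if (is.null(l)) {
    energy <- sv$d^2
    total <- sum(energy)
    l <- if (total == 0) 1L else which(cumsum(energy) / total >=
                                         config$energy_frac)[1L]
  }
  U <- sv$u[, seq_len(l), drop = FALSE]
  starts <- 0:(N - m - M)
  profile <- vapply(starts, function(n) {
    X <- ssa_trajectory(z, n, config)
    R <- X - U %*% crossprod(U, X)
    sum(R^2) / (M * config$K)
  }, numeric(1))
  attr(profile, "l") <- l
  peak <- max(profile)
  onset <- which(profile >= peak / 2)[1L]
  e_cp <- min(max(starts[onset] + m, 1L), N - 1L)
  new_cp_scan("ssa", as.integer(e_cp), peak, profile, starts)
}
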