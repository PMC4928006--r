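#' Exact hit rate of a set of estimates
#'
#' Fraction of estimates equal to the true change point exactly; missing
#' estimates (`NA`) count as non-hits.
#'
#' @param estimates Integer vector of estimated change points (`NA` allowed).
#' @param truth True change-point index.
#' @return Value in `[0, 1]`.
#' @export
hit_rate <- function(estimates, truth) {
  if (length(estimates) == 0L) stop("no estimates supplied", call. = FALSE)
  mean(!is.na(estimates) & estimates == truth)
}

#' Median-location error of a set of estimates
#'
#' `|median(estimates) - truth|` with the lower median on even counts, so the
#' error is always an achievable sample-index distance. `NA` estimates are
#' dropped; an error is raised when none are defined. An error of 0 is
#' achievable with a hit rate below 1 (e.g. estimates 6, 8, 10 against truth
#' 8), which is what makes this location reading of "error" consistent with
#' hit rates below 1 printed alongside zero errors.
#'
#' @inheritParams hit_rate
#' @return Non-negative error in sample indices.
#' @export
error_stat <- function(estimates, truth) {
  est <- estimates[!is.na(estimates)]
  if (length(est) == 0L) stop("all estimates are undefined", call. = FALSE)
  s <- sort(est)
  as.numeric(abs(s[floor((length(s) + 1) / 2)] - truth))
}

#' Accuracy implied by a location error
#'
#' The identity `accuracy = 1 - error/N`, which reproduces printed
#' (error, accuracy) pairs such as (20, .375), (3, .906), (8, .750) at
#' `N = 32`.
#'
#' @param error Location error, `0 <= error <= N`.
#' @param N Series length.
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy_from_error <- function(error, N) {
  if (any(error < 0) || any(error > N)) {
    stop("error must lie in [0, N]", call. = FALSE)
  }
  1 - error / N
}

#' Rank-based ROC AUC of a detection statistic
#'
#' Probability that a randomly chosen alternative-case statistic exceeds a
#' randomly chosen null-case statistic, ties counting one half — the
#' Wilcoxon/Mann-Whitney reading of the area under the swept-threshold ROC
#' curve.
#'
#' @param alt_statistics Statistics from shift-present runs.
#' @param null_statistics Statistics from matched null (no-shift) runs.
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(3, 1), c(2, 0))  # 0.75
#' @export
roc_auc <- function(alt_statistics, null_statistics) {
  alt <- alt_statistics[!is.na(alt_statistics)]
  null <- null_statistics[!is.na(null_statistics)]
  if (length(alt) == 0L || length(null) == 0L) {
    stop("both statistic samples must be non-empty", call. = FALSE)
  }
  r <- rank(c(alt, null))
  na <- length(alt)
  (sum(r[seq_len(na)]) - na * (na + 1) / 2) / (na * length(null))
}

#' Unscaled e.c.d.f. distance between the two segments at a split
#'
#' `sup_x |F_m(x) - G_n(x)|` between `z[1..cp]` and `z[(cp+1)..N]`, without
#' the sample-size scale factor; lies in `[0, 1]` and summarises how well a
#' detected split separates two distributional regimes.
#'
#' @param x A [series()] or numeric vector.
#' @param cp Split index, `1 <= cp <= N-1`.
#' @return Value in `[0, 1]`.
#' @export
vecdf_distance <- function(x, cp) {
  z <- series_values(x)
  N <- length(z)
  if (cp < 1 || cp > N - 1) stop("cp must satisfy 1 <= cp <= N-1",
                                 call. = FALSE)
  v <- sort(unique(z))
  max(abs(findInterval(v, sort(z[1:cp])) / cp -
            findInterval(v, sort(z[(cp + 1):N])) / (N - cp)))
}

run_one_method <- function(method, z, config) {
  if (method == "bstks") {
    res <- bstks_detect(z, config)
    list(e_cp = res$e_cp, statistic = res$statistic)
  } else if (method == "ks") {
    res <- ks_scan(z)
    list(e_cp = res$e_cp, statistic = res$statistic)
  } else if (method == "t") {
    res <- t_scan(z)
    list(e_cp = res$e_cp, statistic = res$statistic)
  } else {
    res <- ssa_detect(z)
    list(e_cp = res$e_cp, statistic = res$statistic)
  }
}

#' Run the synthetic mean-shift benchmark
#'
#' Generates every series demanded by the design ([expand_benchmark()]), runs
#' every requested detector on each, and aggregates per-condition and
#' per-group metrics: exact hit rate, median-location error, the implied
#' accuracy `1 - error/N`, optionally a rank-based AUC against matched null
#' (no-shift) runs, and informational mean wall-clock time per run. Detector
#' failures are caught, logged as warnings, and counted as undefined
#' estimates. Grand means are unweighted means over groups of the per-group
#' means (each group mean itself an unweighted mean over its positions).
#'
#' @param spec A [benchmark_spec()].
#' @param config A [detector_config()] used by the tree-search detector.
#' @param compute_auc Logical; when `TRUE`, every condition is paired with
#'   `reps` null runs (same design, `v = 0`, disjoint seeds) and the AUC of
#'   the final detection statistic is reported (doubles the run count).
#' @return An object of class `bstks_benchmark`: list with `conditions`
#'   (one row per method x group x position), `groups` (per-group means),
#'   `overall` (per-method grand means), plus the `spec` and `config`.
#' @export
run_benchmark <- function(spec, config = detector_config(),
                          compute_auc = FALSE) {
  if (!inherits(spec, "benchmark_spec")) {
    stop("expected a 'benchmark_spec' object", call. = FALSE)
  }
  runs <- expand_benchmark(spec)
  conditions <- unique(runs[, c("group", "N", "v", "position", "cp")])
  cond_rows <- list()
  for (ci in seq_len(nrow(conditions))) {
    cond <- conditions[ci, ]
    sel <- runs[runs$group == cond$group & runs$position == cond$position, ]
    ests <- matrix(NA_real_, nrow = nrow(sel), ncol = length(spec$methods),
                   dimnames = list(NULL, spec$methods))
    stats_ <- ests
    times <- matrix(0, nrow = nrow(sel), ncol = length(spec$methods),
                    dimnames = list(NULL, spec$methods))
    null_stats <- if (compute_auc) ests else NULL
    for (ri in seq_len(nrow(sel))) {
      row <- sel[ri, ]
      z <- make_sample(simulation_spec(row$N, row$cp, row$v,
                                       noise_sd = row$noise_sd,
                                       seed = row$seed))
      for (method in spec$methods) {
        t0 <- proc.time()[["elapsed"]]
        out <- tryCatch(run_one_method(method, z, config),
                        error = function(e) {
                          warning(sprintf("%s failed on seed %d: %s", method,
                                          row$seed, conditionMessage(e)),
                                  call. = FALSE)
                          list(e_cp = NA_integer_, statistic = NA_real_)
                        })
        times[ri, method] <- proc.time()[["elapsed"]] - t0
        ests[ri, method] <- out$e_cp
        stats_[ri, method] <- out$statistic
      }
      if (compute_auc) {
        null_seed <- derive_seed(spec$base_seed, row$group, row$position,
                                 row$rep, null = TRUE)
        z0 <- make_sample(simulation_spec(row$N, row$cp, 0,
                                          noise_sd = row$noise_sd,
                                          seed = null_seed))
        for (method in spec$methods) {
          out <- tryCatch(run_one_method(method, z0, config),
                          error = function(e) list(e_cp = NA_integer_,
                                                   statistic = NA_real_))
          null_stats[ri, method] <- out$statistic
        }
      }
    }
    for (method in spec$methods) {
      err <- tryCatch(error_stat(ests[, method], cond$cp),
                      error = function(e) NA_real_)
      auc <- if (compute_auc &&
                 any(!is.na(stats_[, method])) &&
                 any(!is.na(null_stats[, method]))) {
        roc_auc(stats_[, method], null_stats[, method])
      } else {
        NA_real_
      }
      cond_rows[[length(cond_rows) + 1L]] <- data.frame(
        method = method, group = cond$group, N = cond$N, d = spec$d,
        v = cond$v, position = cond$position, cp = cond$cp,
        n_runs = nrow(sel),
        hit_rate = hit_rate(ests[, method], cond$cp),
        error = err,
        accuracy = if (is.na(err)) NA_real_ else accuracy_from_error(err, cond$N),
        auc = auc,
        mean_time = mean(times[, method])
      )
    }
  }
  cond_df <- do.call(rbind, cond_rows)
  agg <- function(df, by) {
    stats::aggregate(df[, c("hit_rate", "error", "accuracy", "auc",
                            "mean_time")],
                     by = df[by], FUN = function(x) mean(x, na.rm = TRUE))
  }
  groups_df <- agg(cond_df, c("method", "group", "N", "d"))
  overall_df <- agg(groups_df, c("method", "d"))
  structure(list(conditions = cond_df, groups = groups_df,
                 overall = overall_df, spec = spec, config = config),
            class = "bstks_benchmark")
}

#' @export
print.bstks_benchmark <- function(x, ...) {
  cat(sprintf("<bstks_benchmark> d = %g, groups {%s}, %d reps x %d positions\n",
              x$spec$d, paste(x$spec$groups, collapse = ","), x$spec$reps,
              length(x$spec$positions)))
  cat("per-group means:\n")
  print(x$groups, row.names = FALSE, digits = 4)
  cat("grand means over groups:\n")
  print(x$overall, row.names = FALSE, digits = 4)
  invisible(x)
}
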