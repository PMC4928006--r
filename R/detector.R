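#' Asymptotic two-sample Kolmogorov-Smirnov critical value
#'
#' Closed-form large-sample quantile of the scaled two-sample KS statistic:
#' `sqrt(-log(level/2) / 2)`. Monotone decreasing in the significance level.
#'
#' @param level Significance level in (0, 1).
#' @return The critical value (a positive number).
#' @examples
#' ks_critical(0.05)  # 1.358
#' @export
ks_critical <- function(level) {
  if (!is.numeric(level) || any(level <= 0) || any(level >= 1)) {
    stop("significance level must lie strictly in (0, 1)", call. = FALSE)
  }
  sqrt(-log(level / 2) / 2)
}

#' Detector configuration
#'
#' Bundles the significance levels, critical values, and mode flags of the
#' tree-search detector.
#'
#' The three gates are: `crit_alpha` for the per-node e.c.d.f. statistic
#' (criterion 1), `crit_beta` for the variance-fluctuation evidence
#' (criterion 2), and `crit_gamma` for the final leaf-level KS statistic
#' (criterion 3, the overall significance call). `crit_alpha` has the
#' closed-form asymptotic value [ks_critical()]`(alpha)`, the scale the
#' e.c.d.f. statistic lives on. The criterion-2 evidence statistics (the
#' children's raw detail coefficients and the literal variance fluctuations)
#' are standard normal in units of the noise standard deviation under
#' within-block homogeneity, so `crit_beta` is a z-scale threshold: the
#' default `NA` resolves, per series, to the depth-adjusted asymptotic
#' quantile `qnorm(1 - beta / (2 * (log2(N) - 1)))` (a Bonferroni bound on
#' the familywise false-evidence rate along the root-to-leaf path), and is
#' compared against the evidence in units of a robust noise-scale estimate.
#' `crit_gamma` defaults to the asymptotic KS quantile at its level. Both
#' `crit_beta` and `crit_gamma` can be replaced by Monte-Carlo null
#' quantiles with [calibrate_thresholds()].
#'
#' `criterion1_mode` selects where each side's e.c.d.f. gap is evaluated:
#' `"child_level"` (default) at the corresponding child's block mean, or
#' `"literal"` at the parent's block mean. The literal form is provably
#' non-discriminative on equal halves (it yields `S_L == S_R` identically) and
#' is retained for auditability only.
#'
#' `descent_mode = "greedy"` always descends to a leaf and reports an
#' estimate (flagged non-significant when the final statistic is below
#' `crit_gamma`); `"strict"` stops and reports no estimate as soon as neither
#' criterion is decisive, or when the final statistic is non-significant.
#'
#' @param alpha,beta,gamma Significance levels in (0, 1); default 0.05 each.
#' @param crit_alpha Critical value of the criterion-1 statistic; defaults to
#'   the asymptotic KS quantile at `alpha`.
#' @param crit_beta Critical value of the criterion-2 evidence on the z
#'   scale, or `NA` (default) for the per-series depth-adjusted asymptotic
#'   quantile.
#' @param crit_gamma Critical value of the leaf statistic; defaults to the
#'   asymptotic KS quantile at `gamma`.
#' @param criterion1_mode `"child_level"` (default) or `"literal"`.
#' @param descent_mode `"greedy"` (default) or `"strict"`.
#' @param calibration_reps Number of null replicates for
#'   [calibrate_thresholds()]; at least 100.
#' @param calibration_seed RNG seed used by [calibrate_thresholds()].
#' @return An object of class `bstks_config`.
#' @export
detector_config <- function(alpha = 0.05, beta = 0.05, gamma = 0.05,
                            crit_alpha = ks_critical(alpha),
                            crit_beta = NA_real_,
                            crit_gamma = ks_critical(gamma),
                            criterion1_mode = c("child_level", "literal"),
                            descent_mode = c("greedy", "strict"),
                            calibration_reps = 1000L,
                            calibration_seed = 1L) {
  for (lv in c(alpha, beta, gamma)) {
    if (!is.numeric(lv) || lv <= 0 || lv >= 1) {
      stop("significance levels must lie strictly in (0, 1)", call. = FALSE)
    }
  }
  for (cv in c(crit_alpha, crit_gamma)) {
    if (is.na(cv) || cv < 0) {
      stop("crit_alpha and crit_gamma must be set and non-negative",
           call. = FALSE)
    }
  }
  if (!is.na(crit_beta) && crit_beta < 0) {
    stop("crit_beta must be non-negative (or NA for the depth-adjusted ",
         "default)", call. = FALSE)
  }
  if (calibration_reps < 100L) {
    stop("calibration_reps must be at least 100", call. = FALSE)
  }
  structure(
    list(alpha = alpha, beta = beta, gamma = gamma,
         crit_alpha = crit_alpha, crit_beta = crit_beta,
         crit_gamma = crit_gamma,
         criterion1_mode = match.arg(criterion1_mode),
         descent_mode = match.arg(descent_mode),
         calibration_reps = as.integer(calibration_reps),
         calibration_seed = as.integer(calibration_seed),
         calibrated = FALSE),
    class = "bstks_config"
  )
}

# Robust noise-scale estimate: median absolute successive difference,
# rescaled for Gaussian noise. Insensitive to a single mean shift (only one
# difference straddles it) and exactly zero for noiseless step series.
robust_sigma <- function(z) {
  stats::median(abs(diff(z))) / (sqrt(2) * stats::qnorm(0.75))
}

# Per-series resolution of the criterion-2 z-scale gate.
resolve_crit_beta <- function(config, M) {
  if (!is.na(config$crit_beta)) {
    return(config$crit_beta)
  }
  stats::qnorm(1 - config$beta / (2 * max(M - 1, 1)))
}

#' @export
print.bstks_config <- function(x, ...) {
  cat("<bstks_config>\n")
  cat(sprintf("  levels: alpha = %.3g, beta = %.3g, gamma = %.3g\n",
              x$alpha, x$beta, x$gamma))
  cat(sprintf("  critical values: C(alpha) = %.4f, C(beta) = %s, C(gamma) = %.4f%s\n",
              x$crit_alpha,
              if (is.na(x$crit_beta)) "auto (depth-adjusted)"
              else sprintf("%.4f", x$crit_beta),
              x$crit_gamma,
              if (x$calibrated) " [Monte-Carlo calibrated]" else " [asymptotic]"))
  cat(sprintf("  criterion1_mode = %s, descent_mode = %s\n",
              x$criterion1_mode, x$descent_mode))
  invisible(x)
}

#' Block mean at a coefficient-tree node
#'
#' Returns `2^(-k/2) * cA[k, j]`, which equals the arithmetic mean of the
#' samples `a..b` covered by the node.
#'
#' @param pyramid A `haar_pyramid`.
#' @param k,j Node level and within-level index.
#' @return The block mean (scalar).
#' @export
block_mean_level <- function(pyramid, k, j) {
  if (!inherits(pyramid, "haar_pyramid")) {
    stop("expected a 'haar_pyramid' object", call. = FALSE)
  }
  if (k < 1 || k > pyramid$M || j < 1 || j > pyramid$n / 2^k) {
    stop("invalid node (k, j) for this pyramid", call. = FALSE)
  }
  2^(-k / 2) * pyramid$cA[[k]][j]
}

# Scale factor of the per-node statistics: sqrt(n*m/(n+m)) with n = 2^k
# (parent block size) and m = 2^(k-1) (child block size) = sqrt(2^k / 3).
node_scale <- function(k) sqrt(2^k / 3)

#' Per-node e.c.d.f. statistic fluctuations (criterion 1)
#'
#' For the node `(k, j)` covering samples `a..b` with halves `a..c` (left
#' child) and `c+1..b` (right child), each side's statistic is the scaled gap
#' between the parent-block e.c.d.f. and that side's within-block e.c.d.f.:
#' `S = sqrt(nm/(n+m)) * |F_parent(x) - F_side(x)|` with `n = 2^k`,
#' `m = 2^(k-1)`. In `"child_level"` mode (default) each side is evaluated at
#' its own child's block mean; in `"literal"` mode both sides are evaluated at
#' the parent's block mean, which makes `S_L == S_R` identically (the parent
#' e.c.d.f. is the average of the two halves' e.c.d.f.s) — the documented
#' degeneracy that motivates the default.
#'
#' @param pyramid A `haar_pyramid`.
#' @param k,j Node level (`k >= 2`) and index.
#' @param mode `"child_level"` or `"literal"`.
#' @return Named numeric vector `c(S_L = , S_R = )`.
#' @export
criterion1_stats <- function(pyramid, k, j,
                             mode = c("child_level", "literal")) {
  mode <- match.arg(mode)
  if (k < 2) stop("criterion 1 is defined for levels k >= 2", call. = FALSE)
  nb <- block_bounds(k, j, pyramid$n)
  z <- pyramid$leaves
  parent <- z[nb$a:nb$b]
  left <- z[nb$a:nb$c]
  right <- z[(nb$c + 1):nb$b]
  fac <- node_scale(k)
  # Evaluation points are block means, computed directly from the samples:
  # identical to 2^(-k/2) * cA in exact arithmetic, but immune to the
  # floating-point knife-edge of evaluating an indicator at a value that
  # should equal a data point exactly.
  if (mode == "literal") {
    x <- mean(parent)
    s_l <- fac * abs(mean(parent <= x) - mean(left <= x))
    s_r <- fac * abs(mean(parent <= x) - mean(right <= x))
  } else {
    xl <- mean(left)
    xr <- mean(right)
    s_l <- fac * abs(mean(parent <= xl) - mean(left <= xl))
    s_r <- fac * abs(mean(parent <= xr) - mean(right <= xr))
  }
  c(S_L = s_l, S_R = s_r)
}

#' Per-node variance fluctuations and child contrasts (criterion 2)
#'
#' The literal variance-fluctuation statistics compare the parent's
#' normalised detail coefficient with each child's:
#' `D_X = sqrt(nm/(n+m)) * |N' * cD[k, j] - M' * cD_child_X|` with
#' `N' = 2^(-k/2)`, `M' = 2^(-(k-1)/2)`, `n = 2^k`, `m = 2^(k-1)`. The child
#' contrasts `|M' * cD_child_X|` measure each child's own internal mean
#' contrast (half the difference of its halves' means); they are what the
#' descent routes on, while the literal `D` values feed the `C(beta)`
#' significance gate (a noiseless step at three-eighths of the block is a
#' worked counterexample where the literal `D` ordering points at the
#' homogeneous half).
#'
#' @param pyramid A `haar_pyramid`.
#' @param k,j Node level (`k >= 2`) and index.
#' @return Named numeric vector
#'   `c(D_L = , D_R = , contrast_L = , contrast_R = )`.
#' @export
criterion2_stats <- function(pyramid, k, j) {
  if (k < 2) stop("criterion 2 is defined for levels k >= 2", call. = FALSE)
  if (k > pyramid$M || j < 1 || j > pyramid$n / 2^k) {
    stop("invalid node (k, j) for this pyramid", call. = FALSE)
  }
  fac <- node_scale(k)
  n_prime <- 2^(-k / 2)
  m_prime <- 2^(-(k - 1) / 2)
  cd_parent <- pyramid$cD[[k]][j]
  cd_left <- pyramid$cD[[k - 1]][2 * j - 1]
  cd_right <- pyramid$cD[[k - 1]][2 * j]
  c(D_L = fac * abs(n_prime * cd_parent - m_prime * cd_left),
    D_R = fac * abs(n_prime * cd_parent - m_prime * cd_right),
    contrast_L = abs(m_prime * cd_left),
    contrast_R = abs(m_prime * cd_right))
}

#' Leaf-level KS discrepancies (criterion 3)
#'
#' For the selected level-1 node `j` (leaves `2j-1` and `2j`), evaluates the
#' scaled global two-sample e.c.d.f. gap at the two candidate split points
#' `m = 2j-1` (evaluated at `z[2j-1]`) and `m = 2j` (at `z[2j]`), together
#' with the strict-inequality ("minus") variants that capture the gap just
#' before a jump of the step functions:
#' `D = sqrt(mn/(m+n)) * |F_m(x) - G_n(x)|` where `F_m` is the e.c.d.f. of
#' `z[1..m]` and `G_n` of `z[(m+1)..N]`. The side maxima are
#' `D_L' = max(D_L, D_L^-)` and `D_R' = max(D_R, D_R^-)`. The right candidate
#' is evaluated only when `2j <= N-1` (an empty right segment is excluded),
#' otherwise its entries are `NA`.
#'
#' @param x A [series()] or numeric vector (dyadic length not required here).
#' @param j Level-1 node index, `1 <= j <= N/2`.
#' @return List of class `leaf_stats` with `D_L`, `D_L_minus`, `D_R`,
#'   `D_R_minus`, `D_L_prime`, `D_R_prime`, `j`, `m_L`, `m_R`.
#' @export
leaf_stats <- function(x, j) {
  z <- series_values(x)
  N <- length(z)
  if (j < 1 || j > N / 2) {
    stop(sprintf("leaf node index j must be in 1..%d", N %/% 2L),
         call. = FALSE)
  }
  stat_at <- function(m, xval, strict) {
    n <- N - m
    f <- if (strict) mean(z[1:m] < xval) else mean(z[1:m] <= xval)
    g <- if (strict) mean(z[(m + 1):N] < xval) else mean(z[(m + 1):N] <= xval)
    sqrt(m * n / (m + n)) * abs(f - g)
  }
  m_l <- as.integer(2 * j - 1)
  d_l <- stat_at(m_l, z[m_l], strict = FALSE)
  d_l_minus <- stat_at(m_l, z[m_l], strict = TRUE)
  m_r <- as.integer(2 * j)
  if (m_r <= N - 1) {
    d_r <- stat_at(m_r, z[m_r], strict = FALSE)
    d_r_minus <- stat_at(m_r, z[m_r], strict = TRUE)
  } else {
    d_r <- d_r_minus <- NA_real_
    m_r <- NA_integer_
  }
  structure(
    list(D_L = d_l, D_L_minus = d_l_minus,
         D_R = d_r, D_R_minus = d_r_minus,
         D_L_prime = max(d_l, d_l_minus),
         D_R_prime = if (is.na(d_r)) NA_real_ else max(d_r, d_r_minus),
         j = as.integer(j), m_L = as.integer(m_l), m_R = m_r),
    class = "leaf_stats"
  )
}

#' Monte-Carlo calibration of the detector's critical values
#'
#' `C(alpha)` keeps the closed-form asymptotic KS quantile
#' [ks_critical()]`(alpha)`. `C(beta)` and `C(gamma)` are set to the
#' empirical `1 - beta` / `1 - gamma` quantiles of, respectively, the maximal
#' per-node criterion-2 evidence statistic along the search path (on the z
#' scale, i.e. divided by the series' robust noise-scale estimate) and the
#' final leaf-level statistic, over `calibration_reps` i.i.d. Gaussian null
#' series of length `N` with standard deviation `noise_sd`. Reproducible for
#' a fixed `calibration_seed`.
#'
#' @param config A [detector_config()].
#' @param N Series length the thresholds are calibrated for (power of two).
#' @param noise_sd Null noise standard deviation (default 1).
#' @return The config with `crit_beta`, `crit_gamma` replaced and
#'   `calibrated = TRUE`.
#' @export
calibrate_thresholds <- function(config, N, noise_sd = 1) {
  if (!inherits(config, "bstks_config")) {
    stop("expected a 'bstks_config' object", call. = FALSE)
  }
  if (!is_pow2(N) || N < 4) {
    stop("N must be a power of two >= 4", call. = FALSE)
  }
  reps <- config$calibration_reps
  null_cfg <- config
  null_cfg$descent_mode <- "greedy"
  max_ev <- numeric(reps)
  leaf_stat <- numeric(reps)
  set.seed(config$calibration_seed)
  for (r in seq_len(reps)) {
    z <- stats::rnorm(N, mean = 0, sd = noise_sd)
    res <- bstks_detect(z, null_cfg)
    max_ev[r] <- max(res$path$evidence) / res$sigma_hat
    leaf_stat[r] <- res$statistic
  }
  config$crit_beta <- unname(stats::quantile(max_ev, 1 - config$beta))
  config$crit_gamma <- unname(stats::quantile(leaf_stat, 1 - config$gamma))
  config$calibrated <- TRUE
  config
}

#' Coarse-to-fine change-point detection
#'
#' Runs the binary-tree search over the Haar coefficient pyramid of a series
#' of dyadic length. Starting at the root (level `M = log2(N)`), one child is
#' selected per level down to level 1:
#'
#' 1. **Criterion 1** — if one side's e.c.d.f. statistic strictly exceeds the
#'    other's *and* exceeds `C(alpha)`, that child is selected.
#' 2. **Criterion 2, child evidence** — otherwise, if one child's detail
#'    coefficient strictly exceeds the other's in magnitude and the larger
#'    exceeds the z-scale gate `C(beta) * sigma_hat` (with `sigma_hat` a
#'    robust noise-scale estimate from successive differences), the change
#'    boundary lies inside that child: it is selected. The ordering is
#'    identical to ordering the normalised child mean contrasts.
#' 3. **Criterion 2, midpoint evidence** — otherwise, if *both* literal
#'    variance fluctuations exceed the gate (the parent's own mean contrast
#'    is large but unexplained by either child), the boundary is the parent's
#'    own midpoint `c`; since `c` is the last sample of the left half, the
#'    left child is selected and the descent steers right thereafter.
#' 4. Otherwise, in `"strict"` mode the search stops with no estimate; in
#'    `"greedy"` mode (default) the descent steers toward the block edge
#'    shared with the most recently rejected sibling (initially left) — a
#'    block without internal evidence is only ever entered because the change
#'    lies at its boundary with that sibling.
#'
#' At the selected level-1 node, **criterion 3** picks the leaf with the
#' larger side maximum `D'` of the global KS discrepancies ([leaf_stats()]);
#' the estimate `e_cp` is the index of the last pre-change sample and the
#' detection is significant when the winning `D'` exceeds `C(gamma)`. In
#' greedy mode `e_cp` is reported even when non-significant (with
#' `significant = FALSE`); in strict mode a non-significant search returns no
#' estimate. The right-edge candidate `2j = N` is always excluded, so
#' `e_cp <= N - 1`.
#'
#' @param x A [series()] or numeric vector of power-of-two length `>= 4`
#'   (see [normalize_length()]).
#' @param config A [detector_config()].
#' @return An object of class `bstks_result`: list with `e_cp` (1-based index
#'   of the last pre-change sample, `NA` when none), `significant`,
#'   `statistic` (the winning leaf `D'`), `path` (data frame of per-level
#'   node statistics, decisions, and rules from the root down to level 2),
#'   `leaf` (the [leaf_stats()] of the selected node), `sigma_hat`, `offset`,
#'   `config`.
#' @examples
#' res <- bstks_detect(c(0, 0, 0, 1, 1, 1, 1, 1))
#' res$e_cp        # 3
#' res$statistic   # sqrt(15/8)
#' @export
bstks_detect <- function(x, config = detector_config()) {
  if (!inherits(config, "bstks_config")) {
    stop("expected a 'bstks_config' object", call. = FALSE)
  }
  if (is.na(config$crit_alpha) || is.na(config$crit_gamma)) {
    stop("detector thresholds are unset; supply them or run ",
         "calibrate_thresholds()", call. = FALSE)
  }
  z <- series_values(x)
  N <- length(z)
  if (N < 4L || !is_pow2(N)) {
    stop("series length must be a power of two >= 4; ",
         "run normalize_length() first", call. = FALSE)
  }
  pyr <- haar_decompose(z)
  M <- pyr$M
  greedy <- config$descent_mode == "greedy"
  sigma_hat <- robust_sigma(z)
  crit_beta <- resolve_crit_beta(config, M)
  gate <- crit_beta * sigma_hat

  n_steps <- M - 1L
  path <- data.frame(
    k = integer(n_steps), j = integer(n_steps),
    S_L = numeric(n_steps), S_R = numeric(n_steps),
    D_L = numeric(n_steps), D_R = numeric(n_steps),
    contrast_L = numeric(n_steps), contrast_R = numeric(n_steps),
    evidence = numeric(n_steps),
    chosen = character(n_steps), rule = character(n_steps),
    stringsAsFactors = FALSE
  )

  j <- 1L
  tie_dir <- "left"
  seen_evidence <- FALSE
  step <- 0L
  for (k in seq(M, 2L)) {
    step <- step + 1L
    s <- criterion1_stats(pyr, k, j, mode = config$criterion1_mode)
    d <- criterion2_stats(pyr, k, j)
    # Children's raw detail coefficients: |N(0, sigma)| under within-block
    # homogeneity; same ordering as the normalised child contrasts.
    b_l <- d[["contrast_L"]] * 2^((k - 1) / 2)
    b_r <- d[["contrast_R"]] * 2^((k - 1) / 2)
    min_d <- min(d[["D_L"]], d[["D_R"]])
    evidence <- max(b_l, b_r, min_d)
    chosen <- NA_character_
    rule <- NA_character_
    pure_tie <- FALSE
    if (s[["S_L"]] != s[["S_R"]] && max(s) > config$crit_alpha) {
      chosen <- if (s[["S_L"]] > s[["S_R"]]) "left" else "right"
      rule <- "criterion1"
      seen_evidence <- TRUE
    } else if (b_l != b_r && max(b_l, b_r) > gate) {
      chosen <- if (b_l > b_r) "left" else "right"
      rule <- "criterion2"
      seen_evidence <- TRUE
    } else if (min_d > gate) {
      # Parent-midpoint heterogeneity unexplained by either child: the
      # boundary is this node's own split point c, the last sample of the
      # left half.
      chosen <- "left"
      rule <- "criterion2_midpoint"
      seen_evidence <- TRUE
    } else if (!greedy) {
      path[step, c("k", "j")] <- list(k, j)
      path[step, c("S_L", "S_R")] <- as.list(unname(s))
      path[step, c("D_L", "D_R", "contrast_L", "contrast_R")] <-
        as.list(unname(d))
      path[step, "evidence"] <- evidence
      path[step, c("chosen", "rule")] <- list("none", "stopped")
      return(new_bstks_result(NA_integer_, FALSE, NA_real_,
                              path[seq_len(step), ], NULL, sigma_hat, x,
                              config))
    } else {
      rule <- "greedy_fallback"
      if (seen_evidence) {
        # Some ancestor located the boundary at an edge of this block:
        # steer toward it.
        chosen <- tie_dir
        pure_tie <- TRUE
      } else if (b_l != b_r) {
        # No evidence anywhere yet, so no inherited boundary: follow the
        # strongest available ordering.
        chosen <- if (b_l > b_r) "left" else "right"
      } else if (s[["S_L"]] != s[["S_R"]]) {
        chosen <- if (s[["S_L"]] > s[["S_R"]]) "left" else "right"
      } else {
        chosen <- tie_dir
        pure_tie <- TRUE
      }
    }
    if (!pure_tie) {
      tie_dir <- if (chosen == "left") "right" else "left"
    }
    path[step, c("k", "j")] <- list(k, j)
    path[step, c("S_L", "S_R")] <- as.list(unname(s))
    path[step, c("D_L", "D_R", "contrast_L", "contrast_R")] <-
      as.list(unname(d))
    path[step, "evidence"] <- evidence
    path[step, c("chosen", "rule")] <- list(chosen, rule)
    j <- if (chosen == "left") 2L * j - 1L else 2L * j
  }

  leaf <- leaf_stats(z, j)
  if (is.na(leaf$D_R_prime) || leaf$D_L_prime >= leaf$D_R_prime) {
    e_cp <- leaf$m_L
    statistic <- leaf$D_L_prime
  } else {
    e_cp <- leaf$m_R
    statistic <- leaf$D_R_prime
  }
  significant <- is.finite(statistic) && statistic > config$crit_gamma
  if (!greedy && !significant) {
    e_cp <- NA_integer_
  }
  new_bstks_result(e_cp, significant, statistic, path, leaf, sigma_hat, x,
                   config)
}

new_bstks_result <- function(e_cp, significant, statistic, path, leaf,
                             sigma_hat, x, config) {
  structure(
    list(e_cp = e_cp, significant = significant, statistic = statistic,
         path = path, leaf = leaf, sigma_hat = sigma_hat,
         n = length(series_values(x)), offset = series_offset(x),
         series_name = if (inherits(x, "bstks_series")) x$name else "series",
         config = config),
    class = "bstks_result"
  )
}

#' @export
print.bstks_result <- function(x, ...) {
  cat(sprintf("<bstks_result> '%s' (N = %d)\n", x$series_name, x$n))
  if (is.na(x$e_cp)) {
    cat("  no abrupt change detected\n")
  } else {
    cat(sprintf("  estimated change point: %d (last pre-change sample%s)\n",
                x$e_cp + x$offset,
                if (x$offset != 0) ", original coordinates" else ""))
    cat(sprintf("  statistic = %.4f, significant = %s (C(gamma) = %.4f)\n",
                x$statistic, x$significant, x$config$crit_gamma))
  }
  invisible(x)
}
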