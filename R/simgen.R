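#' Specification of a single mean-shift simulation
#'
#' Describes one synthetic series: `cp` i.i.d. Gaussian samples with mean
#' `noise_mean`, followed by `N - cp` samples with the mean shifted up by `v`
#' (in units of the noise standard deviation when `noise_sd = 1`). `cp` is
#' the index of the last pre-change sample.
#'
#' @param N Power-of-two series length.
#' @param cp True change point, `1 <= cp <= N-1`.
#' @param v Shift magnitude, `>= 0`.
#' @param noise_sd,noise_mean Gaussian noise parameters (defaults 1 and 0).
#' @param seed Integer RNG seed.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(N, cp, v, noise_sd = 1, noise_mean = 0,
                            seed = 1L) {
  N <- as.integer(N)
  cp <- as.integer(cp)
  if (!is_pow2(N) || N < 4L) stop("N must be a power of two >= 4",
                                  call. = FALSE)
  if (cp < 1L || cp > N - 1L) stop("cp must satisfy 1 <= cp <= N-1",
                                   call. = FALSE)
  if (v < 0) stop("shift magnitude v must be non-negative", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  structure(list(N = N, cp = cp, v = v, noise_sd = noise_sd,
                 noise_mean = noise_mean, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Draw one mean-shift series
#'
#' Samples `1..cp` are `Normal(noise_mean, noise_sd^2)`; samples `cp+1..N`
#' have their mean shifted by `+v`. Reproducible per seed.
#'
#' @param spec A [simulation_spec()].
#' @return A `bstks_series` with `origin = "synthetic"`.
#' @examples
#' s <- make_sample(simulation_spec(N = 32, cp = 8, v = 3, seed = 7))
#' @export
make_sample <- function(spec) {
  if (!inherits(spec, "simulation_spec")) {
    stop("expected a 'simulation_spec' object", call. = FALSE)
  }
  set.seed(spec$seed)
  z <- stats::rnorm(spec$N, mean = spec$noise_mean, sd = spec$noise_sd)
  if (spec$cp < spec$N) {
    post <- (spec$cp + 1L):spec$N
    z[post] <- z[post] + spec$v
  }
  series(z, name = sprintf("sim-N%d-cp%d-v%g-seed%d",
                           spec$N, spec$cp, spec$v, spec$seed),
         origin = "synthetic")
}

#' Benchmark design over dyadic series-length groups
#'
#' Group `i` (of `1..7`) uses series length `N_i = 2^(4+i)`, shift
#' `v_i = d * (1 + log2(k - 4))` with `k = log2(N_i)`, and 15 candidate test
#' positions `CPK_j = j * 2^(k-4)`, `j = 1..15`, each replicated `reps` times
#' with deterministic per-condition seeds so any single cell can be
#' regenerated in isolation.
#'
#' @param groups Subset of `1:7`.
#' @param d Shift scale.
#' @param reps Replicates per (group, position) condition, `>= 1`.
#' @param positions Subset of `1:15` selecting the test positions `CPK_j`.
#' @param noise_sd Noise standard deviation (default 1).
#' @param base_seed Integer base seed; all per-run seeds derive from it.
#' @param methods Character subset of `c("bstks", "ks", "t", "ssa")`.
#' @return An object of class `benchmark_spec`.
#' @export
benchmark_spec <- function(groups = 1:7, d = 1.0, reps = 200L,
                           positions = 1:15, noise_sd = 1,
                           base_seed = 1L, methods = "bstks") {
  groups <- as.integer(groups)
  if (length(groups) == 0L || any(groups < 1L | groups > 7L)) {
    stop("groups must be a non-empty subset of 1..7", call. = FALSE)
  }
  positions <- as.integer(positions)
  if (length(positions) == 0L || any(positions < 1L | positions > 15L)) {
    stop("positions must be a non-empty subset of 1..15", call. = FALSE)
  }
  if (reps < 1L) stop("reps must be at least 1", call. = FALSE)
  if (d < 0) stop("shift scale d must be non-negative", call. = FALSE)
  methods <- match.arg(methods, c("bstks", "ks", "t", "ssa"),
                       several.ok = TRUE)
  structure(list(groups = groups, d = d, reps = as.integer(reps),
                 positions = positions, noise_sd = noise_sd,
                 base_seed = as.integer(base_seed), methods = methods),
            class = "benchmark_spec")
}

# Deterministic per-run seed; injective over i in 1..7, j in 1..15,
# rep in 1..1030, and bounded well below 2^31. Null (v = 0) companion runs
# for ROC analysis get a disjoint block.
derive_seed <- function(base_seed, i, j, rep, null = FALSE) {
  s <- (abs(as.numeric(base_seed)) %% 1e6) +
    ((i * 31 + j) * 1031 + rep) * 7 +
    if (null) 2^29 else 0
  as.integer(s)
}

#' Expand a benchmark design into per-run simulation parameters
#'
#' One row per (group, position, replicate) with the derived length `N_i`,
#' shift `v_i`, true change point `CPK_j`, and a distinct deterministic seed.
#'
#' @param spec A [benchmark_spec()].
#' @return A data frame with columns `group`, `N`, `v`, `position`, `cp`,
#'   `rep`, `seed`, `noise_sd`; each row parameterises one
#'   [simulation_spec()].
#' @examples
#' head(expand_benchmark(benchmark_spec(groups = 1, d = 3, reps = 2)))
#' @export
expand_benchmark <- function(spec) {
  if (!inherits(spec, "benchmark_spec")) {
    stop("expected a 'benchmark_spec' object", call. = FALSE)
  }
  rows <- expand.grid(rep = seq_len(spec$reps), position = spec$positions,
                      group = spec$groups)
  N <- 2L^(4L + rows$group)
  out <- data.frame(
    group = rows$group,
    N = N,
    v = spec$d * (1 + log2(log2(N) - 4)),
    position = rows$position,
    cp = as.integer(rows$position * 2^rows$group),
    rep = rows$rep,
    seed = mapply(derive_seed, spec$base_seed, rows$group, rows$position,
                  rows$rep),
    noise_sd = spec$noise_sd
  )
  out[order(out$group, out$position, out$rep), , drop = FALSE]
}

#' Concatenate two distributional regimes
#'
#' Builds a series whose first `cp` samples follow regime A and whose
#' remainder follows regime B, each regime a Gaussian or AR(1) process
#' described by `list(mean =, sd =, phi =)` (`phi = 0`, the default, gives
#' i.i.d. Gaussian; `|phi| < 1` gives a stationary AR(1) with marginal
#' standard deviation `sd`). A synthetic stand-in for recordings assembled
#' from two regimes differing in level, scale, or autocorrelation; no claim
#' of physiological fidelity.
#'
#' @param regime_a,regime_b Lists with elements `mean` (default 0),
#'   `sd` (default 1), `phi` (default 0).
#' @param N Series length.
#' @param cp Last index drawn from regime A, `1 <= cp <= N-1`.
#' @param seed Integer RNG seed.
#' @return A `bstks_series` with `origin = "synthetic"`.
#' @export
assemble_pair <- function(regime_a, regime_b, N, cp, seed = 1L) {
  N <- as.integer(N)
  cp <- as.integer(cp)
  if (cp < 1L || cp > N - 1L) stop("cp must satisfy 1 <= cp <= N-1",
                                   call. = FALSE)
  draw <- function(par, n) {
    mean <- if (is.null(par$mean)) 0 else par$mean
    sd <- if (is.null(par$sd)) 1 else par$sd
    phi <- if (is.null(par$phi)) 0 else par$phi
    if (abs(phi) >= 1) stop("AR coefficient must satisfy |phi| < 1",
                            call. = FALSE)
    if (phi == 0) {
      return(stats::rnorm(n, mean, sd))
    }
    innov <- stats::rnorm(n, 0, sd * sqrt(1 - phi^2))
    e <- as.numeric(stats::filter(innov, phi, method = "recursive",
                                  init = stats::rnorm(1, 0, sd)))
    mean + e
  }
  set.seed(as.integer(seed))
  z <- c(draw(regime_a, cp), draw(regime_b, N - cp))
  series(z, name = sprintf("assembled-N%d-cp%d-seed%d", N, cp, seed),
         origin = "synthetic")
}
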