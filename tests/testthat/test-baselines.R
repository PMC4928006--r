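test_that("two-sample KS statistic agrees with the brute-force oracle", {
  expect_equal(two_sample_ks(c(0, 0, 0), c(1, 1, 1, 1, 1)), sqrt(15 / 8),
               tolerance = 1e-12)
  x <- rnorm(10)
  expect_equal(two_sample_ks(x, x), 0)

  set.seed(31)
  for (r in 1:100) {
    m <- sample(2:12, 1)
    n <- sample(2:12, 1)
    x <- round(rnorm(m), 1)  # rounding forces ties across samples
    y <- round(rnorm(n), 1)
    expect_equal(two_sample_ks(x, y), brute_ks(x, y), tolerance = 1e-12)
  }
  expect_error(two_sample_ks(numeric(0), 1), "non-empty")
})

test_that("KS scan profile equals the per-split statistic and is shift invariant", {
  r <- ks_scan(c(0, 0, 0, 1, 1, 1, 1, 1))
  expect_identical(r$e_cp, 3L)
  expect_equal(r$statistic, sqrt(15 / 8), tolerance = 1e-12)
  expect_equal(r$profile[4], sqrt(2) * 0.75, tolerance = 1e-12)

  expect_equal(ks_scan(rep(2, 8))$profile, rep(0, 7))

  set.seed(37)
  z <- rnorm(32)
  rz <- ks_scan(z)
  for (m in c(1, 7, 16, 31)) {
    expect_equal(rz$profile[m], two_sample_ks(z[1:m], z[(m + 1):32]),
                 tolerance = 1e-12)
  }
  expect_equal(ks_scan(z + 100)$profile, rz$profile, tolerance = 1e-9)
  expect_error(ks_scan(rnorm(3)), "too short")
})

test_that("Welch-t scan matches the closed form and survives zero variance", {
  z <- c(1, 2, 3, 10, 11, 12, 13, 14)
  r <- t_scan(z)
  welch <- function(m) {
    abs(mean(z[1:m]) - mean(z[(m + 1):8])) /
      sqrt(var(z[1:m]) / m + var(z[(m + 1):8]) / (8 - m))
  }
  expect_equal(r$profile, vapply(2:6, welch, numeric(1)), tolerance = 1e-12)
  expect_identical(r$e_cp, 3L)
  # the printed-style toy: t = (2 - 11)/sqrt(1/3 + 1/3)
  zt <- c(1, 2, 3, 10, 11, 12)
  t3 <- (mean(zt[1:3]) - mean(zt[4:6])) /
    sqrt(var(zt[1:3]) / 3 + var(zt[4:6]) / 3)
  expect_equal(t3, -11.0227, tolerance = 1e-4)

  # two identical halves: t = 0 at the midpoint
  zh <- c(1, 2, 3, 4, 1, 2, 3, 4)
  expect_equal(t_scan(zh)$profile[3], 0)

  # zero variance on both sides yields an undefined marker, not a crash
  rd <- t_scan(c(0, 0, 0, 0, 1, 1, 1, 1))
  expect_true(is.na(rd$profile[3]))     # split m = 4
  expect_false(is.na(rd$e_cp))
  # fully degenerate profile: no estimate
  expect_true(is.na(t_scan(rep(1, 8))$e_cp))
  expect_error(t_scan(rnorm(4)), "too short")
})

test_that("SSA trajectory matrices are Hankel with the index formula", {
  cfg <- ssa_config(24, m = 4)
  expect_equal(ssa_trajectory(1:6, 0, cfg), rbind(1:3, 2:4))
  expect_true(all(ssa_trajectory(rep(3, 24), 5, cfg) == 3))

  set.seed(41)
  z <- rnorm(64)
  cfg2 <- ssa_config(64, m = 8)
  X <- ssa_trajectory(z, 10, cfg2)
  for (i in 1:(nrow(X) - 1)) {
    for (h in 1:(ncol(X) - 1)) {
      expect_identical(X[i + 1, h], X[i, h + 1])
    }
  }
  expect_error(ssa_trajectory(1:6, 4, cfg), "overruns")
  expect_error(ssa_config(24, m = 5), "even")
})

test_that("SSA detection profile behaves as a subspace distance", {
  # constant series: base subspace contains the constant direction
  rc <- ssa_detect(rep(2, 64), ssa_config(64, m = 8))
  expect_equal(max(rc$profile), 0)
  # full subspace: distances vanish identically
  s <- make_sample(simulation_spec(256, 64, 3, seed = 1))
  cfg <- ssa_config(256, m = 32, l = 16)
  expect_lt(max(ssa_detect(s, cfg)$profile), 1e-20)
  # non-negativity
  r <- ssa_detect(s)
  expect_true(all(r$profile >= 0))
  expect_error(ssa_detect(rnorm(16), ssa_config(16, m = 8)), "too short")
})

test_that("SSA localises a strong mean shift within one window width", {
  hits <- vapply(1:100, function(r) {
    s <- make_sample(simulation_spec(512, 256, 3, seed = 5000 + r))
    ssa_detect(s, ssa_config(512, m = 64))$e_cp
  }, integer(1))
  expect_gte(mean(abs(hits - 256) <= 64), 0.9)
})

test_that("all detectors agree on noiseless step series", {
  # The split at exactly p has zero variance on both sides, which the Welch
  # scan marks undefined; its argmax is therefore the adjacent split.
  N <- 32
  for (p in c(3, 8, 13, 16, 21, 29)) {
    z <- step_series(N, p)
    expect_identical(bstks_detect(z)$e_cp, ks_scan(z)$e_cp)
    if (p >= 3 && p <= N - 3) {
      expect_lte(abs(t_scan(z)$e_cp - p), 1)
    }
  }
})
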