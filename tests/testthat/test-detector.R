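test_that("asymptotic KS critical value is correct and monotone", {
  expect_equal(ks_critical(0.05), sqrt(-log(0.025) / 2), tolerance = 1e-12)
  expect_equal(ks_critical(0.05), 1.3581, tolerance = 1e-4)
  expect_lt(ks_critical(0.10), ks_critical(0.05))
  expect_error(ks_critical(0), "strictly in")
  expect_error(ks_critical(1.2), "strictly in")
})

test_that("criterion-1 statistics match the e.c.d.f. counting oracle", {
  p <- haar_decompose(c(3, 1, 0, 0))
  s <- criterion1_stats(p, 2, 1)
  # oracle: parent [3,1,0,0], left [3,1] evaluated at its mean 2,
  # right [0,0] at its mean 0; scale sqrt(2^2/3)
  fac <- sqrt(4 / 3)
  expect_equal(unname(s[1]), fac * abs(3 / 4 - 1 / 2), tolerance = 1e-12)
  expect_equal(unname(s[2]), fac * abs(2 / 4 - 1), tolerance = 1e-12)
  expect_equal(unname(s), c(0.2886751, 0.5773503), tolerance = 1e-6)

  # constant series: all indicators agree
  pc <- haar_decompose(rep(4, 8))
  expect_equal(unname(criterion1_stats(pc, 3, 1)), c(0, 0))

  # literal mode evaluates both sides at the parent mean
  pl <- haar_decompose(c(5, 0, 0, 0))
  sl <- criterion1_stats(pl, 2, 1, mode = "literal")
  expect_equal(unname(sl), c(0.2886751, 0.2886751), tolerance = 1e-6)

  expect_error(criterion1_stats(p, 1, 1), "k >= 2")
})

test_that("literal-mode degeneracy: S_L equals S_R at every node", {
  # The parent e.c.d.f. is the average of the two halves' e.c.d.f.s, so the
  # literal form cannot discriminate between children; this motivates the
  # child_level default.
  set.seed(19)
  for (r in 1:100) {
    p <- haar_decompose(rnorm(64))
    for (k in 2:6) {
      for (j in seq_len(64 / 2^k)) {
        s <- criterion1_stats(p, k, j, mode = "literal")
        expect_identical(unname(s[1]), unname(s[2]))
      }
    }
  }
})

test_that("criterion-2 statistics match the block-sum oracle", {
  p <- haar_decompose(c(0, 0, 0, 1, 1, 1, 1, 1))
  d <- criterion2_stats(p, 3, 1)
  fac <- sqrt(8 / 3)
  expect_equal(unname(d["D_L"]), fac * abs(-0.375 - (-0.25)),
               tolerance = 1e-12)
  expect_equal(unname(d["D_R"]), fac * abs(-0.375 - 0), tolerance = 1e-12)
  expect_equal(unname(d["contrast_L"]), 0.25, tolerance = 1e-12)
  expect_equal(unname(d["contrast_R"]), 0, tolerance = 1e-12)

  pc <- haar_decompose(rep(2, 8))
  expect_equal(unname(criterion2_stats(pc, 3, 1)), rep(0, 4))
  expect_error(criterion2_stats(p, 1, 1), "k >= 2")
})

test_that("leaf statistics evaluate the global split candidates", {
  z <- c(0, 0, 0, 1, 1, 1, 1, 1)
  ls <- leaf_stats(z, 2)
  expect_equal(ls$D_L, sqrt(15 / 8), tolerance = 1e-12)
  expect_equal(ls$D_L_minus, 0)
  expect_equal(ls$D_R, 0)
  expect_equal(ls$D_R_minus, sqrt(2) * 0.75, tolerance = 1e-12)
  expect_equal(ls$D_L_prime, max(ls$D_L, ls$D_L_minus))
  expect_gt(ls$D_L_prime, ls$D_R_prime)

  z2 <- c(0, 0, 0, 0, 1, 1, 1, 1)
  ls2 <- leaf_stats(z2, 2)
  expect_equal(ls2$D_R_prime, sqrt(2), tolerance = 1e-12)
  expect_gt(ls2$D_R_prime, ls2$D_L_prime)

  # constant series: everything zero
  lsc <- leaf_stats(rep(1, 8), 3)
  expect_equal(c(lsc$D_L, lsc$D_L_minus, lsc$D_R, lsc$D_R_minus),
               rep(0, 4))

  # right-edge candidate 2j = N excluded
  lse <- leaf_stats(z, 4)
  expect_true(is.na(lse$D_R_prime))

  expect_error(leaf_stats(z, 5), "j must be in")
})

test_that("detection on worked step series matches hand computation", {
  r1 <- bstks_detect(c(0, 0, 0, 1, 1, 1, 1, 1))
  expect_identical(r1$e_cp, 3L)
  expect_equal(r1$statistic, sqrt(15 / 8), tolerance = 1e-12)
  expect_true(r1$significant)

  r2 <- bstks_detect(c(0, 0, 0, 0, 1, 1, 1, 1))
  expect_identical(r2$e_cp, 4L)
  expect_equal(r2$statistic, sqrt(2), tolerance = 1e-12)
})

test_that("path structure and degenerate inputs behave as documented", {
  r <- bstks_detect(rnorm(64))
  expect_identical(nrow(r$path), 5L)           # log2(64) - 1 decisions
  expect_identical(r$path$k, 6:2)
  expect_true(all(r$path$chosen %in% c("left", "right")))
  expect_true(all(c(r$path$S_L, r$path$S_R, r$path$D_L, r$path$D_R) >= 0))

  # constant series: greedy flags non-significance, strict returns no e_cp
  cst <- rep(5, 16)
  rg <- bstks_detect(cst)
  expect_false(rg$significant)
  rs <- bstks_detect(cst, detector_config(descent_mode = "strict"))
  expect_true(is.na(rs$e_cp))
  expect_false(rs$significant)

  expect_error(bstks_detect(rnorm(12)), "power of two")
  expect_error(bstks_detect(rnorm(16), config = list()), "bstks_config")
})

test_that("noiseless routing descends into the block containing the jump", {
  # For a jump at p not equal to any visited block midpoint, each decision
  # selects the child whose block contains p.
  N <- 32
  for (p in 1:(N - 1)) {
    z <- step_series(N, p)
    r <- bstks_detect(z)
    j <- 1L
    for (step in seq_len(nrow(r$path))) {
      k <- r$path$k[step]
      nb <- block_bounds(k, j, N)
      if (p != nb$c) {
        inside_left <- p >= nb$a && p < nb$c
        inside_right <- p > nb$c && p < nb$b
        if (inside_left) expect_identical(r$path$chosen[step], "left")
        if (inside_right) expect_identical(r$path$chosen[step], "right")
      }
      j <- if (r$path$chosen[step] == "left") 2L * j - 1L else 2L * j
    }
  }
})

test_that("node statistics are shift invariant and D scales linearly", {
  set.seed(23)
  z <- rnorm(32)
  p0 <- haar_decompose(z)
  p_shift <- haar_decompose(z + 17.3)
  p_scale <- haar_decompose(z * 2.5)
  for (k in 2:5) {
    for (j in seq_len(32 / 2^k)) {
      expect_equal(criterion1_stats(p0, k, j), criterion1_stats(p_shift, k, j),
                   tolerance = 1e-9)
      d0 <- criterion2_stats(p0, k, j)
      expect_equal(d0, criterion2_stats(p_shift, k, j), tolerance = 1e-9)
      expect_equal(2.5 * d0, criterion2_stats(p_scale, k, j),
                   tolerance = 1e-9)
    }
  }
  # decisions are therefore shift and scale invariant
  expect_identical(bstks_detect(z)$e_cp, bstks_detect(z + 17.3)$e_cp)
  expect_identical(bstks_detect(z)$e_cp, bstks_detect(z * 2.5)$e_cp)
})

test_that("threshold calibration is reproducible and orders sensibly", {
  cfg <- detector_config(calibration_reps = 100L, calibration_seed = 9L)
  c1 <- calibrate_thresholds(cfg, 64)
  c2 <- calibrate_thresholds(cfg, 64)
  expect_identical(c1$crit_beta, c2$crit_beta)
  expect_identical(c1$crit_gamma, c2$crit_gamma)
  expect_true(c1$calibrated)
  expect_gt(c1$crit_beta, 0)
  expect_gt(c1$crit_gamma, 0)
  # stricter level gives a larger critical value
  c_strict <- calibrate_thresholds(
    detector_config(beta = 0.01, gamma = 0.01, calibration_reps = 100L,
                    calibration_seed = 9L), 64)
  expect_gt(c_strict$crit_beta, c1$crit_beta)
  expect_gte(c_strict$crit_gamma, c1$crit_gamma)

  expect_error(detector_config(calibration_reps = 10L), "at least 100")
  expect_error(detector_config(alpha = 1.5), "strictly in")
})

test_that("a strong mean shift in noise is localised with median error zero", {
  ests <- vapply(1:200, function(r) {
    s <- make_sample(simulation_spec(256, 64, 3, seed = 7000 + r))
    bstks_detect(s)$e_cp
  }, integer(1))
  expect_equal(error_stat(ests, 64), 0)
  # concentration: the bulk of estimates lies within two samples of the truth
  expect_gt(mean(abs(ests - 64) <= 2), 0.85)
  expect_gt(hit_rate(ests, 64), 0.15)
})
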