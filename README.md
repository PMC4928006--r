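# bstks

Fast single change-point detection in univariate time series by a
coarse-to-fine binary search over Haar wavelet coefficient trees, driven by
a modified two-sample Kolmogorov–Smirnov (KS) statistic ("BSTKS"). Built for
long biomedical recordings (EEG-like signals) where an exhaustive KS scan
over all N−1 splits is too slow, but equally applicable to any univariate
series with a suspected abrupt mean/distribution shift.

## Method in brief

For a series *Z* = {z₁…z_N} of dyadic length N = 2^M, the orthonormal Haar
transform gives per-level approximation and detail coefficients

    cA_{k,j} = 2^(−k/2) Σ_{i=a..b} z_i
    cD_{k,j} = 2^(−k/2) (Σ_{i=a..c} z_i − Σ_{i=c+1..b} z_i)

over blocks a..b (a = 2^k(j−1)+1, c = a−1+2^(k−1), b = 2^k j), forming two
implicit binary trees. The detector descends from the root to a leaf pair in
~log₂N steps, choosing one child per level by three criteria:

1. a scaled empirical-c.d.f. discrepancy between the parent block and each
   child, √(nm/(n+m))·|F_parent(x) − F_child(x)| (n = 2^k, m = 2^(k−1)),
   gated by the asymptotic KS critical value C(α) = √(−ln(α/2)/2);
2. variance-fluctuation evidence from the detail coefficients, which are
   N(0, σ²) under within-block homogeneity, gated on the z scale by
   C(β)·σ̂ (σ̂ a robust noise-scale estimate) — a loud child pulls the
   descent inside it, a loud parent contrast with quiet children marks the
   parent's own midpoint;
3. a leaf-level global KS evaluation D′ at the two candidate splits, whose
   winner is the estimated change point (the last pre-change sample) and
   whose magnitude against C(γ) decides significance.

The package also ships the three classical comparators (exhaustive KS scan,
Welch-t scan, sequential SSA subspace tracking), a fully seeded synthetic
benchmark generator (Gaussian mean-shift design and two-regime
concatenations), and evaluation metrics (exact hit rate, median-location
error, accuracy = 1 − error/N, rank-based AUC, segment e.c.d.f. distance).

## Worked example

```r
library(bstks)

s <- make_sample(simulation_spec(N = 256, cp = 64, v = 2, seed = 42))
bstks_detect(s)
#> <bstks_result> 'sim-N256-cp64-v2-seed42' (N = 256)
#>   estimated change point: 65 (last pre-change sample)
#>   statistic = 4.1789, significant = TRUE (C(gamma) = 1.3581)

ks_scan(s)
#> <cp_scan> method = ks
#>   estimated change point: 63, statistic = 5.1171
```

The true change is after sample 64 (first 64 samples ~ N(0,1), remainder
~ N(2,1)); the tree search lands one sample to its right in ~log₂N
decisions, the exhaustive scan one sample to its left in 255 split
evaluations. The `statistic` is the winning scaled KS discrepancy, compared
against the γ-level critical value for the significance call.

A small slice of the simulation benchmark:

```r
run_benchmark(benchmark_spec(groups = 1, d = 3, reps = 50,
                             positions = c(4, 8, 12), base_seed = 1))
#> <bstks_benchmark> d = 3, groups {1}, 50 reps x 3 positions
#> per-group means:
#>  method group  N d hit_rate  error accuracy auc mean_time
#>   bstks     1 32 3   0.4333 0.6667   0.9792 NaN   0.00164
```

Here `hit_rate` is the fraction of exactly recovered indices, `error` the
absolute deviation of the median estimate from the truth (in samples,
averaged over the three positions), and `accuracy = 1 − error/N`. AUC is
only computed when `compute_auc = TRUE` (it doubles the run count with
matched null series).

## Command line

A thin launcher is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "bstks.R", package = "bstks"))')" \
    detect --input x.csv --method bstks
```

Subcommands: `detect`, `simulate`, `benchmark`, `calibrate`; every run
logs the resolved thresholds and mode flags to stderr, and all randomness
is controlled by `--seed`.

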