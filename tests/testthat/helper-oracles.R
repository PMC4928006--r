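# Independent brute-force oracles used to freeze expected values.

# O(m*n*(m+n)) two-sample KS: evaluate both e.c.d.f.s at every pooled point.
brute_ks <- function(x, y) {
  m <- length(x)
  n <- length(y)
  gaps <- vapply(c(x, y), function(v) {
    abs(mean(x <= v) - mean(y <= v))
  }, numeric(1))
  sqrt(m * n / (m + n)) * max(gaps)
}

# Direct per-node Haar coefficients from scaled block sums, term by term.
haar_direct <- function(z, k, j) {
  a <- 2^k * (j - 1) + 1
  c <- 2^k * (j - 1) + 2^(k - 1)
  b <- 2^k * j
  list(cA = 2^(-k / 2) * sum(z[a:b]),
       cD = 2^(-k / 2) * (sum(z[a:c]) - sum(z[(c + 1):b])))
}

# Step series: p low samples then N - p high samples.
step_series <- function(N, p, low = 0, high = 1) {
  c(rep(low, p), rep(high, N - p))
}

random_dyadic_series <- function(n) {
  stats::rnorm(n)
}
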