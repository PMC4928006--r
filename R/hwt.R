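#' Multilevel Haar wavelet decomposition
#'
#' Decomposes a series of dyadic length `N = 2^M` into `M` levels of
#' orthonormal Haar approximation (`cA`) and detail (`cD`) coefficients.
#' With 1-based inclusive block bounds `a = 2^k*(j-1)+1`,
#' `c = 2^k*(j-1)+2^(k-1)`, `b = 2^k*j`, the level-`k` coefficients are
#'
#' \deqn{cA_{k,j} = 2^{-k/2} \sum_{i=a}^{b} z_i, \qquad
#'       cD_{k,j} = 2^{-k/2}\Big(\sum_{i=a}^{c} z_i - \sum_{i=c+1}^{b} z_i\Big).}
#'
#' The orthonormal scaling makes the transform energy preserving (Parseval):
#' `sum(z^2) == sum(cA[[M]]^2) + sum over k of sum(cD[[k]]^2)`, and
#' `2^(-k/2) * cA[k,j]` equals the arithmetic mean of the block `a..b`.
#'
#' The per-level coefficient vectors are the node values of two implicit
#' binary trees (one over `cA`, one over `cD`): the node at `(k, j)` covers
#' samples `a..b` and its children are `(k-1, 2j-1)` and `(k-1, 2j)`.
#'
#' @param x A [series()] or numeric vector of length `2^M >= 4`.
#' @return An object of class `haar_pyramid`: list with `n`, `M`,
#'   `cA` (list of per-level vectors, level `k` has `n/2^k` entries),
#'   `cD` (same shapes), and `leaves` (the original samples).
#' @seealso [haar_reconstruct()], [block_bounds()]
#' @examples
#' p <- haar_decompose(c(1, 1, 1, 1))
#' p$cA[[2]]  # 2: the scaled total sum
#' @export
haar_decompose <- function(x) {
  z <- series_values(x)
  n <- length(z)
  if (n < 4L || !is_pow2(n)) {
    stop("haar_decompose() needs a series of power-of-two length >= 4 ",
         "(see normalize_length())", call. = FALSE)
  }
  M <- as.integer(round(log2(n)))
  cA <- vector("list", M)
  cD <- vector("list", M)
  prev <- z
  for (k in seq_len(M)) {
    odd <- prev[seq(1L, length(prev), by = 2L)]
    even <- prev[seq(2L, length(prev), by = 2L)]
    cA[[k]] <- (odd + even) / sqrt(2)
    cD[[k]] <- (odd - even) / sqrt(2)
    prev <- cA[[k]]
  }
  structure(list(n = n, M = M, cA = cA, cD = cD, leaves = z),
            class = "haar_pyramid")
}

#' @export
print.haar_pyramid <- function(x, ...) {
  cat(sprintf("<haar_pyramid> N = %d, levels = %d\n", x$n, x$M))
  invisible(x)
}

#' Invert a Haar pyramid
#'
#' Exact inverse of [haar_decompose()]; used as the round-trip oracle for the
#' transform. Level shapes are validated before inversion.
#'
#' @param pyramid A `haar_pyramid`.
#' @return Numeric vector of the reconstructed samples.
#' @export
haar_reconstruct <- function(pyramid) {
  if (!inherits(pyramid, "haar_pyramid")) {
    stop("expected a 'haar_pyramid' object", call. = FALSE)
  }
  n <- pyramid$n
  M <- pyramid$M
  for (k in seq_len(M)) {
    want <- n / 2L^k
    if (length(pyramid$cA[[k]]) != want || length(pyramid$cD[[k]]) != want) {
      stop(sprintf("malformed pyramid: level %d must have %d coefficients",
                   k, want), call. = FALSE)
    }
  }
  cur <- pyramid$cA[[M]]
  for (k in rev(seq_len(M))) {
    cd <- pyramid$cD[[k]]
    odd <- (cur + cd) / sqrt(2)
    even <- (cur - cd) / sqrt(2)
    cur <- numeric(2L * length(cur))
    cur[seq(1L, length(cur), by = 2L)] <- odd
    cur[seq(2L, length(cur), by = 2L)] <- even
  }
  cur
}

#' Sample-index bounds of a coefficient-tree node
#'
#' The node at level `k`, within-level index `j`, of the coefficient tree over
#' a series of length `N` covers samples `a..b` with midpoint split after `c`
#' (all 1-based, inclusive):
#' `a = 2^k*(j-1)+1`, `c = a-1+2^(k-1)`, `b = 2^k*j`. For `k >= 2` the
#' quarter points `lc = a-1+2^(k-2)` and `rc = c+2^(k-2)` are also defined.
#'
#' @param k Level, `1 <= k <= log2(N)`.
#' @param j Within-level index, `1 <= j <= N/2^k`.
#' @param N Series length (power of two).
#' @return An object of class `bst_node`: list with `k`, `j`, `N`, `a`, `c`,
#'   `b`, and (`k >= 2` only, otherwise `NA`) `lc`, `rc`.
#' @examples
#' block_bounds(3, 1, 8)  # a = 1, c = 4, b = 8, lc = 2, rc = 6
#' @export
block_bounds <- function(k, j, N) {
  if (!is_pow2(N)) stop("N must be a power of two", call. = FALSE)
  M <- round(log2(N))
  if (k < 1 || k > M) {
    stop(sprintf("level k must be in 1..%d", M), call. = FALSE)
  }
  if (j < 1 || j > N / 2^k) {
    stop(sprintf("index j must be in 1..%d at level %d", N / 2^k, k),
         call. = FALSE)
  }
  a <- 2^k * (j - 1) + 1
  c <- 2^k * (j - 1) + 2^(k - 1)
  b <- 2^k * j
  lc <- if (k >= 2) 2^k * (j - 1) + 2^(k - 2) else NA_real_
  rc <- if (k >= 2) c + 2^(k - 2) else NA_real_
  structure(list(k = as.integer(k), j = as.integer(j), N = as.integer(N),
                 a = a, c = c, b = b, lc = lc, rc = rc),
            class = "bst_node")
}

#' @export
print.bst_node <- function(x, ...) {
  cat(sprintf("<bst_node> (k = %d, j = %d, N = %d): samples %d..%d, split after %d\n",
              x$k, x$j, x$N, x$a, x$b, x$c))
  invisible(x)
}

#' Children of a coefficient-tree node
#'
#' The node `(k, j)` has children `(k-1, 2j-1)` and `(k-1, 2j)`, whose blocks
#' partition the parent block exactly. For a level-1 node the children are the
#' leaf sample indices `2j-1` and `2j`.
#'
#' @param node A `bst_node` from [block_bounds()].
#' @return List with elements `left` and `right`: `bst_node` objects when the
#'   child level is `>= 1`, plain integer leaf indices for a level-1 parent.
#' @export
node_children <- function(node) {
  if (!inherits(node, "bst_node")) {
    stop("expected a 'bst_node' object", call. = FALSE)
  }
  if (node$k == 1L) {
    return(list(left = 2L * node$j - 1L, right = 2L * node$j))
  }
  list(left = block_bounds(node$k - 1L, 2L * node$j - 1L, node$N),
       right = block_bounds(node$k - 1L, 2L * node$j, node$N))
}
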