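#' Wilcoxon matched-pairs signed-rank test
#'
#' Two-sided paired test. Zero differences are dropped (their count is
#' reported); ties receive average ranks. For `n <= 15` retained pairs the
#' null distribution of the positive-rank sum is computed exactly by
#' convolution over all sign assignments (valid with ties, unlike the
#' textbook no-ties tables); larger samples use the normal approximation
#' with continuity and tie corrections.
#'
#' @param x,y Equal-length numeric vectors of paired observations.
#' @param exact_max Largest `n` for which the exact distribution is used.
#' @return List with `statistic` (positive-rank sum V), `p_value`
#'   (two-sided), `n_used`, `n_zero`, `method`.
#' @export
wilcoxon_paired <- function(x, y, exact_max = 15L) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  d <- x - y
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("degenerate pairing: all differences are zero")
  if (n < 3L) stop("need at least 3 non-zero differences")
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_max) {
    # exact null: T = sum of a random subset of the ranks; enumerate by
    # convolution on doubled ranks (average ranks are half-integers)
    r2 <- as.integer(round(2 * r))
    dist <- numeric(sum(r2) + 1L)  # index = doubled rank sum + 1
    dist[1L] <- 1
    for (rk in r2) {
      shifted <- c(numeric(rk), dist[seq_len(length(dist) - rk)])
      dist <- dist + shifted
    }
    dist <- dist / 2^n
    v2 <- as.integer(round(2 * v))
    p_le <- sum(dist[seq_len(v2 + 1L)])
    p_ge <- sum(dist[seq.int(v2 + 1L, length(dist))])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(statistic = v, p_value = p, n_used = n, n_zero = n_zero,
       method = method)
}

#' Bonferroni adjustment
#'
#' Multiplies each p-value by the number of tests and caps at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param m Number of tests (defaults to `length(p)`).
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (length(p) == 0L) return(numeric(0))
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (m < length(p)) stop("m must be at least length(p)")
  pmin(1, p * m)
}
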