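#' Shannon entropy of clone frequencies
#'
#' `H = -sum(p * log(p))` over clone fractions; zero-frequency terms
#' contribute nothing. Natural log by default, base 2 available;
#' `normalized = TRUE` divides by `log(K)` (Pielou evenness).
#'
#' @param freqs Numeric vector of fractions summing to 1 (within 1e-9),
#'   e.g. from [clone_frequencies()].
#' @param base `"e"` (default) or `"2"`.
#' @param normalized Divide by the maximum attainable entropy.
#' @return Non-negative scalar, at most `log(K)` (1 when normalized).
#' @export
shannon_entropy <- function(freqs, base = c("e", "2"), normalized = FALSE) {
  base <- match.arg(as.character(base), c("e", "2"))
  if (any(freqs < 0)) stop("negative frequency")
  if (abs(sum(freqs) - 1) > 1e-9) stop("frequencies must sum to 1")
  p <- freqs[freqs > 0]
  lg <- if (base == "e") log else log2
  h <- -sum(p * lg(p))
  if (normalized) {
    k <- length(freqs)
    if (k > 1L) h <- h / lg(k) else h <- 0
  }
  h
}

#' Linear trend of entropy over time
#'
#' Ordinary least squares of entropy on months across subjects, reporting
#' the slope, adjusted R-squared and the two-sided p-value of the slope.
#'
#' @param series Data frame with columns `timepoint_months` and `entropy`
#'   (one row per subject-timepoint).
#' @return Named list `slope`, `intercept`, `adj_r2`, `p_value`, `n`.
#' @export
entropy_trend <- function(series) {
  stopifnot(is.data.frame(series),
            all(c("timepoint_months", "entropy") %in% names(series)))
  if (nrow(series) < 3L) stop("need at least 3 points")
  if (length(unique(series$timepoint_months)) < 2L) {
    stop("degenerate design: all timepoints identical")
  }
  fit <- lm(entropy ~ timepoint_months, data = series)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2L]),
       intercept = unname(coef(fit)[1L]),
       adj_r2 = sm$adj.r.squared,
       p_value = sm$coefficients[2L, 4L],
       n = nrow(series))
}

#' Entropy of every sample in a cohort
#'
#' @param cohort A `tcr_cohort`.
#' @param base,normalized Passed to [shannon_entropy()].
#' @param weight Abundance weighting for [clone_frequencies()].
#' @return Data frame with one row per sample and column `entropy`.
#' @export
cohort_entropy <- function(cohort, base = "e", normalized = FALSE,
                           weight = "auto") {
  samples <- list_samples(cohort)
  samples$entropy <- vapply(seq_len(nrow(samples)), function(i) {
    s <- get_sample(cohort, samples$subject_id[i],
                    samples$timepoint_months[i], samples$cell_subset[i])
    shannon_entropy(clone_frequencies(s, "aa", weight), base, normalized)
  }, numeric(1))
  samples
}
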