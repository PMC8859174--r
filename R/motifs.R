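#' Interior k-mers of a CDR3
#'
#' Distinct amino-acid k-mers drawn from the CDR3 interior after trimming
#' conserved residues from each end, following local-similarity motif
#' conventions: CDR3s shorter than `min_cdr3_len` yield nothing, and each
#' distinct k-mer counts once per clonotype.
#'
#' @param cdr3_aa A single CDR3 amino-acid string.
#' @param k_min,k_max k-mer length range (default 3..7).
#' @param trim_left,trim_right Residues trimmed from the start / end
#'   (default 3 and 2).
#' @param min_cdr3_len Minimum CDR3 length analysed (default 7).
#' @return Character vector of distinct k-mers (possibly empty).
#' @export
extract_kmers <- function(cdr3_aa, k_min = 3L, k_max = 7L,
                          trim_left = 3L, trim_right = 2L,
                          min_cdr3_len = 7L) {
  stopifnot(length(cdr3_aa) == 1L)
  L <- nchar(cdr3_aa)
  if (L < min_cdr3_len) return(character(0))
  interior <- substr(cdr3_aa, trim_left + 1L, L - trim_right)
  il <- nchar(interior)
  out <- character(0)
  for (k in seq.int(k_min, k_max)) {
    if (il < k) break
    out <- c(out, substring(interior, seq_len(il - k + 1L),
                            seq.int(k, il)))
  }
  unique(out)
}

# k-mer sets for a vector of clonotype CDR3s (list parallel to input).
kmer_sets <- function(cdr3_aa, ...) {
  lapply(cdr3_aa, extract_kmers, ...)
}

#' Motif enrichment by one-sided Fisher testing
#'
#' For every k-mer present in the sample, tests over-representation of
#' clonotypes containing the motif in the sample versus the reference
#' (one-sided hypergeometric tail on the 2x2 table). Clusters with
#' `p < alpha_fisher` are retained, sorted by p then motif.
#'
#' @param sample_keys,reference_keys Data frames with key columns
#'   (`v_call`/`j_call`/`junction_aa` or `v_gene`/`j_gene`/`cdr3_aa`) or
#'   character vectors of CDR3 amino-acid sequences.
#' @param alpha_fisher Retention threshold (default 1e-3).
#' @param k_min,k_max,trim_left,trim_right,min_cdr3_len Passed to
#'   [extract_kmers()].
#' @return Data frame of class `motif_clusters`: `motif`, `k`,
#'   `sample_count`, `reference_count`, `sample_total`, `reference_total`,
#'   `fisher_p`, `members` (comma-separated member keys).
#' @export
motif_fisher <- function(sample_keys, reference_keys, alpha_fisher = 1e-3,
                         k_min = 3L, k_max = 7L, trim_left = 3L,
                         trim_right = 2L, min_cdr3_len = 7L) {
  skeys <- motif_input(sample_keys)
  rkeys <- motif_input(reference_keys)
  if (nrow(skeys) == 0L) stop("empty sample")
  if (nrow(rkeys) == 0L) stop("empty reference")
  opts <- list(k_min = k_min, k_max = k_max, trim_left = trim_left,
               trim_right = trim_right, min_cdr3_len = min_cdr3_len)
  sk <- do.call(kmer_sets, c(list(skeys$junction_aa), opts))
  rk <- do.call(kmer_sets, c(list(rkeys$junction_aa), opts))
  S <- nrow(skeys); R <- nrow(rkeys)
  s_counts <- table(unlist(sk))
  if (length(s_counts) == 0L) {
    out <- empty_clusters()
    class(out) <- c("motif_clusters", class(out))
    return(out)
  }
  r_counts <- table(unlist(rk))
  motifs <- names(s_counts)
  a <- as.integer(s_counts)
  b <- as.integer(r_counts[motifs]); b[is.na(b)] <- 0L
  # one-sided enrichment p: P(X >= a), X ~ Hypergeom(a+b successes, S draws of S+R)
  p <- phyper(a - 1L, a + b, S + R - a - b, S, lower.tail = FALSE)
  keep <- p < alpha_fisher
  if (!any(keep)) {
    out <- empty_clusters()
  } else {
    motifs <- motifs[keep]; a <- a[keep]; b <- b[keep]; p <- p[keep]
    mem <- vapply(seq_along(motifs), function(i) {
      hit <- vapply(sk, function(s) motifs[i] %in% s, logical(1))
      paste(aa_key(skeys$v_call[hit], skeys$j_call[hit],
                   skeys$junction_aa[hit]), collapse = ",")
    }, character(1))
    out <- data.frame(motif = motifs, k = nchar(motifs),
                      sample_count = a, reference_count = b,
                      sample_total = S, reference_total = R,
                      fisher_p = p, members = mem, stringsAsFactors = FALSE)
    out <- out[order(out$fisher_p, out$motif), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("motif_clusters", class(out))
  out
}

empty_clusters <- function() {
  data.frame(motif = character(), k = integer(), sample_count = integer(),
             reference_count = integer(), sample_total = integer(),
             reference_total = integer(), fisher_p = numeric(),
             members = character(), stringsAsFactors = FALSE)
}

motif_input <- function(x) {
  if (is.character(x)) {
    return(data.frame(v_call = NA_character_, j_call = NA_character_,
                      junction_aa = toupper(x), stringsAsFactors = FALSE))
  }
  nm <- names(x)
  v <- if ("v_call" %in% nm) x$v_call else x$v_gene
  j <- if ("j_call" %in% nm) x$j_call else x$j_gene
  aa <- if ("junction_aa" %in% nm) x$junction_aa else x$cdr3_aa
  data.frame(v_call = as.character(v), j_call = as.character(j),
             junction_aa = toupper(as.character(aa)), stringsAsFactors = FALSE)
}

#' V-gene bias score of a motif cluster
#'
#' The Bonferroni-corrected binomial tail probability of the most
#' over-represented V gene among the cluster's members against reference
#' V-gene usage. Clusters with score below 0.05 are conventionally called
#' V-biased; single-member clusters are reported as 1.
#'
#' @param member_v Character vector of member V genes.
#' @param reference_v_usage Named numeric vector of reference V-gene
#'   frequencies (normalized internally).
#' @return Scalar p-value in `(0, 1]`.
#' @export
v_bias_score <- function(member_v, reference_v_usage) {
  n <- length(member_v)
  if (n < 2L) return(1.0)
  ref <- reference_v_usage / sum(reference_v_usage)
  tab <- table(member_v)
  pv <- vapply(names(tab), function(v) {
    p0 <- if (v %in% names(ref)) ref[[v]] else 1e-6
    pbinom(tab[[v]] - 1L, n, p0, lower.tail = FALSE)
  }, numeric(1))
  min(1, min(pv) * length(tab))
}

#' Add V-bias scores to motif clusters
#'
#' @param clusters A `motif_clusters` data frame with member keys.
#' @param reference_keys Reference repertoire keys (for V usage) or a
#'   named numeric vector of V-gene frequencies.
#' @return `clusters` with columns `v_bias_p` and `v_biased`.
#' @export
score_v_bias <- function(clusters, reference_keys) {
  ref <- if (is.numeric(reference_keys)) reference_keys else {
    rk <- motif_input(reference_keys)
    tab <- table(rk$v_call)
    setNames(as.numeric(tab), names(tab))
  }
  clusters$v_bias_p <- vapply(clusters$members, function(m) {
    keys <- strsplit(m, ",", fixed = TRUE)[[1L]]
    vs <- vapply(strsplit(keys, "|", fixed = TRUE), `[`, character(1), 1L)
    v_bias_score(vs, ref)
  }, numeric(1), USE.NAMES = FALSE)
  clusters$v_biased <- clusters$v_bias_p < 0.05
  clusters
}

#' Repertoire coverage of enriched motifs
#'
#' Fraction of a sample's reads and clonotypes covered by at least one
#' enriched motif; clonotypes belonging to several clusters count once.
#'
#' @param clusters A `motif_clusters` data frame.
#' @param sample Sample records (or aggregated amino-acid table).
#' @param ... Passed to [extract_kmers()] (must match the values used for
#'   the clusters).
#' @return Named numeric vector `c(read_fraction, clonotype_fraction)`.
#' @export
enriched_motif_summary <- function(clusters, sample, ...) {
  agg <- if ("junction" %in% names(sample)) aggregate_to_aa(sample) else sample
  if (nrow(clusters) == 0L || nrow(agg) == 0L) {
    return(c(read_fraction = 0, clonotype_fraction = 0))
  }
  km <- kmer_sets(agg$junction_aa, ...)
  motifs <- clusters$motif
  hit <- vapply(km, function(s) any(motifs %in% s), logical(1))
  w <- as.numeric(agg$duplicate_count)
  c(read_fraction = sum(w[hit]) / sum(w),
    clonotype_fraction = mean(hit))
}
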