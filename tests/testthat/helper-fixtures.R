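# Shared fixtures and independent oracles used across the suite.

# A degenerate model realizing exactly one sequence ("TGTTTT"): one V, one J,
# the single D base always deleted, all deletions/insertions forced.
degenerate_model <- function() {
  vdj_model(
    v = data.frame(name = "V1", seq = "TGT", prob = 1),
    j = data.frame(name = "J1", seq = "TTT", prob = 1),
    d = data.frame(name = "D1", seq = "A", prob = 1),
    v_del = matrix(1, 1, 1), j_del = matrix(1, 1, 1),
    d_del5 = matrix(c(0, 1), 2, 1), d_del3 = matrix(1, 1, 1),
    ins_vd = 1, ins_dj = 1, nt_prob = rep(0.25, 4))
}

# Small two-V / one-D / two-J model with non-degenerate distributions.
small_model <- function() {
  vdj_model(
    v = data.frame(name = c("V1", "V2"), seq = c("TGTG", "TGCA"),
                   prob = c(0.6, 0.4)),
    j = data.frame(name = c("J1", "J2"), seq = c("CTTT", "ATTC"),
                   prob = c(0.7, 0.3)),
    d = data.frame(name = "D1", seq = "GG", prob = 1),
    v_del = rbind(c(0.8, 0.7), c(0.2, 0.3)),
    j_del = rbind(c(0.75, 0.6), c(0.25, 0.4)),
    d_del5 = rbind(0.7, 0.3), d_del3 = rbind(0.6, 0.4),
    ins_vd = c(0.5, 0.5), ins_dj = c(0.7, 0.3),
    nt_prob = c(0.3, 0.2, 0.2, 0.3))
}

# All synonymous nucleotide codings of an amino-acid string (oracle for the
# codon-marginalizing generation probability).
codon_expansions <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- chartr("U", "T", names(gc))
  syn <- lapply(strsplit(aa, "")[[1L]], function(a) names(gc)[gc == a])
  apply(do.call(expand.grid, c(syn, stringsAsFactors = FALSE)), 1L,
        paste, collapse = "")
}

# One-sided hypergeometric tail by explicit summation (oracle for the motif
# Fisher test): P(X >= a) with a+b motif-positive among S sample of S+R.
hyper_tail_oracle <- function(a, b, S, R) {
  m <- a + b
  xs <- a:min(m, S)
  sum(exp(lchoose(m, xs) + lchoose(S + R - m, S - xs) - lchoose(S + R, S)))
}

# Exact two-sided signed-rank p by brute-force enumeration of all 2^n sign
# assignments (oracle for wilcoxon_paired).
wilcoxon_oracle <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  vs <- vapply(0:(2^n - 1L), function(mask) {
    sum(r[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0])
  }, numeric(1))
  p_le <- mean(vs <= v_obs + 1e-9)
  p_ge <- mean(vs >= v_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Minimal clonotype record data frame builder.
make_records <- function(subject = "S1", tp = 0L, subset = "CD4_RO",
                         v = "TRBV1", j = "TRBJ1", junction, reads, umis = reads) {
  data.frame(subject_id = subject, timepoint_months = tp, cell_subset = subset,
             v_call = v, j_call = j, junction = junction,
             junction_aa = clonotrack::translate_nt(junction),
             duplicate_count = reads, umi_count = umis,
             stringsAsFactors = FALSE)
}

# Quick random cohort (no publics) for property tests.
quick_sim <- function(seed, n_subjects = 3L, subsets = "CD4_RO",
                      timepoints = c(0L, 6L), clones = 80L, umis = 400L,
                      n_public = 0L, ...) {
  simulate_cohort(simulation_config(
    n_subjects = n_subjects, subsets = subsets, timepoints = timepoints,
    clones_per_sample = clones, umis_per_sample = umis,
    n_public = n_public, seed = seed, ...))
}

# Public-clone brute-force oracle: double loop over keys and subjects.
public_oracle <- function(cohort, subset, tp, min_reads = 2L, min_subjects = 2L) {
  ct <- cohort$clonotypes
  ct <- ct[ct$cell_subset == subset & ct$timepoint_months == tp, ]
  keys <- unique(paste(ct$v_call, ct$j_call, ct$junction_aa, sep = "|"))
  out <- list()
  for (k in keys) {
    subs <- character(0)
    for (subj in unique(ct$subject_id)) {
      rows <- ct[ct$subject_id == subj &
                   paste(ct$v_call, ct$j_call, ct$junction_aa, sep = "|") == k, ]
      if (sum(rows$duplicate_count) >= min_reads) subs <- c(subs, subj)
    }
    if (length(subs) >= min_subjects) out[[k]] <- sort(subs)
  }
  out
}
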