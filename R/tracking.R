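#' Dominant clones of a sample
#'
#' The `n` most abundant amino-acid clonotypes ("top 100 by read size"),
#' ranked by UMI-corrected abundance when UMIs are present and reads
#' otherwise, with a deterministic tie-break (abundance descending, then
#' CDR3, V gene, J gene).
#'
#' @param sample Data frame of clonotype records, or an already aggregated
#'   amino-acid table from [aggregate_to_aa()].
#' @param n Number of clones (default 100); the full repertoire is
#'   returned when it holds fewer.
#' @param weight Abundance weighting passed to [clone_abundance()].
#' @return Data frame of the top clones (aggregated amino-acid rows, in
#'   rank order).
#' @export
top_n_clones <- function(sample, n = 100L, weight = "auto") {
  if (n <= 0L) stop("n must be positive")
  agg <- if ("junction" %in% names(sample)) aggregate_to_aa(sample) else sample
  agg <- agg[order(-clone_abundance(agg, weight), agg$junction_aa,
                   agg$v_call, agg$j_call), , drop = FALSE]
  out <- head(agg, n)
  rownames(out) <- NULL
  out
}

#' Fraction of baseline dominant clones still detected at follow-up
#'
#' @param baseline_top Data frame of baseline dominant clones (from
#'   [top_n_clones()]) or a character vector of `V|J|CDR3aa` keys.
#' @param followup Follow-up sample (records or aggregated).
#' @param min_count Minimum follow-up abundance to count as detected
#'   (default 1).
#' @param weight Abundance weighting for the detection threshold.
#' @return Fraction in `[0, 1]`.
#' @export
persistence_fraction <- function(baseline_top, followup, min_count = 1L,
                                 weight = "auto") {
  keys <- if (is.character(baseline_top)) baseline_top else
    aa_key(baseline_top$v_call, baseline_top$j_call, baseline_top$junction_aa)
  if (length(keys) == 0L) stop("empty baseline dominant set")
  agg <- if ("junction" %in% names(followup)) aggregate_to_aa(followup) else followup
  fk <- aa_key(agg$v_call, agg$j_call, agg$junction_aa)
  ab <- clone_abundance(agg, weight)
  detected <- fk[ab >= min_count]
  mean(keys %in% detected)
}

#' Partition follow-up repertoire mass into persistent and new
#'
#' Splits the follow-up abundance mass by whether each amino-acid clonotype
#' was detected (any abundance) at baseline.
#'
#' @param baseline,followup Samples (records or aggregated).
#' @param weight Abundance weighting.
#' @return Named numeric vector `c(persistent, new)`; the two fractions
#'   sum to 1.
#' @export
partition_new_persistent <- function(baseline, followup, weight = "auto") {
  bagg <- if ("junction" %in% names(baseline)) aggregate_to_aa(baseline) else baseline
  fagg <- if ("junction" %in% names(followup)) aggregate_to_aa(followup) else followup
  if (nrow(fagg) == 0L) stop("empty follow-up repertoire")
  if (nrow(bagg) == 0L) stop("empty baseline repertoire")
  bkeys <- aa_key(bagg$v_call, bagg$j_call, bagg$junction_aa)
  fkeys <- aa_key(fagg$v_call, fagg$j_call, fagg$junction_aa)
  w <- as.numeric(clone_abundance(fagg, weight))
  persistent <- sum(w[fkeys %in% bkeys]) / sum(w)
  c(persistent = persistent, new = 1 - persistent)
}

#' Repertoire overlap between two samples
#'
#' Shared amino-acid clonotype count and Jaccard index.
#'
#' @param a,b Samples (records or aggregated).
#' @return Named numeric vector `c(shared, jaccard)`. When both
#'   repertoires are empty the Jaccard index is reported as 0 with a
#'   warning.
#' @export
repertoire_overlap <- function(a, b) {
  ka <- if (nrow(a) > 0L) {
    agg <- if ("junction" %in% names(a)) aggregate_to_aa(a) else a
    unique(aa_key(agg$v_call, agg$j_call, agg$junction_aa))
  } else character(0)
  kb <- if (nrow(b) > 0L) {
    agg <- if ("junction" %in% names(b)) aggregate_to_aa(b) else b
    unique(aa_key(agg$v_call, agg$j_call, agg$junction_aa))
  } else character(0)
  shared <- length(intersect(ka, kb))
  uni <- length(union(ka, kb))
  if (uni == 0L) {
    warning("both repertoires empty; Jaccard reported as 0")
    return(c(shared = 0, jaccard = 0))
  }
  c(shared = shared, jaccard = shared / uni)
}

#' Cohort-level dominant-clone persistence kinetics
#'
#' For each subject with a baseline sample in the given subset, computes
#' the fraction of its baseline top-`n` clones still detected at every
#' later timepoint, then summarizes the per-subject fractions
#' ("mean clonal persistence").
#'
#' @param cohort A `tcr_cohort`.
#' @param cell_subset Subset to analyse.
#' @param n Dominant-set size.
#' @param min_count Detection threshold at follow-up.
#' @return Data frame with columns `subject_id`, `timepoint_months`,
#'   `n_dominant`, `persistence`.
#' @export
persistence_kinetics <- function(cohort, cell_subset, n = 100L,
                                 min_count = 1L) {
  samples <- list_samples(cohort)
  samples <- samples[samples$cell_subset == cell_subset, , drop = FALSE]
  tps <- sort(unique(samples$timepoint_months))
  if (length(tps) < 2L) stop("need at least two timepoints")
  base_tp <- tps[1L]
  out <- list()
  for (subj in unique(samples$subject_id)) {
    if (!any(samples$subject_id == subj & samples$timepoint_months == base_tp)) next
    top <- top_n_clones(get_sample(cohort, subj, base_tp, cell_subset), n)
    for (tp in tps[-1L]) {
      if (!any(samples$subject_id == subj & samples$timepoint_months == tp)) next
      fu <- get_sample(cohort, subj, tp, cell_subset)
      out[[length(out) + 1L]] <- data.frame(
        subject_id = subj, timepoint_months = tp, n_dominant = nrow(top),
        persistence = persistence_fraction(top, fu, min_count),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
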