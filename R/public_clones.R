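#' Identify public clonotypes
#'
#' A clonotype (V gene, J gene, CDR3 amino-acid) is public when it is
#' detected in at least `min_subjects` distinct subjects. The read
#' threshold is applied per subject by default ("detected at a size of at
#' least two reads, in two or more individuals"); `threshold = "total"`
#' instead requires the summed abundance across qualifying subjects to
#' reach `min_reads` (with any detection per subject).
#'
#' @param cohort A `tcr_cohort`.
#' @param cell_subset Subset analysed.
#' @param timepoint_months Timepoint analysed, or `NULL` to pool all
#'   timepoints (per-subject counts summed before thresholding).
#' @param min_reads Read threshold (default 2).
#' @param min_subjects Minimum number of subjects (default 2).
#' @param threshold `"per_subject"` (default) or `"total"`.
#' @return Data frame with one row per public key: `v_call`, `j_call`,
#'   `junction_aa`, `n_subjects`, `subjects` (comma-separated).
#' @export
identify_public <- function(cohort, cell_subset, timepoint_months = NULL,
                            min_reads = 2L, min_subjects = 2L,
                            threshold = c("per_subject", "total")) {
  threshold <- match.arg(threshold)
  ct <- cohort$clonotypes
  ct <- ct[ct$cell_subset == cell_subset, , drop = FALSE]
  if (!is.null(timepoint_months)) {
    ct <- ct[ct$timepoint_months %in% timepoint_months, , drop = FALSE]
  }
  if (length(unique(ct$subject_id)) < 2L) {
    stop("fewer than 2 subjects available for the requested sample")
  }
  key <- aa_key(ct$v_call, ct$j_call, ct$junction_aa)
  id <- paste(key, ct$subject_id, sep = "\r")
  reads <- rowsum(ct$duplicate_count, id)
  parts <- strsplit(rownames(reads), "\r", fixed = TRUE)
  df <- data.frame(key = vapply(parts, `[`, character(1), 1L),
                   subject_id = vapply(parts, `[`, character(1), 2L),
                   reads = as.integer(reads), stringsAsFactors = FALSE)
  if (threshold == "per_subject") {
    df <- df[df$reads >= min_reads, , drop = FALSE]
    agg <- split(df$subject_id, df$key)
    agg <- agg[lengths(agg) >= min_subjects]
  } else {
    tot <- rowsum(df$reads, df$key)
    sub <- split(df$subject_id, df$key)
    ok <- names(sub)[lengths(sub) >= min_subjects &
                       as.integer(tot[names(sub), 1L]) >= min_reads]
    agg <- split(df$subject_id, df$key)[ok]
  }
  if (length(agg) == 0L) {
    return(data.frame(v_call = character(), j_call = character(),
                      junction_aa = character(), n_subjects = integer(),
                      subjects = character(), stringsAsFactors = FALSE))
  }
  kp <- strsplit(names(agg), "|", fixed = TRUE)
  out <- data.frame(
    v_call = vapply(kp, `[`, character(1), 1L),
    j_call = vapply(kp, `[`, character(1), 2L),
    junction_aa = vapply(kp, `[`, character(1), 3L),
    n_subjects = lengths(agg),
    subjects = vapply(agg, function(s) paste(sort(unique(s)), collapse = ","),
                      character(1)),
    stringsAsFactors = FALSE)
  out <- out[order(-out$n_subjects, out$junction_aa, out$v_call, out$j_call), ]
  rownames(out) <- NULL
  out
}

#' Sharing distribution of public clonotypes
#'
#' Counts public keys per distinct subject combination (the input to an
#' upset-style plot); counts sum to the number of public keys.
#'
#' @param public_map Data frame from [identify_public()].
#' @return Data frame with columns `subjects` and `n_clonotypes`, sorted
#'   by descending count.
#' @export
sharing_distribution <- function(public_map) {
  if (nrow(public_map) == 0L) {
    return(data.frame(subjects = character(), n_clonotypes = integer(),
                      stringsAsFactors = FALSE))
  }
  tab <- table(public_map$subjects)
  out <- data.frame(subjects = names(tab), n_clonotypes = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_clonotypes, out$subjects), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convergent-recombination counts
#'
#' Number of distinct nucleotide sequences encoding each amino-acid
#' clonotype within one sample ("public clones depicted by different
#' nucleotide reads, 1 to 5").
#'
#' @param sample Data frame of nucleotide clonotype records.
#' @param keys Optional data frame restricting to specific keys
#'   (`v_call`, `j_call`, `junction_aa`); keys absent from the sample are
#'   reported as 0 with a warning.
#' @return Data frame with columns `v_call`, `j_call`, `junction_aa`,
#'   `n_nt_variants`.
#' @export
convergence_counts <- function(sample, keys = NULL) {
  agg <- aggregate_to_aa(sample)
  out <- agg[c("v_call", "j_call", "junction_aa", "n_nt_variants")]
  if (!is.null(keys)) {
    want <- aa_key(keys$v_call, keys$j_call, keys$junction_aa)
    have <- aa_key(out$v_call, out$j_call, out$junction_aa)
    m <- match(want, have)
    if (anyNA(m)) {
      warning(sum(is.na(m)), " requested key(s) absent from sample; reported as 0")
    }
    out <- data.frame(v_call = keys$v_call, j_call = keys$j_call,
                      junction_aa = keys$junction_aa,
                      n_nt_variants = ifelse(is.na(m), 0L,
                                             out$n_nt_variants[m]),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

# Normalize an HLA allele string to LOCUS*GG:PP form (uppercase, no spaces).
normalize_allele <- function(allele) {
  a <- toupper(gsub("[[:space:]]", "", allele))
  if (any(!grepl("^[A-Z0-9]+\\*[0-9]+(:[0-9]+)*$", a))) {
    stop("malformed HLA allele string: ",
         a[which(!grepl("^[A-Z0-9]+\\*[0-9]+(:[0-9]+)*$", a))[1L]])
  }
  a
}

# TRUE when one allele is a field-prefix of the other (handles 2- vs
# 4-digit typing resolution).
allele_matches <- function(entry, carried) {
  e <- strsplit(normalize_allele(entry), "[*:]")[[1L]]
  vapply(carried, function(x) {
    c_ <- strsplit(normalize_allele(x), "[*:]")[[1L]]
    k <- min(length(e), length(c_))
    identical(e[seq_len(k)], c_[seq_len(k)])
  }, logical(1))
}

subject_alleles <- function(subjects_row) {
  a <- strsplit(subjects_row, ",", fixed = TRUE)[[1L]]
  a[nzchar(a)]
}

#' Stratify a cohort by HLA allele carriage
#'
#' @param cohort A `tcr_cohort`.
#' @param allele Allele string, e.g. `"DRB1*15:01"`; matching respects the
#'   typing resolution of the stored alleles (field-prefix matching).
#' @return List with elements `carriers` and `non_carriers`, both
#'   `tcr_cohort`s; their subject sets partition the input.
#' @export
stratify_by_hla <- function(cohort, allele) {
  allele <- normalize_allele(allele)
  carries <- vapply(cohort$subjects$hla_alleles, function(h) {
    al <- subject_alleles(h)
    length(al) > 0L && any(allele_matches(allele, al))
  }, logical(1), USE.NAMES = FALSE)
  split_cohort <- function(ids) {
    ct <- cohort$clonotypes[cohort$clonotypes$subject_id %in% ids, , drop = FALSE]
    sj <- cohort$subjects[cohort$subjects$subject_id %in% ids, , drop = FALSE]
    structure(list(clonotypes = ct, subjects = sj), class = "tcr_cohort")
  }
  list(carriers = split_cohort(cohort$subjects$subject_id[carries]),
       non_carriers = split_cohort(cohort$subjects$subject_id[!carries]))
}
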