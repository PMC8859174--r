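#' Clonotype and cohort containers
#'
#' A cohort holds longitudinal clonotype tables for several subjects. The unit
#' of tracking is the clonotype key: the (V gene, J gene, CDR3 amino-acid)
#' triple; each key may be carried by several nucleotide encodings
#' (convergent recombination), stored one row per nucleotide variant.
#'
#' @section Clonotype table columns:
#' `subject_id`, `timepoint_months`, `cell_subset`, `v_call`, `j_call`,
#' `junction` (nucleotide CDR3 including the conserved C and F codons),
#' `junction_aa`, `duplicate_count` (reads), `umi_count`.
#'
#' @param clonotypes Data frame with the columns above.
#' @param subjects Optional data frame with columns `subject_id`,
#'   `hla_alleles` (comma-separated allele strings, may be empty) and
#'   `treatment_group`. Derived from `clonotypes` when omitted.
#' @return An object of class `tcr_cohort`: a list with elements
#'   `clonotypes` and `subjects`.
#' @export
tcr_cohort <- function(clonotypes, subjects = NULL) {
  required <- c("subject_id", "timepoint_months", "cell_subset", "v_call",
                "j_call", "junction", "junction_aa", "duplicate_count",
                "umi_count")
  missing_cols <- setdiff(required, names(clonotypes))
  if (length(missing_cols) > 0L) {
    stop("clonotype table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  ct <- clonotypes[required]
  ct$subject_id <- as.character(ct$subject_id)
  ct$timepoint_months <- as.integer(ct$timepoint_months)
  ct$cell_subset <- as.character(ct$cell_subset)
  ct$v_call <- as.character(ct$v_call)
  ct$j_call <- as.character(ct$j_call)
  ct$junction <- toupper(as.character(ct$junction))
  ct$junction_aa <- toupper(as.character(ct$junction_aa))
  ct$duplicate_count <- as.integer(ct$duplicate_count)
  ct$umi_count <- as.integer(ct$umi_count)

  if (nrow(ct) > 0L) {
    if (any(ct$junction_aa == "")) stop("empty junction_aa")
    bad_len <- which(nchar(ct$junction) != 3L * nchar(ct$junction_aa))
    if (length(bad_len) > 0L) {
      stop("row ", bad_len[1L], ": junction length is not 3x junction_aa length")
    }
    tr <- translate_nt(ct$junction)
    bad <- which(tr != ct$junction_aa)
    if (length(bad) > 0L) {
      stop("row ", bad[1L], ": junction '", ct$junction[bad[1L]],
           "' does not translate to junction_aa '", ct$junction_aa[bad[1L]], "'")
    }
    if (any(ct$duplicate_count < 0L) || any(ct$umi_count < 0L)) {
      stop("negative counts")
    }
    if (any(ct$umi_count > ct$duplicate_count & ct$duplicate_count > 0L)) {
      stop("umi_count exceeds duplicate_count")
    }
    # aggregate duplicate nucleotide records within a sample
    keyv <- paste(ct$subject_id, ct$timepoint_months, ct$cell_subset,
                  ct$v_call, ct$j_call, ct$junction, sep = "\r")
    if (anyDuplicated(keyv)) {
      dup <- rowsum(cbind(ct$duplicate_count, ct$umi_count), keyv, reorder = FALSE)
      first <- !duplicated(keyv)
      ct <- ct[first, , drop = FALSE]
      m <- match(keyv[first], rownames(dup))
      ct$duplicate_count <- as.integer(dup[m, 1L])
      ct$umi_count <- as.integer(dup[m, 2L])
    }
    ct <- ct[order(ct$subject_id, ct$timepoint_months, ct$cell_subset,
                   ct$v_call, ct$j_call, ct$junction), , drop = FALSE]
    rownames(ct) <- NULL
  }

  if (is.null(subjects)) {
    ids <- sort(unique(ct$subject_id))
    subjects <- data.frame(subject_id = ids,
                           hla_alleles = rep("", length(ids)),
                           treatment_group = rep("AHSCT", length(ids)),
                           stringsAsFactors = FALSE)
  } else {
    subjects <- as.data.frame(subjects, stringsAsFactors = FALSE)
    if (!all(c("subject_id", "hla_alleles", "treatment_group") %in% names(subjects))) {
      stop("subjects table needs subject_id, hla_alleles, treatment_group")
    }
    subjects$subject_id <- as.character(subjects$subject_id)
    subjects$hla_alleles <- as.character(subjects$hla_alleles)
    missing_subj <- setdiff(unique(ct$subject_id), subjects$subject_id)
    if (length(missing_subj) > 0L) {
      stop("samples reference subjects absent from metadata: ",
           paste(missing_subj, collapse = ", "))
    }
    subjects <- subjects[order(subjects$subject_id), , drop = FALSE]
    rownames(subjects) <- NULL
  }
  structure(list(clonotypes = ct, subjects = subjects), class = "tcr_cohort")
}

#' @export
print.tcr_cohort <- function(x, ...) {
  ct <- x$clonotypes
  cat("TCR repertoire cohort\n")
  cat("  subjects:  ", nrow(x$subjects), "\n")
  cat("  samples:   ", nrow(unique(ct[c("subject_id", "timepoint_months",
                                        "cell_subset")])), "\n")
  cat("  records:   ", nrow(ct), " (nucleotide clonotypes)\n")
  if (nrow(ct) > 0L) {
    cat("  timepoints:", paste(sort(unique(ct$timepoint_months)), collapse = ", "),
        "months\n")
    cat("  subsets:   ", paste(sort(unique(ct$cell_subset)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a clonotype table
#'
#' Reads a tab-separated clonotype table (AIRR Rearrangement column names
#' extended with sample annotations) into a [tcr_cohort()].
#'
#' @param path Path to a TSV file.
#' @param subjects Optional subject metadata data frame or path to a TSV with
#'   columns `subject_id`, `hla_alleles`, `treatment_group`.
#' @return A `tcr_cohort`.
#' @export
read_clonotype_table <- function(path, subjects = NULL) {
  ct <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = "character", fileEncoding = "UTF-8",
                   check.names = FALSE)
  if (is.character(subjects) && length(subjects) == 1L) {
    subjects <- read.delim(subjects, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, colClasses = "character",
                           fileEncoding = "UTF-8")
  }
  tcr_cohort(ct, subjects)
}

#' Write a clonotype table
#'
#' Writes the cohort's clonotype records as UTF-8 TSV. Reading the file back
#' with [read_clonotype_table()] reproduces the cohort exactly.
#'
#' @param cohort A `tcr_cohort`.
#' @param path Output path.
#' @param subjects_path Optional path for the subject metadata TSV.
#' @export
write_clonotype_table <- function(cohort, path, subjects_path = NULL) {
  stopifnot(inherits(cohort, "tcr_cohort"))
  write.table(cohort$clonotypes, path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(subjects_path)) {
    write.table(cohort$subjects, subjects_path, sep = "\t", quote = FALSE,
                row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Extract one repertoire sample from a cohort
#'
#' @param cohort A `tcr_cohort`.
#' @param subject_id,timepoint_months,cell_subset Sample coordinates.
#' @return Data frame of the sample's nucleotide clonotype records.
#' @export
get_sample <- function(cohort, subject_id, timepoint_months, cell_subset) {
  ct <- cohort$clonotypes
  out <- ct[ct$subject_id == subject_id &
              ct$timepoint_months == timepoint_months &
              ct$cell_subset == cell_subset, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' List the samples present in a cohort
#'
#' @param cohort A `tcr_cohort`.
#' @return Data frame with one row per (subject, timepoint, subset).
#' @export
list_samples <- function(cohort) {
  s <- unique(cohort$clonotypes[c("subject_id", "timepoint_months", "cell_subset")])
  s <- s[order(s$subject_id, s$timepoint_months, s$cell_subset), , drop = FALSE]
  rownames(s) <- NULL
  s
}

# Canonical clone identifier for an amino-acid clonotype key.
aa_key <- function(v, j, aa) paste(v, j, aa, sep = "|")

#' Aggregate a sample to amino-acid clonotypes
#'
#' Collapses nucleotide-level records sharing a (V, J, CDR3 amino-acid) key:
#' reads and UMIs are summed over nucleotide variants and the number of
#' distinct encodings is recorded.
#'
#' @param sample Data frame of nucleotide clonotype records (see
#'   [get_sample()]).
#' @return Data frame with columns `v_call`, `j_call`, `junction_aa`,
#'   `duplicate_count`, `umi_count`, `n_nt_variants`, `nt_variants`
#'   (comma-separated) sorted by abundance.
#' @export
aggregate_to_aa <- function(sample) {
  if (nrow(sample) == 0L) {
    return(data.frame(v_call = character(), j_call = character(),
                      junction_aa = character(), duplicate_count = integer(),
                      umi_count = integer(), n_nt_variants = integer(),
                      nt_variants = character(), stringsAsFactors = FALSE))
  }
  key <- aa_key(sample$v_call, sample$j_call, sample$junction_aa)
  agg <- rowsum(cbind(sample$duplicate_count, sample$umi_count), key,
                reorder = FALSE)
  first <- !duplicated(key)
  nts <- vapply(split(sample$junction, key)[rownames(agg)],
                function(x) paste(sort(unique(x)), collapse = ","), character(1))
  nn <- vapply(split(sample$junction, key)[rownames(agg)],
               function(x) length(unique(x)), integer(1))
  out <- data.frame(v_call = sample$v_call[first],
                    j_call = sample$j_call[first],
                    junction_aa = sample$junction_aa[first],
                    duplicate_count = as.integer(agg[match(key[first], rownames(agg)), 1L]),
                    umi_count = as.integer(agg[match(key[first], rownames(agg)), 2L]),
                    stringsAsFactors = FALSE)
  m <- match(aa_key(out$v_call, out$j_call, out$junction_aa), rownames(agg))
  out$n_nt_variants <- as.integer(nn[m])
  out$nt_variants <- as.character(nts[m])
  out <- out[order(-clone_abundance(out), out$junction_aa, out$v_call,
                   out$j_call), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Abundance used for ranking: UMI counts when present, reads otherwise.
clone_abundance <- function(df, weight = c("auto", "umis", "reads")) {
  weight <- match.arg(weight)
  if (weight == "reads") return(df$duplicate_count)
  if (weight == "umis") return(df$umi_count)
  if (any(df$umi_count > 0L)) df$umi_count else df$duplicate_count
}

#' Clone frequencies within a sample
#'
#' @param sample Data frame of nucleotide clonotype records.
#' @param level `"aa"` (amino-acid keys, default) or `"nt"` (nucleotide
#'   variants).
#' @param weight `"umis"`, `"reads"`, or `"auto"` (UMIs when present).
#' @return Named numeric vector of fractions summing to 1, sorted by
#'   decreasing frequency then name (deterministic).
#' @export
clone_frequencies <- function(sample, level = c("aa", "nt"),
                              weight = c("auto", "umis", "reads")) {
  level <- match.arg(level)
  weight <- match.arg(weight)
  if (nrow(sample) == 0L) stop("empty repertoire")
  if (level == "aa") {
    agg <- aggregate_to_aa(sample)
    w <- as.numeric(clone_abundance(agg, weight))
    nm <- aa_key(agg$v_call, agg$j_call, agg$junction_aa)
  } else {
    w <- as.numeric(clone_abundance(sample, weight))
    nm <- paste(sample$v_call, sample$j_call, sample$junction, sep = "|")
  }
  tot <- sum(w)
  if (tot <= 0) stop("empty repertoire")
  f <- setNames(w / tot, nm)
  f[order(-f, names(f))]
}
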