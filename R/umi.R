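#' Structured-read layout for UMI-tagged TCR libraries
#'
#' Reads carry a constant adapter, a random unique molecular identifier
#' (UMI), a short spacer, and the insert (the CDR3 region, conserved-C
#' codon through conserved-F codon). Defaults follow a template-switch
#' primer design with a 10 bp UMI.
#'
#' @param adapter Constant adapter preceding the UMI.
#' @param umi_length UMI length in bases (default 10).
#' @param spacer Constant spacer between UMI and insert.
#' @return An object of class `read_structure`.
#' @export
read_structure <- function(adapter = "TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG",
                           umi_length = 10L,
                           spacer = "ACATGGG") {
  stopifnot(nchar(adapter) > 0L, nchar(spacer) > 0L, umi_length > 0L)
  structure(list(adapter = toupper(adapter),
                 umi_length = as.integer(umi_length),
                 spacer = toupper(spacer)),
            class = "read_structure")
}

#' Extract UMI and insert from structured reads
#'
#' Locates the adapter (allowing one mismatch), takes the following
#' `umi_length` bases as the UMI, requires the spacer (one mismatch allowed)
#' immediately after, and returns the remainder as the insert. Failures are
#' classified, not raised: `no_adapter`, `no_spacer`, `too_short`.
#'
#' @param reads Character vector of read sequences.
#' @param structure A [read_structure()].
#' @return Data frame with columns `umi`, `insert`, `ok`, `reason`
#'   (`NA` when extraction succeeded).
#' @export
extract_umi <- function(reads, structure = read_structure()) {
  stopifnot(inherits(structure, "read_structure"))
  n <- length(reads)
  reads <- toupper(reads)
  pos <- .find_approx_cpp(reads, structure$adapter, 1L)
  alen <- nchar(structure$adapter)
  slen <- nchar(structure$spacer)
  ulen <- structure$umi_length
  umi_start <- pos + alen
  spacer_mm <- .count_mm_at_cpp(reads, structure$spacer, umi_start + ulen)
  rlen <- nchar(reads)
  ok <- rep(FALSE, n)
  reason <- rep(NA_character_, n)
  reason[pos == 0L] <- "no_adapter"
  long_enough <- pos > 0L & rlen >= pos + alen + ulen + slen - 1L
  reason[pos > 0L & !long_enough] <- "too_short"
  has_spacer <- long_enough & spacer_mm >= 0L & spacer_mm <= 1L
  reason[long_enough & !has_spacer] <- "no_spacer"
  ok <- has_spacer
  umi <- rep(NA_character_, n)
  insert <- rep(NA_character_, n)
  umi[ok] <- substr(reads[ok], umi_start[ok], umi_start[ok] + ulen - 1L)
  insert[ok] <- substr(reads[ok], umi_start[ok] + ulen + slen, rlen[ok])
  data.frame(umi = umi, insert = insert, ok = ok, reason = reason,
             stringsAsFactors = FALSE)
}

#' Directional UMI collapse
#'
#' Merges UMI `b` into UMI `a` when their Hamming distance is at most 1 and
#' `a`'s read count is at least `2 * count(b) - 1` (the directional
#' adjacency rule), iterating to a fixpoint. Groups are processed in
#' descending read count with ties broken lexicographically by UMI, which
#' makes the result independent of input order.
#'
#' @param groups Data frame with columns `umi` and `read_count`.
#' @return Data frame of the surviving groups (counts summed), sorted by
#'   descending count then UMI.
#' @export
collapse_umis <- function(groups) {
  stopifnot(is.data.frame(groups), all(c("umi", "read_count") %in% names(groups)))
  if (nrow(groups) == 0L) return(groups)
  if (length(unique(nchar(groups$umi))) > 1L) stop("UMIs of unequal length")
  g <- groups[order(-groups$read_count, groups$umi), , drop = FALSE]
  # duplicate UMIs within the input are one molecule
  if (anyDuplicated(g$umi)) {
    cc <- rowsum(g$read_count, g$umi)
    g <- data.frame(umi = rownames(cc), read_count = as.integer(cc),
                    stringsAsFactors = FALSE)
    g <- g[order(-g$read_count, g$umi), , drop = FALSE]
  }
  repeat {
    merged <- FALSE
    i <- 1L
    while (i <= nrow(g)) {
      if (nrow(g) > i) {
        cand <- seq.int(i + 1L, nrow(g))
        d <- .hamming_cpp(rep(g$umi[i], length(cand)), g$umi[cand])
        hit <- cand[d <= 1L & g$read_count[i] >= 2L * g$read_count[cand] - 1L]
        if (length(hit) > 0L) {
          g$read_count[i] <- g$read_count[i] + sum(g$read_count[hit])
          g <- g[-hit, , drop = FALSE]
          g <- g[order(-g$read_count, g$umi), , drop = FALSE]
          merged <- TRUE
          i <- 1L
          next
        }
      }
      i <- i + 1L
    }
    if (!merged) break
  }
  rownames(g) <- NULL
  g
}

#' Call CDR3 and segment attribution from an insert
#'
#' Matches the insert's start against the model's V 3'-flanks and its end
#' against the J 5'-flanks (a match requires at least `min_match` bases
#' with at most one mismatch; longer matches win, then fewer mismatches,
#' then segment order). The CDR3 is the full insert, spanning the
#' conserved-C codon through the conserved-F codon. Failure reasons:
#' `no_v`, `no_j`, `frame` (length not a multiple of 3, or a stop codon).
#'
#' @param inserts Character vector of insert sequences.
#' @param gen A `vdj_model` supplying the flanks.
#' @param min_match Minimum flank match length (default 6).
#' @return Data frame with columns `v_call`, `j_call`, `junction`,
#'   `junction_aa`, `ok`, `reason`.
#' @export
call_cdr3 <- function(inserts, gen, min_match = 6L) {
  stopifnot(inherits(gen, "vdj_model"))
  n <- length(inserts)
  inserts <- toupper(inserts)
  vb <- .best_flank_cpp(inserts, gen$v$seq, min_match, 1L, FALSE)
  jb <- .best_flank_cpp(inserts, gen$j$seq, min_match, 1L, TRUE)
  ok <- rep(FALSE, n)
  reason <- rep(NA_character_, n)
  reason[vb$segment == 0L] <- "no_v"
  reason[vb$segment > 0L & jb$segment == 0L] <- "no_j"
  callable <- vb$segment > 0L & jb$segment > 0L
  aa <- rep(NA_character_, n)
  if (any(callable)) {
    aa[callable] <- translate_nt_or_na(inserts[callable])
  }
  frame_bad <- callable & is.na(aa)
  reason[frame_bad] <- "frame"
  ok <- callable & !is.na(aa)
  data.frame(
    v_call = ifelse(ok, gen$v$name[pmax(vb$segment, 1L)], NA_character_),
    j_call = ifelse(ok, gen$j$name[pmax(jb$segment, 1L)], NA_character_),
    junction = ifelse(ok, inserts, NA_character_),
    junction_aa = aa,
    ok = ok, reason = reason, stringsAsFactors = FALSE)
}

#' Build a clonotype table from structured reads
#'
#' Runs the full UMI pipeline: extract UMI and insert, call CDR3 and V/J,
#' group reads by (V, J, nucleotide CDR3), collapse UMIs within each group,
#' and emit one clonotype record per nucleotide variant with
#' `umi_count` = number of collapsed molecules and
#' `duplicate_count` = total reads. Totals are conserved: assigned plus
#' rejected reads equal the input.
#'
#' @param reads Character vector of read sequences, or a path to a FASTQ
#'   file (read via `Biostrings`).
#' @param structure A [read_structure()].
#' @param gen A `vdj_model` for CDR3 calling.
#' @param subject_id,timepoint_months,cell_subset Sample labels.
#' @return List with elements `sample` (clonotype record data frame) and
#'   `qc` (read tallies by rejection reason).
#' @export
build_clonotype_table <- function(reads, structure = read_structure(), gen,
                                  subject_id = "S1", timepoint_months = 0L,
                                  cell_subset = "CD4_RO") {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- as.character(Biostrings::readDNAStringSet(reads, format = "fastq"))
  }
  n_input <- length(reads)
  ex <- extract_umi(reads, structure)
  qc_extract <- table(factor(ex$reason[!ex$ok],
                             levels = c("no_adapter", "no_spacer", "too_short")))
  called <- call_cdr3(ex$insert[ex$ok], gen)
  qc_call <- table(factor(called$reason[!called$ok],
                          levels = c("no_v", "no_j", "frame")))
  keep <- called$ok
  df <- data.frame(umi = ex$umi[ex$ok][keep],
                   v_call = called$v_call[keep], j_call = called$j_call[keep],
                   junction = called$junction[keep],
                   junction_aa = called$junction_aa[keep],
                   stringsAsFactors = FALSE)
  records <- NULL
  if (nrow(df) > 0L) {
    grp <- paste(df$v_call, df$j_call, df$junction, sep = "\r")
    pieces <- split(df$umi, grp)
    rec_list <- lapply(names(pieces), function(g) {
      umis <- pieces[[g]]
      tab <- table(umis)
      collapsed <- collapse_umis(data.frame(umi = names(tab),
                                            read_count = as.integer(tab),
                                            stringsAsFactors = FALSE))
      parts <- strsplit(g, "\r", fixed = TRUE)[[1L]]
      data.frame(v_call = parts[1L], j_call = parts[2L], junction = parts[3L],
                 duplicate_count = length(umis),
                 umi_count = nrow(collapsed), stringsAsFactors = FALSE)
    })
    records <- do.call(rbind, rec_list)
    records$junction_aa <- translate_nt(records$junction)
  } else {
    records <- data.frame(v_call = character(), j_call = character(),
                          junction = character(), duplicate_count = integer(),
                          umi_count = integer(), junction_aa = character(),
                          stringsAsFactors = FALSE)
  }
  records$subject_id <- rep(subject_id, nrow(records))
  records$timepoint_months <- rep(as.integer(timepoint_months), nrow(records))
  records$cell_subset <- rep(cell_subset, nrow(records))
  records <- records[c("subject_id", "timepoint_months", "cell_subset",
                       "v_call", "j_call", "junction", "junction_aa",
                       "duplicate_count", "umi_count")]
  records <- records[order(records$v_call, records$j_call, records$junction), ,
                     drop = FALSE]
  rownames(records) <- NULL
  qc <- list(
    n_input = n_input,
    n_extracted = sum(ex$ok),
    extract_rejections = as.list(qc_extract),
    n_called = sum(keep),
    call_rejections = as.list(qc_call),
    n_records = nrow(records),
    n_assigned = sum(records$duplicate_count))
  stopifnot(qc$n_assigned + sum(unlist(qc$extract_rejections)) +
              sum(unlist(qc$call_rejections)) == n_input)
  list(sample = records, qc = qc)
}
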