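#' Read an antigen-specificity table
#'
#' Accepts either the package's column names (`v_gene`, `j_gene`,
#' `cdr3_aa`, `epitope`, `antigen_species`, `hla_restriction`) or
#' VDJdb-style names (`v.segm`, `j.segm`, `cdr3`, `antigen.epitope`,
#' `antigen.species`, `mhc.a`).
#'
#' @param path TSV path.
#' @return Data frame of antigen-database entries.
#' @export
read_antigen_db <- function(path) {
  db <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = "character", fileEncoding = "UTF-8")
  map <- c(v.segm = "v_gene", j.segm = "j_gene", cdr3 = "cdr3_aa",
           antigen.epitope = "epitope", antigen.species = "antigen_species",
           mhc.a = "hla_restriction")
  for (old in names(map)) {
    if (old %in% names(db) && !(map[[old]] %in% names(db))) {
      names(db)[names(db) == old] <- map[[old]]
    }
  }
  need <- c("v_gene", "j_gene", "cdr3_aa", "epitope", "antigen_species",
            "hla_restriction")
  missing_cols <- setdiff(need, names(db))
  if (length(missing_cols) > 0L) {
    stop("antigen table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  db <- db[need]
  if (any(!nzchar(as.matrix(db)))) stop("antigen table has empty fields")
  db$hla_restriction <- normalize_allele(db$hla_restriction)
  db$cdr3_aa <- toupper(db$cdr3_aa)
  db
}

#' Annotate a repertoire against an antigen database
#'
#' A clonotype is annotated when a database entry matches its V gene,
#' J gene and CDR3 amino-acid sequence exactly and the entry's HLA
#' restriction is carried by the subject (field-prefix matching across
#' typing resolutions). All matching entries are returned.
#'
#' @param sample Data frame of clonotype records (or aggregated table).
#' @param db Antigen table (see [read_antigen_db()]).
#' @param subject_hla Character vector of the subject's HLA alleles, or a
#'   comma-separated string.
#' @return Data frame with one row per (clonotype, matching entry):
#'   key columns plus `epitope`, `antigen_species`, `hla_restriction`.
#' @export
annotate_repertoire <- function(sample, db, subject_hla) {
  if (length(subject_hla) == 1L && grepl(",", subject_hla)) {
    subject_hla <- subject_alleles(subject_hla)
  }
  subject_hla <- subject_hla[nzchar(subject_hla)]
  agg <- if ("junction" %in% names(sample)) aggregate_to_aa(sample) else sample
  if (nrow(agg) == 0L || nrow(db) == 0L || length(subject_hla) == 0L) {
    return(data.frame(v_call = character(), j_call = character(),
                      junction_aa = character(), epitope = character(),
                      antigen_species = character(),
                      hla_restriction = character(), stringsAsFactors = FALSE))
  }
  db_ok <- db[vapply(db$hla_restriction, function(a)
    any(allele_matches(a, subject_hla)), logical(1)), , drop = FALSE]
  if (nrow(db_ok) == 0L) {
    return(data.frame(v_call = character(), j_call = character(),
                      junction_aa = character(), epitope = character(),
                      antigen_species = character(),
                      hla_restriction = character(), stringsAsFactors = FALSE))
  }
  m <- merge(agg[c("v_call", "j_call", "junction_aa")],
             db_ok, by.x = c("v_call", "j_call", "junction_aa"),
             by.y = c("v_gene", "j_gene", "cdr3_aa"))
  out <- m[c("v_call", "j_call", "junction_aa", "epitope", "antigen_species",
             "hla_restriction")]
  out <- out[order(out$junction_aa, out$v_call, out$j_call, out$epitope), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotated fraction of a repertoire per antigen species
#'
#' Each annotated clonotype is assigned to a single species (the majority
#' species among its matching entries, ties broken alphabetically) so the
#' per-species fractions sum to at most 1.
#'
#' @param sample Sample records (or aggregated table).
#' @param annotations Output of [annotate_repertoire()].
#' @param by `"reads"` (abundance-weighted, default) or `"clonotypes"`.
#' @return Named numeric vector of fractions per species (empty when there
#'   are no annotations).
#' @export
annotated_fraction <- function(sample, annotations,
                               by = c("reads", "clonotypes")) {
  by <- match.arg(by)
  agg <- if ("junction" %in% names(sample)) aggregate_to_aa(sample) else sample
  if (nrow(annotations) == 0L || nrow(agg) == 0L) {
    return(setNames(numeric(0), character(0)))
  }
  akey <- aa_key(annotations$v_call, annotations$j_call,
                 annotations$junction_aa)
  species <- vapply(split(annotations$antigen_species, akey), function(s) {
    tab <- sort(table(s), decreasing = TRUE)
    names(tab)[tab == tab[1L]][1L]
  }, character(1))
  gkey <- aa_key(agg$v_call, agg$j_call, agg$junction_aa)
  w <- if (by == "reads") as.numeric(agg$duplicate_count) else
    rep(1, nrow(agg))
  tot <- sum(w)
  sp <- species[match(gkey, names(species))]
  hit <- !is.na(sp)
  if (!any(hit)) return(setNames(numeric(0), character(0)))
  frac <- vapply(split(w[hit], sp[hit]), sum, numeric(1)) / tot
  frac[order(-frac, names(frac))]
}
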