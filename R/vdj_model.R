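#' Simplified V(D)J recombination generative model
#'
#' Defines the generative process behind CDR3 generation probabilities
#' (P_GEN): a V 3'-flank (beginning at the conserved-C codon) truncated by
#' exonuclease deletions, non-templated VD insertions, a truncated D segment,
#' DJ insertions, and a truncated J 5'-flank (ending at the conserved-F
#' codon). Segment usage, per-segment deletion profiles, insertion-length
#' distributions and an i.i.d. insertion nucleotide distribution are all
#' explicit probability tables.
#'
#' D usage is independent of J, there are no palindromic (negative)
#' deletions, and insertion nucleotides are i.i.d.; these simplifications
#' keep the scenario space exactly enumerable on small models. The maximum
#' supported 5' plus 3' D deletions must not exceed the D length so that
#' every deletion combination yields a valid scenario and total scenario
#' probability is exactly 1.
#'
#' @param v,j Data frames with columns `name`, `seq`, `prob` (V 3'-flanks /
#'   J 5'-flanks).
#' @param d Data frame with columns `name`, `seq`, `prob`.
#' @param v_del,j_del Matrices of deletion probabilities; row `k` is
#'   `P(del = k - 1)`, one column per segment.
#' @param d_del5,d_del3 Deletion matrices for the D 5' and 3' ends.
#' @param ins_vd,ins_dj Numeric vectors of insertion-length probabilities
#'   (index `k` is length `k - 1`).
#' @param nt_prob Length-4 probability vector over A, C, G, T for insertion
#'   nucleotides.
#' @return An object of class `vdj_model`.
#' @export
vdj_model <- function(v, j, d, v_del, j_del, d_del5, d_del3,
                      ins_vd, ins_dj, nt_prob) {
  chk_probs <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-12) {
      stop(what, " probabilities must be non-negative and sum to 1")
    }
  }
  for (seg in list(v, j, d)) {
    stopifnot(all(c("name", "seq", "prob") %in% names(seg)))
    if (any(nchar(seg$seq) == 0L)) stop("segment sequences must be non-empty")
    if (any(!grepl("^[ACGT]+$", seg$seq))) stop("segment sequences must be A/C/G/T")
  }
  chk_probs(v$prob, "V usage"); chk_probs(j$prob, "J usage"); chk_probs(d$prob, "D usage")
  chk_del <- function(m, seqs, what) {
    m <- as.matrix(m)
    if (ncol(m) != length(seqs)) stop(what, ": one column per segment required")
    for (i in seq_along(seqs)) {
      chk_probs(m[, i], what)
      supp <- which(m[, i] > 0) - 1L
      if (length(supp) && max(supp) > nchar(seqs[i])) {
        stop(what, ": deletions exceed segment length for segment ", i)
      }
    }
    m
  }
  v_del <- chk_del(v_del, v$seq, "V deletions")
  j_del <- chk_del(j_del, j$seq, "J deletions")
  d_del5 <- chk_del(d_del5, d$seq, "D 5' deletions")
  d_del3 <- chk_del(d_del3, d$seq, "D 3' deletions")
  max5 <- apply(d_del5, 2, function(p) max(which(p > 0)) - 1L)
  max3 <- apply(d_del3, 2, function(p) max(which(p > 0)) - 1L)
  if (any(max5 + max3 > nchar(d$seq))) {
    stop("supported D 5' + 3' deletions exceed the D segment length")
  }
  chk_probs(ins_vd, "VD insertion length"); chk_probs(ins_dj, "DJ insertion length")
  chk_probs(nt_prob, "insertion nucleotide")
  if (length(nt_prob) != 4L) stop("nt_prob must have 4 entries (A, C, G, T)")
  structure(list(
    v = data.frame(name = as.character(v$name), seq = toupper(v$seq),
                   prob = v$prob, stringsAsFactors = FALSE),
    j = data.frame(name = as.character(j$name), seq = toupper(j$seq),
                   prob = j$prob, stringsAsFactors = FALSE),
    d = data.frame(name = as.character(d$name), seq = toupper(d$seq),
                   prob = d$prob, stringsAsFactors = FALSE),
    v_del = v_del, j_del = j_del, d_del5 = d_del5, d_del3 = d_del3,
    ins_vd = as.numeric(ins_vd), ins_dj = as.numeric(ins_dj),
    nt_prob = setNames(as.numeric(nt_prob), NT_ALPHABET)
  ), class = "vdj_model")
}

#' @export
print.vdj_model <- function(x, ...) {
  cat("V(D)J recombination model\n")
  cat("  V segments:", nrow(x$v), " J segments:", nrow(x$j),
      " D segments:", nrow(x$d), "\n")
  cat("  max deletions (V/J/D5/D3):", nrow(x$v_del) - 1L, nrow(x$j_del) - 1L,
      nrow(x$d_del5) - 1L, nrow(x$d_del3) - 1L, "\n")
  cat("  max insertions (VD/DJ):", length(x$ins_vd) - 1L,
      length(x$ins_dj) - 1L, "\n")
  invisible(x)
}

# Flattened representation consumed by the compiled kernels.
model_for_cpp <- function(model) {
  list(v_seq = model$v$seq, v_prob = model$v$prob, v_del = model$v_del,
       j_seq = model$j$seq, j_prob = model$j$prob, j_del = model$j_del,
       d_seq = model$d$seq, d_prob = model$d$prob,
       d_del5 = model$d_del5, d_del3 = model$d_del3,
       ins_vd = model$ins_vd, ins_dj = model$ins_dj,
       nt_prob = unname(model$nt_prob))
}

segment_mask <- function(names_avail, keep, what) {
  if (is.null(keep)) return(integer(0))
  idx <- match(keep, names_avail)
  if (anyNA(idx)) stop("unknown ", what, " segment: ", keep[which(is.na(idx))[1L]])
  as.integer(names_avail %in% keep)
}

#' Toy generative model with an enumerable scenario space
#'
#' A deliberately small model (6 V, 2 D, 4 J, deletions and insertions of at
#' most 1) whose complete scenario and sequence spaces can be enumerated
#' exactly, used as the reference fixture for generation-probability oracles.
#'
#' @return A `vdj_model`.
#' @export
toy_vdj_model <- function() {
  v <- data.frame(name = paste0("TRBV", 1:6),
                  seq = c("TGTG", "TGTC", "TGTA", "TGCG", "TGCT", "TGCA"),
                  prob = c(0.30, 0.20, 0.15, 0.15, 0.10, 0.10))
  j <- data.frame(name = paste0("TRBJ", 1:4),
                  seq = c("CTTT", "ATTT", "GTTC", "TTTC"),
                  prob = c(0.4, 0.3, 0.2, 0.1))
  d <- data.frame(name = c("TRBD1", "TRBD2"), seq = c("GGG", "ACC"),
                  prob = c(0.6, 0.4))
  vdj_model(
    v = v, j = j, d = d,
    v_del = rbind(c(0.70, 0.60, 0.80, 0.65, 0.75, 0.70),
                  c(0.30, 0.40, 0.20, 0.35, 0.25, 0.30)),
    j_del = rbind(c(0.8, 0.7, 0.75, 0.6), c(0.2, 0.3, 0.25, 0.4)),
    d_del5 = rbind(c(0.7, 0.6), c(0.3, 0.4)),
    d_del3 = rbind(c(0.65, 0.75), c(0.35, 0.25)),
    ins_vd = c(0.6, 0.4), ins_dj = c(0.5, 0.5),
    nt_prob = c(0.2, 0.3, 0.3, 0.2)
  )
}

#' Default cohort-scale generative model
#'
#' A larger model producing realistic CDR3 lengths (roughly 11-15 amino
#' acids, conserved C...F frame) used by the synthetic cohort generator.
#' Flanks begin at the conserved-C codon (V side) and end at the
#' conserved-F codon (J side); insertion nucleotides are G/C-biased as
#' expected for TdT additions.
#'
#' @return A `vdj_model`.
#' @export
default_vdj_model <- function() {
  v <- data.frame(
    name = c("TRBV2", "TRBV5", "TRBV7", "TRBV9", "TRBV12", "TRBV19",
             "TRBV20", "TRBV28"),
    seq = c("TGTGCCAGCAGCCTA", "TGTGCCAGCAGCTTA", "TGTGCCAGCAGTGAA",
            "TGTGCCAGCAGCGTA", "TGTGCCAGCAGTTTA", "TGTGCCAGTAGTATA",
            "TGCAGTGCTAGAGAT", "TGTGCCAGCAGTCTC"),
    prob = c(0.16, 0.14, 0.14, 0.13, 0.12, 0.12, 0.10, 0.09))
  j <- data.frame(
    name = c("TRBJ1-1", "TRBJ1-2", "TRBJ1-5", "TRBJ2-1", "TRBJ2-2",
             "TRBJ2-3", "TRBJ2-5", "TRBJ2-7"),
    seq = c("AACACTGAAGCTTTC", "TATGGCTACACCTTC", "CAGCCCCAGCATTTT",
            "AATGAGCAGTTCTTC", "ACCGGGGAGCTGTTT", "GATACGCAGTATTTT",
            "GAGACCCAGTACTTC", "TACGAGCAGTACTTC"),
    prob = c(0.15, 0.14, 0.13, 0.13, 0.12, 0.12, 0.11, 0.10))
  d <- data.frame(name = c("TRBD1", "TRBD2"),
                  seq = c("GGGACAGGGGGC", "GGGACTAGCGGG"),
                  prob = c(0.55, 0.45))
  geomish <- function(k, r) { p <- r ^ (0:k); p / sum(p) }
  vdj_model(
    v = v, j = j, d = d,
    v_del = vapply(seq_len(nrow(v)), function(i) geomish(4, 0.65), numeric(5)),
    j_del = vapply(seq_len(nrow(j)), function(i) geomish(4, 0.70), numeric(5)),
    d_del5 = vapply(1:2, function(i) geomish(6, 0.75), numeric(7)),
    d_del3 = vapply(1:2, function(i) geomish(6, 0.72), numeric(7)),
    ins_vd = geomish(8, 0.70), ins_dj = geomish(8, 0.70),
    nt_prob = c(A = 0.18, C = 0.28, G = 0.34, T = 0.20)
  )
}

sample_del <- function(del_mat, seg_idx) {
  out <- integer(length(seg_idx))
  for (s in unique(seg_idx)) {
    i <- which(seg_idx == s)
    out[i] <- sample.int(nrow(del_mat), length(i), replace = TRUE,
                         prob = del_mat[, s]) - 1L
  }
  out
}

sample_ins <- function(ins_prob, nt_prob, n) {
  len <- sample.int(length(ins_prob), n, replace = TRUE, prob = ins_prob) - 1L
  total <- sum(len)
  out <- character(n)
  out[len == 0L] <- ""
  if (total > 0L) {
    bases <- sample(NT_ALPHABET, total, replace = TRUE, prob = nt_prob)
    idx <- rep.int(seq_len(n), len)
    out[len > 0L] <- vapply(split(bases, idx), paste, character(1), collapse = "")
  }
  list(len = len, seq = out)
}

#' Sample recombination events from a generative model
#'
#' Draws complete recombination scenarios (segment choices, deletions,
#' insertions) and realizes their CDR3 nucleotide strings. Reproducible via
#' the R random number generator; call `set.seed()` beforehand or pass
#' `seed`.
#'
#' @param model A `vdj_model`.
#' @param n Number of rearrangements to draw.
#' @param seed Optional integer seed.
#' @return Data frame with columns `cdr3_nt`, `v_name`, `d_name`, `j_name`,
#'   `del_v`, `del_d5`, `del_d3`, `del_j`, `ins_vd`, `ins_dj`.
#' @export
sample_rearrangement <- function(model, n = 1L, seed = NULL) {
  stopifnot(inherits(model, "vdj_model"))
  if (!is.null(seed)) set.seed(seed)
  vi <- sample.int(nrow(model$v), n, replace = TRUE, prob = model$v$prob)
  ji <- sample.int(nrow(model$j), n, replace = TRUE, prob = model$j$prob)
  di <- sample.int(nrow(model$d), n, replace = TRUE, prob = model$d$prob)
  dv <- sample_del(model$v_del, vi)
  dj <- sample_del(model$j_del, ji)
  d5 <- sample_del(model$d_del5, di)
  d3 <- sample_del(model$d_del3, di)
  ivd <- sample_ins(model$ins_vd, model$nt_prob, n)
  idj <- sample_ins(model$ins_dj, model$nt_prob, n)
  vlen <- nchar(model$v$seq)[vi]
  jlen <- nchar(model$j$seq)[ji]
  dlen <- nchar(model$d$seq)[di]
  vpart <- substr(model$v$seq[vi], 1L, vlen - dv)
  jpart <- substr(model$j$seq[ji], dj + 1L, jlen)
  dpart <- substr(model$d$seq[di], d5 + 1L, dlen - d3)
  data.frame(
    cdr3_nt = paste0(vpart, ivd$seq, dpart, idj$seq, jpart),
    v_name = model$v$name[vi], d_name = model$d$name[di],
    j_name = model$j$name[ji],
    del_v = dv, del_d5 = d5, del_d3 = d3, del_j = dj,
    ins_vd = ivd$seq, ins_dj = idj$seq, stringsAsFactors = FALSE)
}

#' Generation probability of a nucleotide CDR3
#'
#' Sums the probabilities of every recombination scenario realizing the
#' string, organised as a dynamic program over V-prefix match length,
#' J-suffix match length and D placement within the remaining middle
#' segment (no scenario enumeration).
#'
#' @param model A `vdj_model`.
#' @param cdr3_nt Character vector of nucleotide strings over A/C/G/T.
#' @param v,j Optional segment names restricting the scenario sum to fixed
#'   V and/or J attributions (by default P_GEN marginalizes over all pairs).
#' @return Numeric vector of probabilities in `[0, 1]` (0 when no scenario
#'   realizes the string).
#' @export
pgen_nt <- function(model, cdr3_nt, v = NULL, j = NULL) {
  stopifnot(inherits(model, "vdj_model"))
  if (any(!grepl("^[ACGT]+$", cdr3_nt))) {
    stop("cdr3_nt must be non-empty strings over A/C/G/T")
  }
  mc <- model_for_cpp(model)
  vm <- segment_mask(model$v$name, v, "V")
  jm <- segment_mask(model$j$name, j, "J")
  vapply(cdr3_nt, function(s) .pgen_nt_cpp(mc, s, vm, jm), numeric(1),
         USE.NAMES = FALSE)
}

#' Generation probability of an amino-acid CDR3
#'
#' Equals the sum of [pgen_nt()] over every nucleotide string translating to
#' the amino-acid sequence, computed by codon-level dynamic programming that
#' marginalizes synonymous codings (never by explicit expansion).
#'
#' @param model A `vdj_model`.
#' @param cdr3_aa Character vector over the 20-letter amino-acid alphabet.
#' @param v,j Optional segment-name restrictions as in [pgen_nt()].
#' @return Numeric vector of probabilities.
#' @export
pgen_aa <- function(model, cdr3_aa, v = NULL, j = NULL) {
  stopifnot(inherits(model, "vdj_model"))
  cdr3_aa <- toupper(cdr3_aa)
  mc <- model_for_cpp(model)
  gci <- genetic_code_int()
  vm <- segment_mask(model$v$name, v, "V")
  jm <- segment_mask(model$j$name, j, "J")
  vapply(cdr3_aa, function(s) {
    aa <- match(strsplit(s, "")[[1L]], AA_ALPHABET) - 1L
    if (anyNA(aa) || length(aa) == 0L) {
      stop("cdr3_aa must be non-empty strings over the 20 amino acids: ", s)
    }
    .pgen_aa_cpp(mc, aa, gci, vm, jm)
  }, numeric(1), USE.NAMES = FALSE)
}

# Full scenario table of a small model (one row per scenario), with realized
# strings and probabilities. Guarded by total scenario-space size.
scenario_table <- function(model, guard = 1e7) {
  nv <- nrow(model$v); nj <- nrow(model$j); nd <- nrow(model$d)
  max_ivd <- length(model$ins_vd) - 1L
  max_idj <- length(model$ins_dj) - 1L
  n_ins <- function(maxlen) sum(4 ^ (0:maxlen))
  space <- nv * nrow(model$v_del) * nj * nrow(model$j_del) *
    nd * nrow(model$d_del5) * nrow(model$d_del3) *
    n_ins(max_ivd) * n_ins(max_idj)
  if (space > guard) {
    stop("scenario space too large to enumerate (about ",
         format(space, big.mark = ","), " scenarios; guard is ",
         format(guard, big.mark = ","), ")")
  }
  all_ins <- function(maxlen) {
    out <- ""
    for (k in seq_len(maxlen)) {
      out <- c(out, apply(do.call(expand.grid, rep(list(NT_ALPHABET), k)),
                          1L, paste, collapse = ""))
    }
    out
  }
  g <- expand.grid(vi = seq_len(nv), dv = seq_len(nrow(model$v_del)) - 1L,
                   di = seq_len(nd), d5 = seq_len(nrow(model$d_del5)) - 1L,
                   d3 = seq_len(nrow(model$d_del3)) - 1L,
                   ji = seq_len(nj), dj = seq_len(nrow(model$j_del)) - 1L,
                   ivd = all_ins(max_ivd), idj = all_ins(max_idj),
                   stringsAsFactors = FALSE)
  g$ivd <- as.character(g$ivd); g$idj <- as.character(g$idj)
  keep <- model$v_del[cbind(g$dv + 1L, g$vi)] > 0 &
    model$j_del[cbind(g$dj + 1L, g$ji)] > 0 &
    model$d_del5[cbind(g$d5 + 1L, g$di)] > 0 &
    model$d_del3[cbind(g$d3 + 1L, g$di)] > 0 &
    g$dv <= nchar(model$v$seq)[g$vi] & g$dj <= nchar(model$j$seq)[g$ji] &
    g$d5 + g$d3 <= nchar(model$d$seq)[g$di]
  g <- g[keep, , drop = FALSE]
  pnt <- model$nt_prob
  ins_p <- function(s, len_prob) {
    len <- nchar(s)
    w <- len_prob[len + 1L]
    chars <- strsplit(s, "")
    w * vapply(chars, function(cc) prod(pnt[cc]), numeric(1))
  }
  vlen <- nchar(model$v$seq)[g$vi]; jlen <- nchar(model$j$seq)[g$ji]
  dlen <- nchar(model$d$seq)[g$di]
  g$cdr3_nt <- paste0(substr(model$v$seq[g$vi], 1L, vlen - g$dv),
                      g$ivd,
                      substr(model$d$seq[g$di], g$d5 + 1L, dlen - g$d3),
                      g$idj,
                      substr(model$j$seq[g$ji], g$dj + 1L, jlen))
  g$prob <- model$v$prob[g$vi] * model$v_del[cbind(g$dv + 1L, g$vi)] *
    model$j$prob[g$ji] * model$j_del[cbind(g$dj + 1L, g$ji)] *
    model$d$prob[g$di] * model$d_del5[cbind(g$d5 + 1L, g$di)] *
    model$d_del3[cbind(g$d3 + 1L, g$di)] *
    ins_p(g$ivd, model$ins_vd) * ins_p(g$idj, model$ins_dj)
  g$v_name <- model$v$name[g$vi]
  g$d_name <- model$d$name[g$di]
  g$j_name <- model$j$name[g$ji]
  g
}

#' Enumerate the recombination scenarios realizing a CDR3
#'
#' Exhaustively lists every scenario of a small model that realizes the
#' given nucleotide string, with its probability. Serves as the independent
#' brute-force oracle for [pgen_nt()]; refuses models whose scenario space
#' exceeds the guard.
#'
#' @param model A `vdj_model`.
#' @param cdr3_nt A single nucleotide string.
#' @param guard Maximum scenario-space size (default `1e7`).
#' @return Data frame of scenarios (segment choices, deletions, insertion
#'   strings, `prob`); zero rows when the string is not realizable.
#' @export
enumerate_scenarios <- function(model, cdr3_nt, guard = 1e7) {
  stopifnot(inherits(model, "vdj_model"), length(cdr3_nt) == 1L)
  tab <- scenario_table(model, guard)
  out <- tab[tab$cdr3_nt == cdr3_nt,
             c("v_name", "d_name", "j_name", "dv", "d5", "d3", "dj",
               "ivd", "idj", "prob"), drop = FALSE]
  names(out) <- c("v_name", "d_name", "j_name", "del_v", "del_d5", "del_d3",
                  "del_j", "ins_vd", "ins_dj", "prob")
  rownames(out) <- NULL
  out
}

#' Enumerate every generatable sequence of a small model
#'
#' @param model A `vdj_model` with an enumerable scenario space.
#' @param guard Maximum scenario-space size.
#' @return Data frame with columns `cdr3_nt` and `prob` (total generation
#'   probability, summed over scenarios); probabilities sum to 1.
#' @export
enumerate_sequences <- function(model, guard = 1e7) {
  tab <- scenario_table(model, guard)
  p <- rowsum(tab$prob, tab$cdr3_nt)
  data.frame(cdr3_nt = rownames(p), prob = as.numeric(p),
             stringsAsFactors = FALSE)
}

# Enumerate the amino-acid clonotype key space (V, J, CDR3 aa) of a small
# model, with per-key generation probability restricted to that (V, J) pair.
# Keys exist only for in-frame, stop-free sequences.
enumerate_keys <- function(model, guard = 1e7) {
  tab <- scenario_table(model, guard)
  ok <- nchar(tab$cdr3_nt) %% 3L == 0L
  tab <- tab[ok, , drop = FALSE]
  aa <- translate_nt_or_na(tab$cdr3_nt)
  keep <- !is.na(aa)
  tab <- tab[keep, , drop = FALSE]
  aa <- aa[keep]
  id <- paste(tab$v_name, tab$j_name, aa, sep = "|")
  p <- rowsum(tab$prob, id)
  parts <- strsplit(rownames(p), "|", fixed = TRUE)
  data.frame(v_name = vapply(parts, `[`, character(1), 1L),
             j_name = vapply(parts, `[`, character(1), 2L),
             cdr3_aa = vapply(parts, `[`, character(1), 3L),
             pgen = as.numeric(p), stringsAsFactors = FALSE)
}

# Translation that returns NA for sequences containing stop codons.
translate_nt_or_na <- function(nt) {
  gc <- genetic_code()
  vapply(nt, function(s) {
    n <- nchar(s)
    if (n == 0L || n %% 3L != 0L) return(NA_character_)
    aa <- gc[substring(s, seq(1L, n, 3L), seq(3L, n, 3L))]
    if (anyNA(aa) || any(aa == "*")) return(NA_character_)
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Serialize / deserialize a generative model as YAML
#'
#' @param model A `vdj_model`.
#' @param path File path.
#' @return `read_vdj_model` returns a `vdj_model`.
#' @export
write_vdj_model <- function(model, path) {
  stopifnot(inherits(model, "vdj_model"))
  obj <- list(
    v = list(name = model$v$name, seq = model$v$seq, prob = model$v$prob,
             del = as.list(as.data.frame(model$v_del))),
    j = list(name = model$j$name, seq = model$j$seq, prob = model$j$prob,
             del = as.list(as.data.frame(model$j_del))),
    d = list(name = model$d$name, seq = model$d$seq, prob = model$d$prob,
             del5 = as.list(as.data.frame(model$d_del5)),
             del3 = as.list(as.data.frame(model$d_del3))),
    ins_vd = model$ins_vd, ins_dj = model$ins_dj,
    nt_prob = as.list(model$nt_prob))
  yaml::write_yaml(obj, path, precision = 17L)
  invisible(path)
}

#' @rdname write_vdj_model
#' @export
read_vdj_model <- function(path) {
  obj <- yaml::read_yaml(path)
  as_mat <- function(lst) do.call(cbind, lapply(lst, as.numeric))
  vdj_model(
    v = data.frame(name = obj$v$name, seq = obj$v$seq, prob = obj$v$prob),
    j = data.frame(name = obj$j$name, seq = obj$j$seq, prob = obj$j$prob),
    d = data.frame(name = obj$d$name, seq = obj$d$seq, prob = obj$d$prob),
    v_del = as_mat(obj$v$del), j_del = as_mat(obj$j$del),
    d_del5 = as_mat(obj$d$del5), d_del3 = as_mat(obj$d$del3),
    ins_vd = as.numeric(obj$ins_vd), ins_dj = as.numeric(obj$ins_dj),
    nt_prob = as.numeric(unlist(obj$nt_prob)))
}
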