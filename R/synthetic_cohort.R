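#' Simulation configuration for synthetic longitudinal cohorts
#'
#' Encodes the study design being emulated: a multi-subject cohort sampled
#' at fixed timepoints in four sorted T-cell subsets, power-law (Zipf)
#' clone-size distributions, per-interval attrition of dominant memory
#' clones, low-overlap near-flat naive subsets, and public clonotypes
#' injected across subjects with multiple synonymous nucleotide encodings.
#'
#' @param n_subjects Number of subjects (default 13).
#' @param timepoints Months, strictly increasing from 0
#'   (default `c(0, 6, 12, 24, 36)`).
#' @param subsets Cell subsets (default CD4/CD8 x naive RA / memory RO).
#' @param clones_per_sample Distinct amino-acid clonotypes per sample.
#' @param alpha Zipf exponent of memory clone sizes at baseline (default 1).
#' @param alpha_step Per-interval increase of the memory exponent,
#'   producing the progressive post-ablation skew (default 0.2).
#' @param naive_alpha Zipf exponent for naive subsets (near-flat, 0.3).
#' @param umis_per_sample Total molecules sampled per repertoire.
#' @param mean_reads_per_umi Mean sequencing reads per molecule (>= 3
#'   recommended so directional UMI collapse is unambiguous at zero error).
#' @param read_jitter Extra Poisson reads per molecule (default 0.5).
#' @param dominant_n Size of the dominant-clone set (default 100).
#' @param dominant_survival Per-interval survival probability of dominant
#'   memory clones (default 0.66, matching roughly 19% four-interval
#'   persistence).
#' @param background_survival Per-interval survival of non-dominant memory
#'   clones (default 0.5).
#' @param naive_survival Per-interval survival in naive subsets (0.2).
#' @param n_public Number of injected public clonotypes.
#' @param subjects_per_public Subjects sharing each public clone.
#' @param encoding_probs Probabilities of 1..5 distinct nucleotide
#'   encodings per public clone.
#' @param public_subset Subset receiving the injected public clones.
#' @param risk_allele_carriers Number of subjects carrying the class II
#'   risk allele DRB1*15:01 (default about 40% of the cohort).
#' @param selection Optional `selection_model` used to reweight baseline
#'   clone generation (planted selection).
#' @param error_rate Per-base substitution rate for simulated reads.
#' @param seed Integer seed.
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(n_subjects = 13L,
                              timepoints = c(0L, 6L, 12L, 24L, 36L),
                              subsets = c("CD4_RA", "CD4_RO", "CD8_RA", "CD8_RO"),
                              clones_per_sample = 300L,
                              alpha = 1.0, alpha_step = 0.2, naive_alpha = 0.3,
                              umis_per_sample = 3000L,
                              mean_reads_per_umi = 3L, read_jitter = 0.5,
                              dominant_n = 100L,
                              dominant_survival = 0.66,
                              background_survival = 0.5,
                              naive_survival = 0.2,
                              n_public = 30L, subjects_per_public = 3L,
                              encoding_probs = c(0.75, 0.15, 0.05, 0.03, 0.02),
                              public_subset = "CD4_RO",
                              risk_allele_carriers = ceiling(0.4 * n_subjects),
                              selection = NULL,
                              error_rate = 0.001,
                              seed = 1L) {
  stopifnot(length(timepoints) >= 1L, timepoints[1L] == 0L,
            !is.unsorted(timepoints, strictly = TRUE),
            all(c(dominant_survival, background_survival, naive_survival) >= 0),
            all(c(dominant_survival, background_survival, naive_survival) <= 1),
            abs(sum(encoding_probs) - 1) < 1e-9,
            umis_per_sample >= 3L * clones_per_sample,
            clones_per_sample > 0L, n_subjects >= 1L)
  structure(list(
    n_subjects = as.integer(n_subjects), timepoints = as.integer(timepoints),
    subsets = subsets, clones_per_sample = as.integer(clones_per_sample),
    alpha = alpha, alpha_step = alpha_step, naive_alpha = naive_alpha,
    umis_per_sample = as.integer(umis_per_sample),
    mean_reads_per_umi = as.integer(mean_reads_per_umi),
    read_jitter = read_jitter,
    dominant_n = as.integer(dominant_n),
    dominant_survival = dominant_survival,
    background_survival = background_survival,
    naive_survival = naive_survival,
    n_public = as.integer(n_public),
    subjects_per_public = as.integer(subjects_per_public),
    encoding_probs = encoding_probs, public_subset = public_subset,
    risk_allele_carriers = as.integer(risk_allele_carriers),
    selection = selection, error_rate = error_rate,
    seed = as.integer(seed)), class = "sim_config")
}

is_memory_subset <- function(subset) grepl("RO$", subset)

# Draw `n` distinct productive clonotype keys (optionally reweighted by a
# planted selection model), excluding keys already in `exclude`.
draw_clone_keys <- function(gen, n, exclude = character(0), selection = NULL) {
  out <- NULL
  tries <- 0L
  while (is.null(out) || nrow(out) < n) {
    tries <- tries + 1L
    if (tries > 50L) stop("unable to draw enough distinct clonotype keys")
    want <- n - if (is.null(out)) 0L else nrow(out)
    keys <- if (is.null(selection)) {
      generate_baseline(gen, max(200L, ceiling(want * 1.4)))$keys
    } else {
      simulate_selected_repertoire(gen, selection$lambda,
                                   max(200L, ceiling(want * 1.4)),
                                   pool_factor = 5L)
    }
    keys$key <- aa_key(keys$v_gene, keys$j_gene, keys$cdr3_aa)
    keys <- keys[!duplicated(keys$key) & !(keys$key %in% exclude), , drop = FALSE]
    out <- if (is.null(out)) keys else rbind(out, keys[!(keys$key %in% out$key), ])
  }
  out <- out[seq_len(n), c("v_gene", "j_gene", "cdr3_aa", "cdr3_nt", "key")]
  rownames(out) <- NULL
  out
}

# Silent (synonymous) recodings of a nucleotide CDR3, distinct from `avoid`
# and accepted only when `validate` holds (e.g. unchanged V/J attribution).
silent_variants <- function(cdr3_nt, n_extra, avoid = character(0),
                            validate = function(nt) TRUE) {
  gc <- genetic_code()
  syn <- split(names(gc), gc)
  codons <- substring(cdr3_nt, seq(1L, nchar(cdr3_nt), 3L),
                      seq(3L, nchar(cdr3_nt), 3L))
  out <- character(0)
  tries <- 0L
  while (length(out) < n_extra && tries < 200L) {
    tries <- tries + 1L
    new <- codons
    flip <- sample(seq_along(codons), min(length(codons), 1L + rpois(1L, 1)))
    for (i in flip) {
      alt <- syn[[gc[[new[i]]]]]
      new[i] <- sample(alt, 1L)
    }
    cand <- paste(new, collapse = "")
    if (!(cand %in% c(avoid, out, cdr3_nt)) && isTRUE(validate(cand))) {
      out <- c(out, cand)
    }
  }
  out
}

#' Simulate a longitudinal cohort with known ground truth
#'
#' Baseline repertoires are drawn from the generative model (optionally
#' reweighted by a planted selection model) with Zipf-distributed clone
#' sizes; at each subsequent timepoint every clone survives with its
#' subset- and dominance-specific per-interval probability and new clones
#' refill the repertoire. Dominance is defined on the emitted baseline
#' abundances with the same ranking rule the tracker uses. Public
#' clonotypes — amino-acid keys that recur among independent rearrangement
#' draws, i.e. products of convergent recombination — are injected with
#' identical keys across designated subjects and a configured number of
#' distinct synonymous nucleotide encodings.
#'
#' @param config A [simulation_config()].
#' @param gen A `vdj_model` (default [default_vdj_model()]).
#' @return A list with elements `cohort` (a [tcr_cohort()]) and `truth`
#'   (clone-level presence/frequency table, baseline dominant sets, public
#'   registry, generation probabilities of public vs sampled private
#'   clones, and the config).
#' @export
simulate_cohort <- function(config = simulation_config(),
                            gen = default_vdj_model()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  subjects <- sprintf("HSCT%02d", seq_len(config$n_subjects))

  # --- public registry: convergently generated keys shared across subjects
  publics <- NULL
  if (config$n_public > 0L) {
    pool <- sample_rearrangement(gen, max(20000L, 200L * config$n_public))
    aa <- translate_nt_or_na(pool$cdr3_nt)
    pool <- pool[!is.na(aa), , drop = FALSE]
    pool$cdr3_aa <- aa[!is.na(aa)]
    att <- attribute_vj(gen, pool$cdr3_nt)
    pool$v_gene <- att$v_gene
    pool$j_gene <- att$j_gene
    pool <- pool[!is.na(pool$v_gene) & !is.na(pool$j_gene), , drop = FALSE]
    pool$key <- aa_key(pool$v_gene, pool$j_gene, pool$cdr3_aa)
    tt <- table(pool$key)
    recurrent <- names(tt)[tt >= 2L]
    if (length(recurrent) < config$n_public) {
      stop("too few convergently generated keys for the requested publics (",
           length(recurrent), " < ", config$n_public, "); raise the pool size")
    }
    chosen <- sample(recurrent, config$n_public,
                     prob = as.numeric(tt[recurrent]))
    publics <- do.call(rbind, lapply(chosen, function(k) {
      rows <- pool[pool$key == k, , drop = FALSE]
      n_enc <- sample.int(5L, 1L, prob = config$encoding_probs)
      nts <- unique(rows$cdr3_nt)
      # extra encodings must keep the same sequence-derived V/J attribution
      same_att <- function(nt) {
        a <- attribute_vj(gen, nt)
        identical(a$v_gene, rows$v_gene[1L]) &&
          identical(a$j_gene, rows$j_gene[1L])
      }
      if (length(nts) < n_enc) {
        nts <- c(nts, silent_variants(nts[1L], n_enc - length(nts), nts,
                                      validate = same_att))
      }
      nts <- nts[seq_len(min(n_enc, length(nts)))]
      share <- sample(subjects, min(config$subjects_per_public,
                                    length(subjects)))
      data.frame(v_gene = rows$v_gene[1L], j_gene = rows$j_gene[1L],
                 cdr3_aa = rows$cdr3_aa[1L], key = k,
                 n_encodings = length(nts),
                 nt_variants = paste(nts, collapse = ","),
                 subjects = paste(sort(share), collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  }

  rec_list <- list()
  truth_list <- list()
  dom_list <- list()

  for (subj in subjects) {
    for (subset in config$subsets) {
      memory <- is_memory_subset(subset)
      inject <- if (!is.null(publics) && subset == config$public_subset) {
        publics[vapply(strsplit(publics$subjects, ","), function(s)
          subj %in% s, logical(1)), , drop = FALSE]
      }
      # baseline clone set
      n_base <- config$clones_per_sample
      exclude <- if (!is.null(inject) && nrow(inject)) inject$key else character(0)
      clones <- draw_clone_keys(gen, n_base, exclude = exclude,
                                selection = config$selection)
      state <- data.frame(
        v_gene = clones$v_gene, j_gene = clones$j_gene,
        cdr3_aa = clones$cdr3_aa, key = clones$key,
        nt_variants = clones$cdr3_nt, n_enc = 1L,
        is_public = FALSE, stringsAsFactors = FALSE)
      if (!is.null(inject) && nrow(inject) > 0L) {
        state <- rbind(state, data.frame(
          v_gene = inject$v_gene, j_gene = inject$j_gene,
          cdr3_aa = inject$cdr3_aa, key = inject$key,
          nt_variants = inject$nt_variants, n_enc = inject$n_encodings,
          is_public = TRUE, stringsAsFactors = FALSE))
      }
      dominant_keys <- character(0)

      for (ti in seq_along(config$timepoints)) {
        tp <- config$timepoints[ti]
        if (ti > 1L) {
          # survival draws over one interval, then refill
          p_surv <- if (!memory) config$naive_survival else
            ifelse(state$key %in% dominant_keys,
                   config$dominant_survival, config$background_survival)
          keep <- runif(nrow(state)) < p_surv
          state <- state[keep, , drop = FALSE]
          need <- config$clones_per_sample +
            sum(state$is_public) - nrow(state)
          if (need > 0L) {
            fresh <- draw_clone_keys(gen, need, exclude = state$key,
                                     selection = config$selection)
            state <- rbind(state, data.frame(
              v_gene = fresh$v_gene, j_gene = fresh$j_gene,
              cdr3_aa = fresh$cdr3_aa, key = fresh$key,
              nt_variants = fresh$cdr3_nt, n_enc = 1L,
              is_public = FALSE, stringsAsFactors = FALSE))
          }
        }
        n <- nrow(state)
        a_t <- if (memory) config$alpha + config$alpha_step * (ti - 1L) else
          config$naive_alpha
        w <- sample(n) ^ (-a_t)
        freq <- w / sum(w)
        floor_u <- ifelse(state$is_public, pmax(2L, state$n_enc), state$n_enc)
        spare <- config$umis_per_sample - sum(floor_u)
        if (spare < 0L) stop("umis_per_sample too small for the clone set")
        extra <- if (spare > 0L) as.integer(rmultinom(1L, spare, freq)) else 0L
        umis <- floor_u + extra
        reads <- umis * config$mean_reads_per_umi +
          rpois(n, config$read_jitter * umis)

        # one record per nucleotide variant
        var_split <- strsplit(state$nt_variants, ",", fixed = TRUE)
        nv <- lengths(var_split)
        u_var <- lapply(seq_len(n), function(i) {
          k <- nv[i]
          base <- rep(umis[i] %/% k, k)
          rem <- umis[i] %% k
          if (rem > 0L) base[seq_len(rem)] <- base[seq_len(rem)] + 1L
          base
        })
        r_var <- lapply(seq_len(n), function(i) {
          k <- nv[i]
          base <- rep(reads[i] %/% k, k)
          rem <- reads[i] %% k
          if (rem > 0L) base[seq_len(rem)] <- base[seq_len(rem)] + 1L
          base
        })
        rec <- data.frame(
          subject_id = subj, timepoint_months = tp, cell_subset = subset,
          v_call = rep.int(state$v_gene, nv), j_call = rep.int(state$j_gene, nv),
          junction = unlist(var_split),
          junction_aa = rep.int(state$cdr3_aa, nv),
          duplicate_count = unlist(r_var), umi_count = unlist(u_var),
          stringsAsFactors = FALSE)
        rec_list[[length(rec_list) + 1L]] <- rec

        truth_list[[length(truth_list) + 1L]] <- data.frame(
          subject_id = subj, timepoint_months = tp, cell_subset = subset,
          v_gene = state$v_gene, j_gene = state$j_gene,
          cdr3_aa = state$cdr3_aa, true_freq = freq,
          umi_count = umis, n_encodings = nv,
          is_public = state$is_public,
          stringsAsFactors = FALSE)

        if (ti == 1L) {
          # dominance on emitted abundances, same rule as the tracker
          agg <- aggregate_to_aa(rec)
          topn <- head(agg, config$dominant_n)
          dominant_keys <- aa_key(topn$v_call, topn$j_call, topn$junction_aa)
          dom_list[[length(dom_list) + 1L]] <- data.frame(
            subject_id = subj, cell_subset = subset,
            v_gene = topn$v_call, j_gene = topn$j_call,
            cdr3_aa = topn$junction_aa, stringsAsFactors = FALSE)
        }
      }
    }
  }

  clonotypes <- do.call(rbind, rec_list)
  hla <- vapply(seq_along(subjects), function(i) {
    base <- c(sprintf("A*%02d:01", sample(1:32, 1L)),
              sprintf("B*%02d:01", sample(7:57, 1L)))
    if (i <= config$risk_allele_carriers) {
      paste(c(base, "DRB1*15:01"), collapse = ",")
    } else {
      paste(c(base, sprintf("DRB1*%02d:01", sample(c(1, 3, 4, 7, 11, 13), 1L))),
            collapse = ",")
    }
  }, character(1))
  subj_df <- data.frame(subject_id = subjects, hla_alleles = hla,
                        treatment_group = "AHSCT", stringsAsFactors = FALSE)
  cohort <- tcr_cohort(clonotypes, subj_df)

  # generation probabilities: all publics plus a sample of private clones
  probs <- NULL
  base_truth <- do.call(rbind, truth_list)
  if (!is.null(publics)) {
    priv <- base_truth[base_truth$timepoint_months == 0L &
                         base_truth$cell_subset == config$public_subset &
                         !base_truth$is_public, , drop = FALSE]
    priv <- priv[!duplicated(aa_key(priv$v_gene, priv$j_gene, priv$cdr3_aa)), ]
    priv <- priv[sample.int(nrow(priv), min(200L, nrow(priv))), , drop = FALSE]
    qk <- rbind(
      data.frame(v_gene = publics$v_gene, j_gene = publics$j_gene,
                 cdr3_aa = publics$cdr3_aa, group = "public",
                 stringsAsFactors = FALSE),
      data.frame(v_gene = priv$v_gene, j_gene = priv$j_gene,
                 cdr3_aa = priv$cdr3_aa, group = "private",
                 stringsAsFactors = FALSE))
    qk$pgen <- vapply(seq_len(nrow(qk)), function(i)
      pgen_aa(gen, qk$cdr3_aa[i], v = qk$v_gene[i], j = qk$j_gene[i]),
      numeric(1))
    if (!is.null(config$selection)) {
      qk$ppost <- qk$pgen * exp(log_q(config$selection, qk$v_gene, qk$j_gene,
                                      qk$cdr3_aa))
    } else {
      qk$ppost <- qk$pgen
    }
    probs <- qk
  }

  list(cohort = cohort,
       truth = list(clones = base_truth,
                    dominant_baseline = do.call(rbind, dom_list),
                    public_registry = publics,
                    probabilities = probs,
                    config = config))
}

#' Simulate structured reads for one repertoire sample
#'
#' Emits one molecule per ground-truth UMI with a random UMI tag, spreads
#' the record's reads as evenly as possible over its molecules, and applies
#' i.i.d. per-base substitution errors. Reads follow the
#' [read_structure()] layout (adapter + UMI + spacer + CDR3 insert).
#'
#' @param sample Data frame of clonotype records (see [get_sample()]).
#' @param structure A [read_structure()].
#' @param error_rate Per-base substitution probability.
#' @param seed Optional integer seed.
#' @param path Optional FASTQ output path (4-line records, constant
#'   quality, Phred+33).
#' @return Invisibly, the character vector of read sequences (also written
#'   to `path` when given). The attribute `umi_truth` holds, per input
#'   record, the number of *distinct* UMI tags drawn — the quantity a UMI
#'   pipeline can recover, which falls below the molecule count when tags
#'   collide (birthday effect in the 4^umi_length tag space).
#' @export
simulate_reads <- function(sample, structure = read_structure(),
                           error_rate = 0, seed = NULL, path = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ulen <- structure$umi_length
  reads_out <- vector("list", nrow(sample))
  umi_truth <- integer(nrow(sample))
  for (i in seq_len(nrow(sample))) {
    m <- sample$umi_count[i]
    r <- sample$duplicate_count[i]
    umis <- vapply(seq_len(m), function(k)
      paste(sample(NT_ALPHABET, ulen, replace = TRUE), collapse = ""),
      character(1))
    umi_truth[i] <- length(unique(umis))
    per_mol <- rep(r %/% m, m)
    rem <- r %% m
    if (rem > 0L) per_mol[seq_len(rem)] <- per_mol[seq_len(rem)] + 1L
    reads_out[[i]] <- paste0(structure$adapter,
                             rep.int(umis, per_mol),
                             structure$spacer, sample$junction[i])
  }
  reads <- unlist(reads_out)
  if (error_rate > 0 && length(reads) > 0L) {
    len <- nchar(reads)
    n_err <- rbinom(length(reads), len, error_rate)
    for (i in which(n_err > 0L)) {
      pos <- sample.int(len[i], n_err[i])
      chars <- strsplit(reads[i], "")[[1L]]
      for (p in pos) {
        chars[p] <- sample(setdiff(NT_ALPHABET, chars[p]), 1L)
      }
      reads[i] <- paste(chars, collapse = "")
    }
  }
  attr(reads, "umi_truth") <- umi_truth
  if (!is.null(path)) write_fastq(reads, path)
  invisible(reads)
}

#' Write reads as FASTQ
#'
#' @param reads Character vector of sequences.
#' @param path Output path.
#' @param id_prefix Read-name prefix.
#' @export
write_fastq <- function(reads, path, id_prefix = "read") {
  n <- length(reads)
  qual <- vapply(nchar(reads), function(l)
    paste(rep("I", l), collapse = ""), character(1))
  lines <- character(4L * n)
  if (n > 0L) {
    lines[seq(1L, 4L * n, 4L)] <- paste0("@", id_prefix, seq_len(n))
    lines[seq(2L, 4L * n, 4L)] <- reads
    lines[seq(3L, 4L * n, 4L)] <- "+"
    lines[seq(4L, 4L * n, 4L)] <- qual
  }
  writeLines(lines, path)
  invisible(path)
}
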