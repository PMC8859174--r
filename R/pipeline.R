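#' Run the repertoire-analysis pipeline from a YAML configuration
#'
#' Executes the requested stages in dependency order and writes
#' tab-separated / JSON outputs into the report directory. Stages:
#' `simulate` (synthetic cohort), `clonotype` (FASTQ to clonotype tables),
#' `track` (dominant-clone persistence and new-vs-persistent partition),
#' `diversity` (per-sample entropy and trends), `public` (public clones,
#' sharing, convergence), `annotate` (antigen database screening),
#' `motifs` (k-mer enrichment against a pooled-baseline reference) and
#' `selection` (selection-model fit and P_GEN/P_POST annotation of
#' baseline clones). Every run writes `run_info.json` with the seed and
#' the config file's MD5 hash; outputs are deterministic given
#' (config, seed).
#'
#' @param config Path to a YAML file or an equivalent named list. Fields:
#'   `seed`, `out_dir`, `stages` (character vector), optional `input`
#'   (paths `clonotype_table`, `subjects`, `antigen_db`, `fastq`), and
#'   per-stage parameter blocks (`simulate` accepts
#'   [simulation_config()] arguments; `track`/`public`/`motifs` accept
#'   `cell_subset`).
#' @param out_dir Overrides the config's output directory.
#' @param seed Overrides the config's seed.
#' @return Invisibly, the report directory path.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  cfg_path <- NULL
  if (is.character(config) && length(config) == 1L) {
    cfg_path <- config
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a YAML path or a list")
  stages <- config$stages
  known <- c("simulate", "clonotype", "track", "diversity", "public",
             "annotate", "motifs", "selection")
  if (is.null(stages) || !length(stages)) stop("config field 'stages' is required")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) stop("config field 'out_dir' is required")
  seed <- as.integer(seed %||% config$seed %||% 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE, fileEncoding = "UTF-8")
  }
  info <- list(seed = seed, stages = stages,
               package_version = as.character(utils::packageVersion("clonotrack")),
               config_md5 = if (!is.null(cfg_path))
                 unname(tools::md5sum(cfg_path)) else NA)
  gen <- default_vdj_model()
  cohort <- NULL
  truth <- NULL

  if ("simulate" %in% stages) {
    args <- config$simulate %||% list()
    args$seed <- seed
    sim <- simulate_cohort(do.call(simulation_config, args), gen)
    cohort <- sim$cohort
    truth <- sim$truth
    write_clonotype_table(cohort, file.path(out_dir, "clonotypes.tsv"),
                          file.path(out_dir, "subjects.tsv"))
    if (!is.null(truth$public_registry)) {
      tsv(truth$public_registry, "true_public_registry.tsv")
    }
  } else if (!is.null(config$input$clonotype_table)) {
    cohort <- read_clonotype_table(config$input$clonotype_table,
                                   config$input$subjects)
  }

  if ("clonotype" %in% stages) {
    fq <- config$input$fastq
    if (is.null(fq)) stop("dependency error: stage 'clonotype' needs input$fastq")
    labels <- config$clonotype %||% list()
    built <- build_clonotype_table(
      fq, read_structure(), gen,
      subject_id = labels$subject_id %||% "S1",
      timepoint_months = labels$timepoint_months %||% 0L,
      cell_subset = labels$cell_subset %||% "CD4_RO")
    tsv(built$sample, "called_clonotypes.tsv")
    jsonlite::write_json(built$qc, file.path(out_dir, "clonotype_qc.json"),
                         auto_unbox = TRUE, digits = NA)
    if (is.null(cohort)) cohort <- tcr_cohort(built$sample)
  }

  needs_cohort <- intersect(stages, c("track", "diversity", "public",
                                      "annotate", "motifs", "selection"))
  if (length(needs_cohort) && is.null(cohort)) {
    stop("dependency error: stage(s) ", paste(needs_cohort, collapse = ", "),
         " need clonotype tables (run 'simulate' or provide input$clonotype_table)")
  }

  memory_subsets <- function() {
    ss <- unique(cohort$clonotypes$cell_subset)
    ms <- ss[is_memory_subset(ss)]
    if (length(ms)) ms else ss
  }

  if ("track" %in% stages) {
    subsets <- config$track$cell_subset %||% memory_subsets()
    kin <- do.call(rbind, lapply(subsets, function(ss) {
      k <- persistence_kinetics(cohort, ss, n = config$track$n %||% 100L)
      k$cell_subset <- ss
      k
    }))
    tsv(kin, "persistence_kinetics.tsv")
    parts <- list()
    for (ss in subsets) {
      sm <- list_samples(cohort)
      sm <- sm[sm$cell_subset == ss, ]
      for (subj in unique(sm$subject_id)) {
        tps <- sort(sm$timepoint_months[sm$subject_id == subj])
        if (length(tps) < 2L) next
        base <- get_sample(cohort, subj, tps[1L], ss)
        for (tp in tps[-1L]) {
          pn <- partition_new_persistent(base, get_sample(cohort, subj, tp, ss))
          parts[[length(parts) + 1L]] <- data.frame(
            subject_id = subj, cell_subset = ss, timepoint_months = tp,
            persistent_fraction = pn[["persistent"]],
            new_fraction = pn[["new"]], stringsAsFactors = FALSE)
        }
      }
    }
    tsv(do.call(rbind, parts), "new_vs_persistent.tsv")
    info$track <- list(mean_persistence_final =
                         mean(kin$persistence[kin$timepoint_months ==
                                                max(kin$timepoint_months)]))
  }

  if ("diversity" %in% stages) {
    ent <- cohort_entropy(cohort)
    tsv(ent, "entropy.tsv")
    trends <- do.call(rbind, lapply(unique(ent$cell_subset), function(ss) {
      e <- ent[ent$cell_subset == ss, ]
      tr <- entropy_trend(data.frame(timepoint_months = e$timepoint_months,
                                     entropy = e$entropy))
      data.frame(cell_subset = ss, slope = tr$slope, adj_r2 = tr$adj_r2,
                 p_value = tr$p_value, n = tr$n, stringsAsFactors = FALSE)
    }))
    tsv(trends, "entropy_trends.tsv")
  }

  if ("public" %in% stages) {
    ss <- config$public$cell_subset %||% memory_subsets()[1L]
    tps <- sort(unique(cohort$clonotypes$timepoint_months))
    pub_all <- list()
    for (tp in tps) {
      pm <- identify_public(cohort, ss, tp)
      if (nrow(pm)) {
        pm$timepoint_months <- tp
        pub_all[[length(pub_all) + 1L]] <- pm
      }
    }
    pub <- if (length(pub_all)) do.call(rbind, pub_all) else
      cbind(identify_public(cohort, ss, tps[1L]), timepoint_months = integer(0))
    tsv(pub, "public_clones.tsv")
    base_pub <- pub[pub$timepoint_months == tps[1L], , drop = FALSE]
    tsv(sharing_distribution(base_pub), "public_sharing_baseline.tsv")
    conv <- list()
    for (subj in unique(cohort$subjects$subject_id)) {
      s <- get_sample(cohort, subj, tps[1L], ss)
      if (nrow(s) == 0L || nrow(base_pub) == 0L) next
      keep <- vapply(strsplit(base_pub$subjects, ","), function(x)
        subj %in% x, logical(1))
      if (!any(keep)) next
      cc <- suppressWarnings(convergence_counts(s, base_pub[keep, ]))
      cc$subject_id <- subj
      conv[[length(conv) + 1L]] <- cc
    }
    if (length(conv)) tsv(do.call(rbind, conv), "convergence_counts.tsv")
    info$public <- list(n_public_baseline = nrow(base_pub))
  }

  if ("annotate" %in% stages) {
    dbp <- config$input$antigen_db
    if (is.null(dbp)) stop("dependency error: stage 'annotate' needs input$antigen_db")
    db <- read_antigen_db(dbp)
    sm <- list_samples(cohort)
    rows <- list()
    for (i in seq_len(nrow(sm))) {
      subj <- sm$subject_id[i]
      hla <- cohort$subjects$hla_alleles[cohort$subjects$subject_id == subj]
      s <- get_sample(cohort, subj, sm$timepoint_months[i], sm$cell_subset[i])
      ann <- annotate_repertoire(s, db, hla)
      fr <- annotated_fraction(s, ann, by = "reads")
      if (length(fr)) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = subj, timepoint_months = sm$timepoint_months[i],
          cell_subset = sm$cell_subset[i], antigen_species = names(fr),
          read_fraction = as.numeric(fr), stringsAsFactors = FALSE)
      }
    }
    tsv(if (length(rows)) do.call(rbind, rows) else
      data.frame(subject_id = character(), timepoint_months = integer(),
                 cell_subset = character(), antigen_species = character(),
                 read_fraction = numeric()), "annotated_fractions.tsv")
  }

  if ("motifs" %in% stages) {
    ss <- config$motifs$cell_subset %||% memory_subsets()[1L]
    tps <- sort(unique(cohort$clonotypes$timepoint_months))
    if (length(tps) < 2L) stop("dependency error: motifs need >= 2 timepoints")
    ct <- cohort$clonotypes
    ref <- ct[ct$cell_subset == ss & ct$timepoint_months == tps[1L], ]
    ref_agg <- aggregate_to_aa(ref)  # pooled baseline reference
    rows <- list()
    for (subj in unique(ct$subject_id)) {
      s <- get_sample(cohort, subj, tps[2L], ss)
      if (nrow(s) == 0L) next
      cl <- motif_fisher(aggregate_to_aa(s), ref_agg)
      if (nrow(cl)) {
        cl <- score_v_bias(cl, ref_agg)
        cov <- enriched_motif_summary(cl, s)
        cl$subject_id <- subj
        cl$read_fraction <- cov[["read_fraction"]]
        cl$clonotype_fraction <- cov[["clonotype_fraction"]]
        rows[[length(rows) + 1L]] <- cl
      }
    }
    tsv(if (length(rows)) do.call(rbind, rows) else
      cbind(empty_clusters(), subject_id = character(),
            read_fraction = numeric(), clonotype_fraction = numeric()),
      "motif_clusters.tsv")
  }

  if ("selection" %in% stages) {
    ss <- config$selection$cell_subset %||% memory_subsets()[1L]
    tps <- sort(unique(cohort$clonotypes$timepoint_months))
    ct <- cohort$clonotypes
    base <- ct[ct$cell_subset == ss & ct$timepoint_months == tps[1L], ]
    keys <- aggregate_to_aa(base)
    fit <- fit_selection(gen, keys,
                         baseline_size = config$selection$baseline_size %||%
                           (10L * nrow(keys)),
                         seed = seed)
    jsonlite::write_json(
      list(lambda = as.list(coef(fit)), logZ = fit$logZ,
           meta = fit$meta[c("l2", "baseline_size", "n_observed",
                             "grad_norm", "converged", "iterations")]),
      file.path(out_dir, "selection_model.json"), auto_unbox = TRUE,
      digits = NA)
    ann <- ppost_annotate(fit, gen, utils::head(keys, config$selection$n_annotate
                                                %||% 200L))
    tsv(ann, "probability_annotations.tsv")
    esc <- flag_escapees(ann)
    tsv(esc, "escapees.tsv")
    info$selection <- list(n_escapees = nrow(esc))
  }

  jsonlite::write_json(info, file.path(out_dir, "run_info.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
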