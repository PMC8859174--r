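test_that("the simulator is deterministic given a seed", {
  a <- quick_sim(201, n_public = 5L, n_subjects = 3L)
  b <- quick_sim(201, n_public = 5L, n_subjects = 3L)
  expect_identical(a$cohort$clonotypes, b$cohort$clonotypes)
  expect_identical(a$truth$public_registry, b$truth$public_registry)
  c2 <- quick_sim(202, n_public = 5L, n_subjects = 3L)
  expect_false(identical(a$cohort$clonotypes, c2$cohort$clonotypes))
})

test_that("survival extremes give persistence one and zero", {
  full <- quick_sim(203, dominant_survival = 1, background_survival = 1)
  kin <- persistence_kinetics(full$cohort, "CD4_RO")
  expect_true(all(kin$persistence == 1))
  dead <- quick_sim(204, dominant_survival = 0)
  base_top <- lapply(sprintf("HSCT%02d", 1:3), function(s)
    top_n_clones(get_sample(dead$cohort, s, 0L, "CD4_RO"), 100L))
  for (i in 1:3) {
    expect_equal(persistence_fraction(
      base_top[[i]], get_sample(dead$cohort, sprintf("HSCT%02d", i), 6L,
                                "CD4_RO")), 0)
  }
})

test_that("measured dominant persistence follows the binomial survival kinetics", {
  sim <- simulate_cohort(simulation_config(
    n_subjects = 8L, subsets = "CD4_RO", timepoints = c(0L, 6L, 12L),
    clones_per_sample = 250L, umis_per_sample = 1500L,
    dominant_survival = 0.7, background_survival = 0.5,
    n_public = 0L, seed = 205L))
  kin <- persistence_kinetics(sim$cohort, "CD4_RO")
  p2 <- mean(kin$persistence[kin$timepoint_months == 12L])
  n_draws <- 8L * 100L
  se <- sqrt(0.7^2 * (1 - 0.7^2) / n_draws)
  expect_lt(abs(p2 - 0.7^2), 3 * se)
})

test_that("emitted frequencies and ground truth are mutually consistent", {
  sim <- quick_sim(206, n_public = 6L, n_subjects = 3L)
  truth <- sim$truth$clones
  # every emitted clone has a truth entry and vice versa
  agg <- aggregate_to_aa(get_sample(sim$cohort, "HSCT01", 0L, "CD4_RO"))
  tr <- truth[truth$subject_id == "HSCT01" & truth$timepoint_months == 0L, ]
  expect_setequal(paste(agg$v_call, agg$j_call, agg$junction_aa),
                  paste(tr$v_gene, tr$j_gene, tr$cdr3_aa))
  expect_equal(sum(tr$true_freq), 1, tolerance = 1e-12)
  # emitted UMI counts match the truth table
  m <- match(paste(agg$v_call, agg$j_call, agg$junction_aa),
             paste(tr$v_gene, tr$j_gene, tr$cdr3_aa))
  expect_equal(agg$umi_count, tr$umi_count[m])
})

test_that("clone sizes follow the configured power law", {
  sim <- simulate_cohort(simulation_config(
    n_subjects = 1L, subsets = "CD4_RO", timepoints = 0L,
    clones_per_sample = 2000L, umis_per_sample = 200000L,
    alpha = 1.0, n_public = 0L, seed = 207L))
  tr <- sim$truth$clones
  f <- sort(tr$true_freq, decreasing = TRUE)
  fit <- lm(log(f) ~ log(seq_along(f)))
  expect_lt(abs(-coef(fit)[2L] - 1.0), 0.1)
})

test_that("injected public clones carry the configured encodings in every carrier", {
  sim <- quick_sim(208, n_public = 8L, n_subjects = 4L, umis = 600L)
  reg <- sim$truth$public_registry
  expect_equal(nrow(reg), 8L)
  expect_true(all(reg$n_encodings >= 1L & reg$n_encodings <= 5L))
  for (i in seq_len(nrow(reg))) {
    for (subj in strsplit(reg$subjects[i], ",")[[1L]]) {
      s <- get_sample(sim$cohort, subj, 0L, "CD4_RO")
      cc <- convergence_counts(s, data.frame(
        v_call = reg$v_gene[i], j_call = reg$j_gene[i],
        junction_aa = reg$cdr3_aa[i]))
      expect_equal(cc$n_nt_variants, reg$n_encodings[i])
      # publics are emitted above the two-read detection rule
      agg <- aggregate_to_aa(s)
      row <- agg[agg$junction_aa == reg$cdr3_aa[i] &
                   agg$v_call == reg$v_gene[i] & agg$j_call == reg$j_gene[i], ]
      expect_gte(row$duplicate_count, 2L)
    }
    # all encodings translate to the registered amino-acid sequence
    nts <- strsplit(reg$nt_variants[i], ",")[[1L]]
    expect_true(all(translate_nt(nts) == reg$cdr3_aa[i]))
  }
})

test_that("read simulation matches counts and inverts at zero error", {
  clone <- make_records(junction = "TGTGCCAGCAGCTTAGGGACAGGGAACACTGAAGCTTTC",
                        v = "TRBV5", j = "TRBJ1-1", reads = 15L, umis = 3L)
  reads <- simulate_reads(clone, read_structure(), error_rate = 0, seed = 209L)
  expect_length(reads, 15L)
  ex <- extract_umi(reads, read_structure())
  expect_equal(length(unique(ex$umi)), 3L)
  expect_true(all(table(ex$umi) == 5L))
})
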