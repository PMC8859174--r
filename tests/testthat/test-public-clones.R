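test_that("public detection applies the per-subject read threshold", {
  recs <- rbind(
    make_records(subject = "A", junction = "TGTGCCTTT", reads = 3L),
    make_records(subject = "B", junction = "TGTGCCTTT", reads = 2L),
    make_records(subject = "A", junction = "TGTTGGTTT", reads = 1L),
    make_records(subject = "B", junction = "TGTTGGTTT", reads = 5L))
  co <- tcr_cohort(recs)
  pub <- identify_public(co, "CD4_RO", 0L)
  expect_equal(nrow(pub), 1L)
  expect_equal(pub$junction_aa, "CAF")
  expect_equal(pub$subjects, "A,B")
  # the alternative total-threshold reading admits the second clone
  pub2 <- identify_public(co, "CD4_RO", 0L, threshold = "total")
  expect_setequal(pub2$junction_aa, c("CAF", "CWF"))
  expect_error(identify_public(tcr_cohort(recs[recs$subject_id == "A", ]),
                               "CD4_RO", 0L), "fewer than 2 subjects")
})

test_that("public detection equals the brute-force oracle on random cohorts", {
  for (seed in c(301, 302, 303)) {
    sim <- quick_sim(seed, n_subjects = 4L, clones = 50L, umis = 200L,
                     n_public = 5L, timepoints = 0L)
    pub <- identify_public(sim$cohort, "CD4_RO", 0L)
    oracle <- public_oracle(sim$cohort, "CD4_RO", 0L)
    got <- setNames(strsplit(pub$subjects, ","),
                    paste(pub$v_call, pub$j_call, pub$junction_aa, sep = "|"))
    expect_setequal(names(got), names(oracle))
    for (k in names(oracle)) expect_equal(sort(got[[k]]), oracle[[k]])
  }
})

test_that("publicity is monotone in both thresholds", {
  sim <- quick_sim(304, n_subjects = 5L, clones = 60L, umis = 250L,
                   n_public = 8L, timepoints = 0L)
  base <- identify_public(sim$cohort, "CD4_RO", 0L, min_reads = 2L,
                          min_subjects = 2L)
  bk <- paste(base$v_call, base$j_call, base$junction_aa)
  for (mr in c(3L, 5L)) {
    p <- identify_public(sim$cohort, "CD4_RO", 0L, min_reads = mr)
    expect_true(all(paste(p$v_call, p$j_call, p$junction_aa) %in% bk))
  }
  p3 <- identify_public(sim$cohort, "CD4_RO", 0L, min_subjects = 3L)
  expect_true(all(paste(p3$v_call, p3$j_call, p3$junction_aa) %in% bk))
})

test_that("injected publics are recovered in full", {
  sim <- quick_sim(305, n_subjects = 5L, clones = 60L, umis = 250L,
                   n_public = 10L, timepoints = 0L)
  pub <- identify_public(sim$cohort, "CD4_RO", 0L)
  reg <- sim$truth$public_registry
  regk <- paste(reg$v_gene, reg$j_gene, reg$cdr3_aa)
  pubk <- paste(pub$v_call, pub$j_call, pub$junction_aa)
  expect_equal(mean(regk %in% pubk), 1)
  # chance-convergence false discoveries are possible but each must satisfy
  # the publicity rule (checked against the oracle above); report the rate
  fd <- setdiff(pubk, regk)
  expect_lt(length(fd) / max(1L, length(pubk)), 0.8)
})

test_that("sharing distribution conserves the number of public keys", {
  pm <- data.frame(v_call = "V", j_call = "J",
                   junction_aa = c("CAAF", "CABF", "CACF"),
                   n_subjects = c(2L, 2L, 3L),
                   subjects = c("A,B", "A,B", "A,B,C"))
  sd <- sharing_distribution(pm)
  expect_equal(sd$n_clonotypes[sd$subjects == "A,B"], 2L)
  expect_equal(sd$n_clonotypes[sd$subjects == "A,B,C"], 1L)
  expect_equal(sum(sd$n_clonotypes), nrow(pm))
  expect_equal(nrow(sharing_distribution(pm[0L, ])), 0L)
  sim <- quick_sim(306, n_subjects = 5L, n_public = 10L, timepoints = 0L)
  pub <- identify_public(sim$cohort, "CD4_RO", 0L)
  expect_equal(sum(sharing_distribution(pub)$n_clonotypes), nrow(pub))
})

test_that("convergence counts report nucleotide variants and absent keys", {
  df <- make_records(junction = c("TGTGCCTTT", "TGCGCCTTT", "TGTGCGTTC",
                                  "TGTTGGTTT"),
                     reads = c(1L, 1L, 1L, 1L))
  cc <- convergence_counts(df)
  expect_equal(cc$n_nt_variants[cc$junction_aa == "CAF"], 3L)
  expect_equal(cc$n_nt_variants[cc$junction_aa == "CWF"], 1L)
  expect_warning(
    cc2 <- convergence_counts(df, data.frame(v_call = "TRBV1", j_call = "TRBJ1",
                                             junction_aa = "CQF")),
    "absent")
  expect_equal(cc2$n_nt_variants, 0L)
})

test_that("HLA stratification partitions the cohort", {
  sim <- quick_sim(307, n_subjects = 5L, timepoints = 0L)
  strat <- stratify_by_hla(sim$cohort, "DRB1*15:01")
  carriers <- strat$carriers$subjects$subject_id
  non <- strat$non_carriers$subjects$subject_id
  expect_length(intersect(carriers, non), 0L)
  expect_setequal(c(carriers, non), sim$cohort$subjects$subject_id)
  expect_equal(nrow(strat$carriers$clonotypes) + nrow(strat$non_carriers$clonotypes),
               nrow(sim$cohort$clonotypes))
  # low-resolution query matches 4-digit typing
  strat2 <- stratify_by_hla(sim$cohort, "DRB1*15")
  expect_setequal(strat2$carriers$subjects$subject_id, carriers)
  # an allele carried by nobody leaves everyone in non_carriers
  none <- stratify_by_hla(sim$cohort, "DQB1*99:99")
  expect_equal(nrow(none$carriers$subjects), 0L)
  expect_error(stratify_by_hla(sim$cohort, "not an allele"), "malformed")
})
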