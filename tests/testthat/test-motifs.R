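test_that("k-mer extraction trims the interior and respects the length floor", {
  expect_equal(extract_kmers("CASSLG"), character(0))  # shorter than 7
  km <- extract_kmers("CASSQETQYF")
  expect_setequal(km, c("SQE", "QET", "ETQ", "SQET", "QETQ", "SQETQ"))
  # interior shorter than k yields no k-mers of that k
  expect_false(any(nchar(km) > 5L))
  expect_setequal(extract_kmers("CASSQLF"), character(0))  # interior "SQ" < 3
  expect_setequal(extract_kmers("CASSQELF"), c("SQE"))
})

test_that("the motif Fisher p equals the hypergeometric tail oracle", {
  set.seed(501)
  for (i in 1:100) {
    S <- sample(20:200, 1L)
    R <- sample(100:2000, 1L)
    a <- sample.int(min(S, 40L), 1L)
    b <- sample.int(min(R, 60L), 1L)
    p_pkg <- phyper(a - 1L, a + b, S + R - a - b, S, lower.tail = FALSE)
    expect_equal(p_pkg, hyper_tail_oracle(a, b, S, R), tolerance = 1e-12)
  }
  # through the full interface: spiked motif 30/100 vs 10/1000
  sample_cdr3 <- c(paste0("CASS", "QETQ", sprintf("%02d", 1:30), "EQYF"),
                   paste0("CASSLAPG", sprintf("%03d", 1:70), "YF"))
  sample_cdr3 <- gsub("[0-9]", "G", sample_cdr3)
  sample_cdr3[1:30] <- paste0("CASSQETQ", strrep("G", 4), "EQYF")
  ref_cdr3 <- c(rep(paste0("CASSQETQ", strrep("G", 4), "EQYF"), 10L),
                replicate(990L, paste0(
                  "CASS", paste(sample(clonotrack:::AA_ALPHABET[-2], 8L,
                                       replace = TRUE), collapse = ""), "YF")))
  cl <- motif_fisher(sample_cdr3, ref_cdr3)
  hit <- cl[cl$motif == "QET", ]
  expect_equal(hit$fisher_p,
               hyper_tail_oracle(hit$sample_count, hit$reference_count,
                                 hit$sample_total, hit$reference_total),
               tolerance = 1e-12)
  expect_lt(hit$fisher_p, 1e-3)
  # a motif at equal proportions is not enriched
  eq <- motif_fisher(rep("CASSWGWGWGYF", 10L),
                     rep("CASSWGWGWGYF", 100L))
  expect_false("WGW" %in% eq$motif)
})

test_that("identical sample and reference yield no enrichment", {
  set.seed(502)
  pool <- replicate(150L, paste0(
    "CASS", paste(sample(clonotrack:::AA_ALPHABET, 7L, TRUE), collapse = ""), "QYF"))
  cl <- motif_fisher(pool, pool)
  expect_equal(nrow(cl), 0L)
})

test_that("V-bias scoring matches the binomial tail and flags skewed usage", {
  # all 10 members use a V with reference frequency 0.05
  p <- v_bias_score(rep("TRBV9", 10L), c(TRBV9 = 0.05, TRBV2 = 0.95))
  expect_equal(p, 0.05^10, tolerance = 1e-12)
  expect_lt(p, 0.05)
  # members matching reference usage are not flagged
  set.seed(503)
  ref <- c(TRBV1 = 0.5, TRBV2 = 0.5)
  members <- sample(names(ref), 40L, TRUE, prob = ref)
  expect_gt(v_bias_score(members, ref), 0.05)
  expect_equal(v_bias_score("TRBV1", ref), 1.0)  # singleton undefined -> 1
  # random clusters equal the Bonferroni-corrected enumeration oracle
  for (i in 1:20) {
    vs <- sample(paste0("TRBV", 1:5), sample(3:12, 1L), TRUE)
    ref5 <- setNames(runif(5) + 0.1, paste0("TRBV", 1:5))
    ref5 <- ref5 / sum(ref5)
    tab <- table(vs)
    oracle <- min(1, min(vapply(names(tab), function(v)
      sum(dbinom(tab[[v]]:length(vs), length(vs), ref5[[v]])),
      numeric(1))) * length(tab))
    expect_equal(v_bias_score(vs, ref5), oracle, tolerance = 1e-9)
  }
})

test_that("motif coverage counts overlapping clusters once", {
  s <- make_records(junction = c("TGTGCCAGCAGCCAACCGCAAACTCAATATTTT",
                                 "TGTGCCAGCAGCCAACCGTGGACTCAATATTTT",
                                 "TGTGCCAGCAGCTGGAAATGGCCTCAATATTTT"),
                    reads = c(10L, 20L, 70L))
  agg <- aggregate_to_aa(s)
  clusters <- data.frame(motif = c("QPQ", "SQP"), k = 3L,
                         sample_count = 2L, reference_count = 0L,
                         sample_total = 3L, reference_total = 10L,
                         fisher_p = 1e-5, members = "", stringsAsFactors = FALSE)
  cov <- enriched_motif_summary(clusters, s)
  # first two clonotypes contain both motifs; counted once each
  expect_equal(unname(cov["clonotype_fraction"]), 2 / 3)
  expect_equal(unname(cov["read_fraction"]), 0.3)
  expect_equal(unname(enriched_motif_summary(clusters[0L, ], s)),
               c(0, 0))
  # every clonotype covered gives 1
  all_cl <- rbind(clusters, data.frame(motif = "KWP", k = 3L, sample_count = 1L,
                                       reference_count = 0L, sample_total = 3L,
                                       reference_total = 10L, fisher_p = 1e-5,
                                       members = ""))
  expect_equal(unname(enriched_motif_summary(all_cl, s)["clonotype_fraction"]), 1)
})

test_that("null calibration and spiked power behave as designed", {
  set.seed(504)
  gen <- default_vdj_model()
  pool <- clonotrack:::generate_baseline(gen, 2100L)$keys
  ref <- pool[1:2000, ]
  nul <- pool[2001:2100, ]
  cl <- motif_fisher(nul, ref)
  n_tested <- length(unique(unlist(clonotrack:::kmer_sets(nul$cdr3_aa))))
  lambda <- 1e-3 * n_tested
  expect_lte(nrow(cl), qpois(0.975, lambda))
  # power: motif spiked into 20% of 200 sample clones vs 1% reference
  detected <- vapply(1:10, function(r) {
    set.seed(600 + r)
    samp <- clonotrack:::generate_baseline(gen, 200L)$keys
    spike <- function(aa) paste0(substr(aa, 1L, 4L), "WQV",
                                 substr(aa, 8L, nchar(aa)))
    samp$cdr3_aa[1:40] <- vapply(samp$cdr3_aa[1:40], spike, character(1))
    ref2 <- ref
    ref2$cdr3_aa[1:20] <- vapply(ref2$cdr3_aa[1:20], spike, character(1))
    cl2 <- motif_fisher(samp, ref2)
    "WQV" %in% cl2$motif
  }, logical(1))
  expect_gte(mean(detected), 0.9)
})
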