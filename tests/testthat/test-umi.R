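test_that("UMI extraction parses the read layout and classifies failures", {
  st <- read_structure()
  umi <- "ACGTACGTAC"
  insert <- "TGTGCCAGCAGCTTT"
  good <- paste0(st$adapter, umi, st$spacer, insert)
  ex <- extract_umi(good, st)
  expect_true(ex$ok)
  expect_equal(ex$umi, umi)
  expect_equal(ex$insert, insert)
  # one mismatch in the adapter is tolerated
  mm <- good
  substr(mm, 3L, 3L) <- "A"
  expect_true(extract_umi(mm, st)$ok)
  # missing adapter, corrupt spacer, truncated read
  expect_equal(extract_umi(paste0("AAAA", umi, st$spacer, insert), st)$reason,
               "no_adapter")
  bad_spacer <- paste0(st$adapter, umi, "GGGGGGG", insert)
  expect_equal(extract_umi(bad_spacer, st)$reason, "no_spacer")
  expect_equal(extract_umi(substr(good, 1L, 40L), st)$reason, "too_short")
})

test_that("extraction recovers nearly all reads at a 0.1% error rate", {
  st <- read_structure()
  set.seed(21)
  n <- 4000L
  umis <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 10L, TRUE), collapse = ""),
    character(1))
  reads <- paste0(st$adapter, umis, st$spacer, "TGTGCCAGCAGCTTGGGGACTTT")
  len <- nchar(reads)
  n_err <- rbinom(n, len, 0.001)
  for (i in which(n_err > 0)) {
    chars <- strsplit(reads[i], "")[[1L]]
    for (p in sample.int(len[i], n_err[i])) {
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
    }
    reads[i] <- paste(chars, collapse = "")
  }
  ex <- extract_umi(reads, st)
  # with a 10 bp UMI at 0.1%/base the expected correct-UMI rate is
  # 0.999^10 = 0.99004, right at the 99% target; allow Monte-Carlo error
  correct <- ex$ok & ex$umi == umis
  se <- sqrt(0.99 * 0.01 / n)
  expect_gte(mean(correct), 0.99 - 3 * se)
  expect_lt(abs(mean(ex$umi[ex$ok] == umis[ex$ok]) - 0.999^10), 3 * se)
  expect_gte(mean(ex$ok), 0.998)
})

test_that("directional collapse merges error UMIs and respects the count rule", {
  g <- data.frame(umi = c("AAAAAAAAAA", "AAAAAAAAAT"),
                  read_count = c(10L, 1L))
  out <- collapse_umis(g)
  expect_equal(nrow(out), 1L)
  expect_equal(out$read_count, 11L)
  # distance 2: never merged
  g2 <- data.frame(umi = c("AAAAAAAAAA", "AAAAAAAATT"),
                   read_count = c(10L, 1L))
  expect_equal(nrow(collapse_umis(g2)), 2L)
  # count rule boundary: 5 >= 2*3 - 1 merges, 4 < 2*3 - 1 does not
  g3 <- data.frame(umi = c("AAAAAAAAAA", "AAAAAAAAAT"),
                   read_count = c(5L, 3L))
  expect_equal(nrow(collapse_umis(g3)), 1L)
  g3b <- data.frame(umi = c("AAAAAAAAAA", "AAAAAAAAAT"),
                    read_count = c(4L, 3L))
  expect_equal(nrow(collapse_umis(g3b)), 2L)
  expect_error(collapse_umis(data.frame(umi = c("AAA", "AAAA"),
                                        read_count = c(1L, 1L))),
               "unequal length")
  # order independence given the tie-break rule
  g4 <- data.frame(umi = c("CCCCCCCCCC", "CCCCCCCCCT", "CCCCCCCCTT", "GGGGGGGGGG"),
                   read_count = c(9L, 4L, 2L, 5L))
  expect_equal(collapse_umis(g4), collapse_umis(g4[sample(4L), ]))
})

test_that("collapse recovers true molecule counts under sequencing errors", {
  set.seed(31)
  n_rep <- 200L
  ok <- vapply(seq_len(n_rep), function(i) {
    n_mol <- sample(2:8, 1L)
    true_umis <- vapply(seq_len(n_mol), function(k)
      paste(sample(c("A", "C", "G", "T"), 10L, TRUE), collapse = ""),
      character(1))
    reads <- rep(true_umis, each = 5L)
    # 0.3% per-base errors on the UMI reads
    n_err <- rbinom(length(reads), 10L, 0.003)
    for (j in which(n_err > 0)) {
      chars <- strsplit(reads[j], "")[[1L]]
      for (p in sample.int(10L, n_err[j]))
        chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
      reads[j] <- paste(chars, collapse = "")
    }
    tab <- table(reads)
    out <- collapse_umis(data.frame(umi = names(tab),
                                    read_count = as.integer(tab)))
    nrow(out) == n_mol
  }, logical(1))
  expect_gte(mean(ok), 0.99)
})

test_that("CDR3 calling inverts the simulator and flags frame failures", {
  gen <- default_vdj_model()
  draws <- sample_rearrangement(gen, 300L, seed = 41L)
  called <- call_cdr3(draws$cdr3_nt, gen)
  att <- clonotrack:::attribute_vj(gen, draws$cdr3_nt)
  ok <- called$ok
  expect_equal(called$v_call[ok], att$v_gene[ok])
  expect_equal(called$junction[ok], draws$cdr3_nt[ok])
  # error-free productive rearrangements are always called
  prod <- !is.na(clonotrack:::translate_nt_or_na(draws$cdr3_nt))
  expect_equal(called$reason[prod & !ok][0L], character(0))
  expect_true(all(called$ok[prod]))
  # off-frame insert (one extra middle base, flanks intact) is a frame failure
  good <- draws$cdr3_nt[prod][1L]
  bad <- paste0(substr(good, 1L, 15L), "A", substr(good, 16L, nchar(good)))
  expect_equal(call_cdr3(bad, gen)$reason, "frame")
  expect_equal(call_cdr3("TTTTTTTTTTTTTTTTTTTTT", gen)$reason, "no_v")
})

test_that("the read-to-table pipeline conserves totals and inverts simulation", {
  gen <- default_vdj_model()
  st <- read_structure()
  # 100 error-free reads of one molecule of one clone
  clone <- make_records(junction = "TGTGCCAGCAGCTTAGGGACAGGGAACACTGAAGCTTTC",
                        v = "TRBV5", j = "TRBJ1-1", reads = 100L, umis = 1L)
  reads <- simulate_reads(clone, st, seed = 51L)
  out <- build_clonotype_table(reads, st, gen)
  expect_equal(nrow(out$sample), 1L)
  expect_equal(out$sample$duplicate_count, 100L)
  expect_equal(out$sample$umi_count, 1L)
  # empty input gives an empty sample with all-zero QC
  empty <- build_clonotype_table(character(0), st, gen)
  expect_equal(nrow(empty$sample), 0L)
  expect_equal(empty$qc$n_input, 0L)
  # full inversion at zero error on a simulated sample, via FASTQ on disk
  sim <- quick_sim(52, n_subjects = 1L, timepoints = 0L, clones = 60L,
                   umis = 300L)
  s <- get_sample(sim$cohort, "HSCT01", 0L, "CD4_RO")
  fq <- withr::local_tempfile(fileext = ".fastq")
  simulate_reads(s, st, error_rate = 0, seed = 53L, path = fq)
  out2 <- build_clonotype_table(fq, st, gen, "HSCT01", 0L, "CD4_RO")
  cols <- c("v_call", "j_call", "junction", "duplicate_count", "umi_count")
  expect_equal(out2$sample[cols], s[cols])
  expect_true(all(out2$sample$umi_count <= out2$sample$duplicate_count))
})
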