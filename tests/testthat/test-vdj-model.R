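test_that("a degenerate model realizes exactly one sequence", {
  m <- degenerate_model()
  out <- sample_rearrangement(m, 5L, seed = 1L)
  expect_true(all(out$cdr3_nt == "TGTTTT"))
  expect_equal(pgen_nt(m, "TGTTTT"), 1)
  expect_equal(pgen_nt(m, "TGTATT"), 0)
  sc <- enumerate_scenarios(m, "TGTTTT")
  expect_equal(nrow(sc), 1L)
  expect_equal(sc$prob, 1)
  expect_equal(nrow(enumerate_scenarios(m, "AAAAAA")), 0L)
  # aa level: the only realizable string translates to CF
  expect_equal(pgen_aa(m, "CF"), 1)
})

test_that("sampling is reproducible for a fixed seed", {
  m <- toy_vdj_model()
  a <- sample_rearrangement(m, 50L, seed = 7L)
  b <- sample_rearrangement(m, 50L, seed = 7L)
  expect_identical(a, b)
})

test_that("pgen_nt equals the exhaustive scenario-enumeration oracle", {
  for (m in list(small_model(), toy_vdj_model())) {
    seqs <- enumerate_sequences(m)
    set.seed(11)
    idx <- sample.int(nrow(seqs), 40L)
    dp <- pgen_nt(m, seqs$cdr3_nt[idx])
    oracle <- vapply(seqs$cdr3_nt[idx], function(s)
      sum(enumerate_scenarios(m, s)$prob), numeric(1), USE.NAMES = FALSE)
    expect_true(max(abs(dp - oracle)) < 1e-12)
    # non-realizable strings get probability zero
    expect_equal(pgen_nt(m, "TTTTTTTTTTTTTTTTTT"), 0)
  }
})

test_that("generation probability is conserved over the enumerable sequence space", {
  m <- toy_vdj_model()
  seqs <- enumerate_sequences(m)
  expect_equal(sum(seqs$prob), 1, tolerance = 1e-12)
  total <- sum(pgen_nt(m, seqs$cdr3_nt))
  expect_equal(total, 1, tolerance = 1e-9)
})

test_that("pgen_aa marginalizes synonymous codings exactly", {
  m <- toy_vdj_model()
  keys <- clonotrack:::enumerate_keys(m)
  set.seed(3)
  aa <- sample(unique(keys$cdr3_aa[nchar(keys$cdr3_aa) <= 4L]), 12L)
  for (a in aa) {
    oracle <- sum(pgen_nt(m, codon_expansions(a)))
    expect_equal(pgen_aa(m, a), oracle, tolerance = 1e-12)
  }
  # the aa probability dominates any single coding
  s <- sample_rearrangement(m, 200L, seed = 5L)
  ok <- which(!is.na(clonotrack:::translate_nt_or_na(s$cdr3_nt)))[1:20]
  for (i in ok) {
    expect_gte(pgen_aa(m, translate_nt(s$cdr3_nt[i])) + 1e-15,
               pgen_nt(m, s$cdr3_nt[i]))
  }
})

test_that("V/J-restricted pgen partitions the marginal", {
  m <- small_model()
  seqs <- enumerate_sequences(m)
  set.seed(4)
  for (s in sample(seqs$cdr3_nt, 10L)) {
    parts <- outer(m$v$name, m$j$name, Vectorize(function(v, j)
      pgen_nt(m, s, v = v, j = j)))
    expect_equal(sum(parts), pgen_nt(m, s), tolerance = 1e-14)
  }
})

test_that("the forward sampler agrees with pgen_nt", {
  m <- small_model()
  n <- 1e5L
  draws <- sample_rearrangement(m, n, seed = 9L)
  seqs <- enumerate_sequences(m)
  obs <- table(factor(draws$cdr3_nt, levels = seqs$cdr3_nt))
  # chi-square goodness of fit against the exact distribution (pool rare cells)
  p <- seqs$prob
  pool <- p * n >= 5
  o2 <- c(as.numeric(obs[pool]), sum(obs[!pool]))
  p2 <- c(p[pool], sum(p[!pool]))
  chi <- sum((o2 - n * p2)^2 / (n * p2))
  pval <- pchisq(chi, df = length(o2) - 1L, lower.tail = FALSE)
  expect_gt(pval, 0.01)
  # every observed frequency within 3 Monte-Carlo standard errors
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(as.numeric(obs) / n - p) <= 3 * se + 3 / n))
})

test_that("model validation enforces probability and deletion constraints", {
  expect_error(vdj_model(
    v = data.frame(name = "V1", seq = "TGT", prob = 0.9),
    j = data.frame(name = "J1", seq = "TTT", prob = 1),
    d = data.frame(name = "D1", seq = "A", prob = 1),
    v_del = matrix(1), j_del = matrix(1),
    d_del5 = matrix(1), d_del3 = matrix(1),
    ins_vd = 1, ins_dj = 1, nt_prob = rep(0.25, 4)), "sum to 1")
  expect_error(vdj_model(
    v = data.frame(name = "V1", seq = "TGT", prob = 1),
    j = data.frame(name = "J1", seq = "TTT", prob = 1),
    d = data.frame(name = "D1", seq = "A", prob = 1),
    v_del = matrix(c(0, 0, 0, 0, 1), 5, 1), j_del = matrix(1),
    d_del5 = matrix(1), d_del3 = matrix(1),
    ins_vd = 1, ins_dj = 1, nt_prob = rep(0.25, 4)),
    "exceed segment length")
  expect_error(pgen_nt(toy_vdj_model(), "TGTXX"), "A/C/G/T")
})

test_that("YAML serialization round-trips a model", {
  m <- toy_vdj_model()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_vdj_model(m, path)
  back <- read_vdj_model(path)
  expect_equal(back$v, m$v)
  expect_equal(back$nt_prob, m$nt_prob)
  expect_equal(pgen_nt(back, "TGTGGGGCTTT"), pgen_nt(m, "TGTGGGGCTTT"))
})

test_that("the scenario-space guard refuses oversized models", {
  expect_error(enumerate_scenarios(default_vdj_model(), "TGTGCC"),
               "too large")
})
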