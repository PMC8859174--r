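test_that("featurize emits length, V, J and anchored positional features", {
  f <- featurize("TRBV1", "TRBJ1", "CASF")[[1L]]
  expect_setequal(f, c("len:4", "v:TRBV1", "j:TRBJ1",
                       "l:1:C", "l:2:A", "l:3:S", "l:4:F",
                       "r:1:F", "r:2:S", "r:3:A", "r:4:C"))
  # feature count is 3 + 2 * len, capped by the positional truncation
  for (aa in c("CF", "CASSF", "CASSLGQAYEQYF")) {
    expect_length(featurize("V", "J", aa)[[1L]],
                  3L + 2L * min(nchar(aa), 12L))
  }
  expect_length(featurize("V", "J", strrep("A", 20))[[1L]], 3L + 2L * 12L)
})

test_that("identity selection leaves P_POST equal to P_GEN", {
  m <- toy_vdj_model()
  sel <- selection_model()
  keys <- clonotrack:::enumerate_keys(m)[1:10, ]
  ann <- ppost_annotate(sel, m, data.frame(
    v_gene = keys$v_name, j_gene = keys$j_name, cdr3_aa = keys$cdr3_aa))
  expect_equal(ann$ppost, ann$pgen)
  expect_true(all(ann$q_ratio == 1))
  expect_true(all(ann$bin == "not_rare"))
  # log-linearity: raising one present feature multiplies q_ratio by exp(increment)
  sel2 <- selection_model(c("len:3" = 0.7))
  k3 <- keys[nchar(keys$cdr3_aa) == 3L, ][1L, ]
  ann2 <- ppost_annotate(sel2, m, data.frame(
    v_gene = k3$v_name, j_gene = k3$j_name, cdr3_aa = k3$cdr3_aa))
  expect_equal(ann2$q_ratio, exp(0.7), tolerance = 1e-12)
})

test_that("ratio bins follow the half-open boundary convention", {
  expect_equal(ratio_bin(1, 0.5), "not_rare")
  expect_equal(ratio_bin(1, 5e-5), "rare")
  expect_equal(ratio_bin(1, 0.1), "not_rare")          # boundary to upper class
  expect_equal(ratio_bin(1, 1e-4), "intermediate")     # boundary to upper class
  r_up <- 0.1 * (1 + .Machine$double.eps)
  r_dn <- 0.1 * (1 - .Machine$double.eps)
  expect_equal(ratio_bin(1, r_up), "not_rare")
  expect_equal(ratio_bin(1, r_dn), "intermediate")
  expect_equal(ratio_bin(1, 1e-4 * (1 - .Machine$double.eps)), "rare")
  expect_error(ratio_bin(0, 0.5), "positive")
})

test_that("escapee flagging selects the rare bin and reports the P_POST co-criterion", {
  ann <- data.frame(v_gene = "V", j_gene = "J", cdr3_aa = "CAF",
                    pgen = c(1e-6, 1e-6, 1e-6),
                    ppost = c(1e-11, 2e-7, 5e-7))
  ann$q_ratio <- ann$ppost / ann$pgen
  ann$ungeneratable <- FALSE
  ann$bin <- ratio_bin(ann$pgen, ann$ppost)
  ann$low_ppost <- log10(ann$ppost) < -10
  esc <- flag_escapees(ann)
  expect_equal(nrow(esc), 1L)
  expect_true(esc$low_ppost)
  expect_true(all(esc$bin == "rare"))
  expect_equal(nrow(flag_escapees(ann[0L, ])), 0L)
  # q_ratio 0.2 is not flagged
  expect_false("not_rare" %in% flag_escapees(ann)$bin)
})

test_that("fitting recovers a null model and a planted model", {
  gen <- default_vdj_model()
  obs0 <- clonotrack:::generate_baseline(gen, 4000L, seed = 61L)$keys
  fit0 <- fit_selection(gen, obs0, baseline_size = 40000L, seed = 62L)
  expect_true(fit0$meta$converged)
  expect_lt(max(abs(coef(fit0))), 0.15)

  lam_star <- c("l:5:L" = 1.0, "r:3:E" = 0.8, "v:TRBV19" = -1.0,
                "j:TRBJ2-7" = 0.6, "len:13" = 0.5, "l:7:G" = -0.7,
                "r:4:T" = 0.4, "v:TRBV7" = 0.5, "len:15" = -0.6,
                "l:6:G" = 0.9)
  obs1 <- simulate_selected_repertoire(gen, lam_star, 8000L,
                                       pool_factor = 6L, seed = 63L)
  fit1 <- fit_selection(gen, obs1, baseline_size = 60000L, seed = 64L)
  lh <- coef(fit1)[names(lam_star)]
  expect_true(!anyNA(lh))
  expect_gt(cor(lam_star, lh), 0.85)
  # strong regularization drives the weights toward zero
  fit_big <- fit_selection(gen, obs1[1:1500, ], baseline_size = 15000L,
                           l2 = 100, seed = 65L)
  expect_lt(max(abs(coef(fit_big))), 0.01)
})

test_that("exact renormalization makes P_POST sum to 1 on the toy model", {
  gen <- toy_vdj_model()
  keys <- clonotrack:::enumerate_keys(gen)
  sel <- selection_model(c("len:3" = 0.4, "l:2:A" = -0.3, "j:TRBJ1" = 0.2))
  sel <- renormalize_selection(sel, gen)
  lq <- clonotrack:::log_q(sel, keys$v_name, keys$j_name, keys$cdr3_aa)
  expect_equal(sum(exp(lq) * keys$pgen), 1, tolerance = 1e-9)
})

test_that("selection model methods print and predict", {
  sel <- selection_model(c("len:3" = 0.4, "v:TRBV1" = -0.2), logZ = 0.1)
  expect_output(print(sel), "features: 2")
  expect_output(print(summary(sel)), "feature class")
  ann <- predict(sel, data.frame(v_gene = "TRBV1", j_gene = "TRBJ1",
                                 cdr3_aa = "CAF"), gen = toy_vdj_model())
  expect_true(all(c("pgen", "ppost", "bin") %in% names(ann)))
})
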