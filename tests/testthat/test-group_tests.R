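test_that("one-sided Wilcoxon matches exact enumeration", {
  expect_equal(subgroup_downreg_test(c(1, 2, 3), c(4, 5, 6)), 0.05)
  expect_equal(subgroup_downreg_test(c(1, 2, 3), c(4, 5, 6)),
               oracle_wilcoxon_less(c(1, 2, 3), c(4, 5, 6)))
  expect_gte(subgroup_downreg_test(c(4, 5, 6), c(1, 2, 3)), 0.95)
  # identical multisets: no left shift
  expect_gte(subgroup_downreg_test(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_error(subgroup_downreg_test(numeric(0), 1), "non-empty")

  set.seed(14)
  for (i in 1:25) {
    x <- sample(1000, sample(3:8, 1))
    y <- sample(2000:3000, sample(3:8, 1))
    expect_equal(subgroup_downreg_test(x, y),
                 oracle_wilcoxon_less(x, y), tolerance = 1e-12)
  }
})

test_that("KS direction flags left-shifted distributions", {
  set.seed(15)
  x <- rnorm(60, -1)
  y <- rnorm(60, 0)
  expect_lt(subgroup_downreg_test(x, y, "ks"), 0.01)
  expect_gt(subgroup_downreg_test(y, x, "ks"), 0.5)
})

test_that("characteristic_test is symmetric under group exchange", {
  set.seed(16)
  for (i in 1:20) {
    a <- sample(10000, sample(4:20, 1))
    b <- sample(10001:20000, sample(4:20, 1))
    ab <- characteristic_test(a, b)
    ba <- characteristic_test(b, a)
    expect_equal(ab$p_greater, ba$p_less, tolerance = 1e-12)
    expect_equal(ab$p_less, ba$p_greater, tolerance = 1e-12)
  }
  sep <- characteristic_test(c(4, 5, 6), c(1, 2, 3))
  expect_equal(sep$p_greater, 0.05)
  same <- characteristic_test(1:9, 1:9 + 0.5)
  expect_gt(same$p_greater, 0.25)
  expect_gt(same$p_less, 0.25)
})

test_that("sample_level_score is the strict significant fraction", {
  expect_equal(sample_level_score(c(0.01, 0.2, 0.04, 0.8)), 0.5)
  expect_equal(sample_level_score(rep(0.5, 10)), 0)
  expect_equal(sample_level_score(c(rep(0.01, 70), rep(0.5, 70))), 0.5)
  expect_error(sample_level_score(numeric(0)), "no p-values")
})

test_that("run_feature_scan pools targets, reports empty subgroups as NA,
          and matches per-sample scope for one sample", {
  set.seed(17)
  genes <- sprintf("g%02d", 1:40)
  feats <- make_features(genes,
                         length_group = rep(c("Short", "MedShort",
                                              "MedLong", "Long"), 10))
  # plant a strong knockdown in MedShort targets only
  lr <- setNames(rnorm(40, 0, 0.05), genes)
  lr[feats$length_group == "MedShort"] <-
    lr[feats$length_group == "MedShort"] - 0.5
  r <- make_rna()
  asn <- make_assignments(genes, "r1", n_sites = rep(c(1L, 1L, 1L, 0L), 10))
  e <- make_experiment(samples = list(make_sample("s1", r, lr)))
  res <- run_feature_scan(e, asn, feats, "length")
  expect_equal(nrow(res), 5)
  ms <- res[res$subgroup == "MedShort", ]
  expect_lt(ms$p_value, 0.001)
  expect_equal(which.min(res$p_value), which(res$subgroup == "MedShort"))
  # Long genes are non-targets here and VeryLong has no genes: both NA
  expect_true(is.na(res$p_value[res$subgroup == "VeryLong"]))
  expect_true(is.na(res$p_value[res$subgroup == "Long"]))
  expect_equal(res$neg_log2_p[res$subgroup == "MedShort"],
               -log2(ms$p_value))

  per <- run_feature_scan(e, asn, feats, "length", scope = "per_sample")
  expect_equal(per$p_value, res$p_value)

  bad <- make_experiment(samples = list(
    make_sample("s1", r, c(lr, zz = 0.1))))
  asn_bad <- rbind(asn, make_assignments("zz", "r1", 1L))
  expect_error(run_feature_scan(bad, asn_bad, feats, "length"), "zz")
})

test_that("trend_counts counts experiment and sample support", {
  er <- data.frame(experiment_id = rep(c("e1", "e2"), each = 2),
                   sample_id = NA, feature = "expression",
                   subgroup = rep(c("High", "Low"), 2), method = "wilcoxon",
                   p_value = c(0.01, 0.8, 0.2, 0.9),
                   n_in = 5, n_out = 5, neg_log2_p = 1)
  sr <- data.frame(experiment_id = rep(c("e1", "e2"), each = 4),
                   sample_id = rep(c("a", "b"), 4),
                   feature = "expression",
                   subgroup = rep(rep(c("High", "Low"), each = 2), 2),
                   method = "wilcoxon",
                   p_value = c(0.01, 0.02, 0.5, 0.6, 0.04, 0.9, 0.7, 0.8),
                   n_in = 5, n_out = 5, neg_log2_p = 1)
  tc <- trend_counts(er, sr)
  expect_equal(tc$expr_count[tc$subgroup == "High"], 1)
  expect_equal(tc$expr_count[tc$subgroup == "Low"], 0)
  # e1 High score = 1 (> 0.5), e2 High score = 0.5 (not strictly greater)
  expect_equal(tc$smpl_count[tc$subgroup == "High"], 1)

  tc0 <- trend_counts(er, sr, score_threshold = 1.1)
  expect_equal(tc0$smpl_count, c(0, 0))
})

test_that("trend_correlation reproduces the reference counts and errors on
          degenerate input", {
  t1 <- table1_reference()
  expr <- t1[t1$feature == "expression", ]
  r <- trend_correlation(expr$expr_count, expr$smpl_count)
  expect_equal(round(r$r, 2), 0.91)
  expect_equal(round(r$p, 2), 0.01)

  expect_equal(trend_correlation(c(1, 2, 3), c(2, 4, 6))$r, 1.0)
  expect_error(trend_correlation(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  # agrees with cor.test
  set.seed(18)
  x <- rnorm(8); y <- rnorm(8)
  ct <- cor.test(x, y)
  tr <- trend_correlation(x, y)
  expect_equal(tr$r, unname(ct$estimate))
  expect_equal(tr$p, ct$p.value, tolerance = 1e-12)
})

test_that("competition_test compares T-Endo against T+Endo per subgroup", {
  set.seed(19)
  genes <- sprintf("g%03d", 1:120)
  feats <- make_features(genes, expr_group = rep(c("High", "Low"), 60))
  endo <- rep(c(0L, 1L), each = 60)
  asn <- make_assignments(genes, "r1", n_sites = 1L, n_endo_sites = endo)
  # competition: T+Endo genes up-shifted
  lr <- setNames(rnorm(120, 0, 0.05) + 0.3 * endo, genes)
  r <- make_rna()
  e <- make_experiment(samples = list(make_sample("s1", r, lr)))
  res <- competition_test(e, asn, feats, "expression")
  expect_lt(res$p_value[res$subgroup == "High"], 0.01)
  expect_lt(res$p_value[res$subgroup == "Low"], 0.01)
  # subgroups with an empty side are NA
  expect_true(all(is.na(res$p_value[res$subgroup %in%
                                      c("Medium", "VeryHigh")])))

  inh <- make_experiment(assay = "inhibition",
                         samples = list(make_sample("s1", r, lr)))
  expect_error(competition_test(inh, asn, feats, "expression"),
               "transfection")
})
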