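test_that("find_seed_sites reproduces the canonical worked examples", {
  r <- make_rna()
  # 8mer CUACCUCA embedded with N padding
  s <- find_seed_sites(r, "NNCUACCUCANN")
  expect_equal(s$start, 2L)
  expect_equal(s$end, 10L)
  expect_equal(s$site_type, "8mer")

  # adjacent 7mer-m8 then 8mer
  s <- find_seed_sites(r, "CUACCUCUCUACCUCA")
  expect_equal(s$start, c(0L, 8L))
  expect_equal(s$site_type, c("7mer-m8", "8mer"))

  expect_equal(nrow(find_seed_sites(r, "AAAAAAA")), 0)
  expect_error(find_seed_sites(small_rna("x", "ACGTACGT"), "ACG"), NA)
  expect_error(seed_site_strings("ACGTACG"), "shorter than 8")
})

test_that("every 8mer site truncates to both 7mer definitions", {
  set.seed(4)
  for (i in 1:20) {
    pats <- seed_site_strings(random_seq(21))
    s8 <- pats[["8mer"]]
    expect_equal(substr(s8, 1, 7), pats[["7mer-m8"]])
    expect_equal(substr(s8, 2, 8), pats[["7mer-A1"]])
  }
})

test_that("find_seed_sites matches the brute-force oracle on random pairs", {
  set.seed(11)
  for (i in 1:200) {
    mature <- random_seq(sample(18:23, 1))
    # AT-rich UTRs with the seed core sometimes spliced in to force matches
    utr <- random_seq(sample(60:400, 1))
    if (i %% 3 == 0) {
      core <- seed_site_strings(mature)[["8mer"]]
      pos <- sample(nchar(utr) - 10, 1)
      substr(utr, pos, pos + 7) <- core
    }
    got <- find_seed_sites(mature, utr)
    want <- oracle_seed_sites(mature, utr)
    expect_equal(got$start, want$start, info = paste("case", i))
    expect_equal(got$site_type, want$site_type, info = paste("case", i))
  }
})

test_that("count_sites equals the oracle on a long random UTR", {
  set.seed(21)
  mature <- random_seq(22)
  utr <- random_seq(10000, alphabet = c("A", "C", "G", "T"))
  core <- seed_site_strings(mature)[["8mer"]]
  for (pos in c(100, 2000, 5000)) substr(utr, pos, pos + 7) <- core
  expect_equal(count_sites(mature, utr), nrow(oracle_seed_sites(mature, utr)))
  expect_gte(count_sites(mature, utr), 3)
})

test_that("appending a disjoint seed match never decreases n_sites", {
  set.seed(31)
  r <- make_rna()
  s8 <- seed_site_strings(r)[["8mer"]]
  for (i in 1:25) {
    utr <- random_seq(sample(50:200, 1))
    n0 <- count_sites(r, utr)
    n1 <- count_sites(r, paste0(utr, "TT", s8, "TT"))
    expect_gte(n1, n0 + 1)
  }
})

test_that("scan_sites agrees with the single-gene scanner", {
  set.seed(5)
  genes <- gene_set(sprintf("g%02d", 1:30),
                    vapply(1:30, function(i) random_seq(300), ""))
  rnas <- make_small_rnas(c("a", "b", "c"))
  batch <- scan_sites(rnas, genes)
  for (r in rnas) {
    for (i in seq_len(30)) {
      single <- find_seed_sites(r, genes$utr_seq[i])
      got <- batch[batch$rna_id == r$rna_id &
                     batch$gene_id == genes$gene_id[i], ]
      expect_equal(got$start, single$start)
      expect_equal(got$site_type, single$site_type)
    }
  }
})

test_that("select_endogenous_families takes the top k deterministically", {
  fe <- setNames(c(12, 5, 8, 1, 9, 3, 11, 2, 7, 6, 10, 4),
                 sprintf("f%02d", 1:12))
  top10 <- select_endogenous_families(fe, 10)
  expect_length(top10, 10)
  expect_setequal(top10, names(sort(fe, decreasing = TRUE))[1:10])

  expect_equal(select_endogenous_families(fe, 1), "f01")

  tie <- c(zeta = 5, alpha = 5, beta = 3)
  expect_equal(select_endogenous_families(tie, 1), "alpha")
  expect_equal(select_endogenous_families(tie, 2), c("alpha", "zeta"))

  expect_error(select_endogenous_families(tie, 4), "only 3")
})

test_that("assign_group composes exogenous and endogenous targeting", {
  exo <- make_rna("exo")
  endo1 <- small_rna("endo1", "UUGGCAUGUACCGAUAAGCAA", "miRNA", "famA")
  endo2 <- small_rna("endo2", "ACCGGUUACAUGGAACCAGUU", "miRNA", "famB")
  exo_site <- seed_site_strings(exo)[["8mer"]]
  e1_site <- seed_site_strings(endo1)[["8mer"]]
  e2_site <- seed_site_strings(endo2)[["8mer"]]

  utr <- paste0("TT", exo_site, "TTTT")
  a <- assign_group(utr, exo, list(endo1, endo2))
  expect_equal(a$group, "T-Endo")
  expect_true(a$is_exo_target)
  expect_false(a$is_endo_target)

  utr <- paste0("TTTT", e1_site, "TTTT")
  a <- assign_group(utr, exo, list(endo1, endo2))
  expect_equal(a$group, "NT+Endo")

  utr <- paste0("GG", exo_site, "GG", exo_site, "GG", e1_site, "GG",
                e1_site, "GG", e2_site, "GG")
  a <- assign_group(utr, exo, list(endo1, endo2))
  expect_equal(a$group, "T+Endo")
  expect_equal(a$n_sites, 2)
  expect_equal(a$n_endo_sites, 3)
  # the brute-force oracle agrees per RNA
  expect_equal(a$n_sites, nrow(oracle_seed_sites(exo$mature_seq, utr)))
  expect_equal(a$n_endo_sites,
               nrow(oracle_seed_sites(endo1$mature_seq, utr)) +
                 nrow(oracle_seed_sites(endo2$mature_seq, utr)))

  ag <- assign_groups(gene_set("g1", utr), exo, list(endo1, endo2))
  expect_equal(ag$group, "T+Endo")
  expect_equal(ag$n_sites, 2L)
  expect_equal(ag$n_endo_sites, 3L)
})
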