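small_cfg <- function(...) {
  sim_config(n_genes = 150, ...)
}

test_that("sim_config validates its fields", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_genes = 5), ">= 10")
  expect_error(sim_config(gc_content = 1.2), "probabilities")
  expect_error(sim_config(knockdown_per_site = -1), ">= 0")
})

test_that("generate_genome is deterministic and honors degenerate settings", {
  cfg <- small_cfg(seed = 42)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1, g2)
  g3 <- generate_genome(small_cfg(seed = 43))
  expect_false(identical(g1$utr_seq, g3$utr_seq))

  # conservation prior degenerate at 1 -> every gene fully conserved
  cfg1 <- small_cfg(cons_rate_alpha = 1e9, cons_rate_beta = 1e-9,
                    cons_zero_frac = 0, seed = 1)
  g <- generate_genome(cfg1)
  scores <- vapply(g$cons_track, conservation_score, numeric(1))
  expect_equal(scores, rep(1, length(g)))
})

test_that("NoExp fraction is within binomial 99% bounds of its parameter", {
  cfg <- sim_config(n_genes = 10000, expr_zero_frac = 0.2,
                    with_tracks = FALSE, with_promoters = FALSE, seed = 7)
  g <- generate_genome(cfg)
  n0 <- sum(g$expr_score == 0)
  bounds <- qbinom(c(0.005, 0.995), 10000, 0.2)
  expect_gte(n0, bounds[1])
  expect_lte(n0, bounds[2])
})

test_that("plant_sites plants exactly recoverable sites", {
  set.seed(50)
  cfg <- small_cfg(seed = 50)
  genes <- generate_genome(cfg)
  rnas <- make_small_rnas(c("x1", "x2", "e1"), c("siRNA", "miRNA", "miRNA"))
  pl <- suppressWarnings(plant_sites(genes, rnas, c(0.3, 0.3, 0.2), cfg))
  rec <- count_sites_matrix(rnas, pl$genes)
  key <- paste(rec$gene_id, rec$rna_id)
  tr <- pl$truth[match(key, paste(pl$truth$gene_id, pl$truth$rna_id)), ]
  expect_equal(rec$n_sites, tr$n_sites)
  expect_gt(sum(pl$truth$n_sites), 0)
  # per-site table agrees with find_seed_sites at each planted locus
  for (i in sample(nrow(pl$sites), min(10, nrow(pl$sites)))) {
    row <- pl$sites[i, ]
    utr <- pl$genes$utr_seq[pl$genes$gene_id == row$gene_id]
    rna <- rnas[[which(vapply(rnas, `[[`, "", "rna_id") == row$rna_id)]]
    hits <- find_seed_sites(rna, utr)
    expect_true(row$start %in% hits$start)
  }

  # zero rate -> no targets
  pl0 <- plant_sites(genes, rnas, 0, cfg)
  expect_equal(sum(pl0$truth$n_sites), 0)
  rec0 <- count_sites_matrix(rnas, pl0$genes)
  expect_equal(sum(rec0$n_sites), 0)
})

test_that("simulate_experiment has the stated closed form at zero noise", {
  set.seed(51)
  cfg <- sim_config(n_genes = 60, noise_sd = 0, competition_shift = 0,
                    dilution_strength = 0, array_sensitivity_slope = 0,
                    knockdown_per_site = 0.1, seed = 51)
  genes <- generate_genome(cfg)
  rnas <- make_small_rnas("x1", "miRNA")
  pl <- suppressWarnings(plant_sites(genes, rnas, 0.8, cfg))
  sim <- simulate_experiment(pl$genes, rnas[[1]], list(), "microarray",
                             "transfection", cfg, truth = pl$truth)
  two <- pl$truth$gene_id[pl$truth$n_sites == 2]
  skip_if(length(two) == 0, "no two-site gene drawn")
  expect_equal(unname(sim$sample$log_ratios[two]),
               rep(-0.2, length(two)), tolerance = 1e-12)

  # inhibition flips the exogenous effect sign (raw convention)
  sim_inh <- simulate_experiment(pl$genes, rnas[[1]], list(), "microarray",
                                 "inhibition", cfg, truth = pl$truth)
  expect_equal(unname(sim_inh$sample$log_ratios[two]),
               rep(0.2, length(two)), tolerance = 1e-12)
})

test_that("competition up-shifts endogenous targets", {
  cfg <- sim_config(n_genes = 3000, competition_shift = 0.08,
                    knockdown_per_site = 0.1, with_tracks = FALSE,
                    with_promoters = FALSE, seed = 52)
  genes <- generate_genome(cfg)
  rnas <- make_small_rnas(c("x1", "e1", "e2"), "miRNA")
  pl <- suppressWarnings(plant_sites(genes, rnas, c(0.15, 0.12, 0.12), cfg))
  set.seed(520)
  sim <- simulate_experiment(pl$genes, rnas[[1]], rnas[2:3], "proteomics",
                             "transfection", cfg, truth = pl$truth)
  tr <- sim$truth
  nt <- !tr$is_exo_target
  expect_gt(mean(tr$mu[nt & tr$is_endo_target]),
            mean(tr$mu[nt & !tr$is_endo_target]))
  lr <- sim$sample$log_ratios
  m <- match(names(lr), tr$gene_id)
  up <- mean(lr[nt[m] & tr$is_endo_target[m]])
  flat <- mean(lr[nt[m] & !tr$is_endo_target[m]])
  expect_gt(up, flat)
})

test_that("simulate_study is reproducible and write/read round trips", {
  cfg <- small_cfg(seed = 60)
  s1 <- suppressWarnings(simulate_study(cfg))
  s2 <- suppressWarnings(simulate_study(cfg))
  expect_identical(s1$genes$utr_seq, s2$genes$utr_seq)
  expect_identical(s1$truth, s2$truth)
  expect_identical(
    s1$experiments[[1]]$samples[[1]]$log_ratios,
    s2$experiments[[1]]$samples[[1]]$log_ratios)

  d <- withr::local_tempdir()
  write_study(s1, d)
  expect_true(file.exists(file.path(d, "utrs.fa")))
  st <- read_study(d)
  expect_equal(length(st$genes), length(s1$genes))
  expect_equal(length(st$experiments), nrow(s1$design))
  # the rescanned assignments agree with the planted truth
  asn <- st$assignments
  tru <- s1$assignments
  key <- paste(asn$gene_id, asn$rna_id)
  tru <- tru[match(key, paste(tru$gene_id, tru$rna_id)), ]
  expect_equal(asn$n_sites, tru$n_sites)
  expect_equal(asn$n_endo_sites, tru$n_endo_sites)
})

test_that("simulate_parclip enriches binding among endogenous targets", {
  cfg <- small_cfg(seed = 61)
  study <- suppressWarnings(simulate_study(cfg))
  set.seed(61)
  clip <- simulate_parclip(study, capture_prob = 1, mean_depth = 10,
                           background_rate = 0)
  calls <- call_binding_all(clip$read_map, study$genes$gene_id)
  endo_ids <- vapply(study$endo_rnas, `[[`, "", "rna_id")
  endo_n <- tapply(study$truth$n_sites[study$truth$rna_id %in% endo_ids],
                   study$truth$gene_id[study$truth$rna_id %in% endo_ids],
                   sum)[study$genes$gene_id]
  # with certain capture and depth mostly >= 5, binding tracks targeting
  has_endo <- endo_n > 0
  expect_gt(mean(calls$bound[has_endo]), 0.5)
  expect_lt(mean(calls$bound[!has_endo]), 0.05)
})
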