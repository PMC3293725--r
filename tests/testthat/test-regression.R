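test_that("aggregate_ts_scores sums and negates", {
  expect_equal(aggregate_ts_scores(c(-0.2, -0.3)), 0.5)
  expect_equal(aggregate_ts_scores(numeric(0)), 0)
  expect_equal(aggregate_ts_scores(-0.1), 0.1)
})

test_that("normalize_factor maps linearly and clips", {
  expect_equal(normalize_factor(64, 6.1e-5, 64), 1.0)
  expect_equal(normalize_factor(6.1e-5, 6.1e-5, 64), 0.0)
  expect_equal(normalize_factor(25, 0, 20), 1.0)
  expect_equal(normalize_factor(-3, 0, 20), 0.0)
  expect_equal(normalize_factor(10, 0, 20), 0.5)
  expect_error(normalize_factor(1, 5, 5), "exceed")
})

make_study_rows <- function(n = 400, seed = 30) {
  set.seed(seed)
  genes <- sprintf("g%04d", 1:n)
  feats <- make_features(genes, utr_length = sample(50:3000, n, TRUE),
                         cons_score = runif(n),
                         expr_score = rlnorm(n, -3, 1.5))
  ns <- pmax(1L, rpois(n, 1.4))
  ne <- rpois(n, 1)
  asn <- make_assignments(genes, "r1", ns, ne)
  lr <- setNames(-0.1 * ns + 0.05 * (ne > 0) + rnorm(n, 0, 0.05), genes)
  r <- make_rna("r1")
  e <- make_experiment(samples = list(make_sample("s1", r, lr)))
  list(rows = build_factor_table(list(e), asn, feats), feats = feats,
       asn = asn, e = e)
}

test_that("build_factor_table negates responses, codes platforms, and drops
          non-targets", {
  genes <- c("g1", "g2", "g3")
  feats <- make_features(genes, utr_length = c(500, 1000, 2000),
                         cons_score = c(0.2, 0.5, 0.8),
                         expr_score = c(1, 2, 3))
  asn <- make_assignments(genes, "r1", c(2L, 0L, 1L), c(0L, 1L, 3L))
  r <- make_rna("r1")
  e <- make_experiment(samples = list(
    make_sample("s1", r, c(g1 = -0.3, g2 = 0.2, g3 = 0.1))))
  rows <- build_factor_table(list(e), asn, feats)
  expect_equal(rows$gene_id, c("g1", "g3"))  # g2 is not a target
  expect_equal(rows$response, c(0.3, -0.1))
  expect_equal(rows$p_ma, c(1L, 1L))
  expect_equal(rows$e_oe, c(1L, 1L))
  expect_equal(rows$ln3, c(0.5, 1.0))        # 2000 clips at max 1000
  expect_equal(rows$site_m, c(2, 1) / 20)
  expect_equal(rows$endo_m, c(0, 3) / 30)
  expect_equal(rows$site_s, c(3, 3) / 6000)  # per-sample total
})

test_that("fit_linear recovers exact linear data and validates inputs", {
  set.seed(31)
  n <- 60
  rows <- data.frame(site_m = runif(n), ln3 = runif(n))
  rows$response <- 2 * rows$site_m
  fit <- fit_linear(rows, c("site_m", "ln3"))
  expect_equal(unname(fit$coefficients["site_m"]), 2, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_lte(fit$adjusted_r2, fit$r2)

  rows$flat <- 1
  expect_error(fit_linear(rows, c("site_m", "flat")), "zero-variance")
  tiny <- rows[1:10, ]
  expect_error(fit_linear(tiny, rep(c("site_m", "ln3"), 6)),
               "under-determined|duplicate|absent")
  expect_error(fit_linear(rows, c("site_m", "nope")), "absent")
})

test_that("OLS equals the closed-form normal-equations oracle", {
  set.seed(32)
  n <- 100
  d <- data.frame(a = runif(n), b = runif(n), c = rbinom(n, 1, 0.5))
  d$response <- 0.5 + 1.5 * d$a - 2 * d$b + 0.3 * d$c + rnorm(n, 0, 0.1)
  fit <- fit_linear(d, c("a", "b", "c"))
  X <- cbind(1, d$a, d$b, d$c)
  beta <- solve(t(X) %*% X, t(X) %*% d$response)
  expect_equal(unname(fit$coefficients), as.numeric(beta),
               tolerance = 1e-8)
})

test_that("r2 is invariant to affine rescaling of one factor", {
  st <- make_study_rows()
  fit1 <- fit_linear(st$rows, c("ln3", "site_m", "endo_m"))
  scaled <- st$rows
  scaled$ln3 <- 3 + 10 * scaled$ln3
  fit2 <- fit_linear(scaled, c("ln3", "site_m", "endo_m"))
  expect_equal(fit1$r2, fit2$r2, tolerance = 1e-10)
})

test_that("adding ts_score to the same rows never decreases r2", {
  st <- make_study_rows()
  ts <- data.frame(rna_id = "r1", gene_id = st$rows$gene_id,
                   ts_score = pmin(2, 0.2 * st$rows$site_m * 20 +
                                     runif(nrow(st$rows), 0, 0.1)))
  rows9 <- build_factor_table(list(st$e), st$asn, st$feats, ts_scores = ts)
  base_terms <- c("ln3", "cs3", "exp", "site_m", "endo_m")
  fit_base <- fit_linear(rows9, base_terms)
  fit_ts <- fit_linear(rows9, c(base_terms, "ts_score"))
  expect_gte(fit_ts$r2, fit_base$r2 - 1e-12)
})

test_that("preset term sets fit the synthetic factor table", {
  st <- make_study_rows(n = 500)
  rows <- st$rows
  # a single one-sample experiment leaves p_ma/e_oe/site_s constant;
  # presets need variation in every term
  rows$p_ma <- rbinom(nrow(rows), 1, 0.5)
  rows$e_oe <- rbinom(nrow(rows), 1, 0.5)
  rows$site_s <- runif(nrow(rows))
  fit <- fit_linear(rows, "main_8")
  expect_equal(length(fit$terms), 8)
  expect_gt(unname(fit$coefficients["site_m"]), 0)
  fit_int <- fit_linear(rows, "interactions_8")
  expect_equal(length(fit_int$terms), 8 + choose(8, 2))
  expect_gte(fit_int$r2, fit$r2 - 1e-12)
})
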