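# Linear regression on gene-context factors: TargetScan score aggregation,
# min-max normalization, factor-table construction and OLS fits with
# optional all-pairwise interactions.

#' Aggregate per-site TargetScan context scores to one mRNA-level score
#'
#' Site scores of one miRNA:mRNA pair are summed and negated, so a high
#' aggregated score marks a strong predicted down-regulation candidate
#' (context scores are negative for effective sites).
#'
#' @param site_scores numeric vector of per-site context scores (possibly
#'   empty).
#' @return `-sum(site_scores)`; 0 when there are no sites.
#' @export
aggregate_ts_scores <- function(site_scores) {
  -sum(site_scores)
}

#' Min-max normalize a factor value into \[0,1\]
#'
#' Values outside `[min, max]` are clipped after the linear map, keeping the
#' contract that every regression factor lies in \[0,1\].
#'
#' @param raw raw factor value(s).
#' @param min,max the factor's reference range (`max > min`).
#' @return normalized value(s) in \[0,1\].
#' @export
normalize_factor <- function(raw, min, max) {
  if (max <= min) stop("max must exceed min", call. = FALSE)
  pmin(1, pmax(0, (raw - min) / (max - min)))
}

#' Reference normalization ranges for the regression factors
#'
#' The printed reference ranges: `ln3` (0, 1000), `cs3` (0, 1), `exp`
#' (6.1e-5, 64.0), `site_m` (0, 20), `endo_m` (0, 30), `site_s` (0, 6000),
#' `ts_score` (0, 2). The binary platform/assay factors `p_ma`, `e_oe` are
#' used as-is.
#'
#' @return named list of `c(min, max)` pairs.
#' @export
factor_ranges <- function() {
  list(ln3 = c(0, 1000), cs3 = c(0, 1), exp = c(6.1e-5, 64),
       site_m = c(0, 20), endo_m = c(0, 30), site_s = c(0, 6000),
       ts_score = c(0, 2))
}

#' Build the per-(gene, sample) factor table for regression
#'
#' One row per predicted target gene per sample, across all experiments.
#' Non-target genes are excluded. Factors: `ln3` (UTR length), `cs3`
#' (conservation score), `exp` (expression score), `site_m` (exogenous site
#' count), `endo_m` (endogenous site count), `site_s` (the sample's total
#' site count over its measured targets), `p_ma` (1 = microarray), `e_oe`
#' (1 = transfection), and optionally `ts_score`. Non-binary factors are
#' min-max normalized into \[0,1\] with `ranges`. The response is the negated
#' preprocessed log-ratio, so positive coefficients associate with
#' down-regulation; it is not normalized.
#'
#' @param experiments list of preprocessed [experiment_set()] objects.
#' @param assignments stacked [assign_groups()] rows covering every
#'   experiment's RNAs.
#' @param features feature table from [gene_feature_bins()] (uses
#'   `utr_length`, `cons_score`, `expr_score`).
#' @param ts_scores optional data.frame `rna_id`, `gene_id`, `ts_score`
#'   (mRNA-level aggregated scores from [aggregate_ts_scores()]).
#' @param ranges normalization ranges, see [factor_ranges()].
#' @return data.frame of factor rows with `gene_id`, `sample_id`,
#'   `experiment_id`, the normalized factors and `response`.
#' @export
build_factor_table <- function(experiments, assignments, features,
                               ts_scores = NULL, ranges = factor_ranges()) {
  feat <- features[match(assignments$gene_id, features$gene_id), ]
  akey <- paste(assignments$rna_id, assignments$gene_id, sep = "\r")
  ts_map <- NULL
  if (!is.null(ts_scores)) {
    ts_map <- setNames(ts_scores$ts_score,
                       paste(ts_scores$rna_id, ts_scores$gene_id, sep = "\r"))
  }
  rows <- lapply(experiments, function(exp) {
    stopifnot(isTRUE(exp$preprocessed))
    out <- lapply(exp$samples, function(s) {
      rid <- s$small_rna$rna_id
      sel <- assignments$rna_id == rid & assignments$is_exo_target
      a <- assignments[sel, ]
      f <- feat[sel, ]
      m <- match(a$gene_id, names(s$log_ratios))
      keep <- !is.na(m)
      a <- a[keep, ]; f <- f[keep, ]; m <- m[keep]
      if (nrow(a) == 0) return(NULL)
      if (anyNA(f$gene_id)) {
        stop("missing features for gene ", a$gene_id[is.na(f$gene_id)][1],
             call. = FALSE)
      }
      site_s <- sum(a$n_sites)
      ts <- if (is.null(ts_map)) NULL else {
        v <- unname(ts_map[paste(rid, a$gene_id, sep = "\r")])
        v[is.na(v)] <- 0
        v
      }
      d <- data.frame(
        gene_id = a$gene_id, sample_id = s$sample_id,
        experiment_id = exp$experiment_id,
        ln3 = normalize_factor(f$utr_length, ranges$ln3[1], ranges$ln3[2]),
        cs3 = normalize_factor(f$cons_score, ranges$cs3[1], ranges$cs3[2]),
        exp = normalize_factor(f$expr_score, ranges$exp[1], ranges$exp[2]),
        site_m = normalize_factor(a$n_sites, ranges$site_m[1],
                                  ranges$site_m[2]),
        endo_m = normalize_factor(a$n_endo_sites, ranges$endo_m[1],
                                  ranges$endo_m[2]),
        site_s = normalize_factor(site_s, ranges$site_s[1],
                                  ranges$site_s[2]),
        p_ma = as.integer(exp$platform == "microarray"),
        e_oe = as.integer(exp$assay == "transfection"),
        response = -unname(s$log_ratios[m]))
      if (!is.null(ts)) {
        d$ts_score <- normalize_factor(ts, ranges$ts_score[1],
                                       ranges$ts_score[2])
      }
      d
    })
    do.call(rbind, out)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

MAIN_8 <- c("ln3", "cs3", "exp", "site_m", "endo_m", "site_s", "p_ma", "e_oe")
MAIN_9 <- c(MAIN_8, "ts_score")

#' Ordinary least squares fit of down-regulation on the context factors
#'
#' Fits `response ~ factors` (with intercept) by OLS. Interaction modes add
#' all pairwise products of the chosen main effects (products of the
#' normalized factors).
#'
#' @param rows factor table from [build_factor_table()].
#' @param terms `"main_8"`, `"main_9"`, `"interactions_8"`,
#'   `"interactions_9"`, or a character vector of factor column names.
#' @return list of class `regression_result`: `terms`, `coefficients`
#'   (including `(Intercept)`), `p_values` (two-sided t), `r2`,
#'   `adjusted_r2`, `n_rows`.
#' @export
fit_linear <- function(rows, terms = "main_8") {
  interactions <- FALSE
  if (length(terms) == 1 && terms %in% c("main_8", "main_9",
                                         "interactions_8",
                                         "interactions_9")) {
    interactions <- startsWith(terms, "interactions")
    main <- if (endsWith(terms, "9")) MAIN_9 else MAIN_8
  } else {
    main <- terms
  }
  missing <- setdiff(main, colnames(rows))
  if (length(missing)) {
    stop("factor columns absent from rows: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  d <- rows[c(main, "response")]
  novar <- vapply(d[main], function(x) sd(x) == 0, logical(1))
  if (any(novar)) {
    stop("zero-variance term: ", paste(main[novar], collapse = ", "),
         call. = FALSE)
  }
  rhs <- if (interactions) {
    paste0("(", paste(main, collapse = " + "), ")^2")
  } else {
    paste(main, collapse = " + ")
  }
  n_terms <- if (interactions) {
    length(main) + choose(length(main), 2)
  } else length(main)
  if (nrow(d) <= n_terms + 1) {
    stop(sprintf("under-determined fit: %d rows for %d terms", nrow(d),
                 n_terms), call. = FALSE)
  }
  fit <- lm(stats::as.formula(paste("response ~", rhs)), data = d)
  if (anyNA(coef(fit))) {
    stop("rank-deficient design: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "),
         call. = FALSE)
  }
  sm <- summary(fit)
  structure(list(terms = setdiff(names(coef(fit)), "(Intercept)"),
                 coefficients = coef(fit),
                 p_values = sm$coefficients[, "Pr(>|t|)"],
                 r2 = sm$r.squared, adjusted_r2 = sm$adj.r.squared,
                 n_rows = nrow(d)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> n=%d, %d terms, R2=%.4f (adj %.4f)\n",
              x$n_rows, length(x$terms), x$r2, x$adjusted_r2))
  df <- data.frame(term = names(x$coefficients),
                   coefficient = signif(unname(x$coefficients), 4),
                   p_value = signif(unname(x$p_values), 3))
  print(df, row.names = FALSE)
  invisible(x)
}
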