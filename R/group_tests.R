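# Non-parametric subgroup testing: one-sided Wilcoxon / Kolmogorov-Smirnov
# down-regulation tests per feature subgroup, sample-level scores,
# experiment-vs-sample trend counts and correlations, competition tests, and
# feature-characteristic tests.


#' One-sided down-regulation test between two groups of log-ratios
#'
#' Tests the alternative that `values_in` is stochastically smaller (more
#' down-regulated) than `values_out`. The Wilcoxon rank-sum test is exact
#' when both groups have at most 25 observations and there are no ties,
#' otherwise it uses the normal approximation with continuity and tie
#' correction. The one-sided Kolmogorov-Smirnov alternative is that the
#' empirical CDF of `values_in` lies above that of `values_out`.
#'
#' @param values_in log-ratios of the subgroup under test.
#' @param values_out log-ratios of the remaining genes.
#' @param method `"wilcoxon"` or `"ks"`.
#' @return the one-sided p-value.
#' @export
subgroup_downreg_test <- function(values_in, values_out,
                                  method = c("wilcoxon", "ks")) {
  method <- match.arg(method)
  if (length(values_in) == 0 || length(values_out) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (method == "wilcoxon") {
    exact <- length(values_in) <= 25 && length(values_out) <= 25 &&
      !anyDuplicated(c(values_in, values_out))
    suppressWarnings(
      wilcox.test(values_in, values_out, alternative = "less",
                  exact = exact, correct = TRUE)$p.value)
  } else {
    suppressWarnings(
      ks.test(values_in, values_out, alternative = "greater")$p.value)
  }
}

# Pull pooled (gene, sample) log-ratio pairs of predicted target genes for
# an experiment, annotated with the gene's feature bin.
target_pairs <- function(exp, assignments, features, feature_col) {
  stopifnot(isTRUE(exp$preprocessed))
  bins <- setNames(features[[feature_col]], features$gene_id)
  by_rna <- split(assignments[assignments$is_exo_target, ],
                  assignments$rna_id[assignments$is_exo_target])
  out <- lapply(exp$samples, function(s) {
    a <- by_rna[[s$small_rna$rna_id]]
    if (is.null(a)) return(NULL)
    g <- intersect(a$gene_id, names(s$log_ratios))
    if (length(g) == 0) return(NULL)
    miss <- g[!(g %in% features$gene_id)]
    if (length(miss)) {
      stop("no feature bins for tested gene ", miss[1], call. = FALSE)
    }
    data.frame(sample_id = s$sample_id, gene_id = g,
               log_ratio = unname(s$log_ratios[g]),
               bin = bins[g], row.names = NULL)
  })
  do.call(rbind, out)
}

scan_one_scope <- function(pairs, subgroups, method) {
  res <- lapply(subgroups, function(sg) {
    inb <- !is.na(pairs$bin) & pairs$bin == sg
    n_in <- sum(inb)
    n_out <- sum(!inb)
    p <- if (n_in == 0 || n_out == 0) NA_real_ else
      subgroup_downreg_test(pairs$log_ratio[inb], pairs$log_ratio[!inb],
                            method)
    data.frame(subgroup = as.character(sg), p_value = p,
               n_in = n_in, n_out = n_out,
               neg_log2_p = -log2(p))
  })
  do.call(rbind, res)
}

#' Scan one feature's subgroups for preferential down-regulation
#'
#' For each subgroup of the chosen gene-context feature, tests whether the
#' predicted target genes in the subgroup are more down-regulated than the
#' predicted target genes in all other subgroups. Only predicted target
#' genes of each sample's small RNA enter the test. At `scope =
#' "experiment"` the (gene, sample) pairs of all samples are pooled into one
#' test per subgroup; at `scope = "per_sample"` each sample is tested
#' separately.
#'
#' Subgroups with no target genes are reported with `p_value = NA`.
#'
#' @param exp a preprocessed [experiment_set()].
#' @param assignments data.frame from [assign_groups()] (stacked over the
#'   experiment's RNAs).
#' @param features feature table from [gene_feature_bins()].
#' @param feature one of `"length"`, `"conservation"`, `"expression"`,
#'   `"cpg"`, `"hk"`, `"dev"`.
#' @param method `"wilcoxon"` or `"ks"`.
#' @param scope `"experiment"` or `"per_sample"`.
#' @return data.frame with columns `experiment_id`, `sample_id` (`NA` at
#'   experiment scope), `feature`, `subgroup`, `method`, `p_value`, `n_in`,
#'   `n_out`, `neg_log2_p`.
#' @export
run_feature_scan <- function(exp, assignments, features,
                             feature = names(FEATURE_COLUMNS),
                             method = c("wilcoxon", "ks"),
                             scope = c("experiment", "per_sample")) {
  feature <- match.arg(feature)
  method <- match.arg(method)
  scope <- match.arg(scope)
  col <- FEATURE_COLUMNS[[feature]]
  pairs <- target_pairs(exp, assignments, features, col)
  subgroups <- if (is.factor(features[[col]])) levels(features[[col]]) else
    sort(unique(features[[col]]))
  empty <- data.frame(subgroup = character(0), p_value = numeric(0),
                      n_in = integer(0), n_out = integer(0),
                      neg_log2_p = numeric(0), sample_id = character(0))
  if (scope == "experiment") {
    res <- if (is.null(pairs)) empty else
      cbind(scan_one_scope(pairs, subgroups, method),
            sample_id = NA_character_)
  } else {
    res <- if (is.null(pairs)) empty else do.call(rbind, lapply(
      split(pairs, pairs$sample_id), function(ps) {
        cbind(scan_one_scope(ps, subgroups, method),
              sample_id = ps$sample_id[1])
      }))
  }
  if (nrow(res) == 0) return(res)
  out <- data.frame(experiment_id = exp$experiment_id,
                    sample_id = res$sample_id, feature = feature,
                    subgroup = res$subgroup, method = method,
                    p_value = res$p_value, n_in = res$n_in,
                    n_out = res$n_out, neg_log2_p = res$neg_log2_p,
                    row.names = NULL)
  out[order(out$subgroup, out$sample_id, na.last = FALSE), ]
}

#' Fraction of significant per-sample tests (the sample-level score)
#'
#' @param per_sample_pvalues p-values of one subgroup's test across an
#'   experiment's samples (NA entries, from untestable samples, are dropped).
#' @param alpha significance cutoff (strictly below; default 0.05).
#' @return fraction of p-values strictly below `alpha`, in \[0,1\].
#' @export
sample_level_score <- function(per_sample_pvalues, alpha = 0.05) {
  p <- per_sample_pvalues[!is.na(per_sample_pvalues)]
  if (length(p) == 0) stop("no p-values to score", call. = FALSE)
  mean(p < alpha)
}

#' Count experiment-level and sample-level support per subgroup
#'
#' For each (feature, subgroup): `expr_count` is the number of experiments
#' whose experiment-level test is significant (`p < alpha`); `smpl_count` is
#' the number of experiments whose sample-level score ([sample_level_score()]
#' over the experiment's per-sample tests) is strictly greater than
#' `score_threshold`.
#'
#' @param experiment_results stacked [run_feature_scan()] output at
#'   experiment scope over several experiments.
#' @param sample_results stacked per-sample scope output for the same
#'   experiments.
#' @param alpha experiment-level significance cutoff (default 0.05).
#' @param score_threshold sample-level score threshold (strict; default 0.5).
#' @return data.frame `feature`, `subgroup`, `expr_count`, `smpl_count`.
#' @export
trend_counts <- function(experiment_results, sample_results, alpha = 0.05,
                         score_threshold = 0.5) {
  stopifnot(setequal(unique(experiment_results$experiment_id),
                     unique(sample_results$experiment_id)))
  key <- unique(experiment_results[c("feature", "subgroup")])
  counts <- lapply(seq_len(nrow(key)), function(i) {
    er <- experiment_results[
      experiment_results$feature == key$feature[i] &
        experiment_results$subgroup == key$subgroup[i], ]
    sr <- sample_results[
      sample_results$feature == key$feature[i] &
        sample_results$subgroup == key$subgroup[i], ]
    scores <- vapply(split(sr, sr$experiment_id), function(d) {
      if (all(is.na(d$p_value))) NA_real_ else
        sample_level_score(d$p_value, alpha)
    }, numeric(1))
    data.frame(feature = key$feature[i], subgroup = key$subgroup[i],
               expr_count = sum(er$p_value < alpha, na.rm = TRUE),
               smpl_count = sum(scores > score_threshold, na.rm = TRUE))
  })
  do.call(rbind, counts)
}

#' Pearson correlation between experiment-level and sample-level trends
#'
#' @param expr_counts,smpl_counts equal-length (>= 3) integer vectors of
#'   per-subgroup support counts (see [trend_counts()]).
#' @return list with `r` (Pearson product-moment correlation) and `p`
#'   (two-sided, from `t = r * sqrt(n-2) / sqrt(1-r^2)`).
#' @export
trend_correlation <- function(expr_counts, smpl_counts) {
  n <- length(expr_counts)
  stopifnot(n == length(smpl_counts), n >= 3)
  if (sd(expr_counts) == 0 || sd(smpl_counts) == 0) {
    stop("zero variance in trend counts", call. = FALSE)
  }
  r <- cor(expr_counts, smpl_counts)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(r = r, p = 2 * pt(-abs(t), df = n - 2))
}

#' Competition test: are T-Endo genes more down-regulated than T+Endo genes?
#'
#' Within each subgroup of the chosen feature, one-sidedly tests whether
#' exogenous-target genes *without* endogenous sites (T-Endo) are more
#' down-regulated than exogenous-target genes *with* endogenous sites
#' (T+Endo). Only transfection experiments are admissible: in inhibition
#' experiments the endogenous-competition logic does not apply.
#'
#' Subgroups where either side is empty are reported with `p_value = NA`.
#'
#' @inheritParams run_feature_scan
#' @return data.frame like [run_feature_scan()] with `n_in` = T-Endo pairs
#'   and `n_out` = T+Endo pairs.
#' @export
competition_test <- function(exp, assignments, features,
                             feature = names(FEATURE_COLUMNS),
                             method = c("wilcoxon", "ks"),
                             scope = c("experiment", "per_sample")) {
  feature <- match.arg(feature)
  method <- match.arg(method)
  scope <- match.arg(scope)
  if (exp$assay != "transfection") {
    stop("competition_test requires a transfection experiment", call. = FALSE)
  }
  col <- FEATURE_COLUMNS[[feature]]
  pairs <- target_pairs(exp, assignments, features, col)
  grp <- setNames(assignments$group,
                  paste(assignments$rna_id, assignments$gene_id, sep = "\r"))
  rna_of <- setNames(
    vapply(exp$samples, function(s) s$small_rna$rna_id, ""),
    vapply(exp$samples, `[[`, "", "sample_id"))
  if (!is.null(pairs)) {
    pairs$group <- unname(grp[paste(rna_of[pairs$sample_id], pairs$gene_id,
                                    sep = "\r")])
  }
  subgroups <- if (is.factor(features[[col]])) levels(features[[col]]) else
    sort(unique(features[[col]]))
  one <- function(d, sid) {
    res <- lapply(subgroups, function(sg) {
      sel <- !is.na(d$bin) & d$bin == sg
      vin <- d$log_ratio[sel & d$group == "T-Endo"]
      vout <- d$log_ratio[sel & d$group == "T+Endo"]
      p <- if (length(vin) == 0 || length(vout) == 0) NA_real_ else
        subgroup_downreg_test(vin, vout, method)
      data.frame(subgroup = as.character(sg), p_value = p,
                 n_in = length(vin), n_out = length(vout),
                 neg_log2_p = -log2(p), sample_id = sid)
    })
    do.call(rbind, res)
  }
  res <- if (is.null(pairs)) NULL
  else if (scope == "experiment") one(pairs, NA_character_)
  else do.call(rbind, lapply(split(pairs, pairs$sample_id),
                             function(ps) one(ps, ps$sample_id[1])))
  if (is.null(res)) {
    return(data.frame(experiment_id = character(0), sample_id = character(0),
                      feature = character(0), subgroup = character(0),
                      method = character(0), p_value = numeric(0),
                      n_in = integer(0), n_out = integer(0),
                      neg_log2_p = numeric(0)))
  }
  data.frame(experiment_id = exp$experiment_id, sample_id = res$sample_id,
             feature = feature, subgroup = res$subgroup, method = method,
             p_value = res$p_value, n_in = res$n_in, n_out = res$n_out,
             neg_log2_p = res$neg_log2_p, row.names = NULL)
}

#' Two one-sided Wilcoxon tests characterizing a gene class
#'
#' Compares a feature's values between class members and non-members in both
#' directions, as used to ask e.g. whether high-CpG genes have longer 3'
#' UTRs or higher expression than the rest.
#'
#' @param member_scores feature values of class members.
#' @param nonmember_scores feature values of non-members.
#' @return list with `p_greater` (members greater) and `p_less` (members
#'   smaller), both one-sided Wilcoxon rank-sum p-values.
#' @export
characteristic_test <- function(member_scores, nonmember_scores) {
  if (length(member_scores) == 0 || length(nonmember_scores) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  exact <- length(member_scores) <= 25 && length(nonmember_scores) <= 25 &&
    !anyDuplicated(c(member_scores, nonmember_scores))
  pg <- suppressWarnings(
    wilcox.test(member_scores, nonmember_scores, alternative = "greater",
                exact = exact, correct = TRUE)$p.value)
  pl <- suppressWarnings(
    wilcox.test(member_scores, nonmember_scores, alternative = "less",
                exact = exact, correct = TRUE)$p.value)
  list(p_greater = pg, p_less = pl)
}
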