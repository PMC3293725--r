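# AGO PAR-CLIP binding calls with long/short enrichment tests, the
# target-dilution correlation, and the platform-bias (down-regulation
# enrichment) analysis.

#' Call an AGO binding site from mapped read positions on one 3' UTR
#'
#' A UTR is called bound when at least one position has a mapped read count
#' at or above `depth_threshold` (default 5 reads).
#'
#' @param read_positions data.frame with columns `position`, `read_count`
#'   (or an empty data.frame / `NULL` for no reads).
#' @param depth_threshold minimum read depth at a single position.
#' @return list with `bound` (logical) and `max_depth` (integer; 0 when no
#'   reads).
#' @export
call_binding <- function(read_positions, depth_threshold = 5) {
  if (is.null(read_positions) || nrow(read_positions) == 0) {
    return(list(bound = FALSE, max_depth = 0L))
  }
  if (any(read_positions$read_count < 0)) {
    stop("negative read count", call. = FALSE)
  }
  md <- max(read_positions$read_count)
  list(bound = md >= depth_threshold, max_depth = as.integer(md))
}

#' Binding calls for a whole cohort
#'
#' @param read_map named list gene_id -> data.frame(position, read_count),
#'   as returned by [read_read_positions()].
#' @param gene_ids cohort gene ids; genes absent from `read_map` are unbound.
#' @param depth_threshold see [call_binding()].
#' @return data.frame `gene_id`, `bound`, `max_depth`.
#' @export
call_binding_all <- function(read_map, gene_ids, depth_threshold = 5) {
  calls <- lapply(gene_ids, function(g) {
    call_binding(read_map[[g]], depth_threshold)
  })
  data.frame(gene_id = gene_ids,
             bound = vapply(calls, `[[`, logical(1), "bound"),
             max_depth = vapply(calls, `[[`, integer(1), "max_depth"))
}

#' Long vs short 3' UTR binding enrichment (Fisher's exact test)
#'
#' Merges the five length subgroups into `long` (VeryLong, Long) and `short`
#' (MedLong, MedShort, Short) and tests, one-sidedly, whether bound genes
#' are enriched among long-3'-UTR genes.
#'
#' @param bound logical vector of binding calls per gene.
#' @param length_group factor of length subgroups per gene (levels as in
#'   [bin_length()]).
#' @return list with `odds_ratio`, `p_value` and the 2x2 `table`
#'   (long/short x bound/unbound).
#' @export
long_short_fisher <- function(bound, length_group) {
  stopifnot(length(bound) == length(length_group))
  long <- length_group %in% c("Long", "VeryLong")
  tab <- matrix(c(sum(bound & long), sum(!bound & long),
                  sum(bound & !long), sum(!bound & !long)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("long", "short"),
                                c("bound", "unbound")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate 2x2 table (empty row or column)", call. = FALSE)
  }
  ft <- fisher.test(tab, alternative = "greater")
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value, table = tab)
}

#' Per-length-subgroup bound-gene counts and percentages
#'
#' @param bound logical binding calls per gene.
#' @param length_group factor of length subgroups per gene.
#' @return data.frame `length_group`, `n_genes`, `n_bound`, `pct_bound`.
#' @export
binding_summary <- function(bound, length_group) {
  lg <- factor(length_group, levels = LENGTH_LEVELS)
  n <- tapply(bound, lg, length)
  n[is.na(n)] <- 0L
  nb <- tapply(bound, lg, sum)
  nb[is.na(nb)] <- 0L
  data.frame(length_group = LENGTH_LEVELS,
             n_genes = as.integer(n), n_bound = as.integer(nb),
             pct_bound = ifelse(n > 0, 100 * nb / n, NA_real_),
             row.names = NULL)
}

#' Target-dilution scan: total site count vs mean target log-ratio
#'
#' Per sample, sums the predicted target-site counts over all predicted
#' target genes (the sample's "total number of target sites") and averages
#' the targets' log-ratios, then correlates the two across samples. A
#' positive correlation is the dilution signature: samples whose RNA has
#' many target sites knock each target down less. With `endo_free = TRUE`
#' the per-sample mean is computed over T-Endo genes only (targets without
#' endogenous sites), removing the competition contribution.
#'
#' @param samples list of [mir_sample()] objects (preprocessed log10 scale).
#' @param assignments stacked [assign_groups()] rows covering each sample's
#'   RNA.
#' @param endo_free restrict the averaged targets to T-Endo genes.
#' @return list with `points` (data.frame `sample_id`, `rna_id`, `rna_kind`,
#'   `total_sites`, `mean_target_log_ratio`), `r` and `p` (Pearson, two-sided).
#'   Samples with no measured target genes are dropped with a warning.
#' @export
dilution_scan <- function(samples, assignments, endo_free = FALSE) {
  pts <- lapply(samples, function(s) {
    a <- assignments[assignments$rna_id == s$small_rna$rna_id &
                       assignments$is_exo_target, ]
    g_all <- intersect(a$gene_id, names(s$log_ratios))
    total <- sum(a$n_sites[a$gene_id %in% g_all])
    g <- if (endo_free) {
      intersect(a$gene_id[!a$is_endo_target], g_all)
    } else g_all
    if (length(g) == 0) {
      warning("sample ", s$sample_id, " has no measured target genes; ",
              "point omitted")
      return(NULL)
    }
    data.frame(sample_id = s$sample_id, rna_id = s$small_rna$rna_id,
               rna_kind = s$small_rna$kind, total_sites = total,
               mean_target_log_ratio = mean(s$log_ratios[g]))
  })
  pts <- do.call(rbind, pts)
  if (is.null(pts) || nrow(pts) < 3) {
    stop("need at least 3 samples with target genes", call. = FALSE)
  }
  if (sd(pts$total_sites) == 0 || sd(pts$mean_target_log_ratio) == 0) {
    stop("zero variance across samples; correlation undefined", call. = FALSE)
  }
  ct <- cor.test(pts$total_sites, pts$mean_target_log_ratio)
  list(points = pts, r = unname(ct$estimate), p = ct$p.value)
}


#' Enrichment of down-regulated genes across expression subgroups
#'
#' Per experiment and expression subgroup, computes the log2 enrichment of
#' down-regulated genes relative to all measured genes, then fits, per
#' platform, a line of enrichment against the subgroup ordinal (NoExp = 1 to
#' VeryHigh = 6). A positive microarray slope with a flat proteomics slope
#' is the platform-bias signature: arrays under-report differential
#' expression of lowly expressed genes.
#'
#' Down-regulated means `detection p < alpha` and `log-ratio < lr_cut` on
#' microarrays, and `log-ratio < lr_cut` alone on proteomics. Subgroup
#' points supported by fewer than two down-regulated genes are excluded.
#'
#' @param experiments list of preprocessed [experiment_set()] objects.
#' @param features feature table from [gene_feature_bins()].
#' @param mode `"count_enrichment"` (default):
#'   `log2((n_down_g/n_down_tot) / (n_all_g/n_all_tot))`;
#'   `"ratio_of_means"`: `log2(mean down-regulated log-ratio / mean log-ratio
#'   of all genes)` within the subgroup.
#' @param alpha microarray detection p-value cutoff (default 0.01).
#' @param lr_cut log-ratio cutoff (default -0.01, log10 scale).
#' @return list with `points` (data.frame `experiment_id`, `platform`,
#'   `expr_group`, `ordinal`, `log2_enrichment`, `n_down`, `n_all`) and
#'   `fits` (data.frame `platform`, `slope`, `p_value`, `n_points`).
#' @export
downreg_enrichment <- function(experiments, features,
                               mode = c("count_enrichment", "ratio_of_means"),
                               alpha = 0.01, lr_cut = -0.01) {
  mode <- match.arg(mode)
  bins <- setNames(as.character(features$expr_group), features$gene_id)
  pts <- lapply(experiments, function(exp) {
    stopifnot(isTRUE(exp$preprocessed))
    lr <- unlist(lapply(exp$samples, `[[`, "log_ratios"))
    gid <- unlist(lapply(exp$samples, function(s) names(s$log_ratios)))
    if (exp$platform == "microarray") {
      pv <- unlist(lapply(exp$samples, function(s) {
        if (is.null(s$detection_pvalues)) {
          stop("microarray experiment ", exp$experiment_id,
               " lacks detection p-values; supply them or use the ",
               "proteomics (log-ratio only) rule via the config",
               call. = FALSE)
        }
        out <- setNames(rep(NA_real_, length(s$log_ratios)),
                        names(s$log_ratios))
        out[names(s$detection_pvalues)] <- s$detection_pvalues
        out
      }))
      down <- !is.na(pv) & pv < alpha & lr < lr_cut
    } else {
      down <- lr < lr_cut
    }
    grp <- bins[gid]
    n_down_tot <- sum(down)
    n_all_tot <- length(lr)
    res <- lapply(EXPR_LEVELS, function(g) {
      sel <- !is.na(grp) & grp == g
      n_all <- sum(sel)
      n_down <- sum(sel & down)
      if (n_down < 2 || n_all == 0 || n_down_tot == 0) return(NULL)
      enr <- if (mode == "count_enrichment") {
        log2((n_down / n_down_tot) / (n_all / n_all_tot))
      } else {
        log2(mean(lr[sel & down]) / mean(lr[sel]))
      }
      data.frame(experiment_id = exp$experiment_id,
                 platform = exp$platform, expr_group = g,
                 ordinal = unname(EXPR_ORDINAL[g]),
                 log2_enrichment = enr, n_down = n_down, n_all = n_all)
    })
    do.call(rbind, res)
  })
  pts <- do.call(rbind, pts)
  fits <- lapply(split(pts, pts$platform), function(d) {
    if (nrow(d) < 3 || sd(d$ordinal) == 0) {
      return(data.frame(platform = d$platform[1], slope = NA_real_,
                        p_value = NA_real_, n_points = nrow(d)))
    }
    fit <- summary(lm(log2_enrichment ~ ordinal, data = d))
    data.frame(platform = d$platform[1],
               slope = fit$coefficients["ordinal", "Estimate"],
               p_value = fit$coefficients["ordinal", "Pr(>|t|)"],
               n_points = nrow(d))
  })
  list(points = pts, fits = do.call(rbind, c(fits, make.row.names = FALSE)))
}
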