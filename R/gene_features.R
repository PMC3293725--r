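# Gene-context features and their discretization: 3' UTR length bins,
# conservation score and bins, expression bins, promoter CpG class, and
# housekeeping/developmental labels.


# Reference fixed cuts (upper bin bounds, inclusive) as printed for the
# human RefSeq cohort; used when binning mode = "fixed".
FIXED_LENGTH_CUTS <- c(247, 629, 1372)
FIXED_LENGTH_VERYLONG <- 4000
FIXED_CONS_CUTS <- c(0.054, 0.238)
FIXED_EXPR_CUTS <- c(0.008, 0.0344, 0.0795, 0.2007)

#' Fraction of conserved bases in a conservation track
#'
#' @param cons_track logical (or 0/1) vector of per-base conservation flags.
#' @return number of set flags divided by track length, in \[0,1\].
#' @export
conservation_score <- function(cons_track) {
  if (length(cons_track) == 0) stop("empty conservation track", call. = FALSE)
  mean(as.logical(cons_track))
}

# Empirical k-quantile bin boundaries (upper bound of each bin) of a cohort:
# bin j holds the j-th of k equally sized rank slices, ties assigned to the
# lower bin because boundaries are inclusive upper bounds.
quantile_bounds <- function(cohort, k) {
  if (length(cohort) == 0) stop("empty cohort for quantile binning",
                                call. = FALSE)
  s <- sort(cohort)
  n <- length(s)
  s[ceiling(seq_len(k) * n / k)]
}

# Assign scores to ordered bins given inclusive upper bounds (last bound is
# open above: larger scores fall in the top bin).
bin_by_bounds <- function(score, bounds, labels) {
  idx <- vapply(score, function(x) {
    if (is.na(x)) return(NA_integer_)
    j <- which(x <= bounds)[1]
    if (is.na(j)) length(bounds) + 1L else j
  }, integer(1))
  idx <- pmin(idx, length(labels))
  factor(labels[idx], levels = labels)
}

#' Bin 3' UTR lengths into the five length subgroups
#'
#' Lengths above `fixed_cut` are `VeryLong`; the remaining cohort is split
#' into four equally sized quartile subgroups (`Short`, `MedShort`,
#' `MedLong`, `Long`), either from explicit inclusive upper cuts or from the
#' empirical quartiles of a cohort.
#'
#' @param utr_len integer vector of UTR lengths.
#' @param fixed_cut `VeryLong` threshold (strictly greater than; default 4000).
#' @param quantile_cuts three inclusive upper bounds for
#'   Short/MedShort/MedLong (e.g. the reference cuts 247, 629, 1372), or
#'   `NULL`.
#' @param cohort_lengths cohort to derive empirical quartile cuts from, or
#'   `NULL`. Exactly one of `quantile_cuts`/`cohort_lengths` must be given.
#' @return factor with levels `r paste(LENGTH_LEVELS, collapse = ", ")`.
#' @export
bin_length <- function(utr_len, fixed_cut = 4000, quantile_cuts = NULL,
                       cohort_lengths = NULL) {
  if (any(utr_len < 0)) stop("negative UTR length", call. = FALSE)
  if (is.null(quantile_cuts) == is.null(cohort_lengths)) {
    stop("give exactly one of quantile_cuts or cohort_lengths", call. = FALSE)
  }
  if (is.null(quantile_cuts)) {
    sub <- cohort_lengths[cohort_lengths <= fixed_cut]
    quantile_cuts <- quantile_bounds(sub, 4)[1:3]
  }
  out <- bin_by_bounds(utr_len, c(quantile_cuts, fixed_cut), LENGTH_LEVELS)
  out[utr_len > fixed_cut] <- "VeryLong"
  out
}

#' Bin non-negative scores into k quantile subgroups with a zero class
#'
#' Scores equal to zero get `zero_label`; the non-zero scores are split into
#' `k` equally sized rank subgroups (cohort-derived inclusive upper bounds,
#' ties to the lower bin), or binned by explicit `cuts`.
#'
#' @param score numeric vector of scores.
#' @param zero_label label for exact-zero scores (e.g. `"NoConsv"`, `"NoExp"`).
#' @param k number of non-zero bins (>= 2).
#' @param cohort_scores cohort (non-zero values are used) for empirical cuts.
#' @param labels ordered labels of the k non-zero bins, low to high.
#' @param cuts optional k-1 explicit inclusive upper bounds replacing the
#'   empirical ones.
#' @return factor with levels `c(zero_label, labels)`.
#' @export
bin_by_quantiles <- function(score, zero_label, k, cohort_scores = NULL,
                             labels = NULL, cuts = NULL) {
  stopifnot(k >= 2)
  if (is.null(labels)) labels <- paste0("Q", seq_len(k))
  stopifnot(length(labels) == k)
  if (is.null(cuts)) {
    nz <- cohort_scores[!is.na(cohort_scores) & cohort_scores > 0]
    if (length(nz) == 0) stop("empty non-zero cohort", call. = FALSE)
    cuts <- quantile_bounds(nz, k)[seq_len(k - 1)]
  }
  out <- bin_by_bounds(score, cuts, labels)
  lv <- c(zero_label, labels)
  out <- factor(as.character(out), levels = lv)
  out[!is.na(score) & score == 0] <- zero_label
  out
}

#' Bin conservation scores into NoConsv/Low/Medium/High
#'
#' @param score conservation scores in \[0,1\] (see [conservation_score()]).
#' @param cohort_scores cohort for empirical tercile cuts of non-zero scores.
#' @param cuts explicit inclusive upper bounds for Low and Medium; defaults
#'   to the reference cuts `c(0.054, 0.238)` when no cohort is given.
#' @return factor with levels `r paste(CONS_LEVELS, collapse = ", ")`.
#' @export
bin_conservation <- function(score, cohort_scores = NULL, cuts = NULL) {
  if (is.null(cohort_scores) && is.null(cuts)) cuts <- FIXED_CONS_CUTS
  bin_by_quantiles(score, "NoConsv", 3, cohort_scores,
                   labels = c("Low", "Medium", "High"), cuts = cuts)
}

#' Bin expression scores into NoExp/VeryLow/Low/Medium/High/VeryHigh
#'
#' @param score non-negative expression scores.
#' @param cohort_scores cohort for empirical quintile cuts of non-zero scores.
#' @param cuts explicit inclusive upper bounds (4 values); defaults to the
#'   reference cuts `c(0.008, 0.0344, 0.0795, 0.2007)` when no cohort given.
#' @return factor with levels `r paste(EXPR_LEVELS, collapse = ", ")`.
#' @export
bin_expression <- function(score, cohort_scores = NULL, cuts = NULL) {
  if (is.null(cohort_scores) && is.null(cuts)) cuts <- FIXED_EXPR_CUTS
  bin_by_quantiles(score, "NoExp", 5, cohort_scores,
                   labels = c("VeryLow", "Low", "Medium", "High", "VeryHigh"),
                   cuts = cuts)
}

#' Classify a promoter by CpG frequency with a moving window
#'
#' Slides a `window`-nt window in `step`-nt steps over the promoter. Per
#' window, GC content is the G+C fraction and "CpG content" is the CpG
#' observed/expected ratio `(#CG * window) / (#C * #G)` (0 when the window
#' has no C or no G). The class is `"high"` when at least one window has
#' GC > 0.55 and CpG o/e > 0.75, `"low"` when no window has o/e > 0.48, and
#' `"medium"` otherwise. Promoters shorter than one window are `"unknown"`.
#'
#' @param promoter_seq promoter sequence (1 kb upstream of the TSS, say).
#' @param window window size in nt (default 500).
#' @param step step size in nt (default 5).
#' @return one of `"high"`, `"medium"`, `"low"`, `"unknown"`.
#' @export
cpg_class <- function(promoter_seq, window = 500, step = 5) {
  if (is.na(promoter_seq)) return("unknown")
  s <- normalize_seq(promoter_seq)
  n <- nchar(s)
  if (n < window) return("unknown")
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  isC <- cumsum(c(0, ch == "C"))
  isG <- cumsum(c(0, ch == "G"))
  starts <- seq(1L, n - window + 1L, by = step)
  nC <- isC[starts + window] - isC[starts]
  nG <- isG[starts + window] - isG[starts]
  # a CG dinucleotide starting at i lies inside window [s, s+window-1]
  # iff s <= i <= s+window-2
  di <- c(ch[-n] == "C" & ch[-1] == "G", FALSE)
  cdi <- cumsum(c(0, di))
  nCG <- cdi[starts + window - 1L] - cdi[starts]
  gc <- (nC + nG) / window
  oe <- ifelse(nC > 0 & nG > 0, nCG * window / (nC * nG), 0)
  if (any(gc > 0.55 & oe > 0.75)) return("high")
  if (all(oe <= 0.48)) return("low")
  "medium"
}

#' Label genes by housekeeping/developmental list membership
#'
#' @param genes character vector of gene ids.
#' @param hk_ids,dev_ids character vectors of housekeeping / developmental
#'   gene ids. Non-members are the complement; a gene may be in both lists.
#' @return data.frame `gene_id`, `hk`, `dev`.
#' @export
label_gene_lists <- function(genes, hk_ids, dev_ids) {
  data.frame(gene_id = genes, hk = genes %in% hk_ids,
             dev = genes %in% dev_ids)
}

#' Compute the full per-gene feature-bin table for a cohort
#'
#' @param genes a [gene_set()] with conservation tracks (or `cons_score`
#'   passed directly), expression scores and optionally promoters/labels.
#' @param mode `"quantile"` derives length/conservation/expression cuts from
#'   this cohort (the procedure used on real cohorts); `"fixed"` applies the
#'   printed reference cuts.
#' @param cons_score optional numeric vector overriding track-derived scores.
#' @return data.frame with `gene_id`, `utr_length`, `length_group`,
#'   `cons_score`, `cons_group`, `expr_score`, `expr_group`, `cpg_group`,
#'   `hk`, `dev`.
#' @export
gene_feature_bins <- function(genes, mode = c("quantile", "fixed"),
                              cons_score = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(genes, "gene_set"))
  n <- length(genes)
  utr_len <- nchar(genes$utr_seq)
  if (is.null(cons_score)) {
    cons_score <- if (!is.null(genes$cons_track)) {
      vapply(genes$cons_track, function(t) {
        if (is.null(t)) NA_real_ else conservation_score(t)
      }, numeric(1))
    } else if (!is.null(attr(genes, "cons_score"))) {
      attr(genes, "cons_score")  # generator shortcut, see sim_config()
    } else rep(NA_real_, n)
  }
  expr <- if (is.null(genes$expr_score)) rep(NA_real_, n) else genes$expr_score
  if (mode == "quantile") {
    length_group <- bin_length(utr_len, cohort_lengths = utr_len)
    cons_group <- bin_conservation(cons_score, cohort_scores = cons_score)
    expr_group <- bin_expression(expr, cohort_scores = expr)
  } else {
    length_group <- bin_length(utr_len, quantile_cuts = FIXED_LENGTH_CUTS)
    cons_group <- bin_conservation(cons_score)
    expr_group <- bin_expression(expr)
  }
  cpg <- if (is.null(genes$promoter_seq)) rep("unknown", n) else
    vapply(genes$promoter_seq, cpg_class, "", USE.NAMES = FALSE)
  data.frame(gene_id = genes$gene_id, utr_length = utr_len,
             length_group = length_group, cons_score = cons_score,
             cons_group = cons_group, expr_score = expr,
             expr_group = expr_group,
             cpg_group = factor(cpg, levels = CPG_LEVELS),
             hk = if (is.null(genes$is_housekeeping)) NA else
               genes$is_housekeeping,
             dev = if (is.null(genes$is_developmental)) NA else
               genes$is_developmental)
}
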