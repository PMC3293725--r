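# Seeded generator of complete synthetic studies: genomes with log-normal
# UTR lengths, Beta-distributed gene-level conservation rates, zero-inflated
# log-normal expression; small RNAs with planted, exactly recoverable seed
# sites; and perturbation experiments with planted knockdown, competition,
# dilution and platform-bias effects.


#' Configuration of a synthetic study
#'
#' Defaults describe a reduced but realistically shaped human-like cohort:
#' UTR lengths log-normal with median ~600 nt and ~4% of genes above the
#' 4,000 nt "very long" cut; per-base conservation Bernoulli with
#' Beta(0.6, 2) gene-level rates (mean 0.23, near the reference tercile
#' cuts) and 15% fully unconserved genes; expression zero-inflated
#' log-normal matched to the reference quintile cuts; ten endogenous miRNA
#' families; per-site knockdown of 0.1 log10 units (~20%); competition
#' up-shift of 0.05 log10 units per endogenous target; a mild dilution
#' denominator; microarray sensitivity scaling linearly with expression
#' rank; and proteomics detection centred at expression-rank 0.3.
#'
#' @param n_genes number of genes (>= 10).
#' @param utr_log_mean,utr_log_sd log-normal UTR-length parameters.
#' @param gc_content UTR GC fraction.
#' @param cons_rate_alpha,cons_rate_beta Beta prior of gene conservation
#'   rates.
#' @param cons_zero_frac fraction of genes with no conserved bases.
#' @param expr_zero_frac fraction of unexpressed genes (NoExp).
#' @param expr_log_mean,expr_log_sd log-normal parameters of non-zero
#'   expression scores.
#' @param n_endo_families number of highly expressed endogenous families.
#' @param exo_site_rate_per_kb,endo_site_rate_per_kb expected planted sites
#'   per kb of UTR for exogenous / endogenous RNAs.
#' @param knockdown_per_site planted knockdown per exogenous site, log10
#'   units.
#' @param competition_shift planted up-shift of endogenous targets after
#'   transfection, log10 units.
#' @param dilution_strength dilution denominator coefficient: per-site
#'   knockdown is divided by `1 + dilution_strength * total_sites`.
#' @param array_sensitivity_slope exponent of the expression-rank
#'   attenuation of microarray signal (0 = no platform bias).
#' @param proteomics_detect_midpoint expression rank at which proteomics
#'   detection probability is 0.5.
#' @param noise_sd per-replicate measurement noise, log10 units.
#' @param n_replicates replicates per arm used for microarray p-values.
#' @param promoter_len promoter length in nt.
#' @param with_tracks materialize per-base conservation tracks (`TRUE`); when
#'   `FALSE` only the per-gene conserved-base count is drawn (binomial, the
#'   exact distribution of the track mean) and stored as a `cons_score`
#'   attribute -- faster for large regression/calibration sweeps.
#' @param with_promoters generate promoter sequences.
#' @param seed RNG seed.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000, utr_log_mean = 6.4, utr_log_sd = 1.1,
                       gc_content = 0.45, cons_rate_alpha = 0.6,
                       cons_rate_beta = 2, cons_zero_frac = 0.15,
                       expr_zero_frac = 0.2, expr_log_mean = log(0.0344),
                       expr_log_sd = 2.0, n_endo_families = 10,
                       exo_site_rate_per_kb = 0.15,
                       endo_site_rate_per_kb = 0.08,
                       knockdown_per_site = 0.1, competition_shift = 0.05,
                       dilution_strength = 5e-4,
                       array_sensitivity_slope = 1,
                       proteomics_detect_midpoint = 0.3, noise_sd = 0.08,
                       n_replicates = 3, promoter_len = 1000,
                       with_tracks = TRUE, with_promoters = TRUE, seed = 1) {
  cfg <- as.list(environment())
  if (cfg$n_genes < 10) stop("n_genes must be >= 10", call. = FALSE)
  probs <- c(cfg$gc_content, cfg$cons_zero_frac, cfg$expr_zero_frac,
             cfg$proteomics_detect_midpoint)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must be in [0,1]", call. = FALSE)
  }
  nonneg <- c(cfg$knockdown_per_site, cfg$competition_shift,
              cfg$dilution_strength, cfg$noise_sd,
              cfg$exo_site_rate_per_kb, cfg$endo_site_rate_per_kb)
  if (any(nonneg < 0)) stop("rate/effect parameters must be >= 0",
                            call. = FALSE)
  structure(cfg, class = "sim_config")
}

random_dna <- function(n, gc) {
  paste(sample(BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# One big draw of base codes, cut into per-sequence strings via substring
# (orders of magnitude faster than per-gene sample/paste).
random_dna_many <- function(lens, gc) {
  codes <- utf8ToInt("ACGT")
  all <- sample(codes, sum(lens), replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  big <- intToUtf8(all)
  ends <- cumsum(lens)
  substring(big, ends - lens + 1L, ends)
}

# Promoters by CpG class. "high": mixture of CG dinucleotide tokens and
# GC-biased single bases, giving windows with GC ~0.68 and CpG o/e well
# above 0.75. "medium": random sequence (o/e ~ 1). "low": random sequence
# with every CG broken (o/e = 0).
random_promoters <- function(lens, class) {
  out <- character(length(lens))
  hi <- class == "high"
  if (any(hi)) {
    ntok <- ceiling(lens[hi] * 1.1)
    toks <- sample(c("CG", BASES), sum(ntok), replace = TRUE,
                   prob = c(0.12, 0.176, 0.264, 0.264, 0.176))
    big <- paste(toks, collapse = "")
    tot <- cumsum(c(0, vapply(split(
      nchar(toks), rep.int(seq_along(ntok), ntok)), sum, 0)))
    out[hi] <- substr(substring(big, tot[-length(tot)] + 1L, tot[-1]),
                      1L, lens[hi])
  }
  rest <- !hi
  if (any(rest)) {
    s <- random_dna_many(lens[rest], 0.45)
    lo <- class[rest] == "low"
    s[lo] <- gsub("CG", "CT", s[lo], fixed = TRUE)
    out[rest] <- s
  }
  out
}

#' Generate a synthetic genome
#'
#' Deterministic given `cfg$seed`. Housekeeping labels are enriched among
#' highly expressed genes, developmental labels among lowly expressed genes,
#' and CpG-high promoters among housekeeping genes, mirroring the gene-class
#' characteristics seen in real cohorts.
#'
#' @param cfg a [sim_config()].
#' @return a [gene_set()] with conservation tracks, expression scores,
#'   promoters and HK/Dev labels.
#' @export
generate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_genes
  lens <- pmax(30L, as.integer(round(rlnorm(n, cfg$utr_log_mean,
                                            cfg$utr_log_sd))))
  utr <- random_dna_many(lens, cfg$gc_content)
  rate <- rbeta(n, cfg$cons_rate_alpha, cfg$cons_rate_beta)
  rate[runif(n) < cfg$cons_zero_frac] <- 0
  if (cfg$with_tracks) {
    flags <- rbinom(sum(lens), 1, rep.int(rate, lens)) == 1
    tracks <- split(flags, rep.int(seq_len(n), lens))
    names(tracks) <- NULL
    cons_score <- NULL
  } else {
    tracks <- NULL
    cons_score <- rbinom(n, lens, rate) / lens
  }
  expr <- rlnorm(n, cfg$expr_log_mean, cfg$expr_log_sd)
  expr[runif(n) < cfg$expr_zero_frac] <- 0
  r <- rank(expr, ties.method = "average") / n
  hk <- runif(n) < 0.05 + 0.25 * r^2
  dev <- runif(n) < 0.05 + 0.25 * (1 - r)^2
  p_high <- ifelse(hk, 0.7, 0.25)
  u <- runif(n)
  pclass <- ifelse(u < p_high, "high",
                   ifelse(u < p_high + (1 - p_high) / 2, "medium", "low"))
  prom <- if (cfg$with_promoters) {
    random_promoters(rep(cfg$promoter_len, n), pclass)
  } else NULL
  gs <- gene_set(gene_id = sprintf("g%05d", seq_len(n)), utr_seq = utr,
                 cons_track = tracks, expr_score = expr, promoter_seq = prom,
                 is_housekeeping = hk, is_developmental = dev)
  if (!is.null(cons_score)) attr(gs, "cons_score") <- cons_score
  gs
}

#' Generate a set of synthetic small RNAs with non-interfering seeds
#'
#' Mature sequences are random 21/22-mers whose 6-nt seed cores are pairwise
#' distinct and never occur inside another RNA's site strings, so planted
#' sites for one RNA cannot silently create sites for another.
#'
#' @param ids RNA identifiers.
#' @param kinds `"miRNA"`/`"siRNA"` per RNA (recycled).
#' @param family_ids optional family ids (recycled).
#' @param avoid list of existing [small_rna()] objects the new set must also
#'   not interfere with (checked in both directions).
#' @return list of [small_rna()] objects.
#' @export
make_small_rnas <- function(ids, kinds = "miRNA", family_ids = NA,
                            avoid = list()) {
  n <- length(ids)
  kinds <- rep(kinds, length.out = n)
  family_ids <- rep(family_ids, length.out = n)
  rnas <- vector("list", n)
  sitestrs <- character(0)
  cores <- character(0)
  for (r in avoid) {
    ap <- seed_site_strings(r)
    cores <- c(cores, ap[["core6"]])
    sitestrs <- c(sitestrs, ap[c("8mer", "7mer-m8", "7mer-A1")])
  }
  for (i in seq_len(n)) {
    for (try in 1:200) {
      seq <- random_dna(sample(21:22, 1), 0.5)
      pats <- seed_site_strings(seq)
      # this RNA's core must not occur in any earlier RNA's site strings...
      ok <- !(pats[["core6"]] %in% cores)
      if (ok && length(sitestrs)) {
        ok <- !any(vapply(sitestrs, function(s) {
          grepl(pats[["core6"]], s, fixed = TRUE)
        }, logical(1)))
      }
      # ... and no earlier core may occur in this RNA's site strings
      if (ok && length(cores)) {
        own <- pats[c("8mer", "7mer-m8", "7mer-A1")]
        ok <- !any(vapply(cores, function(cr) {
          any(vapply(own, function(s) grepl(cr, s, fixed = TRUE),
                     logical(1)))
        }, logical(1)))
      }
      if (ok) break
    }
    rnas[[i]] <- small_rna(ids[i], seq, kinds[i], family_ids[i])
    cores <- c(cores, pats[["core6"]])
    sitestrs <- c(sitestrs, pats[c("8mer", "7mer-m8", "7mer-A1")])
  }
  rnas
}

# Remove every spontaneous occurrence of any RNA's 6-nt seed core from the
# UTRs, leaving protected spans untouched. protected: list per gene of
# two-column matrices (start, end), 1-based inclusive.
scrub_cores <- function(seqs, cores) {
  cores <- unique(cores)
  pdicts <- build_pdicts(cores)
  base_codes <- as.raw(utf8ToInt("ACGT"))
  active <- seq_along(seqs)  # sweep 2+ only re-checks mutated sequences
  for (iter in 1:40) {
    # one sweep: search all cores against a single snapshot, mutate the
    # middle base of every match, then re-check on the next sweep
    hits <- match_patterns_many(seqs[active], cores, pdicts)
    if (nrow(hits) == 0) return(seqs)
    hits$gene <- active[hits$gene]
    active <- unique(hits$gene)
    by_gene <- split(hits$start + 3L, hits$gene)  # mutate the middle base
    for (gs in seq_along(by_gene)) {
      g <- as.integer(names(by_gene)[gs])
      pos <- unique(by_gene[[gs]])
      r <- charToRaw(seqs[g])
      cur <- match(r[pos], base_codes)
      # a uniformly chosen base different from the current one
      r[pos] <- base_codes[(cur - 1L +
                              sample.int(3L, length(pos),
                                         replace = TRUE)) %% 4L + 1L]
      seqs[g] <- rawToChar(r)
    }
  }
  stop("seed-core scrubbing did not converge", call. = FALSE)
}

#' Plant exact seed sites into a genome
#'
#' First scrubs every spontaneous seed-core occurrence for all `rnas` from
#' the UTRs, then inserts exact site strings (8mer / 7mer-m8 / 7mer-A1,
#' sampled 2:1:1) at Poisson(`rate * kb`) positions per (gene, RNA), with
#' flanking bases chosen so the written site keeps its type. Planted counts
#' are recorded as ground truth; after planting, the generator verifies by
#' re-scanning that [scan_sites()] recovers exactly the planted sites, and
#' repairs any junction artifact by mutating unprotected bases.
#'
#' Longer UTRs receive proportionally more sites, so endogenous targeting is
#' naturally enriched among long-UTR genes.
#'
#' @param genes a [gene_set()].
#' @param rnas list of [small_rna()] (exogenous and endogenous together).
#' @param site_rate_per_kb expected sites per kb; scalar or one value per RNA.
#' @param cfg a [sim_config()] (unused knobs reserved).
#' @return list with `genes` (mutated UTRs), `truth` (data.frame `gene_id`,
#'   `rna_id`, `n_sites` over all pairs) and `sites` (planted site table).
#' @export
plant_sites <- function(genes, rnas, site_rate_per_kb, cfg = NULL) {
  n <- length(genes)
  rates <- rep(site_rate_per_kb, length.out = length(rnas))
  seqs <- genes$utr_seq
  lens <- nchar(seqs)
  cores <- vapply(rnas, function(r) seed_site_strings(r)[["core6"]], "")
  seqs <- scrub_cores(seqs, cores)

  # per gene: site spans (never mutable) and flank positions with the bases
  # a repair mutation must avoid there (to preserve the planted site's type)
  protected <- rep(list(matrix(integer(0), 0, 2)), n)
  flank_forbid <- rep(list(list()), n)
  n_rna <- length(rnas)
  pats_all <- lapply(rnas, seed_site_strings)
  rna_ids <- vapply(rnas, `[[`, "", "rna_id")
  n_mat <- matrix(0L, n, n_rna)
  want <- matrix(rpois(n * n_rna, outer(lens / 1000, rates)), n, n_rna)

  cap <- sum(want)
  p_gene <- integer(cap); p_rna <- integer(cap); p_start <- integer(cap)
  p_type <- character(cap); np <- 0L

  for (g in which(rowSums(want) > 0)) {
    ch <- strsplit(seqs[g], "", fixed = TRUE)[[1]]
    pr <- protected[[g]]
    ff <- flank_forbid[[g]]
    for (k in which(want[g, ] > 0)) {
      pats <- pats_all[[k]]
      m8 <- attr(pats, "m8")
      for (j in seq_len(want[g, k])) {
        ty <- sample(SITE_TYPES, 1, prob = c(0.5, 0.25, 0.25))
        site <- pats[[ty]]
        w <- nchar(site)
        if (lens[g] < w + 4L) {
          warning("UTR of ", genes$gene_id[g], " too short; site skipped")
          next
        }
        placed <- FALSE
        for (try in 1:60) {
          s1 <- sample(2L:(lens[g] - w), 1)   # site start, 1-based
          lo <- s1 - 1L
          hi <- s1 + w
          if (nrow(pr) && any(lo <= pr[, 2] + 2L & hi >= pr[, 1] - 2L)) next
          ch[s1:(s1 + w - 1L)] <- strsplit(site, "", fixed = TRUE)[[1]]
          ch[lo] <- sample(setdiff(BASES, m8), 1)
          ch[hi] <- if (ty == "7mer-m8") sample(c("C", "G", "T"), 1) else
            sample(BASES, 1)
          pr <- rbind(pr, c(s1, s1 + w - 1L))
          ff[[as.character(lo)]] <- m8
          ff[[as.character(hi)]] <- if (ty == "7mer-m8") "A" else character(0)
          np <- np + 1L
          p_gene[np] <- g; p_rna[np] <- k
          p_start[np] <- s1 - 1L; p_type[np] <- ty
          n_mat[g, k] <- n_mat[g, k] + 1L
          placed <- TRUE
          break
        }
        if (!placed) {
          warning("no room for a site in ", genes$gene_id[g],
                  "; site skipped")
        }
      }
    }
    seqs[g] <- paste(ch, collapse = "")
    protected[[g]] <- pr
    flank_forbid[[g]] <- ff
  }
  idx <- seq_len(np)
  planted <- data.frame(gene_id = genes$gene_id[p_gene[idx]],
                        rna_id = rna_ids[p_rna[idx]],
                        start = p_start[idx],
                        end = p_start[idx] +
                          ifelse(p_type[idx] == "8mer", 8L, 7L),
                        site_type = p_type[idx])

  genes$utr_seq <- seqs
  # verify & repair: re-scan and mutate unprotected bases inside any
  # spurious (unplanted) match until recovery is exact; after the first full
  # scan only the repaired genes are rescanned
  pkey <- paste(planted$gene_id, planted$rna_id, planted$start)
  check_ids <- NULL  # NULL = scan everything
  for (iter in 1:30) {
    if (is.null(check_ids)) {
      found <- scan_sites(rnas, genes)
      pk <- pkey
      pl <- planted
    } else {
      idx <- match(check_ids, genes$gene_id)
      sub <- gene_set(genes$gene_id[idx], genes$utr_seq[idx])
      found <- scan_sites(rnas, sub)
      keep <- planted$gene_id %in% check_ids
      pk <- pkey[keep]
      pl <- planted[keep, , drop = FALSE]
    }
    fkey <- paste(found$gene_id, found$rna_id, found$start)
    spurious <- found[!(fkey %in% pk), , drop = FALSE]
    missing <- pl[!(pk %in% fkey), , drop = FALSE]
    if (nrow(spurious) == 0 && nrow(missing) == 0) break
    if (nrow(spurious) == 0 && nrow(missing) > 0) {
      stop("planted sites lost during repair", call. = FALSE)
    }
    check_ids <- unique(spurious$gene_id)
    for (i in seq_len(nrow(spurious))) {
      g <- match(spurious$gene_id[i], genes$gene_id)
      span <- (spurious$start[i] + 1L):(spurious$end[i])
      pr <- protected[[g]]
      inside <- vapply(span, function(p) {
        nrow(pr) > 0 && any(p >= pr[, 1] & p <= pr[, 2])
      }, logical(1))
      free <- span[!inside]
      if (length(free) == 0) next
      # prefer non-flank positions; a flank mutation must keep the adjacent
      # planted site's type, so its forbidden bases are excluded
      fl <- flank_forbid[[g]]
      is_flank <- as.character(free) %in% names(fl)
      pos <- if (any(!is_flank)) {
        nf <- free[!is_flank]
        nf[ceiling(length(nf) / 2)]
      } else free[1]
      cur <- substr(genes$utr_seq[g], pos, pos)
      avoid <- c(cur, fl[[as.character(pos)]])
      choices <- setdiff(BASES, avoid)
      if (length(choices) == 0) next
      substr(genes$utr_seq[g], pos, pos) <- sample(choices, 1)
    }
    if (iter == 30) stop("site planting did not stabilize", call. = FALSE)
  }

  truth <- data.frame(
    gene_id = rep(genes$gene_id, times = length(rnas)),
    rna_id = rep(vapply(rnas, `[[`, "", "rna_id"), each = n),
    n_sites = as.integer(n_mat))
  list(genes = genes, truth = truth, sites = planted)
}

truth_counts <- function(truth, rna_id) {
  t <- truth[truth$rna_id == rna_id, ]
  setNames(t$n_sites, t$gene_id)
}

truth_endo_counts <- function(truth, endo_ids) {
  t <- truth[truth$rna_id %in% endo_ids, ]
  out <- tapply(t$n_sites, t$gene_id, sum)
  out[unique(truth$gene_id)]
}

#' Simulate one perturbation sample
#'
#' The true log10 ratio of gene *g* is
#' `-kd * n_sites(g) / (1 + dilution * total_sites) + shift * [g is an
#' endogenous target]` plus Gaussian noise; inhibition assays flip the sign
#' of the exogenous term (targets are de-repressed) and are emitted in the
#' raw convention that [preprocess_log_ratios()] later negates. Microarray
#' signal is attenuated by `rank^array_sensitivity_slope` of the gene's
#' expression rank and per-gene detection p-values come from a z test of the
#' observed change against its known replicate-averaged noise sd (the
#' large-df limit of a replicate t test); proteomics reports a gene at all with
#' probability logistic in expression rank but measures unattenuated change.
#'
#' @param genes a [gene_set()] (after [plant_sites()]).
#' @param exo exogenous [small_rna()].
#' @param endo_rnas list of endogenous [small_rna()] objects.
#' @param platform,assay experiment platform and assay.
#' @param cfg a [sim_config()].
#' @param sample_id sample identifier.
#' @param truth optional planted-truth table from [plant_sites()]; when
#'   absent, counts are obtained by rescanning.
#' @return list with `sample` (a [mir_sample()]) and `truth` (per-gene true
#'   mean log-ratios and target status).
#' @export
simulate_experiment <- function(genes, exo, endo_rnas, platform, assay, cfg,
                                sample_id = "s1", truth = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- length(genes)
  endo_ids <- vapply(endo_rnas, `[[`, "", "rna_id")
  if (is.null(truth)) {
    cm <- count_sites_matrix(c(list(exo), endo_rnas), genes)
    truth <- cm
  }
  n_sites <- truth_counts(truth, exo$rna_id)[genes$gene_id]
  n_sites[is.na(n_sites)] <- 0L
  endo_n <- truth_endo_counts(truth, endo_ids)[genes$gene_id]
  endo_n[is.na(endo_n)] <- 0L
  total_sites <- sum(n_sites)
  exo_term <- -cfg$knockdown_per_site * n_sites /
    (1 + cfg$dilution_strength * total_sites)
  if (assay == "inhibition") exo_term <- -exo_term
  mu <- as.vector(exo_term + cfg$competition_shift * (endo_n > 0))
  rank_r <- rank(genes$expr_score, ties.method = "average") / n

  nr <- cfg$n_replicates
  if (platform == "microarray") {
    atten <- rank_r^cfg$array_sensitivity_slope
    signal <- mu * atten
    se <- cfg$noise_sd * sqrt(2 / nr)  # sd of an nr-vs-nr replicate contrast
    lr <- signal + rnorm(n, 0, se)
    # detection p: z test of the observed change against its known sampling
    # sd -- the large-df limit of a replicate t test, as probe-averaged
    # array statistics effectively are; exactly calibrated under the null
    pv <- if (se > 0) 2 * pnorm(-abs(lr) / se) else as.numeric(lr == 0)
    lrs <- setNames(lr, genes$gene_id)
    pvs <- setNames(pv, genes$gene_id)
    smp <- mir_sample(sample_id, exo, lrs, pvs)
  } else {
    detect <- runif(n) < plogis((rank_r - cfg$proteomics_detect_midpoint) /
                                  0.1)
    lr <- mu + rnorm(n, 0, cfg$noise_sd * sqrt(2 / nr))
    lrs <- setNames(lr[detect], genes$gene_id[detect])
    smp <- mir_sample(sample_id, exo, lrs)
  }
  list(sample = smp,
       truth = data.frame(gene_id = genes$gene_id, mu = mu,
                          n_sites = as.integer(n_sites),
                          n_endo_sites = as.integer(endo_n),
                          is_exo_target = n_sites > 0,
                          is_endo_target = endo_n > 0))
}

default_design <- function() {
  data.frame(experiment_id = c("ma_tx", "prot_tx", "ma_inh"),
             platform = c("microarray", "proteomics", "microarray"),
             assay = c("transfection", "transfection", "inhibition"),
             n_samples = c(4L, 3L, 2L))
}

#' Simulate a complete synthetic study
#'
#' Generates a genome, one exogenous small RNA per sample (alternating
#' miRNA/siRNA), `cfg$n_endo_families` endogenous families (plus three
#' lower-expressed decoy families with no planted sites) with an expression
#' ranking, plants seed sites, simulates every sample of every experiment,
#' and derives synthetic mRNA-level TargetScan-like scores correlated with
#' the planted site counts. Fully deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param design data.frame `experiment_id`, `platform`, `assay`,
#'   `n_samples` (default: one microarray and one proteomics transfection
#'   set plus a small microarray inhibition set).
#' @return list with `genes`, `exo_rnas`, `endo_rnas`, `family_expression`,
#'   `truth`, `sites`, `experiments` (raw, not yet preprocessed),
#'   `sample_truth`, `ts_scores`, `assignments`, `cfg`, `design`.
#' @export
simulate_study <- function(cfg, design = default_design()) {
  stopifnot(inherits(cfg, "sim_config"))
  genes <- generate_genome(cfg)   # seeds the RNG stream
  n_exo <- sum(design$n_samples)
  n_endo <- cfg$n_endo_families
  n_decoy <- 3L
  exo_rnas <- make_small_rnas(sprintf("exo-%02d", seq_len(n_exo)),
                              kinds = rep(c("miRNA", "siRNA"),
                                          length.out = n_exo))
  fam <- sprintf("fam-%02d", seq_len(n_endo + n_decoy))
  endo_all <- make_small_rnas(sprintf("endo-%02d", seq_len(n_endo + n_decoy)),
                              kinds = "miRNA", family_ids = fam,
                              avoid = exo_rnas)
  fam_expr <- setNames(sort(rexp(n_endo + n_decoy, rate = 0.5),
                            decreasing = TRUE), fam)
  top_fams <- select_endogenous_families(fam_expr, n_endo)
  endo_rnas <- endo_all[fam %in% top_fams]
  rates <- c(rep(cfg$exo_site_rate_per_kb, n_exo),
             ifelse(fam %in% top_fams, cfg$endo_site_rate_per_kb, 0))
  pl <- plant_sites(genes, c(exo_rnas, endo_all), rates, cfg)
  genes <- pl$genes

  experiments <- list()
  sample_truth <- list()
  i_rna <- 0L
  for (e in seq_len(nrow(design))) {
    samples <- list()
    for (s in seq_len(design$n_samples[e])) {
      i_rna <- i_rna + 1L
      sid <- sprintf("%s_s%02d", design$experiment_id[e], s)
      sim <- simulate_experiment(genes, exo_rnas[[i_rna]], endo_rnas,
                                 design$platform[e], design$assay[e], cfg,
                                 sample_id = sid, truth = pl$truth)
      samples[[s]] <- sim$sample
      sim$truth$sample_id <- sid
      sample_truth[[sid]] <- sim$truth
    }
    experiments[[e]] <- experiment_set(design$experiment_id[e],
                                       design$platform[e], design$assay[e],
                                       samples)
  }

  # synthetic mRNA-level TargetScan-like scores: per planted exogenous site
  # a context score around -0.2, aggregated (summed, negated) per pair
  exo_ids <- vapply(exo_rnas, `[[`, "", "rna_id")
  tt <- pl$truth[pl$truth$rna_id %in% exo_ids & pl$truth$n_sites > 0, ]
  ts <- vapply(tt$n_sites, function(k) {
    aggregate_ts_scores(-pmax(0.02, rnorm(k, 0.2, 0.08)))
  }, numeric(1))
  ts_scores <- data.frame(rna_id = tt$rna_id, gene_id = tt$gene_id,
                          ts_score = ts)

  endo_ids <- vapply(endo_rnas, `[[`, "", "rna_id")
  endo_n <- truth_endo_counts(pl$truth, endo_ids)[genes$gene_id]
  endo_n[is.na(endo_n)] <- 0L
  assignments <- do.call(rbind, lapply(exo_ids, function(rid) {
    ns <- truth_counts(pl$truth, rid)[genes$gene_id]
    data.frame(gene_id = genes$gene_id, rna_id = rid,
               n_sites = as.integer(ns), is_exo_target = ns >= 1,
               n_endo_sites = as.integer(endo_n),
               is_endo_target = endo_n >= 1,
               group = group_label(ns >= 1, endo_n >= 1))
  }))

  list(genes = genes, exo_rnas = exo_rnas, endo_rnas = endo_rnas,
       family_expression = fam_expr, truth = pl$truth, sites = pl$sites,
       experiments = experiments,
       sample_truth = do.call(rbind, sample_truth), ts_scores = ts_scores,
       assignments = assignments, cfg = cfg, design = design)
}

#' Simulate AGO PAR-CLIP read positions for a synthetic study
#'
#' Emits a read pile at each planted endogenous site with probability
#' `capture_prob` (depth 1 + Poisson(`mean_depth - 1`)) plus sparse shallow
#' background reads, so AGO binding tracks endogenous targeting and, through
#' it, 3' UTR length.
#'
#' @param study output of [simulate_study()].
#' @param ago_id identifier used in downstream tables.
#' @param capture_prob probability that a real site yields a read pile.
#' @param mean_depth mean read depth of captured piles.
#' @param background_rate expected background read positions per kb.
#' @return list with `read_map` (as from [read_read_positions()]) and
#'   `bed` (character vector of BED5 lines).
#' @export
simulate_parclip <- function(study, ago_id = "AGO1", capture_prob = 0.75,
                             mean_depth = 9, background_rate = 0.05) {
  genes <- study$genes
  endo_ids <- vapply(study$endo_rnas, `[[`, "", "rna_id")
  sites <- study$sites[study$sites$rna_id %in% endo_ids, ]
  keep <- runif(nrow(sites)) < capture_prob
  sites <- sites[keep, , drop = FALSE]
  depth <- 1L + rpois(nrow(sites), mean_depth - 1)
  df <- data.frame(gene_id = sites$gene_id, position = sites$start,
                   read_count = depth)
  lens <- nchar(genes$utr_seq)
  nbg <- rpois(length(genes), background_rate * lens / 1000)
  bg_gene <- rep(genes$gene_id, nbg)
  bg_len <- rep(lens, nbg)
  if (length(bg_gene)) {
    bg <- data.frame(gene_id = bg_gene,
                     position = as.integer(floor(runif(length(bg_gene)) *
                                                   (bg_len - 1))),
                     read_count = 1L + rpois(length(bg_gene), 1))
    df <- rbind(df, bg)
  }
  df <- df[order(df$gene_id, df$position), ]
  bed <- sprintf("%s\t%d\t%d\t%s\t%d", df$gene_id, df$position,
                 df$position + 1L, ago_id, df$read_count)
  list(read_map = split(df[c("position", "read_count")], df$gene_id),
       bed = bed)
}
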