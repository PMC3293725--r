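# Canonical stringent seed-site detection (8mer, 7mer-m8, 7mer-A1) and
# classification of genes into exogenous/endogenous target groups.


revcomp <- function(seq) {
  chartr("ACGTUN", "TGCAAN", seq) |>
    strsplit("") |>
    vapply(function(x) paste(rev(x), collapse = ""), "")
}


#' Seed-match strings for a small RNA
#'
#' For a mature sequence with 5' positions 1..n, the seed core `S` is the
#' reverse complement of positions 2-7 and `m8` is the complement of
#' position 8. A UTR site (read 5' to 3') is then:
#' \describe{
#'   \item{8mer}{`m8 + S + A` (8 nt; the A faces miRNA position 1 and must
#'     be a literal A).}
#'   \item{7mer-m8}{`m8 + S` not followed by A.}
#'   \item{7mer-A1}{`S + A` not preceded by `m8`.}
#' }
#'
#' @param rna a [small_rna()] or a mature sequence string (>= 8 nt).
#' @return named character vector with elements `core6`, `8mer`, `7mer-m8`,
#'   `7mer-A1` and attribute `m8` (the single m8 character).
#' @export
seed_site_strings <- function(rna) {
  seq <- if (inherits(rna, "small_rna")) rna$mature_seq else normalize_seq(rna)
  if (is.na(seq) || nchar(seq) < 8L) {
    stop("mature sequence shorter than 8 nt", call. = FALSE)
  }
  core <- revcomp(substr(seq, 2, 7))              # matches positions 2-7
  m8 <- unname(COMPLEMENT[substr(seq, 8, 8)])     # matches position 8
  out <- c(core6 = core,
           `8mer` = paste0(m8, core, "A"),
           `7mer-m8` = paste0(m8, core),
           `7mer-A1` = paste0(core, "A"))
  attr(out, "m8") <- m8
  out
}

# Greedy non-redundant overlap resolution shared by the single-gene and
# batch scanners: candidates are taken in precedence order
# 8mer > 7mer-m8 > 7mer-A1, within a type left to right, and a candidate is
# kept only if it does not overlap an already accepted site.
resolve_overlaps <- function(start, end, type) {
  ord <- order(match(type, SITE_TYPES), start)
  keep <- logical(length(start))
  acc_s <- integer(0)
  acc_e <- integer(0)
  for (i in ord) {
    if (!any(start[i] < acc_e & end[i] > acc_s)) {
      keep[i] <- TRUE
      acc_s <- c(acc_s, start[i])
      acc_e <- c(acc_e, end[i])
    }
  }
  which(keep)[order(start[keep])]
}

fixed_matches <- function(pattern, subject) {
  m <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Find canonical seed sites of a small RNA in one 3' UTR
#'
#' Scans the UTR (sense strand, 5' to 3') for the three stringent seed types
#' defined by [seed_site_strings()]. Matching is literal after U -> T
#' normalization; `N` never matches. Overlapping candidates are resolved
#' non-redundantly with precedence 8mer > 7mer-m8 > 7mer-A1, so an 8mer is
#' never additionally counted as its embedded 7mers.
#'
#' @param rna a [small_rna()] or mature sequence string.
#' @param utr_seq the 3' UTR sequence.
#' @return data.frame with columns `start` (0-based), `end` (half-open),
#'   `site_type`; sorted by `start`.
#' @export
find_seed_sites <- function(rna, utr_seq) {
  pats <- seed_site_strings(rna)
  m8 <- attr(pats, "m8")
  utr <- normalize_seq(utr_seq)
  n <- nchar(utr)

  s8 <- fixed_matches(pats[["8mer"]], utr)
  s7m8 <- fixed_matches(pats[["7mer-m8"]], utr)
  # qualifier: not followed by A (that would be the 8mer)
  if (length(s7m8)) {
    nxt <- substr(rep(utr, length(s7m8)), s7m8 + 7L, s7m8 + 7L)
    s7m8 <- s7m8[nxt != "A"]
  }
  s7a1 <- fixed_matches(pats[["7mer-A1"]], utr)
  # qualifier: not preceded by the m8 match (that would be the 8mer)
  if (length(s7a1)) {
    prev <- substr(rep(utr, length(s7a1)), s7a1 - 1L, s7a1 - 1L)
    s7a1 <- s7a1[s7a1 == 1L | prev != m8]
  }

  start <- c(s8, s7m8, s7a1) - 1L            # to 0-based
  width <- c(rep(8L, length(s8)), rep(7L, length(s7m8) + length(s7a1)))
  type <- c(rep("8mer", length(s8)), rep("7mer-m8", length(s7m8)),
            rep("7mer-A1", length(s7a1)))
  if (length(start) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      site_type = character(0)))
  }
  keep <- resolve_overlaps(start, start + width, type)
  data.frame(start = start[keep], end = (start + width)[keep],
             site_type = type[keep])
}

#' Count canonical seed sites of a small RNA in a gene's 3' UTR
#'
#' @param rna a [small_rna()] or mature sequence string.
#' @param gene a [gene_set()] entry index/id pair is not needed; pass the
#'   UTR sequence or a single-gene `gene_set`.
#' @return integer site count; 0 means the gene is not a predicted target.
#' @export
count_sites <- function(rna, gene) {
  utr <- if (inherits(gene, "gene_set")) gene$utr_seq[1] else gene
  nrow(find_seed_sites(rna, utr))
}

# Multi-pattern exact search over many sequences: the sequences are joined
# with N spacers (N never matches) into one subject and each constant-width
# pattern group is searched with a single Aho-Corasick pass (matchPDict).
# Returns data.frame(pat, gene, start) with 1-based per-sequence starts.
build_pdicts <- function(patterns) {
  lapply(unique(nchar(patterns)), function(w) {
    sel <- which(nchar(patterns) == w)
    list(sel = sel,
         pd = Biostrings::PDict(Biostrings::DNAStringSet(patterns[sel])))
  })
}

match_patterns_many <- function(seqs, patterns, pdicts = NULL) {
  sep <- strrep("N", 10L)
  big <- Biostrings::DNAString(paste(seqs, collapse = sep))
  offs <- cumsum(c(0, nchar(seqs) + 10L))[seq_along(seqs)]
  if (is.null(pdicts)) pdicts <- build_pdicts(patterns)
  out <- list()
  for (grp in pdicts) {
    sel <- grp$sel
    m <- Biostrings::matchPDict(grp$pd, big)
    st <- Biostrings::startIndex(m)
    cnt <- lengths(st)
    if (sum(cnt) == 0) next
    gs <- unlist(st, use.names = FALSE)
    gi <- findInterval(gs, offs + 1L)
    out[[length(out) + 1]] <- data.frame(
      pat = rep(sel, cnt), gene = gi, start = gs - offs[gi])
  }
  if (length(out) == 0) {
    return(data.frame(pat = integer(0), gene = integer(0),
                      start = integer(0)))
  }
  do.call(rbind, out)
}

#' Batch seed-site scan over a gene set
#'
#' Equivalent to [find_seed_sites()] applied to every (RNA, gene) pair, but
#' implemented with a single multi-pattern Aho-Corasick pass per site width
#' for speed on whole cohorts.
#'
#' @param rnas list of [small_rna()] objects.
#' @param genes a [gene_set()].
#' @return data.frame with columns `gene_id`, `rna_id`, `start`, `end`,
#'   `site_type`.
#' @export
scan_sites <- function(rnas, genes) {
  stopifnot(inherits(genes, "gene_set"))
  n_rna <- length(rnas)
  pats_all <- lapply(rnas, seed_site_strings)
  # pattern table: one row per (rna, site type)
  pat_seq <- unlist(lapply(pats_all, function(p) p[SITE_TYPES]),
                    use.names = FALSE)
  pat_rna <- rep(seq_len(n_rna), each = 3L)
  pat_type <- rep(SITE_TYPES, n_rna)
  hits <- match_patterns_many(genes$utr_seq, pat_seq)
  if (nrow(hits) == 0) {
    return(data.frame(gene_id = character(0), rna_id = character(0),
                      start = integer(0), end = integer(0),
                      site_type = character(0)))
  }
  gi <- hits$gene
  s1 <- hits$start
  ty <- pat_type[hits$pat]
  rk <- pat_rna[hits$pat]
  m8 <- vapply(pats_all, attr, "", "m8")[rk]
  # type qualifiers relative to the embedding 8mer
  nxt <- substr(genes$utr_seq[gi], s1 + 7L, s1 + 7L)
  prev <- substr(genes$utr_seq[gi], s1 - 1L, s1 - 1L)
  keep <- (ty == "8mer") |
    (ty == "7mer-m8" & nxt != "A") |
    (ty == "7mer-A1" & (s1 == 1L | prev != m8))
  gi <- gi[keep]; s1 <- s1[keep]; ty <- ty[keep]; rk <- rk[keep]
  width <- ifelse(ty == "8mer", 8L, 7L)
  cd <- data.frame(rna = rk, gene = gi, start = s1 - 1L, width = width,
                   site_type = ty)
  # overlap resolution is only needed where a (rna, gene) has >1 candidate
  key <- cd$rna * (length(genes) + 1L) + cd$gene
  multi <- key %in% key[duplicated(key)]
  res <- cd[!multi, , drop = FALSE]
  if (any(multi)) {
    fixed <- lapply(split(cd[multi, , drop = FALSE], key[multi]),
                    function(g) {
      keep <- resolve_overlaps(g$start, g$start + g$width, g$site_type)
      g[keep, , drop = FALSE]
    })
    res <- rbind(res, do.call(rbind, fixed))
  }
  rna_ids <- vapply(rnas, `[[`, "", "rna_id")
  out <- data.frame(gene_id = genes$gene_id[res$gene],
                    rna_id = rna_ids[res$rna], start = res$start,
                    end = res$start + res$width, site_type = res$site_type)
  rownames(out) <- NULL
  out[order(match(out$rna_id, rna_ids), res$gene, out$start), , drop = FALSE]
}

#' Per (gene, RNA) site counts from a batch scan
#'
#' @param rnas list of [small_rna()] objects.
#' @param genes a [gene_set()].
#' @return data.frame `gene_id`, `rna_id`, `n_sites` including zero rows for
#'   unmatched pairs.
#' @export
count_sites_matrix <- function(rnas, genes) {
  sites <- scan_sites(rnas, genes)
  rid <- vapply(rnas, `[[`, "", "rna_id")
  grid <- expand.grid(gene_id = genes$gene_id, rna_id = rid,
                      stringsAsFactors = FALSE)
  key <- paste(sites$gene_id, sites$rna_id, sep = "\r")
  tab <- table(key)
  grid$n_sites <- as.integer(tab[paste(grid$gene_id, grid$rna_id,
                                       sep = "\r")])
  grid$n_sites[is.na(grid$n_sites)] <- 0L
  grid
}

#' Select the most highly expressed endogenous miRNA families
#'
#' @param family_expression named numeric vector, family_id -> expression
#'   rank score.
#' @param k number of families to keep (default 10, the usual "top ten").
#' @return character vector of `k` family ids, ties at the k-th rank broken
#'   by lexicographic family id for determinism.
#' @export
select_endogenous_families <- function(family_expression, k = 10) {
  stopifnot(k >= 1)
  if (length(family_expression) < k) {
    stop(sprintf("only %d families available, need k=%d",
                 length(family_expression), k), call. = FALSE)
  }
  ord <- order(-family_expression, names(family_expression))
  names(family_expression)[ord][seq_len(k)]
}


group_label <- function(is_exo, is_endo) {
  paste0(ifelse(is_exo, "T", "NT"), ifelse(is_endo, "+Endo", "-Endo"))
}

#' Assign one gene to the exogenous/endogenous target groups
#'
#' A gene is an exogenous target (`T`) when it has at least one stringent
#' seed site for the exogenous RNA, and an endogenous target (`+Endo`) when
#' it has at least one site for at least one of the endogenous RNAs
#' (typically one representative per highly expressed family).
#'
#' @param gene UTR sequence (or single-gene [gene_set()]).
#' @param exo exogenous [small_rna()].
#' @param endo_rnas list of endogenous [small_rna()] objects.
#' @return list with `n_sites`, `is_exo_target`, `n_endo_sites`,
#'   `is_endo_target`, `group`.
#' @export
assign_group <- function(gene, exo, endo_rnas) {
  utr <- if (inherits(gene, "gene_set")) gene$utr_seq[1] else gene
  sites <- find_seed_sites(exo, utr)
  n_endo <- sum(vapply(endo_rnas, function(r) nrow(find_seed_sites(r, utr)),
                       integer(1)))
  n <- nrow(sites)
  list(sites = sites, n_sites = n, is_exo_target = n >= 1L,
       n_endo_sites = n_endo, is_endo_target = n_endo >= 1L,
       group = group_label(n >= 1L, n_endo >= 1L))
}

#' Assign every gene in a cohort to target groups for one exogenous RNA
#'
#' Batch version of [assign_group()] built on [count_sites_matrix()].
#'
#' @param genes a [gene_set()].
#' @param exo exogenous [small_rna()].
#' @param endo_rnas list of endogenous [small_rna()] objects.
#' @param counts optional precomputed [count_sites_matrix()] over
#'   `c(list(exo), endo_rnas)` to avoid rescanning in pipelines.
#' @return data.frame `gene_id`, `rna_id`, `n_sites`, `is_exo_target`,
#'   `n_endo_sites`, `is_endo_target`, `group`.
#' @export
assign_groups <- function(genes, exo, endo_rnas, counts = NULL) {
  if (is.null(counts)) {
    counts <- count_sites_matrix(c(list(exo), endo_rnas), genes)
  }
  exo_n <- counts[counts$rna_id == exo$rna_id, ]
  exo_n <- setNames(exo_n$n_sites, exo_n$gene_id)[genes$gene_id]
  endo_ids <- vapply(endo_rnas, `[[`, "", "rna_id")
  endo <- counts[counts$rna_id %in% endo_ids, ]
  endo_n <- tapply(endo$n_sites, endo$gene_id, sum)[genes$gene_id]
  endo_n[is.na(endo_n)] <- 0L
  data.frame(gene_id = genes$gene_id, rna_id = exo$rna_id,
             n_sites = as.integer(exo_n),
             is_exo_target = exo_n >= 1L,
             n_endo_sites = as.integer(endo_n),
             is_endo_target = endo_n >= 1L,
             group = group_label(exo_n >= 1L, endo_n >= 1L),
             row.names = NULL)
}
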