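# Independent oracles used to validate the package implementations. These
# deliberately share no code with R/: the seed matcher walks every offset
# with substr, the rank test enumerates arrangements, and the Fisher oracle
# sums hypergeometric point masses.

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", U = "A")
  paste(rev(comp[strsplit(toupper(s), "")[[1]]]), collapse = "")
}

# Offset-by-offset stringent seed matcher with the same precedence rule
# (8mer > 7mer-m8 > 7mer-A1, then left to right, non-overlapping).
oracle_seed_sites <- function(mature, utr) {
  mature <- chartr("Uu", "TT", toupper(mature))
  utr <- chartr("Uu", "TT", toupper(utr))
  core <- oracle_revcomp(substr(mature, 2, 7))
  m8 <- oracle_revcomp(substr(mature, 8, 8))
  n <- nchar(utr)
  cand <- list()
  for (i in seq_len(max(0, n - 6))) {
    if (i + 7 <= n && substr(utr, i, i + 7) == paste0(m8, core, "A")) {
      cand[[length(cand) + 1]] <- list(start = i - 1, w = 8, type = "8mer")
    } else if (i + 6 <= n && substr(utr, i, i + 6) == paste0(m8, core) &&
               (i + 7 > n || substr(utr, i + 7, i + 7) != "A")) {
      cand[[length(cand) + 1]] <- list(start = i - 1, w = 7,
                                       type = "7mer-m8")
    } else if (i + 6 <= n && substr(utr, i, i + 6) == paste0(core, "A") &&
               (i == 1 || substr(utr, i - 1, i - 1) != m8)) {
      cand[[length(cand) + 1]] <- list(start = i - 1, w = 7,
                                       type = "7mer-A1")
    }
  }
  if (length(cand) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      site_type = character(0)))
  }
  prec <- c(`8mer` = 1, `7mer-m8` = 2, `7mer-A1` = 3)
  ord <- order(vapply(cand, function(x) prec[[x$type]], 0),
               vapply(cand, `[[`, 0, "start"))
  acc <- list()
  for (i in ord) {
    x <- cand[[i]]
    clash <- any(vapply(acc, function(a) {
      x$start < a$start + a$w && x$start + x$w > a$start
    }, logical(1)))
    if (!clash) acc[[length(acc) + 1]] <- x
  }
  st <- vapply(acc, `[[`, 0, "start")
  w <- vapply(acc, `[[`, 0, "w")
  ty <- vapply(acc, `[[`, "", "type")
  o <- order(st)
  data.frame(start = as.integer(st[o]), end = as.integer((st + w)[o]),
             site_type = ty[o])
}

# Exact one-sided Wilcoxon p (alternative: x smaller) by full enumeration
# of which ranks the x-group can occupy.
oracle_wilcoxon_less <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  n <- length(pooled)
  obs <- sum(rank(pooled)[seq_along(x)])
  combos <- utils::combn(n, length(x))
  sums <- colSums(matrix(seq_len(n)[combos], nrow = length(x)))
  mean(sums <= obs)
}

# One-sided Fisher p (enrichment of bound among long) as the upper
# hypergeometric tail of the observed table.
oracle_fisher_greater <- function(a, b, c, d) {
  m <- a + c          # bound
  nn <- b + d         # unbound
  k <- a + b          # long
  xs <- a:min(m, k)
  sum(dhyper(xs, m, nn, k))
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
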