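# Small in-code fixtures shared across test files.

LET7 <- "UGAGGUAGUAGGUUGUAUAGUU"

make_rna <- function(id = "r1", seq = LET7, kind = "miRNA",
                     family = NA_character_) {
  small_rna(id, seq, kind, family)
}

make_sample <- function(sample_id, rna, lr, pv = NULL) {
  mir_sample(sample_id, rna, lr, pv)
}

# One preprocessed experiment with explicit per-gene log-ratios.
make_experiment <- function(experiment_id = "e1", platform = "microarray",
                            assay = "transfection", samples,
                            preprocessed = TRUE) {
  experiment_set(experiment_id, platform, assay, samples, preprocessed)
}

# A tiny feature table keyed by gene id with one bin column of interest.
make_features <- function(gene_id, length_group = "Short",
                          expr_group = "Medium", cons_group = "Low",
                          utr_length = 100, cons_score = 0.1,
                          expr_score = 0.05) {
  n <- length(gene_id)
  data.frame(gene_id = gene_id, utr_length = rep_len(utr_length, n),
             length_group = factor(rep_len(length_group, n),
                                   levels = mirconfound:::LENGTH_LEVELS),
             cons_score = rep_len(cons_score, n),
             cons_group = factor(rep_len(cons_group, n),
                                 levels = mirconfound:::CONS_LEVELS),
             expr_score = rep_len(expr_score, n),
             expr_group = factor(rep_len(expr_group, n),
                                 levels = mirconfound:::EXPR_LEVELS),
             cpg_group = factor(rep_len("medium", n),
                                levels = mirconfound:::CPG_LEVELS),
             hk = rep_len(FALSE, n), dev = rep_len(FALSE, n))
}

# Assignment rows for one RNA over a set of genes.
make_assignments <- function(gene_id, rna_id = "r1", n_sites = 1L,
                             n_endo_sites = 0L) {
  n <- length(gene_id)
  ns <- rep_len(n_sites, n)
  ne <- rep_len(n_endo_sites, n)
  data.frame(gene_id = gene_id, rna_id = rna_id, n_sites = ns,
             is_exo_target = ns >= 1, n_endo_sites = ne,
             is_endo_target = ne >= 1,
             group = paste0(ifelse(ns >= 1, "T", "NT"),
                            ifelse(ne >= 1, "+Endo", "-Endo")))
}

random_dna_lens <- function(lens) vapply(lens, random_seq, "")

table1_reference <- function() {
  read.delim(system.file("extdata", "trend_counts_reference.tsv",
                         package = "mirconfound"))
}
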