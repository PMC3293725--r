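# Shared constants: alphabets, site types, and the ordered factor levels of
# the gene-context feature bins. Kept in one early-loading file because
# several modules reference them at load time.

BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", U = "A", N = "N")
SITE_TYPES <- c("8mer", "7mer-m8", "7mer-A1")

LENGTH_LEVELS <- c("Short", "MedShort", "MedLong", "Long", "VeryLong")
CONS_LEVELS <- c("NoConsv", "Low", "Medium", "High")
EXPR_LEVELS <- c("NoExp", "VeryLow", "Low", "Medium", "High", "VeryHigh")
CPG_LEVELS <- c("low", "medium", "high", "unknown")
GROUP_LEVELS <- c("T+Endo", "T-Endo", "NT+Endo", "NT-Endo")

EXPR_ORDINAL <- setNames(seq_along(EXPR_LEVELS), EXPR_LEVELS)

FEATURE_COLUMNS <- c(length = "length_group", conservation = "cons_group",
                     expression = "expr_group", cpg = "cpg_group",
                     hk = "hk", dev = "dev")
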