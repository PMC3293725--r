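Package: mirconfound
Title: Gene-Context Confounders in miRNA and siRNA High-Throughput Experiments
Version: 0.1.0
Authors@R:
    person("mirconfound", "developers", email = "mirconfound@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for quantifying how target-site-independent,
    gene-context features confound microRNA (miRNA) and siRNA high-throughput
    perturbation experiments. Detects canonical seed sites (8mer, 7mer-A1,
    7mer-m8) in 3' UTRs, bins genes by 3' UTR length, conservation, expression
    level, promoter CpG class and housekeeping/developmental status, and runs
    one-sided rank-based subgroup tests of log-ratio knockdown, competition
    tests between exogenous and endogenous miRNA targets, PAR-CLIP AGO
    binding-site enrichment, target-dilution correlations, platform-bias
    enrichment fits, and multi-factor linear regression on min-max normalized
    covariates. Includes a seeded synthetic-data generator that plants
    recoverable targeting, competition, dilution and platform-bias effects so
    the whole pipeline can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
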