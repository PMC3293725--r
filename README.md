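# mirconfound

Gene-context confounders in miRNA / siRNA high-throughput perturbation
experiments.

## The problem

High-throughput perturbation experiments — transfect (or inhibit) a miRNA
or siRNA, then measure per-gene expression log-ratios on microarrays or by
quantitative proteomics — are the workhorse for characterizing small-RNA
regulation. But the *average* knockdown observed for a group of genes is
confounded by target-site-independent, gene-context features:

* **3' UTR length, conservation, and mRNA expression level** correlate with
  the apparent response;
* **competition**: the exogenous RNA competes with endogenous miRNAs for
  the silencing machinery, de-repressing endogenous targets — which sit
  preferentially in long 3' UTRs;
* **target dilution**: an RNA with many target sites knocks each target
  down less;
* **platform bias**: microarrays measure everything but detect *changes*
  poorly for lowly expressed genes, whereas proteomics misses lowly
  expressed genes but measures changes without expression bias.

`mirconfound` is an R package for quantifying these effects. It
implements canonical stringent seed-site prediction (8mer, 7mer-m8,
7mer-A1: for miRNA positions 1..n, a site is the reverse complement of
positions 2–8 and/or a literal A opposite position 1), feature binning
(length quartiles above/below the 4,000 nt "very long" cut, conservation
terciles, expression quintiles, promoter CpG class by windowed GC and CpG
observed/expected ratio, housekeeping/developmental labels), one-sided
Wilcoxon / Kolmogorov–Smirnov subgroup tests of log-ratio knockdown with
per-sample support scores and trend correlations, T−Endo vs T+Endo
competition tests, AGO PAR-CLIP binding calls (≥ 5 reads at a position)
with long-vs-short Fisher enrichment, target-dilution correlations,
platform-bias enrichment fits, and an OLS model

```
-log ratio = ln3 + cs3 + exp + #site_m + #endo_m + #site_s + p_ma + e_oe (+ ts_score)
```

on min-max-normalized factors. A seeded synthetic-data generator plants
all of these effects with exactly recoverable ground truth, so the entire
pipeline is validated without downloading anything.

## Worked example

```r
library(mirconfound)

cfg   <- sim_config(n_genes = 1000, seed = 42)     # one synthetic study
study <- simulate_study(cfg)
exps  <- lapply(study$experiments, preprocess_log_ratios,
                input_log_base = 10)
feats <- gene_feature_bins(study$genes, mode = "quantile")

# Are highly expressed targets preferentially down-regulated on the array?
scan <- run_feature_scan(exps[[1]], study$assignments, feats,
                         feature = "expression")
scan[, c("subgroup", "p_value", "n_in", "n_out", "neg_log2_p")]
#>  subgroup  p_value n_in n_out neg_log2_p
#>      High 3.22e-06   85   426   1.82e+01
#>       Low 7.42e-01   86   425   4.30e-01
#>    Medium 1.30e-01   87   424   2.94e+00
#>     NoExp 1.00e+00   94   417   5.49e-11
#>  VeryHigh 4.38e-05   72   439   1.45e+01
#>   VeryLow 9.70e-01   87   424   4.47e-02
```

The planted per-site knockdown is identical for every target, yet the
High/VeryHigh subgroups test as strongly "more down-regulated"
(p ≈ 3e-06 and 4e-05) while NoExp/VeryLow show nothing — the simulated
microarray attenuates changes for lowly expressed genes, and the subgroup
test faithfully reports the resulting *apparent* expression dependence.
That is the confounder, reproduced from known ground truth.

```r
rows <- build_factor_table(exps, study$assignments, feats)
fit_linear(rows, "main_8")
#> <regression_result> n=1037, 8 terms, R2=0.2193 (adj 0.2132)
#>         term coefficient  p_value
#>  (Intercept)    0.037640 2.39e-01
#>          ln3   -0.007322 4.66e-01
#>          cs3    0.001515 8.97e-01
#>          exp    1.068000 4.16e-04
#>       site_m    0.970800 5.13e-33
#>       endo_m    0.027060 3.17e-01
#>       site_s    0.141600 9.32e-01
#>         p_ma   -0.033120 4.83e-02
#>         e_oe   -0.028040 1.75e-06
```

Positive coefficients promote knockdown (the response is the negated
log-ratio). The number of exogenous sites (`site_m`) dominates, as
planted, and expression (`exp`) carries the platform bias. At this small
cohort size the competition (`endo_m`) and dilution (`site_s`)
coefficients are individually noisy; the acceptance suite shows that at
the full design (5,000 genes, 10 samples) the fitted signs of `site_m`
(+) and `endo_m` (−) are recovered in ≥ 95% of seeds.

The same pipeline runs from the command line on a study directory
(`exec/mirconfound`, or `mirconfound_main()` from R):

```sh
Rscript -e 'mirconfound::mirconfound_main()' simulate --out study --seed 7
Rscript -e 'mirconfound::mirconfound_main()' test --study study --out results \
    --feature expression
```

Subcommands: `simulate`, `features`, `scan`, `test`, `competition`,
`parclip`, `dilution`, `enrichment`, `regress`, `trend`. Every result
table is tab-delimited with a `#` header carrying the package version,
seed, and config hash.

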