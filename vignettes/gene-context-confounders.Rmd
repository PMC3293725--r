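---
title: "Gene-context confounders in miRNA and siRNA high-throughput experiments"
author: "mirconfound developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-context confounders in miRNA and siRNA high-throughput experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirconfound)
```

## The problem

When a miRNA or siRNA is transfected into cells and expression changes are
read out on microarrays or by quantitative proteomics, the average
knockdown observed for a group of genes depends on much more than whether
those genes carry seed-complementary target sites. Gene-context features
that have nothing to do with the individual target site — 3' UTR length,
3' UTR conservation, baseline mRNA expression, promoter CpG class,
housekeeping/developmental status — correlate with the apparent response,
and two mechanisms can generate such correlations without any direct
regulatory role:

* **Competition.** The transfected RNA competes with endogenous miRNAs for
  the silencing machinery, so genes under endogenous miRNA control are
  *de-repressed* after transfection. Because endogenous target sites
  accumulate in long 3' UTRs, this masquerades as "long UTRs are poor
  targets".
* **Platform bias.** Microarrays measure almost every transcript but
  detect *changes* poorly for lowly expressed genes; proteomics detects
  mostly highly expressed proteins but measures their changes without an
  expression-dependent bias. Averaging log-ratios across expression strata
  therefore gives platform-dependent answers.

`mirconfound` implements the complete analysis machinery needed to expose
these confounders — canonical seed-site prediction, feature binning,
one-sided rank tests per subgroup, competition tests, AGO PAR-CLIP
enrichment, target-dilution correlations, platform-bias fits, and a joint
linear model — together with a seeded synthetic-data generator that plants
all of the above effects with known magnitudes, so every stage of the
pipeline is testable without any external download.

## Seed-site model

For a mature small RNA with 5'→3' positions $1..n$, let $S$ be the reverse
complement of positions 2–7 and $m8$ the complement of position 8. On the
UTR (sense strand, 5'→3') the three stringent site types are

| type | UTR string | qualifier |
|------|------------|-----------|
| 8mer | $m8 + S + \mathrm{A}$ | — |
| 7mer-m8 | $m8 + S$ | next base ≠ A |
| 7mer-A1 | $S + \mathrm{A}$ | previous base ≠ $m8$ |

The A opposite position 1 is required to be a literal A, following the
standard stringent-seed convention. U and T are interchangeable; `N` never
matches. Because published counting rules do not state how overlapping
matches are resolved, we count **non-redundantly**: candidates are ranked
8mer > 7mer-m8 > 7mer-A1 and then left to right, and a candidate is kept
only when it does not overlap an already accepted site. The qualifiers
already prevent an 8mer from also being reported as its two embedded
7mers; the greedy pass additionally resolves genuinely distinct
overlapping occurrences. A gene is a predicted target when it has at least
one site (`n_sites >= 1`), and it is an endogenous target (`+Endo`) when it
has at least one site for at least one of the top-`k` (default ten) most
highly expressed endogenous miRNA families, each represented by one mature
sequence (family members share the seed). Ties at the `k`-th family rank
are broken lexicographically for determinism.

## Feature bins

* **3' UTR length**: `VeryLong` strictly above 4,000 nt; the remaining
  cohort is split into four equally sized rank quartiles (`Long`,
  `MedLong`, `MedShort`, `Short`). The package also ships the printed
  reference cuts (247 / 629 / 1,372) as a fixed mode for reproducing
  published bins.
* **3' UTR conservation**: fraction of conserved bases in a binary
  per-base track; zero scores are `NoConsv` and non-zero scores are split
  into terciles (reference cuts 0.054 / 0.238).
* **Expression**: zero scores are `NoExp`, non-zero scores quintiles
  (reference cuts 0.008 / 0.0344 / 0.0795 / 0.2007).
* Bin boundaries are **inclusive upper bounds** with ties assigned to the
  lower bin, so binning is deterministic and order-independent.
* **Promoter CpG class**: a 500-nt window moved 5 nt at a time; per window
  the GC fraction and the CpG observed/expected ratio
  $(\#CG \cdot w)/(\#C \cdot \#G)$. `high` requires one window with
  GC > 0.55 **and** o/e > 0.75; `low` requires every window at o/e ≤ 0.48;
  the rest are `medium`; promoters shorter than one window are `unknown`.
  The published rule says "> 75% CpG content", which cannot be a literal
  dinucleotide frequency; we interpret it as the Weber-style o/e ratio and
  flag this as an interpretation, not a received fact.

## Statistical machinery

All log-ratios are converted to log10 (log2 inputs are scaled by
$\log_{10} 2$) and inhibition experiments are negated so that *negative
always means candidate down-regulation*. The subgroup test asks, for each
bin of a feature, whether predicted-target log-ratios inside the bin are
stochastically smaller than predicted-target log-ratios in the remaining
bins: a one-sided Wilcoxon rank-sum test (exact when both sides have ≤ 25
values and no ties; otherwise normal approximation with continuity and tie
correction), or a one-sided Kolmogorov–Smirnov test (alternative: the CDF
of the bin lies above). Experiment-level tests pool the (gene, sample)
pairs of all samples in an experiment — a gene targeted in several samples
contributes once per sample; this pooling rule is our choice, as the
source analyses report one p-value per subgroup per experiment without
stating one. Per-sample tests plus the *sample-level score* (the fraction
of samples significant at α = 0.05, strictly below) summarize how many
individual perturbations support an experiment-level trend; an experiment
"supports" a subgroup when its score strictly exceeds a threshold (0.5 by
default; strictness at exactly 0.5 is our choice). Trends are compared
between the experiment level and the sample level with a Pearson
correlation whose p-value comes from the usual
$t = r\sqrt{n-2}/\sqrt{1-r^2}$.

The competition test restricts to transfection experiments (inhibition
experiments suppress endogenous miRNAs, so the competition contrast is
undefined there and the function refuses them) and, within each feature
subgroup, tests one-sidedly whether T−Endo genes are more down-regulated
than T+Endo genes. No multiple-testing adjustment is applied anywhere, in
keeping with the raw-heatmap style of the original analyses; the CLI can
optionally emit Benjamini–Hochberg q-values.

**PAR-CLIP**: a UTR has an AGO binding site when any position carries ≥ 5
mapped reads. Length subgroups are merged into long (VeryLong, Long) vs
short (rest) and binding enrichment among long is tested with a one-sided
Fisher exact test.

**Dilution**: per sample, the total number of target sites over predicted
target genes, against the mean target log-ratio, correlated across
samples (Pearson). Restricting the averaged targets to T−Endo genes
(`endo_free = TRUE`) removes the competition contribution from the same
statistic.

**Platform bias**: per experiment and expression subgroup, the log2
enrichment of down-regulated genes. Down-regulated means detection
p < 0.01 *and* log-ratio < −0.01 on microarrays, and log-ratio < −0.01
alone on proteomics. Two enrichment definitions exist in the source
material — a ratio of average log-ratios and an enrichment of
down-regulated gene *counts* — and they disagree; both are implemented,
and `count_enrichment`
$\log_2\big((n^{down}_g/n^{down})/(n^{all}_g/n^{all})\big)$
is the default because a ratio of two negative means is sign-ambiguous.
Points supported by fewer than two down-regulated genes are excluded, and
a line is fitted per platform against the subgroup ordinal.

## Regression

One row per predicted target gene per sample: `ln3`, `cs3`, `exp`,
`site_m` (exogenous sites), `endo_m` (endogenous sites), `site_s` (the
sample's total site count), binary `p_ma` (1 = microarray) and `e_oe`
(1 = transfection), optionally `ts_score` (mRNA-level aggregated
TargetScan-style context scores: per-site scores summed per miRNA:mRNA
pair and negated, so larger = stronger predicted repression). Non-binary
factors are min-max normalized into [0, 1] with the reference ranges
(`ln3` 0–1000, `exp` 6.1e-5–64, `site_m` 0–20, `endo_m` 0–30, `site_s`
0–6000, `ts_score` 0–2); values outside the range are clipped after the
linear map, because leaving them outside would break the documented [0, 1]
contract. The response is the *negated* preprocessed log-ratio — positive
coefficients mean "this factor promotes knockdown" — and is deliberately
not normalized, keeping coefficients in interpretable log10 units. (The
published normalization list contains an `ln (min −2, max 2)` entry that we
read as a reporting range for the response, not as a regressor.) The model
is ordinary least squares with an intercept; interaction modes add all
pairwise products of the normalized main effects. Degenerate designs
(zero-variance terms, rank deficiency, fewer rows than terms) are errors,
not silent drops.

## The synthetic world

`sim_config()` fixes one synthetic cohort per seed:

* UTR lengths log-normal (`meanlog` 6.4, `sdlog` 1.1): median ≈ 600 nt and
  ≈ 4% of genes above the 4,000 nt cut, matching the shape of a human
  RefSeq cohort.
* Per-base conservation Bernoulli with gene-level rates from Beta(0.6, 2)
  (mean 0.23, straddling the reference tercile cuts) and 15% fully
  unconserved genes.
* Expression zero-inflated (20% `NoExp`) log-normal (`meanlog`
  log 0.0344, `sdlog` 2), centred on the reference quintile cuts.
* Ten endogenous families (plus three lower-ranked decoys that receive no
  planted sites, so top-`k` selection is actually exercised); exogenous
  RNAs at 0.15 planted sites/kb and endogenous at 0.08/kb. Poisson
  placement per kb makes long UTRs proportionally richer in endogenous
  sites — the competition/UTR-length entanglement of real data.
* Per-site knockdown 0.1 log10 units (~20%), divided by
  $1 + d \cdot \text{total sites}$ (dilution, $d = 5\times10^{-4}$);
  competition up-shift 0.05 log10 units for endogenous targets;
  per-replicate noise 0.08 log10 units with 3 replicates per arm.
* Microarray observations attenuate the true change by
  $\text{rank}^{s}$ of the gene's expression rank (default $s = 1$; 0
  disables the platform bias) and carry per-gene detection p-values from a
  z test of the observed change against its known replicate-averaged noise
  sd — the large-df limit of a replicate t-test, chosen because gene-level
  array statistics average many probes; a small-df t-test stand-in has
  essentially no power at the planted effect sizes and would erase the
  sensitivity-rises-with-expression mechanism the generator must emulate.
  Proteomics reports a gene
  at all with probability logistic in expression rank (midpoint 0.3) but
  measures the change unattenuated. Inhibition assays flip the sign of the
  exogenous term and are emitted in the raw convention that
  `preprocess_log_ratios()` negates.

Sites are planted *exactly*: every spontaneous occurrence of any RNA's
6-nt seed core is first scrubbed from the UTRs, RNA sets are generated so
that no RNA's core occurs in another RNA's site strings, planted sites get
flank bases that preserve their type, and after planting the generator
re-scans and repairs until the recovered site set equals the planted set.
Ground truth is therefore exact by construction, and the tests assert it.

What a green test does **not** establish: the generator has uniform base
composition within a sequence, no 3'-supplementary pairing, no probe-level
microarray artifacts, no isoform structure, and independence between genes
— so green results validate the *machinery* (directions, calibration,
recovery of planted effects), not biological effect sizes. The published
headline numbers (specific subgroup p-values, PAR-CLIP percentages, R²
values near 0.04–0.09, dilution r = 0.37) depend on the original external
datasets and are intentionally out of scope; the in-package checks cover
the three reference trend correlations (0.91, 0.79, 0.81), which are
functions of printed count tables, plus oracle-exact tests of every
computational primitive.

For long simulation sweeps the generator can skip materializing per-base
conservation tracks (`with_tracks = FALSE` draws the per-gene conserved
count binomially — the exact distribution of the track mean — and carries
it as an attribute) and promoter sequences (`with_promoters = FALSE`);
these switches marginalize storage, not the stated world.

## Numerical conventions and degenerate inputs

* Bin boundaries: inclusive upper bounds; quantile ties to the lower bin.
* `VeryLong` is strictly greater than the 4,000 nt cut.
* Sample-level scores and trend thresholds use strict inequalities.
* Wilcoxon switches to the exact distribution only when both sides have
  ≤ 25 observations and no ties.
* Empty test sides, degenerate 2×2 tables, zero-variance regressors,
  zero-variance correlations, and missing feature bins for tested genes
  raise errors naming the offender; subgroups with no testable genes are
  reported with `NA` p-values rather than dropped silently.
* CpG o/e is 0 when a window lacks C or G entirely.

## Known limitations

* The seed scanner is exact-match only; G:U wobble, seedless, and
  3'-supplementary sites are out of scope.
* TargetScan context scores are consumed, never computed.
* The per-sample pooling rule for experiment-level tests is one defensible
  choice among several; alternatives (e.g. per-gene averaging across
  samples) would change n but rarely direction.
* The synthetic microarray p-values are a stand-in honoring the
  "p < 0.01" filter semantics; real array pipelines differ.
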