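---
title: "Discovering copy-number-linked expression changes with scnvdeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering copy-number-linked expression changes with scnvdeg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scnvdeg)
```

## The problem and the model

Tumor genomes accumulate somatic copy-number variations (SCNVs). A gene
inside an amplicon may or may not follow the dosage at the mRNA level, and
even when it does, the change may simply reflect linkage to a nearby driver.
`scnvdeg` frames the question as a pair of differential-expression contrasts
per gene:

* **SCNV vs diploid**: tumors carrying the alteration against diploid
  tumors, telling whether dosage propagates to expression;
* **tumor vs normal**: all tumors against healthy tissue, telling whether
  the gene is deregulated in the disease at all.

Counts are modeled as negative binomial with a *common dispersion*:
for gene $g$ in sample $s$, $y_{gs} \sim \mathrm{NB}(\mu_{gs}, \phi)$ with
$\mathrm{Var}(y) = \mu + \phi\mu^2$. One $\phi$ is shared by all genes of a
contrast — the small, asymmetric groups produced by per-gene sample splits
(often 3–30 altered samples) do not support stable per-gene dispersions, and
the conditional-likelihood machinery below is exact under this assumption.

### Conditional ML dispersion

After library-size equalization (each sample scaled to the geometric mean of
library sizes and rounded), the within-group count splits are conditioned on
their group totals. For a group of $n$ samples with counts $y_1..y_n$,
total $z$, and $r = 1/\phi$:

$$\log P(y \mid z) = \sum_i \log\Gamma(y_i + r) + \log\Gamma(nr)
 - \log\Gamma(z + nr) - n\log\Gamma(r) + \log z! - \sum_i \log y_i!$$

The sum of this quantity over genes and groups is maximized over
$\log_{10}\phi \in [-4, 0.6]$ by golden-section search with tolerance
$10^{-3}$. The bounds cover realistic bulk RNA-seq dispersions
($\phi \approx 10^{-4}$ is effectively Poisson, $\phi \approx 4$ is extreme
overdispersion); a boundary hit is flagged on the returned estimate. Poisson
data therefore yield $\hat\phi \approx 10^{-4}$, not an error.

### The exact test

Conditional on the two-group total $T = S_A + S_B$, the group-A sum follows

$$P(S = s \mid T) \propto f(s;\, n_A/\phi)\; f(T-s;\, n_B/\phi),$$

where $f$ is the NB mass at the common per-sample mean (which cancels by
conditioning) and $n_g/\phi$ the group size parameter; at $\phi = 0$ the law
reduces to $\mathrm{Binomial}(T, n_A/(n_A+n_B))$. The two-sided p-value
follows the Fisher-exact convention: the sum over all splits whose
probability does not exceed the observed one. Numerically the weights are
computed on the log scale, normalized by their maximum, and ties are
recognized with a relative tolerance of $10^{-8}$ — large enough to absorb
floating-point noise in `lgamma`, far too small to merge genuinely distinct
outcomes. $T = 0$ returns $p = 1$ by convention. P-values are adjusted by
Benjamini–Hochberg step-up, and significance requires both
`fdr < fdr_threshold` and `|log2_fc| > logfc_threshold`.

The exact test consumes integer pseudo-counts (raw counts after
equalization), never the normalized matrix: the conditional NB law assumes
integer counts with equal library sizes. The normalized matrix serves
reporting. The log2 fold change uses group means with a $0.5/n$ offset per
group, keeping zero-count genes finite and symmetric under label swap.

## Tunable parameters

| key | default | meaning |
|---|---|---|
| `cor_cut` | 0.6 | minimum mean Spearman correlation (on log2(count+1)) for a sample to be kept |
| `low_expr_quartile` | 0.25 | gene-mean quantile below which genes are removed |
| `within_lane` / `within_lane_bins` | `gc` / 10 | per-sample covariate normalization (gc, length, off) |
| `between_lane` | `full_quantile` | cross-sample normalization (or `upper_quartile`, `off`) |
| `logfc_threshold` | 0.58 | minimum \|log2FC\| (a 50 % change) |
| `fdr_threshold` | 0.05 | BH-adjusted significance level |
| `cn_mode` | `deep` | which calls count as altered: deep (±2), shallow (±1), combined |
| `min_altered` | 3 | minimum altered *and* diploid group size per contrast |
| `fdr_scope` | `genome` | FDR over all genes of a contrast, or over queried genes only |
| `tn_policy` | `all_tumors` | tumor-vs-normal contrast uses all tumors, or per-gene diploid tumors only |
| `cooccur_alpha` | 0.05 | retention threshold for driver co-occurrence pairs |
| `window_size` | 1e7 | genomic tiling width in bp |
| `dep_amp_cutoff`, `dep_dip_low` | 2.5, 1.5 | cell-line copy-number bands |
| `dep_median_diff`, `dep_alpha`, `dep_min_group` | 0.10, 0.05, 5 | dependency significance rule |

Every preprocessing step is individually skippable; skips are recorded in
the JSON run summary. `min_altered = 3` is the smallest group for which the
dispersion machinery is defined at all (two groups of ≥ 2 are needed for the
conditional likelihood; 3 keeps a margin) and is logged prominently in the
summary. The 2.5 copy-number boundary belongs to the amplified band and is
excluded from the diploid band, keeping the bands disjoint; the thresholds
are applied verbatim to whatever scale the input tables carry, and the
summary records that assumption.

## Design decisions in ambiguous corners

* **Outlier aggregation.** "Samples associated with a correlation below the
  cutoff" does not say how pairwise values aggregate; we use the mean of a
  sample's correlations with all others, in a single pass. It is the
  simplest stable reading — iterating would make removal order-dependent.
* **Quartile convention.** The low-expression filter uses the
  linear-interpolation quantile (R type 7) with a strict `<` comparison,
  fixed and documented so runs are reproducible across implementations.
* **Two tumor-vs-normal policies.** Comparing *all* tumors against normals
  answers "is the gene deregulated in disease"; comparing only a gene's
  *diploid* tumors answers "is the baseline shifted independently of the
  SCNV". Both are legitimate and both are implemented (`tn_policy`);
  `all_tumors` is the default and is computed exactly once per run. Note
  that under `all_tumors` a strong dosage effect at high recurrence bleeds
  into the tumor-vs-normal contrast, moving hits from subset a to b — the
  `diploid_only` policy removes that bleed-through.
* **Directional contrasts.** Amplification and deletion are always tested
  independently per gene; a gene can in principle emit one record of each
  type.
* **Subclass precedence.** The genomic-context subclasses overlap as prose;
  we make them a partition with precedence i (census driver) > ii_b
  (trans-linked to a driver SCNV-DEG) > iii (cis linkage: shared enriched
  window with a driver record, or same-chromosome co-occurrence) > ii_a (no
  driver linkage). Co-occurrence among non-drivers never demotes a record.
* **Window assignment and enrichment.** A gene belongs to the 10-Mb window
  containing its interval midpoint (unambiguous for boundary-straddling
  genes); coordinates are 0-based half-open throughout, converting the
  1-based TSV dialect on read. Enrichment uses strict `>` on both rules
  (count > 2 to be a candidate, count > candidate mean to be enriched), so
  an all-tied candidate set yields no enriched window.
* **Ranking.** Within each 2×2 stratum (driver co-occurrence × enriched
  window), records sort by recurrence descending, then SCNV-contrast FDR
  ascending, then gene symbol — the lexicographic combination of the two
  stated keys, with a deterministic tie-break.
* **Fisher sidedness.** Co-occurrence tests are two-sided, with the
  relation (co-occurring vs mutually exclusive) read from the sample odds
  ratio (Haldane +0.5 correction only when a zero cell exists). Retention
  uses the uncorrected p < 0.05 rule; a BH column is emitted alongside for
  users who prefer corrected calls.
* **Dependency orientation.** `median_diff = median(diploid) −
  median(amplified)`, so positive values mean amplified lines are *more*
  dependent (Chronos scores are more negative when a knockout hurts).

## The synthetic cohort generator

`simulate_cohort()` is first-class, tested code that stands in for cohort
downloads. It emulates: log-normal baseline expression (meanlog log 50,
sdlog 1), NB sampling noise at a global $\phi$, deep (±2) calls for
configured true genes at a configured recurrence, signed dosage effects on
the log2 mean, optional expression-neutral ±1 call noise, optional
tumor-vs-normal baseline effects, a toy genome (3 chromosomes × 100 Mb) with
optional clustering of true genes into one 10-Mb window, and a census
labeling drivers both inside and outside the truth set. True SCNV-DEG
baselines are drawn from the expressed part of the baseline distribution
(above its 40th percentile): a transcript below the low-expression filter
cannot display dosage-linked differential expression, and the margin over
the filter's 25th percentile also covers the mean shrinkage a recurrent
deletion itself induces.

What it does **not** emulate — and hence what passing tests cannot certify
about real data: realistic SCNV breakpoint structure and segment lengths,
tumor purity and subclonality (real dosage effects are attenuated and
heterogeneous), per-gene dispersion variation, GC/length biases coupled to
real genome composition, batch effects, and driver census incompleteness.
Benchmarks on this generator measure the statistical machinery under its own
assumptions, not performance on TCGA-scale cohorts.

The default benchmark configuration is 500 genes × 100 tumors + 8 normals,
$\phi = 0.1$, 20 true SCNV-DEGs with dosage |log2FC| = 2 at recurrence
0.3 — sizes chosen so every contrast is well-posed while a full pipeline run
completes in well under a minute; the acceptance script uses exactly these
sizes and reports the problem size alongside every number.

## Degenerate inputs and numerical corners

* An all-zero sample is an error for between-lane normalization and library
  equalization (its scale is undefined); an all-zero count matrix is an
  error for dispersion estimation.
* An empty driver census downgrades driver-dependent outputs (no pairs,
  subclasses fall to ii_a/iii by window evidence alone) with a warning.
* Queried symbols absent from the inputs go to a skipped-genes table; the
  run continues.
* `T = 0` exact tests return 1; missing dependency values are dropped
  pairwise; under-sized dependency arms are reported with a reason instead
  of a p-value.
* The Wilcoxon contrast uses exact enumeration when both arms have ≤ 10
  untied values and the tie-corrected normal approximation otherwise.
* All outputs are written with fixed column order, 17-significant-digit
  numerics and `\n` line endings, so identical configuration and seed give
  byte-identical files; per-gene contrasts are independent, making results
  invariant to any parallelism degree.

## Known limitations

Only discrete thresholded calls are supported (no continuous log-ratio or
allele-specific input); dispersion is common per contrast (no tagwise
shrinkage); the tumor-vs-normal contrast requires ≥ 2 normals or subsets
degrade to `no_normal`; cluster enrichment uses a plain count rule, not a
permutation test; and the dependency screen ignores lineage structure
across cell lines.
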