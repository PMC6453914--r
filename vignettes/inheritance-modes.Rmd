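---
title: "Classifying transcriptome inheritance in F1 hybrids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying transcriptome inheritance in F1 hybrids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybmode)
library(dplyr)
```

## The model

An F1 hybrid inherits one allele of every autosomal gene from each parent,
and its expression level can resemble either parent, sit between them, or
escape the parental range altogether. With `P_Cor`, `P_WL` and `H` the
normalized expression of the Cornish parent, the White Leghorn parent and
the hybrid, we call two values *similar* when their symmetric ratio
`max(x, y) / min(x, y)` is strictly below a threshold `t = 1.25`, and
classify:

* **conserved** — `H` similar to both parents;
* **Cor/WL dominant** — `H` similar to exactly one parent;
* **additive** — `H` different from both and strictly between them;
* **over-/under-dominant** (*mis-expressed*) — `H` beyond both parents.

The symmetric ratio on the linear scale is exactly equivalent to an
absolute log-fold cutoff `|log(x) - log(y)| < log(t)` while remaining
defined at zero: two zeros are identical (ratio 1), one zero is infinitely
different. A gene silent in all three members of a group is
`unclassified_zero` and excluded from category counts — it carries no
information in that group, though it may be classifiable in another group
(the parental units are shared between the cross and reciprocal-cross
groups, so a gene expressed only in one hybrid is, by the rule above,
over-dominant there).

Two boundary decisions are deliberate and configurable only in one
direction each: the threshold itself (`threshold` argument) and the
convention that a ratio of exactly `t` counts as *different* — similarity
is defined by a strict inequality. A hybrid similar to both parents is
conserved even when the parents differ from each other by more than
`t`-fold: the definitions reference only hybrid–parent contrasts, and the
recorded fold ratios (`fold_h_cor`, `fold_h_wl`) let users re-examine such
genes. "Between" in the additive branch is a strict inequality; equality
with a parent is unreachable there because it would have made the hybrid
similar to that parent first.

## Normalization

Counts are processed in the order **filter → average → normalize**.
Filtering removes Z-linked genes (dosage compensation in chicken is
incomplete, so Z expression differs systematically between ZZ males and
ZW females and would contaminate the sex-stratified groups) and genes with
zero counts in every sample. Replicates are then averaged arithmetically
within each breed–sex unit, and each unit is scaled to percentage
expression: gene mean divided by the unit's total over retained genes,
times 100. Filtering first keeps the denominator consistent across units;
whether the original analyses computed their denominator before or after
filtering is not documented, and we adopt the post-filter denominator as
the internally consistent choice. The scaling makes profiles invariant to
library depth, which the test suite asserts as an exact property.

## The four analysis groups and consolidation

The design crosses Cornish males to White Leghorn females (`CL` hybrids)
and the reciprocal (`LC`), with pure-bred `CC` and `CW` families standing
in for the parents. Classification runs separately in four groups — MC
(WL♂, Cor♂, CL♂), FC (WL♀, Cor♀, CL♀), MR and FR with the `LC` hybrids —
so sex and cross direction never mix inside a contrast.

Across groups, a gene showing the same mode in two or more groups of a
tissue is *assigned* that mode; genes identical in all four groups are
additionally flagged consistent. A 2–2 split between two modes is labelled
`ambiguous` and excluded from per-mode gene lists — the ≥2-group rule does
not resolve ties, and silently preferring one mode would bias the
direction-specific tallies. `venn_partition()` reports the full 15-region
membership structure underlying the four-way Venn diagram.

## Category-count tests

The tallies arrive as one count per group — four observations per tissue
per category. At that granularity we use rank tests: Kruskal–Wallis across
the three tissues on mis-expressed counts, and Mann–Whitney within a
tissue comparing Cor-dominant with WL-dominant counts, exact p-values when
there are no ties. The package ships the published per-tissue count tables
(`published_mode_counts()` and relatives) so these tests, and every
percentage derived from the tables, can be recomputed directly; the
acceptance script does exactly that.

## ASE analysis of dominant genes

Dominance at the whole-gene level says nothing about mechanism; the
allelic split inside the hybrid does. Genes with at least one informative
(breed-diagnostic) SNP contribute summed per-allele counts. Genes are
first filtered by coverage: allele totals are rescaled so every hybrid
unit has the same total (depth standardization — the same total-count
logic as the expression normalization, kept on the read scale rather than
converted to percentages, because a 10-read threshold is only meaningful
on the read scale) and genes under 10 standardized reads are dropped, the
boundary kept.

Dominant genes are split by parental direction (Cor > WL vs Cor < WL) so
opposite-signed effects cannot cancel, then `log2(WL)` is regressed on
`log2(Cor)` by unweighted ordinary least squares twice: on parental
normalized expression and on hybrid allele counts. Log base 2 is used
throughout; genes with a zero on either side are excluded from log fits
(no pseudocounts) with the exclusion count reported. The cis signal is the
Pearson correlation between parental and allelic `log2(Cor/WL)` ratios.
Interpretation: allele-stratum slope ≈ 1 and intercept ≈ 0 means balanced
alleles (trans regulation); a strong ratio correlation means allelic
imbalance tracking the parental difference (cis regulation). Slope and
Pearson r are invariant to a common rescaling of all allele counts — only
the intercept absorbs depth — which is tested as an exact property.

## SNP filtering and pseudo-genomes

Mapping hybrid reads to a single reference biases allele counts toward the
reference allele, so parental pseudo-genomes substitute breed-diagnostic
alleles into the reference. SNPs are retained when supported by strictly
more than 10 reads in *each* breed, lowered to strictly more than 4 on the
Z chromosome, where female coverage is halved. "More than" is taken
literally: boundary depths are rejected. Only biallelic SNVs are
substituted; indels and multi-allelic records are skipped with a warning,
and heterozygous-within-breed sites are outside this toy-scale model — a
single haploid pseudo-sequence cannot carry two alleles. Substitution
validates the reference base at every site (1-based VCF coordinates) and
fails loudly on mismatch, which also makes accidental double-substitution
impossible unless the check is explicitly disabled.

## The synthetic-data generator

No raw sequencing data accompany the study design this package models, so
validation rests on simulation with known truth. The generator emulates:

* ~15,000 genes, four crosses × two sexes × three replicates,
  negative-binomial counts (gene-shared dispersion 100) at a library depth
  of 3.6 million mapped reads — the scale of the motivating experiment;
* log-normal baseline expression (`mean_log2_expression = 5`,
  `sd_log2_expression = 2`);
* a configurable mode mixture (default 55% conserved, 13/11% dominant,
  8/7% over/under-dominant, 6% additive — brain-like proportions);
* parental divergence drawn as a per-mode floor plus an exponential log2
  spread, keeping most divergences under two-fold;
* 4% Z-linked genes, 2% never-expressed genes, Poisson(2.6) informative
  SNPs per gene.

Expected means respect the mode definitions with safety margins: contrasts
that must be called different are at least 1.5-fold, contrasts that must
be called similar at most 1.1-fold. The margins keep effects away from the
1.25 decision boundary so that recovery tests are well-posed — a simulated
additive gene sitting at exactly 1.25-fold would be classified by noise
alone. Because the additive hybrid mean is the arithmetic mid-parent
(the natural reading of "between the parents"), the additive parental
ratio must be at least `max(2m − 1, m / (2 − m)) = 3` for margin
`m = 1.5`; the generator enforces this floor. Hybrid expectations are
identical for the two reciprocal crosses — the generator does not model
parent-of-origin effects.

For ASE, a dominant gene is cis-driven with probability `cis_fraction`
(default 0.5), in which case its allelic ratio equals the parental ratio;
otherwise alleles are balanced. Allele counts are binomial splits of the
gene's hybrid reads, so totals are conserved exactly.

What the simulation does *not* emulate: mapping bias, SNP-calling error,
overdispersion heterogeneity across genes, correlated replicates,
parent-of-origin or dosage-compensation effects, and tissue structure
(each simulated dataset is one tissue). Passing recovery tests therefore
demonstrates correctness of the decision rules and estimators, not
robustness to those artefacts.

## Numerical and scale choices

Problem sizes in the tests and acceptance script are chosen for sharp
statistical expectations at interactive run times: exhaustive classifier
checks on a 9³ value grid against a brute-force oracle; 10,000 genes with
dispersion 10⁴ and 2×10⁷ reads for the ≥99% recovery check (at that noise
level the coefficient of variation of group means is well under 5% for all
but the rarest low-expression genes); 4,000 genes for the ASE regime
checks. OLS estimates are validated against the closed-form normal
equations at 10⁻¹⁰. A single integer seed drives every stage, split
internally per sub-generator, and identical configurations reproduce
byte-identical outputs.

## Limitations

The classifier is a deterministic rule on point estimates; it propagates
no uncertainty, and genes near the 1.25 boundary flip categories under
resampling. The alternative significance-based rule
(`classify_all_binomial()`, similarity declared when a per-gene binomial
test's BH-adjusted FDR exceeds 0.005) is provided for sensitivity
analysis but is not the default. Differential-expression calling is
consumed, not performed: `summarize_divergence()` turns externally
produced DE counts into the reported percentages. Formal cis/trans
classification (joint TReC/ASE likelihood models) is out of scope; the
ASE module implements the ratio-regression analysis only.
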