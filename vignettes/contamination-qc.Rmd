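---
title: "Detecting choroid plexus contamination in brain expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting choroid plexus contamination in brain expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plexusQC)
```

## The problem

The choroid plexus is a small, highly vascularized, ciliated tissue in the
brain ventricles that produces cerebrospinal fluid. Because it sits directly
against structures that neuroscientists routinely dissect — hippocampus most
of all — fragments of plexus are easily carried over into bulk tissue samples.
A handful of genes (transthyretin *TTR*, folate receptor 1 *FOLR1*, prolactin
receptor *PRLR*) are expressed orders of magnitude higher in choroid plexus
than in brain parenchyma, so even a contaminating fraction below 1% of a
sample's RNA can move those markers from near-silence to the top of the
expression distribution. If contamination happens to fall unevenly across
experimental groups, the markers (and the genes co-expressed with them)
masquerade as differential expression.

plexusQC screens expression datasets for this artifact. It never tries to
prove contamination in any individual sample — that is not identifiable from
expression alone — but it quantifies how marker abundance is distributed
within and across samples and groups, and whether that distribution is the
kind produced by uneven tissue carryover.

## The statistics, in order of the pipeline

**Within-sample percentile rank.** For a sample with $n$ genes, a gene with
expression $x$ receives

$$\mathrm{rank}(x) = 100 \cdot \frac{\#\{x_j < x\} + \tfrac12\,\#\{x_j = x\}}{n},$$

the midrank convention on a 0–100 scale. Ranks depend only on within-sample
ordering, so they are comparable across platforms, units and library depths;
the mean rank in every sample is exactly 50, and total ties map to 50. Ties
could alternatively be resolved by the maximum rank; midrank was chosen
because it is symmetric and matches the common definition of percentile
ranks. Mitochondrial genes are removed first (symbol prefix `MT-`,
case-insensitive, configurable): they are so uniformly abundant that they
compress the upper tail of the rank scale.

**Five-level profile classification.** A *profile* is one dataset's
per-sample marker rank plus experimental-group labels. Marker rank is
compared across groups with a classic one-way ANOVA ($F$ with $k-1$, $N-k$
degrees of freedom), and p-values are Bonferroni-corrected across the family
of profiles whose ANOVA is defined. Profiles whose ANOVA is undefined (a
single group, no residual degrees of freedom, or zero variance throughout)
are flagged NA and excluded both from the correction family and from the
summary denominator. Each retained profile gets a priority:

1. adjusted $p < 0.05$ — marker differs strongly between groups;
2. $0.05 \le$ adjusted $p < 0.1$ — moderate group difference;
3. residual — marker present, no clear pattern;
4. rank $\ge 80$ in strictly more than 80% of samples — uniformly high;
5. rank $\le 20$ in strictly more than 80% of samples — uniformly low.

The rules are evaluated in the fixed precedence 1, 2, 4, 5, 3. The precedence
is a design choice: group-difference evidence is the actionable finding (it
is what can bias a downstream analysis), so it wins over the uniform
patterns, and "no clear pattern" is the residual class. A profile with an NA
ANOVA can still earn 4 or 5 from its rank fractions. The uniform rules use
ranks rather than raw values by default because values are platform
dependent; `classifier_config(use_values = TRUE)` switches to values, mapped
onto percent of the profile's observed range. Inequalities are exactly as
stated: $\ge$ on the rank cut, strict $>$ on the sample fraction.

**Contamination grouping.** Samples are assigned by the log2 marker
expression of a TPM-like unit: below `low_cut` → low contamination, above
`high_cut` → high, in between → unassigned (and excluded). The defaults are
the conventional TTR cuts 3.32 / 5.32 (roughly 10 and 40 TPM) and −1 / +1 for
FOLR1. Before taking logs an offset of $2^{-10}$ is added, so a sample with
zero marker expression maps to exactly −10: finite, and far below every low
cut — the offset can never lift a genuinely silent sample across a threshold.

**Differential-expression confirmation.** Between the low and high groups the
package runs a full count-style DE analysis, written in-package:

* **CPM filter**: keep genes with CPM strictly above 2 in at least 3 samples
  (both configurable). TPM input is deliberately allowed through the same
  CPM/TMM path — depth information is already gone from TPM, but the filter
  and scaling still operate on the right scale, and this matches how
  TPM-distributed archives are commonly analyzed.
* **TMM scaling**: the reference sample is the one whose upper-quartile CPM is
  closest to the mean upper quartile; per sample, gene-wise log-ratios
  $M$ and abundances $A$ against the reference (genes positive in both) are
  doubly trimmed — 30% of each $M$ tail, 5% of each $A$ tail — and the factor
  is $2^{\bar M_w}$ with inverse-asymptotic-variance weights. Factors are
  rescaled to geometric mean 1. The trim constants are the canonical
  published values for this estimator.
* **Precision weights**: $\log_2\mathrm{CPM}$ with the $(y+0.5)/(\tilde N+1)$
  offsets; residual standard deviations from a gene-wise linear fit are
  smoothed against average log-count with lowess (span 0.5 — wide enough to
  be stable at a few thousand genes, local enough to track the mean-variance
  bend), and each observation's weight is the inverse fourth power of the
  trend at its fitted log-count.
* **Weighted linear model**: per gene, weighted least squares on an intercept,
  the high-vs-low contamination indicator (its coefficient is the log2 fold
  change), and covariates — by default sex and age bin. Age bins are ordered
  with few levels, so the default encoding is a single ordinal integer;
  `age_encoding = "categorical"` fits one coefficient per bin instead.
  Covariates that are constant in the analyzed samples are dropped with a
  warning; a genuinely rank-deficient design is an error naming the aliased
  columns.
* **Empirical-Bayes moderation**: gene variances are shrunk toward a prior
  $(d_0, s_0^2)$ estimated by closed-form moment matching on $\log s^2$
  (digamma/trigamma inversion, Newton steps). Posterior variance
  $(d_0 s_0^2 + d\,s^2)/(d_0+d)$; moderated $t$ with $d_0 + d$ degrees of
  freedom, two-sided p-values. If the observed variances are literally
  constant, the prior spread is taken as zero and posterior variances equal
  the observed value exactly; if the excess spread is non-positive, $d_0$ is
  infinite and all posteriors equal $s_0^2$.
* **Call**: BH-adjusted $p < 0.05$ and $|\log_2 \mathrm{FC}| > 1$, in either
  direction. BH is applied within one analysis, never across analyses.

The analysis is rerun per sex (covariates minus sex) to check that the marker
signal is not a sex artifact; strata with fewer than 3 samples in either
contamination group are skipped with a warning rather than fitted
underpowered.

**Enrichment.** Upregulated genes are tested against user-supplied GMT gene
sets by the upper-tail hypergeometric probability, with the post-filter gene
list as the default universe (standard over-representation practice), and BH
across sets.

**Kruskal–Wallis across age bins.** To check that marker expression is not an
age effect, log2 marker values are compared across age bins with the
tie-corrected Kruskal–Wallis $H$ (age bins are heavily tied). Degrees of
freedom are always $k - 1$, the number of bins minus one; some published
analyses print sample-count-based degrees of freedom for this test, but the
chi-square reference with $k-1$ is the standard form and is what this package
reports.

## The simulator: what it emulates and what it does not

`simulate_dataset()` provides ground truth for everything above. Each
sample's expected expression is a mixture

$$\mu_{gs} = (1 - f_s)\,\mu_g^{\mathrm{tissue}} + f_s\,\mu_g^{\mathrm{cont}},$$

with $f_s$ the true contamination fraction, and counts drawn negative
binomial with mean $\mu_{gs} L_s / \sum_g \mu_{gs}$ and constant dispersion.
The fixed defaults describe one realistic study condition:

* non-marker baselines log-normal(meanlog 3, sdlog 2) — several orders of
  magnitude of expression, giving a realistic rank spread;
* marker baseline mean 1 (near-silent in clean tissue) and
  `marker_fold = 1e4`, so the contaminant-to-tissue ratio spans the orders of
  magnitude seen in marker genes; non-marker genes have equal means in both
  tissues, so the contamination signal is carried entirely by the panel;
* $f \sim \mathrm{Beta}(2, 18)$ (mean 0.1) for contaminated samples, with a
  point mass of clean samples (`clean_probability`, 0.5 in `random` mode) —
  the "some samples but not others" pattern; in `group_biased` mode the
  biased group is fully contaminated and the clean group has $f = 0$
  (`group_bias` multiplies the contamination *probability* per group);
* dispersion 0.1, library sizes uniform on 0.8–1.2 million, 2000 genes with
  3 markers, 6 + 6 samples, sex and age bins assigned uniformly.

No quantitative contamination-fraction distribution is established for real
dissections; these are deliberate stand-ins, exposed in `sim_config()` rather
than asserted as facts. One global seed feeds a counter-based substream per
sample, so enlarging a design never perturbs the samples already generated.

What the simulator does **not** emulate: correlated co-expression of the
contaminant transcriptome (only the markers move), batch effects beyond the
group bias, gene-length effects, isoforms, read-level noise, and single-cell
phenomena. Passing the recovery tests therefore shows the pipeline detects
*marker-carried mixture contamination under negative-binomial noise* — it
does not certify behavior under correlated confounders that the generator
does not produce.

## Numerical and serialization conventions

* Percentile ranks: midrank ties (configurable intent documented above).
* log2 offset $2^{-10}$ (exactly −10 at zero), chosen to never cross the 3.32
  or −1 thresholds from below.
* TMM: trims 30%/5%, upper-quartile reference, delta-method weights; factors
  exactly geometric-mean 1.
* Trigamma inversion: Newton iteration from $y = 0.5 + 1/x$, relative
  tolerance $10^{-8}$.
* Expression matrices serialize at 17 significant digits so write–read
  round-trips are bit-exact; derived result tables use 6 significant digits
  and the string `NA` for missing values, which keeps outputs diff-stable.
* Delimiters come from the file extension (`.tsv`/`.csv`), never content
  sniffing. Duplicate gene ids are summed for counts and are an error for
  any other unit (counts are additive; TPM is not).
* Degenerate ANOVA inputs give NA-flagged results and leave the
  multiple-testing family; a zero within-group variance with real separation
  gives $F = \infty$, $p = 0$.

## Validation scale

The test suite and the acceptance script validate recovery on 50 seeded
replicates per contamination mode at the default 2000 genes and 6 + 6
samples, null calibration on 20 label permutations, and the variance-prior
moment estimator on 100 replicates of 200 genes — sizes at which every check
runs in well under a minute on a laptop while leaving the binomial noise of
the rate estimates small. The rank–fraction association is summarized as one
Spearman correlation pooled over all samples of the random-mode batch:
per-replicate correlations at 12 samples are dominated by the tie mass at
$f = 0$ and are poor estimators of the same association.

## Known limitations

* The classifier inspects one marker per profile; a panel-level profile test
  (e.g. joint rank of TTR/FOLR1/PRLR) is not implemented.
* The contamination fraction $f$ itself is not estimated — marker percentile
  rank is the reported evidence, as in standard practice.
* Thresholds (3.32/5.32, −1/+1) are conventions for log2 TPM-scale data; for
  other units they must be re-derived by inspecting the marker histogram.
* With a single profile, the Bonferroni family is of size one, so ~10% of
  truly clean datasets will land in priorities 1–2 by chance; the five-level
  summary is most meaningful over a survey of many profiles.
* GEO/Allen/GTEx retrieval is out of scope: loaders accept already-downloaded
  delimited tables only, and there is no network access anywhere in the
  package.
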