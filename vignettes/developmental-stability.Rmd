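---
title: "Quantifying developmental stability from twin-embryo transcriptomes"
author: "devstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying developmental stability from twin-embryo transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(devstab)
```

## The scientific problem

Vertebrate embryos pass through a mid-embryonic, *phylotypic* period in
which the body plan is established and whose transcriptome is the most
conserved part of development across species. One candidate explanation
for that conservation is *developmental stability*: if the phylotypic
period intrinsically produces fewer phenotypic variations under pure
developmental noise — with genetics and environment held fixed — there
is simply less variation for evolution to act on. `devstab` implements
the analysis chain needed to test this idea on whole-embryo
transcriptomes of genetically matched twin pairs: it treats the
transcriptome as a multivariate phenotype, measures between-twin
variation per developmental stage, separates it from measurement error,
and relates per-gene expression stability to micro- and
macroevolutionary conservation, pleiotropy, functional annotation and
regulatory-sequence features.

Because the sequencing cohorts behind such a study are not practical to
re-derive on a desktop, the package ships a synthetic-data generator
that reproduces the statistical structure the analysis assumes. All
tests and the acceptance script run end to end on generated data with
known ground truth.

## The whole-embryo distance V

Expression is analysed as $x_j^i = \log_{10}(\mathrm{TPM}_j^i + 1)$ for
gene $j$ in individual $i$. Genes with $x_j^i < 0.1$ in any individual
of the analysed cohort are removed first (`filter_low_expression()`;
the boundary is inclusive, and the filter is applied per comparison
set).

For a twin pair $(i, k)$ let $y_j^{ik} = x_j^i - x_j^k$. The
whole-embryo distance is the *population* variance of these per-gene
differences,

$$V^{ik} = \frac{1}{N} \sum_{j=1}^{N}
  \left(y_j^{ik} - \overline{y^{ik}}\right)^2 ,$$

implemented literally with the $1/N$ divisor (`pair_variance()`).
Mean-centering makes $V$ invariant to a constant shift between the two
profiles (a pure library-size effect on the log scale); scaling both
profiles by $c$ scales $V$ by $c^2$. A stage's developmental stability
is the mean of $V^{ik}$ over its sex-matched twin pairs; intraspecies
diversity is the same quantity over all sex-matched pairs drawn from
two wild populations. A rank-based alternative, $1 - \rho$ with
Spearman's $\rho$ (`spearman_distance()`), is provided as a
cross-check; the two indices rank the distinguishable stages
identically on synthetic data.

Stage differences are tested with a Kruskal–Wallis omnibus test on the
per-pair $V$ values followed by Steel–Dwass all-pairs comparisons (see
below).

## Separating biology from technical error

Technical error is estimated from a quadruplicate: one RNA pool split
into four subsamples. For each gene the six pairwise absolute
differences $|x_j^{\mathrm{tech},i} - x_j^{\mathrm{tech},k}|$ (all
$\binom{4}{2}$ combinations) form the technical sample, and their mean
is reported as the per-gene technical error. A one-sided Wilcoxon
rank-sum test asks whether the twin differences are stochastically
greater than the technical differences; genes with $p < 0.01$ (raw
p-values, no multiplicity correction) form the universe of all
variation analyses (`filter_by_technical_error()`). The test uses the
exact distribution when the smaller sample has at most 8 values and no
ties, and the mid-rank normal approximation with continuity and tie
correction otherwise.

One operating characteristic deserves emphasis: the six technical
contrasts are built from only four replicate values and are therefore
mutually dependent. Under an exact per-gene null (technical noise equal
to biological noise), the realized pass fraction at $\alpha = 0.01$ is
about 0.04, not 0.01; with six hypothetical *independent* technical
contrasts it is 0.010. The filter is thus a screen with a somewhat
anti-conservative level, not a calibrated test — a property of the
published procedure itself, reproduced faithfully here. Its power is
monotone in the ratio of biological to technical noise, which is the
property that matters for its use.

## Per-gene stability and the running-median correction

The variation of gene $j$ is the mean of $|x_j^i - x_j^k|$ over pairs
(`gene_variation()`): twin pairs for stability, all sex-matched
cross-population pairs for intraspecies variation, and 1:1 ortholog
pairs of replicate-averaged profiles for interspecies variation
(`interspecies_gene_variation()`, with orthologs resolved as
reciprocal best hits by `resolve_rbh()` — best means smallest e-value,
ties broken by larger bitscore then lexicographic subject id, hits kept
below an e-value cutoff of $10^{-5}$).

Raw variation depends strongly on the expression level, so all
variation tables are detrended with a running median
(`running_median_correct()`): sort genes by mean expression over all
individuals of the cohort (ties broken by gene id for determinism);
subtract from each gene's raw variation the median over itself and
$\pm 250$ neighbours (window 501); near the edges the window shrinks
symmetrically so both sides keep equal counts, which forces the first
and last gene's correction to zero exactly. Corrected values can be
negative; only their ranks are used downstream. On synthetic data with
the default mean-variance coupling, the Spearman correlation between
variation and mean expression moves from about $-0.65$ (raw) to within
$\pm 0.05$ of zero (corrected), and the implementation agrees exactly
with a brute-force window recomputation.

Stability-conservation coupling is summarized by Spearman's $\rho$
between two corrected tables over their shared genes
(`stability_conservation_correlation()`), with the exact permutation
p-value when $n \le 10$ and the large-sample approximation otherwise.

## Rank-based stage comparisons

`kruskal_wallis()` wraps the tie-corrected H statistic referred to a
$\chi^2_{k-1}$ law. `steel_dwass()` implements the nonparametric
all-pairs comparison: for each pair of groups the rank-sum statistic on
that pair alone is standardized with tie correction and $\sqrt{2}\,|t|$
is referred to the studentized-range distribution with $k$ groups and
infinite degrees of freedom.

Two numerical choices matter here. First, the rank-sum statistic is
discrete, so a continuity correction of $1/2$ is applied by default
(`continuity = FALSE` restores the plain form). Measured against a
10,000-permutation max-statistic reference on balanced null groups of
10, the plain form shows a systematic mean gap of about 0.027 while the
corrected form's mean gap is about 0.012 (90th percentile 0.021): the
correction is retained because it halves the approximation error at the
sample sizes this design uses (13–25 pairs per stage). Second, a
permutation mode (`method = "permutation"`) computes the family-wise
p-value directly as the tail of the maximum standardized pairwise
statistic under global reshuffling; it is the reference the asymptotic
form is validated against, and the residual gap between the two is an
intrinsic finite-sample property of the studentized-range
approximation, not removable by implementation.

## Gene sets, pleiotropy and enrichment

A gene is *expressed in a context* (tissue or stage) if its mean TPM
over that context's replicates is at least 1 (inclusive); spatial and
temporal pleiotropy are the counts of such contexts
(`context_expression_count()`, 25 tissues / 16 stages in the study
design). Developmental genes are those annotated to the developmental-
process root term or any descendant, with the closure computed from a
supplied child-parent edge list for determinism and offline use.
Constitutive genes clear log-expression 0.1 at every stage.

Enrichment of the 10% least-variable genes (floor of $0.1 n$, ties at
the cut broken by gene id) against the remaining genes uses the
one-sided Fisher's exact test — the hypergeometric upper tail, computed
with `phyper` and cross-checked against `fisher.test` and exhaustive
enumeration in the test suite — with Benjamini–Hochberg q-values and a
frequency-ratio fold enrichment; the reporting rule keeps terms with
fold strictly greater than 2 and flags $q \le 0.01$.

## Regulatory features

Peaks (0-based half-open intervals, BED at the file boundary) are
linked to the gene with the closest TSS; exact distance ties go to the
lexicographically smaller gene id. A linked peak is retained as a
potential regulatory region only if more than half of its length lies
inside the union of the distal window ($\pm 5000$ bp around the TSS)
and the strand-aware proximal window ($-100..+50$ along the gene
strand, 150 bp half-open; flipping the strand mirrors it about the
TSS). A peak overlapping exactly half its length is excluded — the
boundary case is part of the test suite. Substitution events are
counted per (site, carrier sample) inside the retained peaks clipped to
the distal window, with merged intervals so overlapping peaks never
double-count. TATA boxes are counted as exact-string matches of the
four motifs TATAAAAA, TATAAATA, TATATAAA and TATATATA at every offset,
with overlapping matches (two-base shifts of TATA repeats) and
reverse-strand matches counted separately.

## The synthetic-data generator

`sim_config()` fixes the study conditions once:

* four stages `early, phylo1, phylo2, hatch` with biological noise sd
  (0.20, 0.10, 0.10, 0.25) on the log10 scale — an hourglass profile
  with the two phylotypic stages quietest;
* 20 sex-matched twin pairs per stage (the study used 13–25);
* baseline log expression $\mu_j = 0.5 + \mathrm{Gamma}(2, 1.6)$,
  giving a realistic right-skewed log-TPM distribution bounded away
  from zero;
* a per-gene lognormal noise multiplier $s_j$ (mean 1, sdlog 0.4)
  shared between within-population noise and the between-population
  shift $\delta_j \sim N(0, 0.15\, s_j)$ — this shared factor *is* the
  planted stability-conservation correlation;
* a decreasing convex mean-variance coupling
  $g(\mu) = 0.25 + 1.5 e^{-1.2\mu}$, so the running-median correction
  has a real, non-linear trend to remove;
* technical noise sd 0.05 (the study does not report its magnitude;
  chosen clearly below the biological scales). Technical noise carries
  the same $s_j\, g(\mu_j)$ factors as biological noise, so equating
  the two sd parameters produces an exact per-gene null for filter
  calibration;
* one planted annotation term at 5-fold frequency among the 10% of
  genes with the smallest $s_j$, and pleiotropy masks whose expression
  probability decreases with the rank of $s_j$ — the signals recovered
  by the enrichment and pleiotropy analyses.

Noise is Normal on the $\log_{10}(\mathrm{TPM}+1)$ scale, where all
statistics are computed; log values are not truncated at zero (the TPM
export truncates instead), which keeps the closed-form variance of twin
differences exact — the per-stage pooled variance of $y_j$ equals
$\operatorname{mean}_j 2(\mathrm{sd}\cdot s_j g(\mu_j))^2$ to
Monte-Carlo accuracy. TPM values are not renormalized to sum to $10^6$
after the inverse transform, since downstream statistics use the log
matrix directly. The toy genome plants peaks wholly inside distal
windows (plus two boundary-test peaks at exactly half and
three-quarters overlap), substitutions with known carrier counts inside
those peaks, and promoters over an {A, C, G} background with C-padded
TATA motifs so the planted match counts are exact under the counting
rules.

What the generator does *not* emulate: count-level noise models
(negative-binomial dispersion), read mapping artefacts, batch effects,
sex-specific expression, and correlated co-expression modules. Passing
tests therefore demonstrate that the statistical machinery recovers
planted structure of the assumed form, not that the biological
conclusions of any particular dataset are correct.

## Problem sizes and reproducibility

The test suite and acceptance script use 2000 genes for the 20-seed
hourglass-recovery and ordering-consistency loops, 5000 genes for the
running-median, correlation-recovery and planted-enrichment checks, and
10,000 permutations for the Steel–Dwass reference — sizes at which the
Monte-Carlo error of each criterion is small relative to its tolerance.
Every generator draws from an explicit seed; identical configuration
and seed give bit-identical output, and stage-specific sub-streams keep
the per-gene truth shared across stages.

## Known limitations

* The technical filter's realized level exceeds its nominal
  $\alpha$ (see above); results downstream of the filter inherit this.
* The two phylotypic stages are simulated with identical noise, so
  their mutual order under any stability metric is an exchangeable coin
  flip; consistency checks between $V$ and $1-\rho$ are therefore
  formulated over stage pairs with distinct injected noise.
* The asymptotic Steel–Dwass p-values carry a residual ~0.01 mean
  approximation error at 10 observations per group; use
  `method = "permutation"` when exact family-wise control at small
  samples matters.
* Interspecies comparisons assume replicate-averaged profiles at each
  species' phylotypic stage and inherit whatever bias the upstream
  ortholog hit tables carry.
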