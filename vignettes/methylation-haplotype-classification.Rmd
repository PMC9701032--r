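---
title: "Methylation haplotype markers for plasma ctDNA classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation haplotype markers for plasma ctDNA classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplomark)
```

## The problem

Circulating tumour DNA (ctDNA) carries the methylation signature of its
tissue of origin, but in early-stage cancer it is heavily diluted in the
total cell-free DNA of plasma. Methylation haplotype blocks (MHBs) —
short genomic regions whose CpG sites are tightly co-methylated on single
DNA molecules — let a classifier exploit *read-level* co-methylation
rather than per-CpG averages, which substantially improves the
signal-to-noise ratio for detecting trace tumour-derived molecules.
`haplomark` implements the full analytical chain for this setting:
read-level haplotype measurements over MHBs, multi-stage marker
discovery, an incremental-feature-selection SVM classifier, optional
integration of the serum marker CA19-9, and the matching evaluation
statistics. Because no patient-level data ship with the package, a
synthetic cohort generator reproduces the statistical structure the
pipeline assumes, so every stage can be exercised and benchmarked end to
end.

## Block-level measurements

For a region with $M$ CpGs, each sequencing read contributes an ordered
pattern over $\{0, 1\}$ (unmethylated/methylated) covering a contiguous
run of the region's CpGs. Seven measurements summarise the pooled reads
of one sample:

* **AMF** — average methylation fraction,
  $\sum_i N_{C,i} / \sum_i (N_{C,i} + N_{T,i})$, pooling every CpG
  observation.
* **MHL** — methylation haplotype load,
  $\sum_{i=1}^{l} w_i P(\mathrm{MH}_i) / \sum_{i=1}^{l} w_i$ with
  $w_i = i$, where $P(\mathrm{MH}_i)$ is the fraction of fully
  methylated length-$i$ substrings among all length-$i$ substrings of
  all reads (weighted by read count). **MHL3** uses $w_i = i^3$,
  up-weighting long co-methylated stretches.
* **UMHL / UMHL3** — the same loads computed for fully *unmethylated*
  substrings, capturing co-unmethylation, which roughly doubles the pool
  of usable markers.
* **MHFm / MHFu** — the fraction of full-span reads that are entirely
  methylated / entirely unmethylated.

Two conventions required a decision because ragged read coverage leaves
them open. First, substring denominators pool across reads: a length
$i$ with no spanning substring is dropped from both sums of the load
quotient, which keeps MHL defined under partial coverage and reduces to
the textbook definition when all reads are full-span. Second, MHFm/MHFu
are computed over full-span reads only (the fraction refers to the
haplotype over the whole region); an any-span variant is available via
`full_span_only = FALSE`. A computable zero is always a value; only the
depth rule and empty denominators produce missingness. With a single
CpG, MHL and MHL3 collapse to AMF, and flipping every read bit swaps
(AMF, MHL, MHL3, MHFm) with (1−AMF, UMHL, UMHL3, MHFu) exactly — both
facts are property-tested against a brute-force substring enumeration
oracle.

```{r metrics-example}
haps <- tibble::tibble(first_idx = 1L, pattern = c("11", "10"),
                       count = c(2L, 1L))
region_metrics(haps, region = 2L)
```

## Discovery filters and contrasts

The discovery phase mirrors a tiered case–control design. Regions with
sequencing depth below 10 in a sample are missing in that sample; regions
missing in more than 10% of samples, or with cross-sample variance below
0.02 on the chosen measurement, are removed (`filter_mhbs()`; both
boundaries are strict and tested). Differential regions come from
two-sided Wilcoxon rank-sum tests with Benjamini–Hochberg correction at
FDR 0.05 (`differential_mhbs()`). The Wilcoxon statistic is computed
in-package (exact `pwilcox` null for small untied groups, normal
approximation with tie correction otherwise) because the discovery loop
runs it hundreds of thousands of times inside the resampled selection;
`stats::wilcox.test` serves as the independent oracle in the test suite.

Plasma-versus-plasma contrasts use a balanced resampling scheme
(`p2p_selection()`): 500 iterations each draw 20 cases and 20 controls,
split them 15+15 discovery / 5+5 validation, select differential regions
in the discovery split, train a 500-tree random forest on them and keep
the iteration's regions only when the validation AUC reaches 0.75;
regions tallied in more than 300 iterations are selected ("more than"
read strictly, configurable). Promoter-proximity marker sets come from
strand-aware TSS windows (−1500 to +1000 bp), and `assemble_panel()`
combines the contrasts as
(T2T ∩ T2P) ∪ (T2T ∩ literature) ∪ P2P.

## Classifier construction

For each candidate marker the most discriminative of the seven
measurements is chosen by single-covariate logistic regression — the
smallest two-sided Wald p-value wins, ties broken by the fixed metric
order, perfect separation handled by an in-package Firth-penalised refit
and flagged (`select_measurement()`). A 10-window chi-square screen
(`chi_square_window_select()`) is available as the alternative
measurement selector; the logistic route is the default because it
yields the p-value ranking the incremental selection consumes.

Preprocessing is learned on training data only: missing values are
imputed from the 5 nearest training neighbours (Euclidean distance over
mutually observed, scaled markers; ties broken by sample order), then
each marker is scaled by its training median and 25–75% IQR. Markers
with zero training IQR are dropped with a warning.

Marker count is set by incremental forward selection
(`incremental_select()`): markers enter in ascending p-value order; a
candidate joins the set when the mean 10-fold cross-validated SVM AUC of
the enlarged set does not fall below the current set's (ties accept —
the generous reading; the full trace is returned so alternates can be
audited). The fold assignment is stratified and fixed by one seed for
the whole pass. The final linear SVM (`C = 1`, a deliberately
low-variance choice for the small-n/moderate-p regime; RBF available)
is refit on all training samples; its signed margin is squashed through
a logistic link fitted on the training margins so scores live in
$[0, 1]$, and the decision cutoff is set on the training ROC by
Youden's J (a fixed-specificity mode, default 89%, is available for
sensitivity comparisons). `combine_ca199()` integrates the serum marker
CA19-9 by logistic regression on the classifier score and
$\log_{10}(\text{CA19-9} + 1)$ — the transform tames the heavy right
skew of U/ml values; constant covariates drop out so the combined model
degrades gracefully to the informative parent.

## Evaluation statistics

`roc_auc()` uses the Mann–Whitney identity with half-credit for ties.
Sensitivity and specificity intervals are exact Clopper–Pearson beta
quantiles. AUC intervals are class-stratified bootstrap percentiles
(1000 replicates by default), whose replicate variance also feeds the
variance-ratio comparison
$T = (\mathrm{AUC}_a - \mathrm{AUC}_b)^2 / (s_a^2 + s_b^2) \sim \chi^2_1$
(`auc_compare_T()`). A DeLong placement-value test (`delong_test()`,
cross-checked against `pROC::roc.test`), an exact binomial McNemar test
for paired sensitivities, and an upper-tail hypergeometric enrichment
test complete the set. The T statistic ignores the covariance of the two
correlated AUCs, so it is conservative when the compared scores share
signal; the calibration suite therefore simulates its null with weakly
correlated score pairs, where the uniformity of the p-value is
verifiable (Kolmogorov–Smirnov distance below 0.1 over 500 simulations).

## What the synthetic cohort emulates

`cohort_design()` fixes the study conditions; `simulate_cohort()` draws
from them:

* **Background methylation** — each region sits at a low (0.15) or high
  (0.85) mode; a sample's latent level is
  $\theta \sim \mathrm{Beta}(\mu\kappa, (1-\mu)\kappa)$ with
  concentration $\kappa = 4$. $\kappa$ is the one generator parameter
  calibrated to the pipeline's own filter constants: the discovery phase
  removes regions with cross-sample variance below 0.02, and the
  between-sample variance of the latent level is
  $\mu(1-\mu)/(\kappa+1) \approx 0.026$ at the 0.15 mode, so background
  regions clear the filter the way markers on a real panel do. Larger
  $\kappa$ would silently empty the discovery stage.
* **Tumour signal** — at 20 designated true-marker regions (of 200), a
  case's reads are replaced with probability $f = 0.2$ (the tumour
  fraction) by reads at the shifted level $\mu \pm \Delta$,
  $\Delta = 0.4$, directed away from the background mode and clipped to
  $[0.02, 0.98]$. Applying the shift at read level mirrors ctDNA
  dilution — bulk AMF shifts by $f\Delta = 0.08$ in expectation (checked
  to ±0.02), while haplotype-level metrics see a distinct subpopulation
  of reads.
* **Reads** — per-region counts are negative binomial (mean 50,
  dispersion 5); a read spans the full CpG ladder with probability 0.7,
  otherwise a random contiguous sub-window; within a read all CpGs share
  one Bernoulli draw with probability $\rho = 0.7$ (co-methylation),
  else CpGs are independent. Regions drop out entirely at rate 0.02.
* **CA19-9** — lognormal by group (healthy median 4 U/ml, case median
  400 U/ml), with 10% of cases redrawn truncated below the 37 U/ml
  positivity threshold to emulate Lewis-negative individuals.
* **Cohorts** — train 60 cases / 60 controls plus a held-out 30/30
  split; stages assigned to cases at realistic frequencies.

The generator reproduces the *statistical* structure the method exploits
— read-level mixtures, co-methylation, coverage noise, missingness — but
not genomic sequence context, bisulfite conversion errors, batch
effects, or the between-patient heterogeneity of real tumour fractions.
A green benchmark therefore demonstrates that the pipeline recovers
planted signal of the stated size under its own model assumptions, not
that a particular clinical accuracy would be attained on patients.

## Benchmarks and numerical choices

The test suite runs the full pipeline at the default design for five
seeds and requires held-out AUC ≥ 0.85 with planted-marker precision
≥ 0.7 in at least four; on a null design ($f = 0$) the held-out AUC must
stay within $[0.35, 0.65]$ for all five seeds — the incremental
selection must not leak training signal into held-out performance — and
resampled selection on permuted labels must select nothing. Problem
sizes (200 regions, 90+90 samples per run, 500 resampling iterations,
200–500 bootstrap replicates inside the benchmark loops) were chosen so
the whole suite completes comfortably on a single CPU while keeping
every Monte-Carlo margin well away from its threshold.

Other numerical conventions: quartiles by linear interpolation (R type
7); chi-square windows `[0, 0.1), ..., [0.9, 1]` with the last window
closed; degrees of freedom equal to non-empty windows minus one and
`p = 1` below two non-empty windows; LD $r^2$ from the 2×2 joint
methylation counts of co-covering reads, with a monomorphic-but-
concordant pair treated as linked and a pair with no co-coverage as a
block boundary; all derived seeds are produced by a deterministic mix of
the master seed and a stage tag, so every stage is reproducible in
isolation and the whole run is byte-identical under a fixed
configuration.

## Limitations

The MHB partitioner is a faithful-convention implementation (adjacent
pair $r^2 \ge 0.5$, at least 3 CpGs) rather than a reproduction of any
specific published segmentation, whose exact windowing rules are not
restated here. Which measurement the discovery-phase tests use is
configurable (AMF by default) because tissue contrasts and plasma
contrasts plausibly favour different metrics; measurement selection
proper happens only in the classifier stage. Cohort-dependent headline
accuracies from any particular patient study are not reproducible from
this package — the benchmarks quantify behaviour under the synthetic
design only.
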