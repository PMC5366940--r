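---
title: "Sex classification from whole-genome bisulfite methylomes: models and methods"
author: "methylsex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex classification from whole-genome bisulfite methylomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylsex)
```

## Scope

`methylsex` implements an analysis of sex-specific DNA methylation in a
dioecious tree cohort assayed by whole-genome bisulfite sequencing (WGBS):

1. per-cytosine differential methylation (DM) testing between females and
   males, with Benjamini–Hochberg correction and an effect-size threshold;
2. gene-feature methylation profiles (promoter, exons, introns) around a
   candidate sex-determining-region (SDR) gene, and a DM-based ranking of an
   SDR gene panel;
3. genome-wide sex classification from 500 bp tile methylation via
   penalized logistic regression (PLR) with supervised feature clustering,
   evaluated by repeated K-fold cross-validation with feature-recurrence
   mapping.

Because no public WGBS cohort accompanies this analysis, the package ships a
beta-binomial methylome simulator whose defaults emulate the study design the
analysis assumes: ~40 xylem samples from 20 genotypes of two sexes, clonally
replicated in two common gardens, with one planted sex-linked differentially
methylated gene on the SDR chromosome.

## Data model and conventions

A cytosine call is (chromosome, position, strand, context, #Cs, #Ts), where
#Cs and #Ts are methylated and unmethylated read counts. The methylation
ratio is #Cs/(#Cs + #Ts); at zero coverage it is *undefined* (`NA`), never 0,
so that averages of ratios are not biased downward by uncovered sites.

Internally all coordinates are 0-based half-open; the two supported Bismark
file dialects (6-column coverage, 7-column cytosine/CX report) are 1-based
and converted only at the I/O boundary. CG, CHG and CHH contexts are
processed separately throughout, because plant methyltransferase pathways
differ by context. CpG calls are kept per strand by default; an optional
symmetric-dyad merge (`merge_cpg_dyads()`) is provided but off, since it is
an analysis decision rather than a property of the data.

The standard pre-filter retains cytosines with coverage strictly greater
than 10x (`filter_coverage()`, configurable).

## Differential methylation test

At each site covered in at least two samples of each sex, the test is a
logistic regression of methylation proportion on group membership with
per-sample binomial totals, assessed by the likelihood ratio against
chi-square with 1 df. With group membership as the only covariate the
per-group MLE is the pooled proportion, so the LRT statistic reduces to the
G-statistic of the pooled 2x2 (methylated/unmethylated by sex) table; the
implementation computes this closed form, vectorised over sites, and the
test suite verifies equality with a per-sample binomial `glm()` deviance
difference. The reported effect is the pooled male minus female ratio in
percentage points.

q-values are Benjamini–Hochberg. A site is called a DMC when q < 0.001 and
|difference| >= 25 points (the conventional preset; a 20-point preset is
also shipped, see `dm_preset()`). No overdispersion correction is applied in
the test itself — consequently its calibration is checked on binomial nulls,
and the beta-binomial simulator makes the power checks conservative. DM
testing pools the two gardens; a stratified analysis is possible by running
per-site tests on site subsets.

`rank_sdr_genes()` orders candidate genes by the number of significant DMCs
overlapping the gene (promoter plus transcribed span), breaking ties by the
largest absolute significant difference and then gene id, mirroring the
single-gene scan of an SDR panel.

## Tile features

`tile_genome()` cuts each chromosome into consecutive 500 bp windows
(terminal windows truncated). A tile's value in a sample is the
coverage-weighted fraction sum(#Cs)/sum(#Cs+#Ts) over its covered sites; a
tile with no covered site is missing, not 0. "Detected" means at least one
covered cytosine after the coverage filter (`min_sites` raises this bar).

Feature filtering applies, in order: (1) detection in at least 80% of
samples; (2) across-sample inter-quartile range strictly greater than the
median IQR of the detection-passing tiles. The order matters: the median IQR
is computed only over detection-passing features. Residual missing entries
are imputed by the feature median — robust, and guaranteed to stay inside
[0, 1]; the pre-imputation mask is kept for audit.

## The classifier

The classifier is a penalized logistic regression with supervised feature
clustering in the pelora family: it greedily builds *meta-features* —
clusters of features whose oriented average is one predictor — under the
criterion

$$\mathrm{crit}(\beta) \;=\; -\ell(\beta) \;+\; \lambda \sum_{k \ge 1} \beta_k^2,$$

the l2-penalized negative log-likelihood of the logistic model (intercept
unpenalized). Features are standardized with training means and SDs; a
cluster's centroid is the arithmetic mean of its members, each taken with an
orientation sign. Orientation is searched explicitly (+x and -x), because a
region may be hyper- or hypo-methylated in either sex.

Cluster growth is forward selection with recurrent pruning: at each step
every candidate (feature, orientation) is evaluated by refitting the full
model with the enlarged centroid, the single best is accepted only if it
*strictly* lowers the criterion (tolerance 1e-12, which also prevents
add/prune cycling); after each accepted addition, members whose removal
strictly lowers the criterion are pruned. Ties are broken toward the lowest
feature index with positive orientation. Clusters are built sequentially up
to `n_clusters` (default q = 10), earlier centroids remaining in the model
as fixed covariates with freely refitted coefficients; fitting stops early
when a new cluster cannot improve the criterion. A feature may serve in
several clusters; within a cluster members are unique. Greedy search with
pruning is a local search: it is not guaranteed to attain the best
enumerable cluster, and the test suite checks it against an independent
brute-force implementation of the same search rule, plus exhaustive
enumeration where the enumeration optimum is greedy-reachable.

Numerical choices: the inner solver is Newton/IRLS on the penalized
criterion with backtracking line search, converged when the gradient
max-norm falls below 1e-8 (cap 100 iterations); weights are floored at
1e-10; perfect separation stays finite because of the ridge term. The
solver and the batch candidate evaluation are implemented in compiled code
(RcppArmadillo). When the number of candidate columns exceeds `2 * screen`
(default `screen = 25`), candidates are first ranked by a score-test
approximation of the criterion decrease at the current fit — the exact
Newton decrement for the swapped centroid column — and only the top
`screen` are refitted exactly. With few features (all oracle comparisons)
the search is fully exact; `screen = Inf` disables screening.

Defaults follow the conventional configuration of this analysis:
lambda = 1/32, q = 10 clusters, K = 5 folds, R = 50 repetitions. We read
"q" as the number of clusters (predictors); with ~60 selected features and
~6 features per predictor this is the only consistent reading. Pruning runs
after every accepted addition; a sparser cadence would also fit the
published description but is strictly weaker.

Prediction standardizes new samples with the *training* parameters, forms
the stored centroids, and thresholds the logistic probability at 0.5.
`project_centroids()` returns each sample's coordinates on predictors 1 and
2 — the 2-D discrimination plot; `plot()` draws it.

## Cross-validation and recurrence

`make_folds()` builds K sex-stratified folds, R times, each repetition
reshuffled with a seed derived deterministically from (seed, r). The default
split strategy keeps all clonal replicates of a genotype in one fold —
clones are near-replicates, so splitting them across the train/validation
boundary would leak; a fully-random strategy is available for comparison.
The held-out test set is likewise split by genotype (70% of genotypes per
sex for training).

`run_cv()` records, per fit, the selected clusters and held-out errors, and
reports the misclassification rate both as the mean of per-fold rates and
pooled over all CV predictions (the two differ when folds are unequal).
`recurrence()` counts how often each feature was selected across the K x R
fits — once per fit even if it joins several clusters — and bins the
frequency: F4 > 80%, F3 in (20%, 80%], F2 in (10%, 20%], F1 <= 10%.

`chromosome_summary()` reports, per chromosome, the mean (SD) number of
selected features per fit (total and unique) and the *relative cluster
prevalence*: the chromosome's share of all selections across fits divided by
its share of the input features. This operationalises "prevalence relative
to minimal expectance" as enrichment over uniform selection: a value of 1 is
chance; values far above 1 mark chromosomes with concentrated predictive
signal. Under uniform random selection the statistic is ~1 for every
chromosome (verified by simulation in the test suite).

## The simulator

`build_genome()` creates a karyotype (default 19 chromosomes of 60 kb at 25
cytosine sites/kb — a deliberately desk-scale genome), places a 13-gene
panel on the SDR chromosome, and flags the middle gene as the SDR gene with
six exons so that introns 1, 4 and 5 exist. `simulate_cohort()` draws, per
site and sample, coverage from a negative binomial (mean 30, size 10 — so
the >10x filter removes a realistic minority of sites) and methylated counts
beta-binomially (dispersion rho = 0.05) around the applicable level, adjusted
on the logit scale by a genotype random intercept (SD 0.3) and a fixed site
shift (0.1). The default planted pattern:

* background 0.15 everywhere, both sexes;
* SDR promoter: female 0.30 / male 0.80; SDR intron 1: 0.20 / 0.70
  (strongly male-biased, the planted differential signal);
* SDR intron 4: 0.90 both sexes; SDR intron 5: 0.02 both sexes
  (methylation that is strong, respectively absent, in *both* sexes — DM
  controls);
* five weakly sex-biased 500 bp regions (0.15 / 0.30) on non-SDR
  chromosomes, emulating scattered weak genome-wide sex signals.

Several of these choices — the noise model and dispersion, the coverage
law, the variance components, the promoter window (2 kb upstream of the
TSS), and the reduced genome scale — are the package's own; none of them is
derivable from the study description, and all are exposed as arguments. The
problem sizes used by the test suite and the acceptance script (28,500
sites, 40 samples, ~1,100 retained CG tiles, K = 5 x R = 50 = 250 CV fits)
were chosen so a full run completes in minutes on one CPU.

What the simulator does *not* emulate: read-level data (no FASTQ, no
alignment or bisulfite-conversion error), linkage between neighbouring
sites (sites are conditionally independent given the region effect),
context-specific background levels, and genome-scale feature counts.
Passing tests therefore demonstrate correctness of the statistical
machinery on data with the assumed structure, not performance on real WGBS
cohorts.

## Known limitations

* The DM test ignores overdispersion and covariates (garden, genotype); on
  strongly overdispersed real data its p-values are anti-conservative.
* Greedy cluster search is a heuristic; only its agreement with the search
  rule, not global optimality, can be guaranteed.
* Permutation null controls at this cohort scale are noisy: with ~14
  training genotypes, a random genotype-level relabelling can agree with
  the true sexes in over two-thirds of genotypes and then retains genuine
  sex-linked signal (cross-validated error visibly below 0.5), and for a
  fixed relabelling the best spurious tile can be re-selected stably across
  folds. Distribution-level statements (error centred on 0.5 across many
  permutations) are reliable; per-permutation bounds are not, and only
  become so as the number of genotypes grows.
* With a dominant planted signal the greedy clusters are often singletons;
  cluster sizes comparable to real data (~6 features) arise only when many
  correlated weak features carry the signal.
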