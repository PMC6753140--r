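---
title: "Methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical procedures implemented in `methloss`,
the defaults they ship with, and the design decisions taken where more than
one reasonable convention exists. It states no empirical result beyond what
the package's own tests and `scripts/acceptance.R` compute.

## The scientific setting

Successive tumour cell divisions leave two opposing marks. Replication errors
raise the mutation burden, which generates neoantigens and tends to favour
response to checkpoint blockade. At the same time the methylation-maintenance
machinery falls behind in late-replicating chromatin, producing long-range
methylation loss organized into partially methylated domains (PMDs), with
focal CpG-island (CGI) promoter hypermethylation inside them. Because many
immunomodulatory genes lie in short PMDs near highly methylated domain (HMD)
boundaries, globally demethylated tumours tend to repress them and evade
immune attack despite a high mutation load. The package quantifies each link
in that chain.

## Global methylation score

Young LINE-1 elements (L1HS, L1PA lineage) are dispersed genome-wide and
heavily methylated in normal tissue, so the mean beta value over array probes
that genuinely interrogate them is a compact global methylation estimate.

`select_l1_probes()` retains a probe when its `repeat_family` matches
`^L1HS$|^L1PA` **and** `mapped_len >= 45` bp **and**
`mapped_len / probe_len >= 0.90`. Both numeric thresholds are applied as a
conjunction: that is the conservative reading of a filter quoted with both an
absolute and a relative cutoff, and the two rules differ whenever probes are
longer than 50 bp. `global_methylation()` then averages non-missing betas per
sample; missing cells are dropped, never imputed, and a sample with no
non-missing selected probe is a named error rather than an `NaN`.

The sequencing-level variant (`wgbs_global_methylation()`) keeps repeat
elements with at least 3 CpGs covered at ≥ 10 reads and scores a sample as
the **unweighted mean of element means** — not a CpG-weighted mean — so that
deeply covered elements do not dominate.

## Focal CGI hypermethylation in short PMDs

`count_hyper_cgi()` estimates, per sample, how many promoter CGI probes in
short PMDs are hypermethylated relative to that sample's own baseline. The
baseline is the mean and standard deviation of CGI-probe betas inside merged
HMDs (sample SD, n−1 denominator). The count uses a one-sided, strict rule:
`beta > mean + 2 SD`. Ties exactly at the cutoff do not count. By default the
baseline uses *all* CGI probes in HMDs; `baseline = "promoter"` restricts it
to promoter-flagged probes for users who prefer a like-for-like baseline —
the choice is exposed because either reading is defensible.

## Domain merging and PMD subclasses

Domain annotations arrive as fixed 100-kb units. `merge_domains()` merges
maximal runs of adjacent units of the same type (adjacent means the end of
one unit equals the start of the next) and keeps merged domains strictly
longer than 300 kb; a 300-kb run is dropped. Feature values
(`meth_variability`, `rep_timing`) of a merged domain are the means of its
units. The operation is idempotent and logs the dropped length in an
attribute.

`cluster_pmds()` standardizes the two features, runs agglomerative
clustering with Ward linkage (`ward.D2`) on Euclidean distance and cuts at
`k = 3` — the number of subclasses that the variability/timing plane supports
— then labels the cluster with the smallest **median** genomic length as the
"short PMD" subclass. Inputs are sorted by (chrom, start) before linkage so
labels are reproducible; `stats::hclust` breaks ties by merge order.

## Proximity of gene sets to HMD boundaries

`proximity_test()` asks whether a gene set inside PMDs hugs HMD boundaries.
The distance of a gene is the edge-to-edge gap in bp between the gene body
and the nearest HMD (0 when touching or overlapping) — edges rather than
midpoints, because the hypothesis concerns the boundary itself. The observed
statistic is the mean over the set; the null redraws sets of the same size
uniformly **without replacement** from the PMD gene universe. The empirical
P is one-sided ("closer than expected") with add-one smoothing,
`(1 + #[null ≤ obs]) / (1 + n_perm)`, so it is never exactly zero. Distances
are measured to the *original* (unmerged) HMD annotation by default; pass
merged HMDs explicitly to use the filtered set — the merged table drops short
HMDs, which would silently lengthen distances.

## Aneuploidy

A copy-number segment contributes when `|log2 ratio| >= 0.2` (inclusive by
default; `inclusive = FALSE` for a strict comparison) and it is large:
intersecting at least 10% of a chromosome arm or spanning at least 5% of the
chromosome. The score is Σ |log2| × length over qualifying segments, divided
by the total autosome length. The normalization is a package choice — it
makes the score independent of genome size — and affects only the scale:
every downstream use is rank- or threshold-based. Sex chromosomes are
excluded by default, consistent with their exclusion from the gene-level
analyses.

## Replication timing

Tracks are 5-kb-binned wavelet-smoothed signal per cell line, higher =
earlier replication. `normalize_tracks()` removes windows missing in any
line, z-scales each line, and quantile-normalizes lines against the mean of
the sorted distributions (`limma::normalizeQuantiles`). `window_ttest()` is
the equal-variance two-sample Student's t (not Welch: the groups are small
and the equal-variance form is the documented convention here), computed as
cancer minus normal so that **negative t = later in cancer**. Windows with
zero variance in both groups return t = 0, P = 1, flagged `degenerate`.

`gene_level_timing()` assigns windows to genes by any overlap of the gene
body (a `"majority"` rule is available; any-overlap is the default because a
gene "spans" every window it touches). Single-window genes inherit the
window statistics; multi-window genes get the mean t and Fisher's combined
P (X² = −2 Σ log pᵢ, df = 2k, upper tail; zeros floored at the smallest
positive double so the statistic stays finite). Bonferroni correction runs
over genes with at least one window — untested genes cannot generate
discoveries and should not dilute the correction.

## Per-gene association models

`fit_gene_models()` fits, per gene, ordinary least squares of expression on
global methylation, mutation burden, aneuploidy, purity, age and (optionally)
tumour stage. Stage enters as a single ordinal covariate (I–IV → 1–4),
matching the single-coefficient formulation. Mutation burden enters as
`log10(1 + burden)` by default (`log_burden = FALSE` for raw counts): counts
span orders of magnitude and the log stabilizes leverage. The per-term "z
score" is coefficient/SE — t-distributed under Gaussian errors, and the
two-sided P uses the t reference with n − p df. BH q values are computed per
predictor across genes. A rank-deficient design is an error naming the
offending predictor rather than a silent drop.

### Direction convention for enrichment

The pipeline's headline gene ranking is **association with methylation
loss**: the negated z score of the methylation-level coefficient (identical
to entering demethylation = −methylation as the predictor). On this ranking a
gene set repressed in demethylated samples shows a *negative* enrichment
score, which matches the biological statement being tested ("immune genes are
repressed under methylation loss"). `demethylation_ranking()` implements the
convention in one place.

## Enrichment statistics

`preranked_enrichment()` is a weighted Kolmogorov–Smirnov running sum: genes
sorted by decreasing score; set genes increment by |score| (normalized over
the set; weight exponent 1), others decrement by 1/(N−m); the ES is the
signed extremum of the walk (the walk itself ends near zero; a set equal to
the whole universe degenerates to the hit ECDF). Significance uses
gene-label permutation — only a ranking is available, so sample permutation
is not an option — with `NES = ES / mean(|null ES| of matching sign)` and the
standard two-tail FDR ratio of pooled null NES to observed NES. Defaults
mirror the analysis constants: minimum set size 10, enrichment FDR threshold
0.25, regression FDR 0.05.

`ssgsea_score()` is the single-sample variant: the sum over the ranked list
of the difference between the weighted ECDF of set genes (weights =
rank^α, α = 0.25 — the conventional exponent; the source analyses do not
state one) and the ECDF of non-set genes. It is rank-based, hence invariant
to monotone transforms of the expression vector.

`partial_spearman()` uses the first-order formula on rank-transformed data
with a t approximation at n − 3 df. When the conditioning variable is
collinear with an argument the coefficient is defined as 0 (nothing left to
correlate) instead of NaN.

## Survival and response

`stratify()` implements the median rule (ties at the median go to the low
group — a documented, configurable choice; the source convention is
unstated) and the 30/70 percentile rule with the middle excluded.
`km_logrank()` wraps the product-limit estimator and the two-group log-rank
test, and reports a convenience hazard ratio of low vs high from a Cox fit
on the group indicator. `cox_fit()` uses the Efron tie correction — the
default of the statistical environment this analysis style comes from — and
flags monotone likelihood via diverging standardized coefficients.
`response_logistic()` models durable clinical benefit: CR/PR, or SD lasting
more than 6 months (`months_to_days()` uses 30.44 days/month), versus
PD or short SD. Follow-up is kept in days.

## The synthetic cohort generator

`simulate_cohort()` exists so that every stage has a planted truth. One
latent factor d ~ Uniform(0, 1) per sample drives, with fixed signs:

| layer | coupling | default |
|---|---|---|
| open-sea LINE-1 beta | mean = 0.75 − 0.25·d + N(0, 0.04), clamped to [0.001, 0.999] | `demethylation_effect = 0.25` |
| short-PMD promoter CGI | hypermethylated (beta ≈ 0.55 vs 0.08) with probability 0.35·d | `hyperme_gain_rate = 0.35` |
| mutation burden | Poisson, log-mean log 30 + 1.5·d | `mutation_link = 1.5` |
| arm-scale CNA events | per-arm probability plogis(−2 + 2.5·d) | `cna_link = 2.5` |
| immune gene expression | mean shift −2·d (SD 0.5) | fixed |
| hazard | low-methylation half of the cohort × 2 | `planted_hr = 2` |

The low/high groups are defined by the median of the *realized* global
score, so the planted hazard ratio refers to exactly the contrast the
survival stage estimates. Survival times are exponential with administrative
censoring at 350 days, chosen to censor roughly 30% of subjects at the
default hazard (1/400 per day). The genome is three autosomes (60/50/40 Mb)
tiled with alternating HMD and PMD blocks of 100-kb units; short/mid/long
PMD blocks carry well-separated (variability, timing) signatures so the
subclassing stage has a recoverable truth, and immune genes are placed
20–120 kb from a short-PMD edge while other PMD genes sit in mid/long-PMD
interiors. Replication tracks are a shared smooth profile plus line noise
(SD 0.3), with a planted −1.5 shift over immune genes in the cancer lines
and 2% missing values to exercise the exclusion rule.

Effect sizes are free parameters of the generator, documented here, not
claims about biology; they were chosen once to give each stage a clearly
detectable but noisy signal at the default cohort size (n = 120) and are not
tuned per test. What the generator does **not** emulate: probe chemistry and
normalization artefacts, batch effects, purity-driven signal mixing,
covariance between mutation burden and focal CNAs beyond the shared latent
factor, non-exponential hazards, and informative censoring. Passing tests
therefore demonstrate correctness of the statistical machinery under a clean
generative model, not robustness to the failure modes of real cohorts.

## Numerical choices and degenerate inputs

- Beta values are validated into [0, 1]; simulated betas are clamped to
  [0.001, 0.999] after noise so the range invariant holds.
- Fisher combination floors P at the smallest positive double before logs.
- Empirical permutation P values use add-one smoothing (never exactly 0).
- Quantile normalization of a constant track leaves it centred at 0 rather
  than NaN.
- `cluster_pmds()` with a constant feature sets its standardized column to 0.
- All RNG-consuming operations take an explicit seed; `simulate_cohort()`
  seeds once and is bit-reproducible.

## Problem sizes used in the tests

The test suite checks parameter recovery on 100 simulated cohorts of n = 400
(coverage of the planted log hazard ratio within ±3 SE), regression type-I
error on 1,000 null genes at n = 200, permutation-test calibration with 200
replicates at 2,000 permutations (a scaled-down permutation count that keeps
the suite fast while leaving the add-one smoothing negligible), and exact
oracle equivalence for the Fisher combination and the enrichment running sum
on small universes. These sizes are the package's own trade-off between
statistical resolution and test runtime.

## Known limitations

- The preranked enrichment is a minimal implementation (weight exponent 1,
  gene-label nulls); it is not a bit-for-bit reimplementation of the desktop
  GSEA tool, whose tie-handling and FDR pooling differ in detail.
- Partial correlations support a single conditioning variable.
- The aneuploidy score consumes pre-segmented copy-number calls; it does not
  segment.
- No competing-risks or interval-censored survival models.
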