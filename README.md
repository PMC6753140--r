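# methloss

Tools for studying how genome-wide DNA methylation loss relates to immune
gene repression and the outcome of checkpoint-blockade immunotherapy.

Tumour cells lose DNA methylation progressively with cell division, mostly in
late-replicating **partially methylated domains (PMDs)**, while CpG-island
(CGI) promoters in the same regions gain methylation. Because many
immunomodulatory genes sit inside short PMDs close to highly methylated
domain (HMD) boundaries, globally demethylated tumours tend to silence them —
so a tumour can carry a high mutation burden (normally a favourable marker
for immunotherapy) and still evade immune attack. `methloss` implements the
quantitative machinery needed to investigate this on methylation-array,
copy-number, expression, replication-timing and clinical data:

- **Global methylation score** — the mean beta value over array probes whose
  sequence maps predominantly (≥ 45 bp and ≥ 90% of the probe) to young
  LINE-1 subfamilies (L1HS/L1PA); an element-level bisulfite-sequencing
  variant (≥ 3 CpGs at ≥ 10× per element) validates it.
- **Domain analysis** — merging of 100-kb PMD/HMD units (retaining runs
  > 300 kb), Ward clustering of PMDs on methylation variability and
  replication timing into subclasses, and the count of promoter CGI probes in
  short PMDs exceeding the sample's HMD baseline by > 2 SD.
- **Replication timing** — per-5-kb-window pooled-variance t statistics
  (cancer vs normal cell lines, after z-scaling and quantile normalization),
  combined per gene by Fisher's method (X² = −2 Σ log pᵢ, df = 2k) with
  Bonferroni control.
- **Boundary proximity** — a permutation null for the mean distance of a gene
  set to the nearest HMD (10,000 random same-size draws from the PMD gene
  universe, add-one-smoothed one-sided P).
- **Aneuploidy** — Σ |log₂ ratio| × length over segments with |log₂| ≥ 0.2
  covering ≥ 10% of an arm or ≥ 5% of a chromosome, normalized by autosome
  length.
- **Association models** — per-gene OLS of expression on global methylation,
  mutation burden, aneuploidy, purity, age and stage
  (y ~ β₁·meth + β₂·burden + β₃·aneuploidy + β₄·purity + β₅·age + β₆·stage),
  with BH FDR per predictor; preranked running-sum enrichment (ES/NES/FDR),
  ssGSEA-style single-sample scores, first-order partial Spearman
  correlations, and Mann–Whitney / paired-t group comparisons.
- **Survival** — median or 30th/70th-percentile stratification,
  Kaplan–Meier + log-rank, multivariable Cox (Efron ties) and logistic models
  of durable clinical benefit (DCB = CR/PR or SD > 6 months).
- **Synthetic cohorts** — `simulate_cohort()` plants a latent per-sample
  demethylation factor that couples every data layer with known signs and a
  known hazard ratio, so the whole pipeline is testable without patient data.

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` for fitted objects, `autoplot()` for the main result types.

## Worked example

```r
library(methloss)

cohort <- simulate_cohort(simulation_config(seed = 1))
run <- run_pipeline(cohort, pipeline_config(seed = 1))

head(run$global_methylation, 3)
#> # A tibble: 3 × 3
#>   sample_id score n_probes_used
#>   <chr>     <dbl>         <int>
#> 1 S0001     0.684           200
#> 2 S0002     0.654           200
#> 3 S0003     0.611           200

run$km
#> Kaplan-Meier / log-rank (n = 120, events = 94)
#>   log-rank chi-square = 5.715, P = 0.0168
#>   HR (low vs high) = 1.65 [1.09, 2.48]

tidy(run$enrichment)
#> # A tibble: 1 × 6
#>   set_id  size     es   nes  p_perm   fdr
#>   <chr>  <int>  <dbl> <dbl>   <dbl> <dbl>
#> 1 immune    60 -0.956 -2.83 0.00104     0

run$proximity
#> Proximity permutation test (60 genes, 10000 permutations)
#>   observed mean distance to nearest HMD: 71714 bp
#>   null mean (median): 335440 bp
#>   one-sided empirical P (closer than expected): 1e-04
```

Reading the output: samples in the low-methylation half of the cohort
progress about 1.65× faster under therapy than the high-methylation half
(the generator planted a hazard ratio of 2 at the population level); the
immune gene set is strongly *negatively* enriched in the ranking of genes by
association with methylation loss (NES −2.83, i.e. repressed in demethylated
samples); and the immune genes sit on average 72 kb from the nearest HMD,
far closer than random PMD genes (null median 335 kb, empirical P = 1e-4).

`autoplot(run$km)`, `autoplot(run$enrichment)`, `autoplot(run$proximity)`
and `autoplot(run$pmd_clusters)` draw the corresponding figures.

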