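Package: methloss
Title: Global DNA Methylation Loss, Immune Gene Repression and Immunotherapy Outcome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for linking genome-wide DNA methylation loss to immune gene
    repression and immunotherapy outcome. Implements LINE-1 probe based global
    methylation scoring (array and bisulfite-sequencing variants), merging and
    subclassification of partially methylated domains (PMDs), counting of
    focally hypermethylated CpG-island promoters in short PMDs, replication
    timing differential analysis on 5-kb windows with Fisher combination at the
    gene level, a permutation null for proximity of gene sets to highly
    methylated domain boundaries, a length-weighted aneuploidy score from copy
    number segments, per-gene multi-predictor regression with preranked and
    single-sample enrichment scoring, and survival stratification (Kaplan-Meier,
    log-rank, Cox, logistic response models). A synthetic cohort generator with
    a planted latent demethylation factor makes every stage testable without
    access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    limma,
    readr,
    rlang,
    S4Vectors,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    fgsea,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
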