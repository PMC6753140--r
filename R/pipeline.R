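#' Pipeline configuration with the analysis defaults
#'
#' Bundles every tunable threshold of the end-to-end analysis, at its default
#' value: LINE-1 probe selection (>= 45 bp and >= 90% of the probe mapped to
#' L1HS/L1PA), merged-domain length filter (> 300 kb), the 2-SD rule for
#' focal CGI hypermethylation, aneuploidy calling (|log2| >= 0.2 on >= 10% of
#' an arm or >= 5% of a chromosome), regression FDR 0.05, enrichment FDR 0.25
#' with minimum set size 10, 30th/70th percentile grouping, and 10,000
#' permutations for the proximity null. Overrides are recorded in the run
#' manifest.
#'
#' @param probe_min_bp,probe_min_frac LINE-1 probe filter.
#' @param pmd_min_length Merged-domain length filter in bp.
#' @param pmd_k Number of PMD subclasses.
#' @param hyper_n_sd SD multiplier for the hypermethylation rule.
#' @param aneuploidy_threshold,arm_frac,chrom_frac Segment qualification rule.
#' @param regression_fdr,enrichment_fdr,min_set_size Association thresholds.
#' @param low_cut,high_cut Percentile cuts for group comparison.
#' @param n_perm_proximity,n_perm_enrichment Permutation counts.
#' @param seed Integer seed for all randomized stages.
#' @return A list of class `methloss_pipeline_config`.
#' @export
pipeline_config <- function(probe_min_bp = 45, probe_min_frac = 0.90,
                            pmd_min_length = 3e5, pmd_k = 3, hyper_n_sd = 2,
                            aneuploidy_threshold = 0.2, arm_frac = 0.10,
                            chrom_frac = 0.05, regression_fdr = 0.05,
                            enrichment_fdr = 0.25, min_set_size = 10,
                            low_cut = 30, high_cut = 70,
                            n_perm_proximity = 10000, n_perm_enrichment = 1000,
                            seed = 1234) {
  structure(
    list(
      probe_min_bp = probe_min_bp, probe_min_frac = probe_min_frac,
      pmd_min_length = pmd_min_length, pmd_k = pmd_k, hyper_n_sd = hyper_n_sd,
      aneuploidy_threshold = aneuploidy_threshold, arm_frac = arm_frac,
      chrom_frac = chrom_frac, regression_fdr = regression_fdr,
      enrichment_fdr = enrichment_fdr, min_set_size = min_set_size,
      low_cut = low_cut, high_cut = high_cut,
      n_perm_proximity = n_perm_proximity,
      n_perm_enrichment = n_perm_enrichment, seed = seed
    ),
    class = "methloss_pipeline_config"
  )
}

#' Run the end-to-end analysis on a cohort bundle
#'
#' Executes the stages in dependency order on a simulated (or equivalently
#' structured) bundle: global methylation scoring, domain merging and PMD
#' subclassification, focal CGI hypermethylation counting, aneuploidy
#' scoring, replication-timing classification (when tracks are present),
#' per-gene regression with enrichment of the immune set on the
#' demethylation-association ranking, the boundary-proximity permutation
#' test, and survival stratification (Kaplan-Meier / log-rank / Cox /
#' logistic; skipped with a note when the clinical table is absent). A run
#' manifest records the seed, thresholds and per-stage status; given the same
#' bundle and seed the result is reproducible.
#'
#' @param bundle A `methloss_cohort` (from [simulate_cohort()] or assembled
#'   from files with the `read_*` helpers).
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, per-stage TSVs are written.
#' @return A list of class `methloss_run` with one element per stage plus
#'   `manifest`.
#' @export
run_pipeline <- function(bundle, config = pipeline_config(), out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage `", name, "` failed: ", conditionMessage(e)))
    })
  }
  res <- list()
  status <- list()

  # 1. global methylation score
  res$global_methylation <- stage("global_methylation", {
    probes <- select_l1_probes(bundle$manifest,
                               min_mapped_bp = config$probe_min_bp,
                               min_mapped_frac = config$probe_min_frac)
    global_methylation(bundle$beta, probes)
  })
  status$global_methylation <- "ok"

  # 2. domain merging + PMD subclasses
  res$merged_domains <- stage("merge_domains",
    merge_domains(bundle$domains, min_length = config$pmd_min_length))
  res$pmd_clusters <- stage("cluster_pmds",
    cluster_pmds(res$merged_domains, k = config$pmd_k))
  status$domains <- "ok"

  short_pmds <- res$pmd_clusters[res$pmd_clusters$is_short,
                                 c("chrom", "start", "end")]
  hmds <- res$merged_domains[res$merged_domains$dtype == "HMD",
                             c("chrom", "start", "end")]

  # 3. focal CGI hypermethylation in short PMDs
  res$hyper_cgi <- stage("hyper_cgi",
    count_hyper_cgi(bundle$beta, bundle$manifest, hmds, short_pmds,
                    n_sd = config$hyper_n_sd))
  status$hyper_cgi <- "ok"

  # 4. aneuploidy
  res$aneuploidy <- stage("aneuploidy", {
    flagged <- call_qualifying_segments(
      bundle$segments, bundle$geometry,
      threshold = config$aneuploidy_threshold,
      arm_frac = config$arm_frac, chrom_frac = config$chrom_frac
    )
    aneuploidy_level(flagged, bundle$geometry)
  })
  status$aneuploidy <- "ok"

  # 5. replication timing (optional)
  if (!is.null(bundle$tracks)) {
    res$gene_timing <- stage("replication_timing", {
      tr <- normalize_tracks(bundle$tracks)
      ws <- window_ttest(tr)
      gene_level_timing(ws, bundle$gene_models)
    })
    status$replication_timing <- "ok"
  } else {
    status$replication_timing <- "skipped: no tracks"
  }

  # 6. per-sample feature table (clinical covariates joined when available)
  res$features <- stage("features", {
    ft <- res$global_methylation |>
      select("sample_id", global_methylation = "score") |>
      left_join(res$aneuploidy[, c("sample_id", "level")], by = "sample_id") |>
      rename(aneuploidy = "level") |>
      mutate(aneuploidy = ifelse(is.na(.data$aneuploidy), 0, .data$aneuploidy)) |>
      left_join(res$hyper_cgi[, c("sample_id", "n_hyper")], by = "sample_id")
    clin_covars <- intersect(c("mutation_burden", "purity", "age", "stage"),
                             names(bundle$clinical %||% tibble()))
    if (length(clin_covars)) {
      ft <- left_join(ft, bundle$clinical[, c("sample_id", clin_covars)],
                      by = "sample_id")
    }
    ft
  })

  # 7. per-gene regression + enrichment of the immune set on the
  #    demethylation-association ranking (needs the clinical covariates)
  needed <- c("mutation_burden", "purity", "age", "stage")
  if (all(needed %in% names(res$features))) {
    res$gene_lm <- stage("gene_regression",
      fit_gene_models(bundle$expression, res$features))
    res$enrichment <- stage("enrichment", {
      preranked_enrichment(
        demethylation_ranking(res$gene_lm),
        sets = list(immune = bundle$gene_sets$immune),
        n_perm = config$n_perm_enrichment,
        min_size = config$min_set_size,
        seed = config$seed
      )
    })
    status$association <- "ok"
  } else {
    status$association <- "skipped: clinical covariates unavailable"
  }

  # 8. proximity of immune genes to HMD boundaries; distances are taken to the
  #    original (unmerged) HMD annotation, not the merged/filtered one
  res$proximity <- stage("proximity", {
    proximity_test(
      genes = intersect(bundle$gene_sets$immune, bundle$gene_sets$pmd_universe),
      universe = bundle$gene_sets$pmd_universe,
      gene_models = bundle$gene_models,
      hmds = bundle$domains[bundle$domains$dtype == "HMD",
                            c("chrom", "start", "end")],
      n_perm = config$n_perm_proximity,
      seed = config$seed
    )
  })
  status$proximity <- "ok"

  # 9. survival stratification
  has_clinical <- !is.null(bundle$clinical) &&
    all(c("pfs_time", "event") %in% names(bundle$clinical))
  if (has_clinical) {
    res$strata <- stage("stratify",
      stratify(res$global_methylation |> select("sample_id", "score")))
    res$km <- stage("km_logrank", km_logrank(bundle$clinical, res$strata))
    res$cox <- stage("cox", {
      covars <- res$features |>
        mutate(log_burden = log10(1 + .data$mutation_burden)) |>
        select("sample_id", "global_methylation", "log_burden")
      cox_fit(bundle$clinical, covars)
    })
    if ("response" %in% names(bundle$clinical)) {
      res$logistic <- stage("logistic", {
        covars <- res$features |>
          mutate(log_burden = log10(1 + .data$mutation_burden)) |>
          select("sample_id", "global_methylation", "log_burden")
        response_logistic(bundle$clinical[, c("sample_id", "response")], covars)
      })
    }
    status$survival <- "ok"
  } else {
    status$survival <- "skipped: no clinical table"
  }

  res$manifest <- list(
    seed = config$seed,
    thresholds = unclass(config),
    stages = status,
    n_samples = ncol(bundle$beta),
    package_version = as.character(utils::packageVersion("methloss")),
    input_hash = rlang::hash(list(bundle$manifest, dim(bundle$beta),
                                  bundle$segments, bundle$clinical)),
    result_hash = NA_character_
  )
  res$manifest$result_hash <- rlang::hash(res[setdiff(names(res), "manifest")])

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(res$global_methylation, file.path(out_dir, "global_methylation.tsv"))
    readr::write_tsv(res$merged_domains, file.path(out_dir, "merged_domains.tsv"))
    readr::write_tsv(as_tibble(res$pmd_clusters), file.path(out_dir, "pmd_clusters.tsv"))
    readr::write_tsv(res$hyper_cgi, file.path(out_dir, "hyper_cgi.tsv"))
    readr::write_tsv(res$aneuploidy, file.path(out_dir, "aneuploidy.tsv"))
    if (!is.null(res$gene_timing)) {
      readr::write_tsv(res$gene_timing, file.path(out_dir, "gene_timing.tsv"))
    }
    readr::write_tsv(as_tibble(res$gene_lm), file.path(out_dir, "gene_regression.tsv"))
    readr::write_tsv(as_tibble(res$enrichment), file.path(out_dir, "enrichment.tsv"))
    if (!is.null(res$km)) {
      readr::write_tsv(tidy(res$km), file.path(out_dir, "km_curves.tsv"))
      readr::write_tsv(glance(res$km), file.path(out_dir, "km_summary.tsv"))
    }
    manifest_json <- res$manifest
    manifest_json$thresholds$seed <- NULL
    writeLines(
      paste0(utils::capture.output(utils::str(manifest_json)), collapse = "\n"),
      file.path(out_dir, "run_manifest.txt")
    )
  }
  structure(res, class = "methloss_run")
}

#' @export
print.methloss_run <- function(x, ...) {
  cat("methloss pipeline run (seed ", x$manifest$seed, ")\n", sep = "")
  for (s in names(x$manifest$stages)) {
    cat("  ", format(s, width = 20), x$manifest$stages[[s]], "\n", sep = "")
  }
  invisible(x)
}
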