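#' Merge consecutive same-type methylation domains and drop short runs
#'
#' Domain annotations come as fixed-size (typically 100-kb) units labelled PMD
#' (partially methylated domain) or HMD (highly methylated domain). Maximal
#' runs of adjacent units of the same type (the end of one unit equals the
#' start of the next, on the same chromosome) are merged into one domain;
#' merged domains not longer than `min_length` bp are discarded. Per-domain
#' methylation variability and replication timing are the means of the
#' constituent units.
#'
#' @param domains Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open, sorted and non-overlapping within a chromosome), `dtype`
#'   (`"PMD"` or `"HMD"`) and optionally `meth_variability`, `rep_timing`.
#' @param min_length Retain merged domains strictly longer than this (default
#'   300 kb).
#'
#' @return A tibble of merged domains with `n_units` and averaged features;
#'   a `dropped_bp` attribute records the total length removed by the filter.
#' @export
merge_domains <- function(domains, min_length = 3e5) {
  check_intervals(domains, "domain table")
  if (!"dtype" %in% names(domains)) abort("domain table needs a `dtype` column")
  if (!all(domains$dtype %in% c("PMD", "HMD"))) abort("dtype must be PMD or HMD")
  domains <- arrange(as_tibble(domains), .data$chrom, .data$start)
  by_chrom <- split(domains, domains$chrom)
  overlap <- any(vapply(by_chrom, function(d) {
    nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)])
  }, logical(1)))
  if (overlap) abort("domain units overlap within a chromosome")

  has_var <- "meth_variability" %in% names(domains)
  has_rt <- "rep_timing" %in% names(domains)

  merged <- lapply(by_chrom, function(d) {
    new_run <- c(TRUE, d$start[-1] != d$end[-nrow(d)] | d$dtype[-1] != d$dtype[-nrow(d)])
    run <- cumsum(new_run)
    out <- tibble(
      chrom = d$chrom[!duplicated(run)],
      start = as.numeric(tapply(d$start, run, min)),
      end = as.numeric(tapply(d$end, run, max)),
      dtype = d$dtype[!duplicated(run)],
      n_units = as.integer(tabulate(run))
    )
    if (has_var) out$meth_variability <- as.numeric(tapply(d$meth_variability, run, mean))
    if (has_rt) out$rep_timing <- as.numeric(tapply(d$rep_timing, run, mean))
    out
  })
  merged <- bind_rows(merged) |> arrange(.data$chrom, .data$start)
  keep <- (merged$end - merged$start) > min_length
  dropped_bp <- sum((merged$end - merged$start)[!keep])
  out <- merged[keep, , drop = FALSE]
  attr(out, "dropped_bp") <- dropped_bp
  out
}

#' Subclassify merged PMDs by hierarchical clustering
#'
#' PMDs separate into subclasses when clustered on their methylation
#' variability and replication timing; the subclass with the smallest median
#' genomic length (the "short PMDs") is the one where immunomodulatory genes
#' concentrate. Features are standardized, domains are clustered with Ward
#' linkage (`ward.D2`) on Euclidean distance and the tree is cut at `k`.
#' Inputs are sorted by (chrom, start) beforehand so labels are deterministic.
#'
#' @param merged Merged domain table from [merge_domains()]; only `dtype ==
#'   "PMD"` rows are used and they must carry `meth_variability` and
#'   `rep_timing`.
#' @param k Number of subclasses (default 3).
#'
#' @return An object of class `methloss_pmd_clusters`: the PMD tibble with a
#'   `cluster` label and `is_short` flag, plus per-cluster summaries in
#'   attributes.
#' @export
cluster_pmds <- function(merged, k = 3) {
  pmds <- merged |>
    filter(.data$dtype == "PMD") |>
    arrange(.data$chrom, .data$start)
  if (!all(c("meth_variability", "rep_timing") %in% names(pmds))) {
    abort("merged PMDs must carry meth_variability and rep_timing")
  }
  if (k < 1) abort("k must be >= 1")
  if (nrow(pmds) < k) abort(paste0("k = ", k, " exceeds the number of PMDs (", nrow(pmds), ")"))
  feats <- scale(as.matrix(pmds[, c("meth_variability", "rep_timing")]))
  feats[is.nan(feats)] <- 0  # constant feature: no contribution
  if (k == 1) {
    cl <- rep(1L, nrow(pmds))
  } else {
    tree <- hclust(dist(feats), method = "ward.D2")
    cl <- as.integer(cutree(tree, k = k))
  }
  pmds$cluster <- cl
  pmds$length <- pmds$end - pmds$start
  med_len <- tapply(pmds$length, pmds$cluster, median)
  short_cluster <- as.integer(names(med_len)[which.min(med_len)])
  pmds$is_short <- pmds$cluster == short_cluster
  structure(
    pmds,
    class = c("methloss_pmd_clusters", class(pmds)),
    k = k,
    short_cluster = short_cluster,
    median_length = med_len
  )
}

#' Permutation test for proximity of a gene set to HMD boundaries
#'
#' Tests whether a gene set lying inside PMDs sits closer to highly methylated
#' domains than random PMD genes do. The distance of a gene is the minimum gap
#' in bp between its gene body and any HMD interval (0 when they touch or
#' overlap); the observed statistic is the mean distance over `genes`. The
#' null draws `length(genes)` ids uniformly without replacement from
#' `universe` and recomputes the mean, `n_perm` times. The empirical P value
#' uses add-one smoothing for the one-sided "closer than expected"
#' alternative: `(1 + #[null <= observed]) / (1 + n_perm)`.
#'
#' @param genes Character vector of gene ids (must be a subset of `universe`).
#' @param universe Character vector: all genes inside PMDs.
#' @param gene_models Data frame with `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param hmds HMD interval table (`chrom`, `start`, `end`).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed for reproducible draws.
#'
#' @return An object of class `methloss_proximity` with the observed mean
#'   distance, the vector of null means, and `p_empirical`.
#' @export
proximity_test <- function(genes, universe, gene_models, hmds,
                           n_perm = 10000, seed = NULL) {
  if (!nrow(hmds)) abort("HMD table is empty")
  genes <- unique(as.character(genes))
  universe <- unique(as.character(universe))
  if (!all(genes %in% universe)) abort("`genes` must be a subset of `universe`")
  if (length(universe) < length(genes)) abort("universe smaller than the test set")
  check_intervals(gene_models, "gene models")
  gm <- gene_models[gene_models$gene_id %in% universe, , drop = FALSE]
  missing_genes <- setdiff(universe, gm$gene_id)
  if (length(missing_genes)) {
    abort(paste0("gene model missing for: ", paste(head(missing_genes, 5), collapse = ", ")))
  }
  gr <- intervals_to_gr(gm)
  hit <- GenomicRanges::distanceToNearest(gr, intervals_to_gr(hmds))
  d <- rep(NA_real_, length(gr))
  d[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance
  if (anyNA(d)) abort("some genes have no HMD on their chromosome; distance undefined")
  names(d) <- gm$gene_id

  observed <- mean(d[genes])
  if (!is.null(seed)) set.seed(seed)
  k <- length(genes)
  nu <- length(universe)
  null_means <- vapply(
    seq_len(n_perm),
    function(i) mean(d[sample.int(nu, k)]),
    numeric(1)
  )
  p <- (1 + sum(null_means <= observed)) / (1 + n_perm)
  structure(
    list(
      observed_mean_distance = observed,
      null_means = null_means,
      p_empirical = p,
      n_perm = n_perm,
      n_genes = k,
      distances = d[genes]
    ),
    class = "methloss_proximity"
  )
}

#' @export
print.methloss_proximity <- function(x, ...) {
  cat("Proximity permutation test (", x$n_genes, " genes, ",
      x$n_perm, " permutations)\n", sep = "")
  cat("  observed mean distance to nearest HMD: ",
      format(round(x$observed_mean_distance)), " bp\n", sep = "")
  cat("  null mean (median): ", format(round(median(x$null_means))), " bp\n", sep = "")
  cat("  one-sided empirical P (closer than expected): ",
      format(x$p_empirical, digits = 3), "\n", sep = "")
  invisible(x)
}
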