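#' Select methylation-array probes that track young LINE-1 elements
#'
#' Global demethylation in tumours is conventionally read off the young LINE-1
#' subfamilies (L1HS and the L1PA lineage), whose CpGs are heavily methylated in
#' normal tissue and lose methylation with successive cell divisions. A probe is
#' retained when most of its sequence genuinely interrogates such an element:
#' at least `min_mapped_bp` of the probe sequence (and at least `min_mapped_frac`
#' of its length) align to an L1HS/L1PA repeat.
#'
#' @param manifest A data frame with one row per probe and columns `probe_id`,
#'   `repeat_family` (`NA` for non-repeat probes), `mapped_len` (bp of the probe
#'   sequence aligned to the repeat) and `probe_len`.
#' @param min_mapped_bp Minimum aligned length in bp (default 45).
#' @param min_mapped_frac Minimum aligned fraction of the probe (default 0.90).
#' @param families Regular expression for qualifying repeat families.
#'
#' @return Character vector of qualifying probe ids.
#' @export
#' @examples
#' man <- tibble::tibble(
#'   probe_id = c("a", "b", "c"),
#'   repeat_family = c("L1HS", "L1PA3", "AluY"),
#'   mapped_len = c(46, 44, 50), probe_len = 50
#' )
#' select_l1_probes(man)
select_l1_probes <- function(manifest, min_mapped_bp = 45, min_mapped_frac = 0.90,
                             families = "^L1HS$|^L1PA") {
  if (!nrow(manifest)) abort("probe manifest is empty")
  need <- c("probe_id", "repeat_family", "mapped_len", "probe_len")
  miss <- setdiff(need, names(manifest))
  if (length(miss)) abort(paste0("manifest missing column(s): ", paste(miss, collapse = ", ")))
  if (any(manifest$mapped_len > manifest$probe_len, na.rm = TRUE)) {
    abort("mapped_len cannot exceed probe_len")
  }
  fam_ok <- !is.na(manifest$repeat_family) & grepl(families, manifest$repeat_family)
  len_ok <- !is.na(manifest$mapped_len) &
    manifest$mapped_len >= min_mapped_bp &
    manifest$mapped_len / manifest$probe_len >= min_mapped_frac
  out <- manifest$probe_id[fam_ok & len_ok]
  if (!length(out)) abort("no qualifying LINE-1 probes in manifest")
  as.character(out)
}

#' Per-sample global methylation score from LINE-1 probes
#'
#' The global methylation level of a sample is the mean beta value over the
#' selected LINE-1 probes; missing betas are dropped per probe-sample cell.
#'
#' @param beta Beta values in \[0, 1\]: a probes x samples matrix with probe ids
#'   as rownames, or a data frame with a `probe_id` column followed by one
#'   column per sample.
#' @param probes Character vector of probe ids (typically from
#'   [select_l1_probes()]); must all be present in `beta`.
#'
#' @return A tibble with columns `sample_id`, `score` and `n_probes_used`.
#' @export
global_methylation <- function(beta, probes) {
  m <- check_beta_range(as_beta_matrix(beta))
  probes <- as.character(probes)
  missing_probes <- setdiff(probes, rownames(m))
  if (length(missing_probes)) {
    abort(paste0("probes absent from beta matrix: ",
                 paste(head(missing_probes, 5), collapse = ", ")))
  }
  sub <- m[probes, , drop = FALSE]
  n_used <- colSums(!is.na(sub))
  if (any(n_used == 0)) {
    abort(paste0("sample(s) with no non-missing beta over selected probes: ",
                 paste(colnames(sub)[n_used == 0], collapse = ", ")))
  }
  tibble(
    sample_id = colnames(sub),
    score = unname(colMeans(sub, na.rm = TRUE)),
    n_probes_used = as.integer(unname(n_used))
  )
}

#' Global methylation score from bisulfite-sequencing repeat elements
#'
#' Element-level variant of the global score used to validate the array-based
#' one: a repeat element is retained when it has at least `min_cpgs` CpG sites
#' each covered by at least `min_coverage` reads; the element's methylation is
#' the mean beta over its qualifying CpGs, and the sample score is the
#' unweighted mean of element means.
#'
#' @param records Long-format data frame with columns `sample_id`,
#'   `element_id`, `coverage` and `beta` (one row per CpG).
#' @param min_cpgs Minimum qualifying CpGs per element (default 3).
#' @param min_coverage Minimum read coverage per CpG (default 10).
#'
#' @return A tibble with `sample_id`, `score`, `n_elements`.
#' @export
wgbs_global_methylation <- function(records, min_cpgs = 3, min_coverage = 10) {
  need <- c("sample_id", "element_id", "coverage", "beta")
  miss <- setdiff(need, names(records))
  if (length(miss)) abort(paste0("records missing column(s): ", paste(miss, collapse = ", ")))
  if (any(records$coverage < 0)) abort("coverage must be >= 0")
  if (any(records$beta < 0 | records$beta > 1, na.rm = TRUE)) abort("beta values must lie in [0, 1]")
  elements <- records |>
    filter(.data$coverage >= min_coverage, !is.na(.data$beta)) |>
    group_by(.data$sample_id, .data$element_id) |>
    summarise(n_cpgs = n(), element_mean = mean(.data$beta), .groups = "drop") |>
    filter(.data$n_cpgs >= min_cpgs)
  if (!nrow(elements)) abort("no repeat element passes the CpG count/coverage filter")
  elements |>
    group_by(.data$sample_id) |>
    summarise(score = mean(.data$element_mean), n_elements = n(), .groups = "drop")
}

#' Count hypermethylated CpG-island promoters in short PMDs
#'
#' Focal CpG-island (CGI) promoter hypermethylation accompanies long-range
#' methylation loss. For each sample a baseline is taken from the CGI probes
#' lying in merged highly methylated domains (HMDs): their mean and standard
#' deviation define what "normally methylated" looks like in that sample. The
#' statistic is the number of promoter-flagged CGI probes inside short PMDs
#' whose beta exceeds the baseline mean by more than `n_sd` standard deviations
#' (one-sided, strict inequality).
#'
#' @param beta Beta values (see [global_methylation()]).
#' @param manifest Probe manifest with `probe_id`, `chrom`, `pos`, `cgi_class`
#'   (`island`, `shore`, `shelf`, `opensea`) and `promoter_flag`.
#' @param hmds Merged HMD intervals (`chrom`, `start`, `end`), 0-based half-open.
#' @param short_pmds Short-PMD intervals in the same format.
#' @param n_sd Number of baseline SDs above the mean (default 2).
#' @param baseline Which HMD CGI probes set the baseline: all of them
#'   (`"all"`, default) or promoter-flagged only (`"promoter"`).
#'
#' @return A tibble with `sample_id`, `n_hyper`, `baseline_mean`, `baseline_sd`.
#' @export
count_hyper_cgi <- function(beta, manifest, hmds, short_pmds, n_sd = 2,
                            baseline = c("all", "promoter")) {
  baseline <- match.arg(baseline)
  m <- check_beta_range(as_beta_matrix(beta))
  check_intervals(hmds, "HMD table")
  check_intervals(short_pmds, "short-PMD table")

  probe_gr <- GenomicRanges::GRanges(
    manifest$chrom, IRanges::IRanges(manifest$pos + 1L, width = 1L)
  )
  in_hmd <- IRanges::overlapsAny(probe_gr, intervals_to_gr(hmds))
  in_short <- IRanges::overlapsAny(probe_gr, intervals_to_gr(short_pmds))

  base_sel <- in_hmd & manifest$cgi_class == "island"
  if (baseline == "promoter") base_sel <- base_sel & manifest$promoter_flag
  base_ids <- intersect(manifest$probe_id[base_sel], rownames(m))
  if (length(base_ids) < 2) {
    abort("fewer than 2 HMD CGI probes available; baseline SD undefined")
  }
  target_ids <- intersect(
    manifest$probe_id[in_short & manifest$cgi_class == "island" & manifest$promoter_flag],
    rownames(m)
  )

  base <- m[base_ids, , drop = FALSE]
  mu <- colMeans(base, na.rm = TRUE)
  sigma <- apply(base, 2, sd, na.rm = TRUE)
  if (length(target_ids)) {
    tgt <- m[target_ids, , drop = FALSE]
    cut <- matrix(mu + n_sd * sigma, nrow = nrow(tgt), ncol = ncol(tgt), byrow = TRUE)
    n_hyper <- colSums(tgt > cut, na.rm = TRUE)
  } else {
    n_hyper <- setNames(rep(0L, ncol(m)), colnames(m))
  }
  tibble(
    sample_id = colnames(m),
    n_hyper = as.integer(n_hyper),
    baseline_mean = unname(mu),
    baseline_sd = unname(sigma)
  )
}
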