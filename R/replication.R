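#' Normalize replication-timing tracks across cell lines
#'
#' Wavelet-smoothed replication-timing signal binned on a fixed 5-kb grid is
#' made comparable across cell lines in two steps: each cell line is z-scaled,
#' then the cell lines are quantile-normalized against the mean of their
#' sorted distributions (so every line ends with the same sorted value
#' multiset). Windows with a missing value in any cell line are excluded
#' before normalization.
#'
#' @param tracks Long-format data frame with columns `chrom`, `start`, `end`,
#'   `cell_line`, `group` (`"normal"` or `"cancer"`) and `signal` (`NA` for
#'   missing windows).
#'
#' @return An object of class `methloss_tracks`: a list with `windows` (tibble
#'   of retained windows), `signal` (windows x cell-lines matrix) and `groups`
#'   (named character vector).
#' @export
normalize_tracks <- function(tracks) {
  need <- c("chrom", "start", "end", "cell_line", "group", "signal")
  miss <- setdiff(need, names(tracks))
  if (length(miss)) abort(paste0("tracks missing column(s): ", paste(miss, collapse = ", ")))
  groups <- tracks |> distinct(.data$cell_line, .data$group)
  if (any(duplicated(groups$cell_line))) abort("a cell line appears in two groups")
  grp <- setNames(groups$group, groups$cell_line)
  if (sum(grp == "normal") < 2 || sum(grp == "cancer") < 2) {
    abort("need at least 2 cell lines per group (normal and cancer)")
  }
  wide <- tracks |>
    select("chrom", "start", "end", "cell_line", "signal") |>
    tidyr::pivot_wider(names_from = "cell_line", values_from = "signal") |>
    arrange(.data$chrom, .data$start)
  sig <- as.matrix(wide[, names(grp), drop = FALSE])
  keep <- complete.cases(sig)
  sig <- sig[keep, , drop = FALSE]
  windows <- wide[keep, c("chrom", "start", "end")]
  sig <- scale(sig)  # per cell line z-scaling
  sig[, attr(sig, "scaled:scale") == 0] <- 0  # constant track: centred only
  sig <- limma::normalizeQuantiles(sig)
  dimnames(sig) <- list(NULL, names(grp))
  structure(
    list(windows = as_tibble(windows), signal = sig, groups = grp),
    class = "methloss_tracks"
  )
}

#' Per-window Student's t-test of replication timing, cancer vs normal
#'
#' Equal-variance (pooled) two-sample t-test for each retained 5-kb window.
#' Higher signal means earlier replication, and t is computed as cancer minus
#' normal, so positive t = earlier in cancer and negative t = later in cancer.
#' Windows with zero variance in both groups get `t = 0`, `p = 1` and are
#' flagged `degenerate`.
#'
#' @param tracks A `methloss_tracks` object from [normalize_tracks()].
#'
#' @return A tibble with `chrom`, `start`, `end`, `t`, `p`, `degenerate`.
#' @export
window_ttest <- function(tracks) {
  if (!inherits(tracks, "methloss_tracks")) abort("tracks must come from normalize_tracks()")
  sig <- tracks$signal
  is_cancer <- tracks$groups[colnames(sig)] == "cancer"
  x <- sig[, is_cancer, drop = FALSE]   # cancer
  y <- sig[, !is_cancer, drop = FALSE]  # normal
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
  se <- sqrt(sp2 * (1 / nx + 1 / ny))
  degenerate <- se == 0
  tt <- ifelse(degenerate, 0, (mx - my) / se)
  p <- ifelse(degenerate, 1, 2 * pt(-abs(tt), df = nx + ny - 2))
  out <- tracks$windows
  out$t <- tt
  out$p <- p
  out$degenerate <- degenerate
  out
}

#' Combine P values with Fisher's method
#'
#' \eqn{X^2 = -2 \sum \log p_i} is referred to a chi-square distribution with
#' \eqn{2k} degrees of freedom (upper tail). With a single P value the
#' combined P equals it exactly. Zeros are floored at the smallest positive
#' double so the statistic stays finite.
#'
#' @param p Numeric vector of P values in (0, 1].
#' @return A single combined P value.
#' @export
fisher_combine <- function(p) {
  p <- p[!is.na(p)]
  if (!length(p)) return(NA_real_)
  p <- pmax(p, .Machine$double.xmin)
  pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}

#' Gene-level replication-timing classification
#'
#' Maps genes to 5-kb windows by interval overlap of the gene body. A gene
#' overlapping a single window inherits its t and P; a gene spanning several
#' windows gets the mean t and the Fisher-combined P across them. P values
#' are Bonferroni-adjusted over the tested genes (those overlapping at least
#' one window), and genes are classified `late_in_cancer` (adjusted P < alpha
#' and negative mean t), `early_in_cancer` (positive mean t) or
#' `unclassified`. Genes overlapping no window are returned unclassified with
#' missing statistics.
#'
#' @param window_stats Per-window results from [window_ttest()].
#' @param gene_models Data frame with `gene_id`, `chrom`, `start`, `end`.
#' @param alpha Significance level on the Bonferroni-adjusted P (default 0.05).
#' @param overlap `"any"` (default) assigns a window to a gene on any overlap;
#'   `"majority"` requires more than half of the window to be covered.
#'
#' @return A tibble with `gene_id`, `n_windows`, `t_mean`, `p_combined`,
#'   `p_adj`, `class`.
#' @export
gene_level_timing <- function(window_stats, gene_models, alpha = 0.05,
                              overlap = c("any", "majority")) {
  overlap <- match.arg(overlap)
  check_intervals(gene_models, "gene models")
  win_gr <- intervals_to_gr(window_stats)
  gene_gr <- intervals_to_gr(gene_models)
  hits <- GenomicRanges::findOverlaps(gene_gr, win_gr)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  if (overlap == "majority") {
    ov <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(gene_gr)[qh], IRanges::ranges(win_gr)[sh]
    ))
    keep <- ov > IRanges::width(win_gr)[sh] / 2
    qh <- qh[keep]; sh <- sh[keep]
  }
  stats_by_gene <- tibble(
    gene_id = gene_models$gene_id[qh],
    t = window_stats$t[sh],
    p = window_stats$p[sh]
  ) |>
    group_by(.data$gene_id) |>
    summarise(
      n_windows = n(),
      t_mean = mean(.data$t),
      p_combined = fisher_combine(.data$p),
      .groups = "drop"
    )
  n_tested <- nrow(stats_by_gene)
  stats_by_gene$p_adj <- pmin(1, stats_by_gene$p_combined * n_tested)
  stats_by_gene$class <- ifelse(
    stats_by_gene$p_adj < alpha,
    ifelse(stats_by_gene$t_mean < 0, "late_in_cancer", "early_in_cancer"),
    "unclassified"
  )
  out <- tibble(gene_id = gene_models$gene_id) |>
    left_join(stats_by_gene, by = "gene_id")
  out$n_windows[is.na(out$n_windows)] <- 0L
  out$class[is.na(out$class)] <- "unclassified"
  out
}

#' Overlap-weighted mean replication timing over an interval
#'
#' Weighted mean of window signal values across an interval, with weights the
#' overlap length between each window and the interval.
#'
#' @param track Data frame with `chrom`, `start`, `end`, `signal`.
#' @param interval A one-row data frame or list with `chrom`, `start`, `end`.
#' @return A single numeric value, or `NA` when nothing overlaps.
#' @export
domain_weighted_timing <- function(track, interval) {
  same <- track$chrom == interval$chrom
  ov <- pmin(track$end, interval$end) - pmax(track$start, interval$start)
  w <- ifelse(same & ov > 0, ov, 0)
  if (sum(w) == 0) return(NA_real_)
  sum(w * track$signal) / sum(w)
}
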