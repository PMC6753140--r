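#' Per-gene multi-predictor linear model
#'
#' For every gene, mRNA expression is regressed on the sample-level features
#' global methylation level, mutation burden, aneuploidy level, tumour purity,
#' age and (optionally) tumour stage by ordinary least squares. The per-term
#' z score is the coefficient divided by its standard error (t-distributed
#' under Gaussian errors; the two-sided P uses the t reference with n - p
#' degrees of freedom), and a Benjamini-Hochberg q value is computed per
#' predictor across genes. Mutation burden is log-scaled as
#' `log10(1 + burden)` by default.
#'
#' @param expr Expression values: genes x samples matrix with gene ids as
#'   rownames, or a data frame with a `gene_id` column. Columns must match
#'   `features$sample_id`.
#' @param features Data frame with `sample_id`, `global_methylation`,
#'   `mutation_burden`, `aneuploidy`, `purity`, `age` and (if
#'   `include_stage`) `stage` (ordinal 1-4). Rows with missing required
#'   predictors are an error.
#' @param include_stage Include the tumour-stage term (default `TRUE`).
#' @param log_burden Enter mutation burden as `log10(1 + burden)` (default).
#'
#' @return An object of class `methloss_gene_lm`: a tibble with one row per
#'   gene x term (`gene_id`, `term`, `estimate`, `se`, `z`, `p`, `q`).
#' @export
fit_gene_models <- function(expr, features, include_stage = TRUE, log_burden = TRUE) {
  y <- as_expr_matrix(expr)
  terms <- c("global_methylation", "mutation_burden", "aneuploidy", "purity", "age")
  if (include_stage) terms <- c(terms, "stage")
  miss <- setdiff(c("sample_id", terms), names(features))
  if (length(miss)) abort(paste0("features missing column(s): ", paste(miss, collapse = ", ")))
  features <- features[match(colnames(y), features$sample_id), , drop = FALSE]
  if (anyNA(features$sample_id)) abort("expression columns and features$sample_id do not match")
  X <- cbind(`(Intercept)` = 1, as.matrix(features[, terms]))
  if (log_burden) X[, "mutation_burden"] <- log10(1 + X[, "mutation_burden"])
  if (anyNA(X)) {
    bad <- terms[colSums(is.na(X[, terms, drop = FALSE])) > 0]
    abort(paste0("missing values in predictor(s): ", paste(bad, collapse = ", ")))
  }
  n <- nrow(X); p <- ncol(X)
  if (n < p + 2) abort("need at least (number of predictors + 2) samples")
  qrx <- qr(X)
  if (qrx$rank < p) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1):p]]
    abort(paste0("singular design: predictor(s) ", paste(dropped, collapse = ", "),
                 " are constant or collinear"))
  }
  yt <- t(y)                                  # samples x genes
  beta <- qr.coef(qrx, yt)                    # p x genes
  res <- yt - X %*% beta
  sigma2 <- colSums(res^2) / (n - p)
  xtx_inv <- chol2inv(qr.R(qrx))
  se <- sqrt(outer(diag(xtx_inv), sigma2))    # p x genes
  z <- beta / se
  pv <- 2 * pt(-abs(z), df = n - p)
  out <- tibble(
    gene_id = rep(colnames(beta), each = p),
    term = rep(rownames(beta), times = ncol(beta)),
    estimate = as.vector(beta),
    se = as.vector(se),
    z = as.vector(z),
    p = as.vector(pv)
  ) |>
    filter(.data$term != "(Intercept)") |>
    group_by(.data$term) |>
    mutate(q = p.adjust(.data$p, method = "BH")) |>
    ungroup()
  structure(out, class = c("methloss_gene_lm", class(out)),
            n_samples = n, terms = terms)
}

#' Ranking of genes by association with methylation loss
#'
#' Extracts, from a per-gene model fit, the gene ranking used for enrichment:
#' the z score of the global-methylation coefficient with its sign flipped,
#' so positive scores mean higher expression in demethylated tumours and
#' negative scores mean repression under methylation loss.
#'
#' @param fit A `methloss_gene_lm` object.
#' @return A named numeric vector of demethylation-association scores.
#' @export
demethylation_ranking <- function(fit) {
  if (!inherits(fit, "methloss_gene_lm")) abort("fit must come from fit_gene_models()")
  sub <- fit[fit$term == "global_methylation", ]
  setNames(-sub$z, sub$gene_id)
}

#' First-order partial Spearman correlation
#'
#' Rank-based correlation of `x` and `y` adjusted for a single covariate `z`
#' via the first-order formula
#' \eqn{(r_{xy} - r_{xz} r_{yz}) / \sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}}
#' applied to Spearman correlations. The P value uses the t approximation
#' with n - 3 degrees of freedom.
#'
#' @param x,y,z Numeric vectors of equal length; incomplete triples dropped.
#' @return A tibble with `estimate`, `statistic`, `p_value`, `n`.
#' @export
partial_spearman <- function(x, y, z) {
  keep <- complete.cases(x, y, z)
  x <- x[keep]; y <- y[keep]; z <- z[keep]
  n <- length(x)
  if (n < 4) abort("need at least 4 complete (x, y, z) triples")
  if (sd(x) == 0 || sd(y) == 0 || sd(z) == 0) {
    abort("partial Spearman undefined: a variable is constant")
  }
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  r_xy <- cor(rx, ry); r_xz <- cor(rx, rz); r_yz <- cor(ry, rz)
  den <- sqrt((1 - r_xz^2) * (1 - r_yz^2))
  r <- if (den == 0) 0 else (r_xy - r_xz * r_yz) / den
  r <- clamp(r, -1, 1)
  tstat <- r * sqrt((n - 3) / (1 - r^2))
  tibble(
    estimate = r,
    statistic = tstat,
    p_value = 2 * pt(-abs(tstat), df = n - 3),
    n = n
  )
}

#' Identify genes specifically expressed in the immune system
#'
#' Flags genes whose mean expression in immune tissues (leukocytes and lymph
#' nodes) is at least `fold` times the mean over the remaining tissues. A
#' pseudocount is added to the denominator so genes silent outside the immune
#' system are handled.
#'
#' @param tissue_expr Genes x tissues matrix (rownames = gene ids) or data
#'   frame with a `gene_id` column.
#' @param immune_tissues Column names of the immune tissues.
#' @param fold Fold-change cutoff (default 5).
#' @param eps Pseudocount added to the non-immune mean (default 1e-8).
#' @return Character vector of immune-specific gene ids.
#' @export
immune_specific_genes <- function(tissue_expr,
                                  immune_tissues = c("leukocyte", "lymph_node"),
                                  fold = 5, eps = 1e-8) {
  m <- as_expr_matrix(tissue_expr)
  miss <- setdiff(immune_tissues, colnames(m))
  if (length(miss)) abort(paste0("tissue column(s) missing: ", paste(miss, collapse = ", ")))
  other <- setdiff(colnames(m), immune_tissues)
  if (!length(other)) abort("need at least one non-immune tissue column")
  imm_mean <- rowMeans(m[, immune_tissues, drop = FALSE])
  other_mean <- rowMeans(m[, other, drop = FALSE])
  rownames(m)[imm_mean / (other_mean + eps) >= fold]
}

#' Normalize and standardize repeat-element expression
#'
#' Mapped read counts per repeat class are divided by the sample's total
#' aligned reads, then z-standardized within each tumour type (and repeat
#' class). Tumour types with a single sample get a missing z score.
#'
#' @param counts Data frame with `sample_id`, `element_class`, `count`.
#' @param totals Data frame with `sample_id`, `total_reads` (> 0).
#' @param tumour_types Data frame with `sample_id`, `tumour_type`.
#' @return A tibble with the rate and the within-type z score.
#' @export
normalize_repeat_expression <- function(counts, totals, tumour_types) {
  if (any(totals$total_reads <= 0)) abort("total_reads must be > 0 for every sample")
  counts |>
    inner_join(totals, by = "sample_id") |>
    inner_join(tumour_types, by = "sample_id") |>
    mutate(rate = .data$count / .data$total_reads) |>
    group_by(.data$tumour_type, .data$element_class) |>
    mutate(
      z = if (n() > 1 && sd(.data$rate) > 0) {
        (.data$rate - mean(.data$rate)) / sd(.data$rate)
      } else {
        NA_real_
      }
    ) |>
    ungroup()
}

#' Compare a per-sample statistic between low and high methylation groups
#'
#' Partitions samples by percentiles of a score (by default the 30th/70th
#' percentiles of global methylation, middle excluded) and compares the value
#' of interest between the two groups with a two-sided Mann-Whitney U test.
#' An already-computed grouping can be supplied instead of a score.
#'
#' @param data Data frame with one row per sample.
#' @param value Column name (string) of the statistic to compare.
#' @param score Column name of the stratifying score; ignored when `group`
#'   is given.
#' @param group Optional column name holding `"low"`/`"high"` labels.
#' @param low_cut,high_cut Percentile cuts (defaults 30 and 70).
#' @return A tibble with the U statistic, P value and group summaries.
#' @export
group_compare <- function(data, value, score = "global_methylation", group = NULL,
                          low_cut = 30, high_cut = 70) {
  if (is.null(group)) {
    s <- data[[score]]
    lo <- quantile(s, low_cut / 100)
    hi <- quantile(s, high_cut / 100)
    g <- ifelse(s < lo, "low", ifelse(s > hi, "high", NA))
  } else {
    g <- data[[group]]
  }
  v <- data[[value]]
  x <- v[!is.na(g) & g == "low"]
  y <- v[!is.na(g) & g == "high"]
  if (length(x) < 2 || length(y) < 2) abort("need at least 2 samples per group")
  wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE))
  tibble(
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    n_low = length(x),
    n_high = length(y),
    median_low = median(x),
    median_high = median(y)
  )
}

#' Paired comparison of gene-set expression between methylation groups
#'
#' Expression is z-scored per gene across all samples, then averaged within
#' the low and the high methylation group; the two per-gene group means are
#' compared with a paired t-test (pairing by gene).
#'
#' @param expr Genes x samples matrix or data frame with `gene_id`.
#' @param groups Data frame with `sample_id` and `group` (`"low"`/`"high"`).
#' @param genes Optional subset of gene ids (default all).
#' @return A tibble with the paired-t statistic, P value and group means.
#' @export
compare_gene_expression <- function(expr, groups, genes = NULL) {
  m <- as_expr_matrix(expr)
  if (!is.null(genes)) m <- m[rownames(m) %in% genes, , drop = FALSE]
  if (nrow(m) < 2) abort("need at least 2 genes to pair")
  zs <- t(scale(t(m)))
  zs <- zs[apply(zs, 1, function(r) all(is.finite(r))), , drop = FALSE]
  low_ids <- groups$sample_id[groups$group == "low"]
  high_ids <- groups$sample_id[groups$group == "high"]
  low_mean <- rowMeans(zs[, colnames(zs) %in% low_ids, drop = FALSE])
  high_mean <- rowMeans(zs[, colnames(zs) %in% high_ids, drop = FALSE])
  tt <- t.test(low_mean, high_mean, paired = TRUE)
  tibble(
    statistic = unname(tt$statistic),
    p_value = tt$p.value,
    n_genes = nrow(zs),
    mean_low = mean(low_mean),
    mean_high = mean(high_mean)
  )
}
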