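# Preranked enrichment (weighted Kolmogorov-Smirnov running sum) and
# single-sample enrichment scores.

# Running-sum enrichment score for one set over a ranking.
# scores: numeric, already sorted in decreasing order; in_set: logical.
# Weight exponent is 1 (hit increments proportional to |score|).
# The reported ES is the signed extremum of the running sum (the walk itself
# always returns to ~0 at the end; a set equal to the whole universe
# degenerates to the hit ECDF alone).
running_es <- function(scores, in_set) {
  n <- length(scores)
  m <- sum(in_set)
  w <- abs(scores)
  nr <- sum(w[in_set])
  hit <- ifelse(in_set, if (nr > 0) w / nr else 1 / max(m, 1), 0)
  miss <- ifelse(in_set, 0, 1 / max(n - m, 1))
  running <- cumsum(hit - miss)
  running[which.max(abs(running))]
}

#' Preranked enrichment analysis of gene sets
#'
#' Weighted running-sum enrichment of gene sets in a ranked gene list. Genes
#' are sorted by decreasing score; walking down the list, hitting a set gene
#' increments the running sum proportionally to `|score|` (normalized over the
#' set) and missing decrements it by `1 / (N - m)`. The enrichment score (ES)
#' is the signed extremum of this walk. Significance comes from gene-label
#' permutation: `n_perm` random sets of the same size. The normalized score is
#' `NES = ES / mean(|null ES| of matching sign)`, the permutation P compares
#' `|ES|` to the same-sign null, and the FDR uses the standard two-tail ratio
#' of pooled null NES to observed NES. Sets smaller than `min_size` (after
#' intersection with the ranked universe) are dropped.
#'
#' @param scores Named numeric vector (gene ids as names) or a data frame with
#'   `gene_id` and `score`.
#' @param sets Named list of character vectors (gene sets).
#' @param n_perm Number of gene-label permutations (default 1000).
#' @param min_size Minimum set size after intersection (default 10).
#' @param seed Optional integer seed.
#'
#' @return An object of class `methloss_enrichment`: a tibble with `set_id`,
#'   `size`, `es`, `nes`, `p_perm`, `fdr`; the ranked scores and null ES are
#'   kept as attributes for plotting.
#' @export
preranked_enrichment <- function(scores, sets, n_perm = 1000, min_size = 10,
                                 seed = NULL) {
  if (is.data.frame(scores)) scores <- setNames(scores$score, scores$gene_id)
  if (is.null(names(scores))) abort("scores must be named by gene id")
  scores <- scores[is.finite(scores)]
  if (!length(scores)) abort("empty ranking: no finite scores")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  universe <- names(s)
  n <- length(s)

  sets <- lapply(sets, function(g) intersect(g, universe))
  sizes <- vapply(sets, length, integer(1))
  sets <- sets[sizes >= min_size]
  if (!length(sets)) abort(paste0("no gene set with >= ", min_size, " genes in the ranking"))
  sizes <- vapply(sets, length, integer(1))

  es_obs <- vapply(sets, function(g) running_es(s, universe %in% g), numeric(1))

  if (!is.null(seed)) set.seed(seed)
  null_by_size <- lapply(unique(sizes), function(m) {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n, m)
      memb <- logical(n)
      memb[idx] <- TRUE
      running_es(s, memb)
    }, numeric(1))
  })
  names(null_by_size) <- as.character(unique(sizes))

  norm_one <- function(es, null_es) {
    pos_mean <- mean(abs(null_es[null_es > 0]))
    neg_mean <- mean(abs(null_es[null_es < 0]))
    if (es >= 0) es / pos_mean else es / neg_mean
  }
  nes <- numeric(length(sets))
  p_perm <- numeric(length(sets))
  null_nes_pool <- list()
  for (i in seq_along(sets)) {
    null_es <- null_by_size[[as.character(sizes[i])]]
    same <- if (es_obs[i] >= 0) null_es[null_es > 0] else null_es[null_es < 0]
    p_perm[i] <- (1 + sum(abs(same) >= abs(es_obs[i]))) / (1 + length(same))
    nes[i] <- norm_one(es_obs[i], null_es)
    null_nes_pool[[i]] <- vapply(null_es, norm_one, numeric(1), null_es = null_es)
  }
  pool <- unlist(null_nes_pool)

  fdr <- vapply(seq_along(sets), function(i) {
    v <- nes[i]
    if (is.na(v)) return(NA_real_)
    if (v >= 0) {
      null_frac <- sum(pool >= v) / max(1, sum(pool >= 0))
      obs_frac <- sum(nes >= v) / max(1, sum(nes >= 0))
    } else {
      null_frac <- sum(pool <= v) / max(1, sum(pool <= 0))
      obs_frac <- sum(nes <= v) / max(1, sum(nes <= 0))
    }
    clamp(null_frac / max(obs_frac, .Machine$double.eps), 0, 1)
  }, numeric(1))

  out <- tibble(
    set_id = names(sets),
    size = sizes,
    es = unname(es_obs),
    nes = nes,
    p_perm = p_perm,
    fdr = fdr
  )
  structure(out, class = c("methloss_enrichment", class(out)),
            ranked_scores = s, sets = sets, n_perm = n_perm)
}

#' Single-sample enrichment score (ssGSEA-style)
#'
#' For each sample, genes are ranked by expression and the score is the sum
#' over the ranked list of the difference between the weighted ECDF of set
#' genes (weights = rank^alpha, normalized within the set) and the ECDF of
#' non-set genes. Being rank-based, the score is invariant to strictly
#' monotone transforms of the expression vector.
#'
#' @param expr Genes x samples matrix (rownames = gene ids) or data frame with
#'   `gene_id`.
#' @param gene_set Character vector of gene ids.
#' @param alpha Rank weight exponent (default 0.25).
#' @return A tibble with `sample_id`, `score`, `n_set_genes`; samples where no
#'   set gene is present get `NA`.
#' @export
ssgsea_score <- function(expr, gene_set, alpha = 0.25) {
  m <- as_expr_matrix(expr)
  in_set_all <- rownames(m) %in% gene_set
  n_overlap <- sum(in_set_all)
  if (n_overlap == 0) {
    return(tibble(sample_id = colnames(m), score = NA_real_, n_set_genes = 0L))
  }
  n <- nrow(m)
  score_one <- function(ev) {
    r <- rank(ev, ties.method = "average")       # highest expression -> rank n
    ord <- order(ev, decreasing = TRUE)
    in_set <- in_set_all[ord]
    w <- r[ord]^alpha
    p_in <- cumsum(ifelse(in_set, w, 0)) / sum(w[in_set])
    p_out <- cumsum(!in_set) / max(1, n - n_overlap)
    sum(p_in - p_out)
  }
  tibble(
    sample_id = colnames(m),
    score = apply(m, 2, score_one),
    n_set_genes = n_overlap
  )
}
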