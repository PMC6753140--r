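make_features <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    sample_id = sprintf("s%03d", seq_len(n)),
    global_methylation = runif(n, 0.4, 0.8),
    mutation_burden = rpois(n, 50),
    aneuploidy = runif(n),
    purity = runif(n, 0.3, 0.9),
    age = runif(n, 40, 80),
    stage = sample(1:4, n, replace = TRUE)
  )
}

test_that("per-gene regression recovers a noiseless coefficient and is permutation-invariant", {
  ft <- make_features(60)
  y <- rbind(
    g1 = 2 * ft$global_methylation + 0.01 * ft$age,
    g2 = rnorm(60)
  )
  colnames(y) <- ft$sample_id
  fit <- fit_gene_models(y, ft)
  b1 <- fit[fit$gene_id == "g1" & fit$term == "global_methylation", ]
  expect_equal(b1$estimate, 2, tolerance = 1e-8)
  expect_lt(b1$p, 1e-12)
  expect_true(all(fit$q >= fit$p - 1e-15))
  expect_equal(sign(fit$z), sign(fit$estimate))

  # joint permutation of samples leaves estimates unchanged
  perm <- sample(60)
  fit_p <- fit_gene_models(y[, perm], ft[perm, ])
  expect_equal(fit_p$estimate, fit$estimate, tolerance = 1e-10)

  # a constant predictor is a named error
  ft_bad <- dplyr::mutate(ft, purity = 0.5)
  expect_error(fit_gene_models(y, ft_bad), "purity")
})

test_that("demethylation ranking is the negated methylation z score", {
  ft <- make_features(40)
  y <- rbind(g1 = 3 * ft$global_methylation + rnorm(40, 0, 0.1),
             g2 = -3 * ft$global_methylation + rnorm(40, 0, 0.1))
  colnames(y) <- ft$sample_id
  fit <- fit_gene_models(y, ft)
  r <- demethylation_ranking(fit)
  z <- fit$z[fit$term == "global_methylation"]
  expect_equal(unname(r), -z)
  # a gene repressed under methylation loss (positive methylation coefficient)
  # ranks at the bottom
  expect_lt(r["g1"], 0)
  expect_gt(r["g2"], 0)
})

test_that("partial Spearman equals the first-order closed form and its limits", {
  set.seed(3)
  for (i in 1:5) {
    x <- rnorm(30); y <- rnorm(30); z <- rnorm(30)
    got <- partial_spearman(x, y, z)
    rx <- rank(x); ry <- rank(y); rz <- rank(z)
    r_xy <- cor(rx, ry); r_xz <- cor(rx, rz); r_yz <- cor(ry, rz)
    expect_equal(got$estimate,
                 (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2)),
                 tolerance = 1e-12)
  }
  # independent z: partial ~ marginal Spearman
  set.seed(4)
  x <- rnorm(500); y <- x + rnorm(500); z <- rnorm(500)
  expect_equal(partial_spearman(x, y, z)$estimate,
               cor(x, y, method = "spearman"), tolerance = 0.02)
  # y identical to z: nothing left to correlate
  expect_equal(partial_spearman(x, z, z)$estimate, 0)
  expect_error(partial_spearman(rep(1, 10), rnorm(10), rnorm(10)), "constant")
})

test_that("immune-specific filter applies the five-fold rule with a pseudocount", {
  m <- rbind(
    hi = c(10, 10, 1.9, 1.9),
    lo = c(10, 10, 2.1, 2.1),
    silent = c(1e-3, 1e-3, 0, 0)
  )
  colnames(m) <- c("leukocyte", "lymph_node", "t1", "t2")
  out <- immune_specific_genes(m)
  expect_true("hi" %in% out)       # 10 / 1.9 ~ 5.26
  expect_false("lo" %in% out)      # 10 / 2.1 < 5
  expect_true("silent" %in% out)   # denominator rescued by the pseudocount
  expect_error(immune_specific_genes(m[, c("t1", "t2")]), "missing")
})

test_that("repeat expression is rate-normalized then standardized within tumour type", {
  counts <- tibble::tibble(
    sample_id = c("a", "b", "c", "d"),
    element_class = "LINE1",
    count = c(10, 20, 30, 5)
  )
  totals <- tibble::tibble(sample_id = c("a", "b", "c", "d"),
                           total_reads = c(1e6, 2e6, 1e6, 1e6))
  types <- tibble::tibble(sample_id = c("a", "b", "c", "d"),
                          tumour_type = c("LUAD", "LUAD", "LUAD", "SKCM"))
  out <- normalize_repeat_expression(counts, totals, types)
  # equal rates for a and b
  expect_equal(out$rate[out$sample_id == "a"], out$rate[out$sample_id == "b"])
  # single-sample tumour type: z undefined
  expect_true(is.na(out$z[out$sample_id == "d"]))
  # rescaling all totals leaves z untouched
  out2 <- normalize_repeat_expression(counts,
    dplyr::mutate(totals, total_reads = total_reads * 3), types)
  expect_equal(out2$z, out$z)
  expect_error(normalize_repeat_expression(counts,
    dplyr::mutate(totals, total_reads = 0), types), "total_reads")
})

test_that("Mann-Whitney group comparison matches exhaustive pair counting", {
  set.seed(5)
  x <- rnorm(7); y <- rnorm(6)
  df <- tibble::tibble(
    v = c(x, y), g = rep(c("low", "high"), c(7, 6))
  )
  got <- group_compare(df, "v", group = "g")
  u_brute <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  expect_equal(got$statistic, u_brute)

  # identical distributions -> P near 1; separated -> tiny P
  same <- tibble::tibble(v = rep(1:20, 2), g = rep(c("low", "high"), each = 20))
  expect_gt(group_compare(same, "v", group = "g")$p_value, 0.9)
  apart <- tibble::tibble(v = c(rnorm(20), rnorm(20) + 50),
                          g = rep(c("low", "high"), each = 20))
  expect_lt(group_compare(apart, "v", group = "g")$p_value, 1e-6)

  # percentile grouping: 30/70 cuts exclude the middle
  df10 <- tibble::tibble(global_methylation = 1:10, v = 1:10)
  res <- group_compare(df10, "v")
  expect_equal(res$n_low, 3)
  expect_equal(res$n_high, 3)
})

test_that("paired gene-level comparison z-scores per gene and pairs by gene", {
  set.seed(6)
  m <- matrix(rnorm(200), nrow = 10,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("s%02d", 1:20)))
  grp <- tibble::tibble(sample_id = colnames(m),
                        group = rep(c("low", "high"), each = 10))
  m[, grp$group == "low"] <- m[, grp$group == "low"] - 2
  out <- compare_gene_expression(m, grp)
  expect_lt(out$p_value, 1e-4)
  expect_lt(out$mean_low, out$mean_high)
  expect_equal(out$n_genes, 10)
})

test_that("single-sample enrichment is rank-based and extremal for top-ranked sets", {
  set.seed(7)
  ev <- rnorm(50)
  names(ev) <- sprintf("g%02d", 1:50)
  m <- cbind(s1 = ev)
  top_set <- names(sort(ev, decreasing = TRUE))[1:5]
  other_set <- names(sort(ev, decreasing = TRUE))[21:25]
  s_top <- ssgsea_score(m, top_set)$score
  s_other <- ssgsea_score(m, other_set)$score
  expect_gt(s_top, s_other)
  # maximum attainable: any other same-size set scores lower
  for (i in 1:10) {
    rnd <- sample(names(ev), 5)
    expect_lte(ssgsea_score(m, rnd)$score, s_top + 1e-12)
  }
  # invariance under strictly monotone transform
  m2 <- cbind(s1 = exp(2 * ev))
  expect_equal(ssgsea_score(m2, other_set)$score, s_other, tolerance = 1e-12)
  # no overlap -> missing
  expect_true(is.na(ssgsea_score(m, c("zz1", "zz2"))$score))
})
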