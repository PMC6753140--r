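test_that("LINE-1 probe filter applies family, length and fraction rules jointly", {
  man <- toy_manifest()
  sel <- select_l1_probes(man)
  # p1: L1HS, 46/50 -> in; p2: 44 bp fails the floor; p3: wrong family;
  # p4: L1PA lineage, full map -> in; p5: 45/60 = 0.75 fails the fraction
  expect_setequal(sel, c("p1", "p4"))
  expect_error(
    select_l1_probes(dplyr::mutate(man, repeat_family = "AluY")),
    "no qualifying"
  )
  expect_error(
    select_l1_probes(dplyr::mutate(man, mapped_len = probe_len + 1)),
    "mapped_len"
  )
})

test_that("global methylation is the per-sample mean over selected probes", {
  beta <- toy_beta(list(a = c(0.2, 0.5), b = c(0.4, 0.5), c = c(0.6, 0.5)))
  gs <- global_methylation(beta, c("a", "b", "c"))
  expect_equal(gs$score, c(0.4, 0.5))
  expect_equal(gs$n_probes_used, c(3L, 3L))

  # probe and sample order are irrelevant
  shuf <- beta[c(3, 1, 2), c(2, 1)]
  gs2 <- global_methylation(shuf, c("b", "c", "a"))
  expect_equal(sort(gs2$score), sort(gs$score))

  # adding a probe whose beta equals the current score changes nothing
  beta3 <- rbind(beta, d = c(0.4, 0.5))
  gs3 <- global_methylation(beta3, c("a", "b", "c", "d"))
  expect_equal(gs3$score, gs$score)

  # missing cells are dropped; a fully-missing sample is an error by name
  beta_na <- toy_beta(list(a = c(0.2, NA), b = c(0.6, 0.5)))
  expect_equal(global_methylation(beta_na, c("a", "b"))$score, c(0.4, 0.5))
  expect_error(global_methylation(beta_na, "a"), "s2")
  expect_error(global_methylation(beta, c("a", "zzz")), "zzz")
})

test_that("element-level bisulfite score filters CpGs then averages element means", {
  rec <- tibble::tibble(
    sample_id = "s1",
    element_id = c("e1", "e1", "e1", "e2", "e2", "e2"),
    coverage = c(12, 11, 9, 15, 20, 10),
    beta = c(0.8, 0.6, 0.9, 0.8, 0.6, 0.7)
  )
  # e1 has only two CpGs at coverage >= 10 -> dropped; e2 mean = 0.7
  out <- wgbs_global_methylation(rec)
  expect_equal(out$score, 0.7)
  expect_equal(out$n_elements, 1L)

  # sample score is the unweighted mean of element means
  rec2 <- tibble::tibble(
    sample_id = "s1",
    element_id = rep(c("e1", "e2"), c(3, 4)),
    coverage = 10,
    beta = c(0.6, 0.6, 0.6, 0.8, 0.8, 0.8, 0.8)
  )
  expect_equal(wgbs_global_methylation(rec2)$score, 0.7)
  expect_error(wgbs_global_methylation(dplyr::mutate(rec, coverage = 1)),
               "no repeat element")
})

test_that("hyper-CGI count uses a per-sample HMD baseline and a strict 2-SD rule", {
  manifest <- tibble::tibble(
    probe_id = c("h1", "h2", "h3", "t1", "t2", "t3", "n1"),
    chrom = "chr1",
    pos = c(100L, 200L, 300L, 1000100L, 1000200L, 1000300L, 1000400L),
    cgi_class = c(rep("island", 6), "island"),
    promoter_flag = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE)
  )
  hmds <- tibble::tibble(chrom = "chr1", start = 0, end = 1e4)
  short_pmds <- tibble::tibble(chrom = "chr1", start = 1e6, end = 2e6)
  # baseline {0.05, 0.10, 0.15}: mean 0.10, sd 0.05 -> cutoff 0.20
  beta <- toy_beta(list(
    h1 = 0.05, h2 = 0.10, h3 = 0.15,
    t1 = 0.25, t2 = 0.15, t3 = 0.12, n1 = 0.99
  ))
  out <- count_hyper_cgi(beta, manifest, hmds, short_pmds)
  expect_equal(out$baseline_mean, 0.10)
  expect_equal(out$baseline_sd, 0.05)
  expect_equal(out$n_hyper, 1L)  # only 0.25 > 0.20; n1 is not a promoter

  # values exactly at the baseline mean never count
  beta_eq <- toy_beta(list(
    h1 = 0.05, h2 = 0.10, h3 = 0.15, t1 = 0.10, t2 = 0.10, t3 = 0.10, n1 = 0.1
  ))
  expect_equal(count_hyper_cgi(beta_eq, manifest, hmds, short_pmds)$n_hyper, 0L)

  # a tie exactly at mean + 2 SD is not counted (strict inequality)
  beta_tie <- toy_beta(list(
    h1 = 0.05, h2 = 0.10, h3 = 0.15, t1 = 0.20, t2 = 0.10, t3 = 0.10, n1 = 0.1
  ))
  expect_equal(count_hyper_cgi(beta_tie, manifest, hmds, short_pmds)$n_hyper, 0L)

  expect_error(
    count_hyper_cgi(beta, manifest[c(1, 4:7), ], hmds, short_pmds),
    "fewer than 2"
  )
})

test_that("array score tracks an element-level score computed from the same latent factor", {
  cohort <- shared_cohort()
  probes <- select_l1_probes(cohort$manifest)
  array_score <- global_methylation(cohort$beta, probes)

  # independent element-level emulation driven by the same latent factor
  set.seed(42)
  d <- cohort$latent$d
  n_elem <- 40
  rec <- tidyr::expand_grid(
    sample_id = cohort$latent$sample_id,
    element_id = sprintf("e%02d", seq_len(n_elem)),
    cpg = 1:3
  )
  rec$coverage <- 15
  base <- 0.75 - 0.25 * d[match(rec$sample_id, cohort$latent$sample_id)]
  rec$beta <- pmin(pmax(base + rnorm(nrow(rec), 0, 0.05), 0), 1)
  wgbs_score <- wgbs_global_methylation(rec)

  j <- dplyr::inner_join(array_score, wgbs_score, by = "sample_id")
  expect_gt(cor(j$score.x, j$score.y, method = "spearman"), 0.9)
})
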