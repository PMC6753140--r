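# Small track builder: windows on a 5-kb grid for the given cell lines.
toy_tracks <- function(values, groups) {
  nw <- length(values[[1]])
  dplyr::bind_rows(lapply(names(values), function(line) {
    tibble::tibble(
      chrom = "chr1", start = (seq_len(nw) - 1) * 5e3, end = seq_len(nw) * 5e3,
      cell_line = line, group = groups[[line]], signal = values[[line]]
    )
  }))
}

grp4 <- c(n1 = "normal", n2 = "normal", c1 = "cancer", c2 = "cancer")

test_that("track normalization equalizes distributions and drops incomplete windows", {
  set.seed(1)
  v <- rnorm(50)
  tr <- toy_tracks(list(n1 = v, n2 = 2 * v + 1, c1 = rev(v), c2 = v^3), grp4)
  nt <- normalize_tracks(tr)
  # identical sorted multiset in every line after quantile normalization
  sorted <- apply(nt$signal, 2, sort)
  for (k in 2:4) expect_equal(sorted[, k], sorted[, 1])

  # a window missing in one line disappears from all
  tr_na <- tr
  tr_na$signal[tr_na$cell_line == "c1"][10] <- NA
  nt_na <- normalize_tracks(tr_na)
  expect_equal(nrow(nt_na$windows), 49)
  expect_false(10 %in% (nt_na$windows$start / 5e3 + 1))

  expect_error(
    normalize_tracks(dplyr::filter(tr, cell_line != "n2")),
    "at least 2"
  )
})

test_that("per-window t matches the textbook pooled-variance formula", {
  set.seed(2)
  v <- lapply(setNames(seq_along(grp4), names(grp4)), function(i) rnorm(30))
  nt <- normalize_tracks(toy_tracks(v, grp4))
  ws <- window_ttest(nt)
  # independent oracle: stats::t.test with var.equal on each window
  for (i in c(1, 7, 30)) {
    ref <- t.test(nt$signal[i, c("c1", "c2")], nt$signal[i, c("n1", "n2")],
                  var.equal = TRUE)
    expect_equal(ws$t[i], unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ws$p[i], ref$p.value, tolerance = 1e-12)
  }
  # antisymmetric under swapping group labels
  swapped <- setNames(ifelse(grp4 == "normal", "cancer", "normal"), names(grp4))
  ws_sw <- window_ttest(normalize_tracks(toy_tracks(v, swapped)))
  expect_equal(ws_sw$t, -ws$t)

  # degenerate windows: zero variance in both groups
  flat <- toy_tracks(list(n1 = rep(1, 3), n2 = rep(1, 3),
                          c1 = rep(1, 3), c2 = rep(1, 3)), grp4)
  nt_flat <- normalize_tracks(flat)
  ws_flat <- window_ttest(nt_flat)
  expect_true(all(ws_flat$degenerate))
  expect_equal(ws_flat$t, rep(0, 3))
  expect_equal(ws_flat$p, rep(1, 3))
})

test_that("Fisher combination matches the chi-square oracle and its limits", {
  # k = 2, both P = 0.05
  expect_equal(fisher_combine(c(0.05, 0.05)),
               pchisq(-4 * log(0.05), df = 4, lower.tail = FALSE))
  expect_equal(round(fisher_combine(c(0.05, 0.05)), 5), 0.01748)
  # k = 1: identity
  expect_equal(fisher_combine(0.3), 0.3, tolerance = 1e-12)
  # monotone decreasing in each input
  expect_lt(fisher_combine(c(0.04, 0.2)), fisher_combine(c(0.05, 0.2)))
  # zero input stays finite
  expect_gt(fisher_combine(c(0, 0.5)), 0)
})

test_that("gene-level stats inherit, combine, and classify by sign and Bonferroni", {
  ws <- tibble::tibble(
    chrom = "chr1",
    start = c(0, 5e3, 10e3), end = c(5e3, 10e3, 15e3),
    t = c(-4, -6, 2), p = c(0.01, 0.001, 0.5)
  )
  gm <- tibble::tibble(
    gene_id = c("one_win", "two_win", "none"),
    chrom = "chr1",
    start = c(1000, 4000, 9e5), end = c(2000, 12e3, 9.1e5)
  )
  out <- gene_level_timing(ws, gm, alpha = 0.05)
  one <- out[out$gene_id == "one_win", ]
  expect_equal(one$p_combined, 0.01)
  expect_equal(one$t_mean, -4)
  two <- out[out$gene_id == "two_win", ]
  expect_equal(two$n_windows, 3L)
  expect_equal(two$p_combined, fisher_combine(c(0.01, 0.001, 0.5)))
  expect_equal(two$t_mean, mean(c(-4, -6, 2)))
  # Bonferroni over the 2 tested genes only
  expect_equal(one$p_adj, min(1, 0.01 * 2))
  none <- out[out$gene_id == "none", ]
  expect_equal(none$class, "unclassified")
  expect_true(is.na(none$p_combined))
  expect_equal(one$class, "late_in_cancer")
})

test_that("planted later-replicating genes are recovered; null genes are not", {
  cfg <- simulation_config(
    genome = tibble::tibble(chrom = "chr1", length = 8e6, centromere = 4e6),
    seed = 99
  )
  gm <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:100), chrom = "chr1",
    start = seq(0, 99) * 8e4, end = seq(0, 99) * 8e4 + 4e4
  )
  set.seed(99)
  planted <- gm$gene_id[1:10]
  tr <- simulate_replication_tracks(cfg, gm, late_genes = planted, shift = 2,
                                    n_normal = 4, n_cancer = 4)
  out <- gene_level_timing(window_ttest(normalize_tracks(tr)), gm)
  called_late <- out$gene_id[out$class == "late_in_cancer"]
  expect_gte(length(intersect(called_late, planted)), 9)
  expect_lte(length(setdiff(called_late, planted)), 2)

  # coordinate validation
  bad <- dplyr::mutate(gm[1, ], end = 9e6)
  expect_error(simulate_replication_tracks(cfg, bad), "outside")
})

test_that("interval timing is the overlap-length-weighted window mean", {
  track <- tibble::tibble(
    chrom = "chr1", start = c(0, 5e3, 10e3), end = c(5e3, 10e3, 15e3),
    signal = c(1, 3, 5)
  )
  expect_equal(domain_weighted_timing(track, list(chrom = "chr1", start = 5e3, end = 10e3)), 3)
  expect_equal(domain_weighted_timing(track, list(chrom = "chr1", start = 0, end = 10e3)), 2)
  # half of window 2 and a quarter of window 3: (2500*3 + 1250*5)/3750
  expect_equal(
    domain_weighted_timing(track, list(chrom = "chr1", start = 7.5e3, end = 11.25e3)),
    (2500 * 3 + 1250 * 5) / 3750
  )
  expect_true(is.na(domain_weighted_timing(track, list(chrom = "chr2", start = 0, end = 1e3))))
})
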