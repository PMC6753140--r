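# Shared fixtures, built in code. The default cohort is simulated once per
# test run and memoized; tests that need different parameters simulate their
# own.

.fixture_cache <- new.env(parent = emptyenv())

shared_cohort <- function() {
  if (is.null(.fixture_cache$cohort)) {
    .fixture_cache$cohort <- simulate_cohort(simulation_config(seed = 20260101))
  }
  .fixture_cache$cohort
}

shared_run <- function() {
  if (is.null(.fixture_cache$run)) {
    .fixture_cache$run <- run_pipeline(
      shared_cohort(),
      pipeline_config(n_perm_proximity = 2000, n_perm_enrichment = 1000,
                      seed = 20260101)
    )
  }
  .fixture_cache$run
}

# Minimal manifest for probe-filter tests.
toy_manifest <- function() {
  tibble::tibble(
    probe_id = c("p1", "p2", "p3", "p4", "p5"),
    chrom = "chr1",
    pos = c(100L, 200L, 300L, 400L, 500L),
    cgi_class = "opensea",
    promoter_flag = FALSE,
    repeat_family = c("L1HS", "L1HS", "AluY", "L1PA3", "L1HS"),
    mapped_len = c(46, 44, 50, 50, 45),
    probe_len = c(50, 50, 50, 50, 60)
  )
}

# Beta matrix from a named list of per-probe value vectors.
toy_beta <- function(values, samples = NULL) {
  m <- do.call(rbind, values)
  rownames(m) <- names(values)
  colnames(m) <- if (is.null(samples)) paste0("s", seq_len(ncol(m))) else samples
  m
}

# 100-kb unit domain table from a run-length encoding like
# list(c("HMD", 4), c("PMD", 3), ...) on one chromosome.
toy_domain_units <- function(blocks, chrom = "chr1", unit = 1e5,
                             var_by_type = c(PMD = 0.1, HMD = 0.02),
                             rt_by_type = c(PMD = -1, HMD = 1)) {
  pos <- 0
  rows <- list()
  for (b in blocks) {
    n_units <- as.integer(b[[2]])
    dtype <- b[[1]]
    starts <- pos + unit * (seq_len(n_units) - 1)
    rows[[length(rows) + 1]] <- tibble::tibble(
      chrom = chrom, start = starts, end = starts + unit, dtype = dtype,
      meth_variability = unname(var_by_type[dtype]),
      rt = unname(rt_by_type[dtype])
    )
    pos <- pos + n_units * unit
  }
  out <- dplyr::bind_rows(rows)
  names(out)[names(out) == "rt"] <- "rep_timing"
  out
}

# Best-agreement rate between two labelings up to relabeling (small k).
label_agreement <- function(a, b) {
  la <- unique(a)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    unlist(lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(p) c(v[i], p))
    }), recursive = FALSE)
  }
  best <- 0
  for (p in perms(unique(b))) {
    map <- stats::setNames(p[seq_along(la)], la)
    best <- max(best, mean(map[as.character(a)] == b))
  }
  best
}
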