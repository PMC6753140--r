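#' Default synthetic genome geometry
#'
#' Three autosomes with centromere positions, small enough that every stage of
#' the pipeline runs in seconds but large enough to hold hundreds of
#' methylation domains and genes.
#'
#' @return A tibble with `chrom`, `length`, `centromere`.
#' @export
default_genome <- function() {
  tibble(
    chrom = c("chr1", "chr2", "chr3"),
    length = c(60e6, 50e6, 40e6),
    centromere = c(25e6, 20e6, 18e6)
  )
}

#' Configuration for the synthetic cohort generator
#'
#' The generator plants a single latent per-sample demethylation factor
#' `d ~ Uniform(0, 1)` that couples, with fixed signs, every layer of the
#' bundle: open-sea LINE-1 beta values fall linearly in `d`
#' (`demethylation_effect` per unit `d`), CpG-island promoter probes in short
#' PMDs gain methylation with probability `hyperme_gain_rate * d`, mutation
#' burden has log-mean increasing in `d` (`mutation_link`), arm-scale copy
#' number events become more likely with `d` (`cna_link` on the logit scale),
#' immune-gene expression declines in `d`, and the low-methylation half of the
#' cohort carries `planted_hr` times the baseline hazard. Effect sizes are free
#' parameters of the generator, not claims about biology; the defaults give
#' each downstream stage a clearly detectable but noisy signal at the default
#' cohort size.
#'
#' @param n_samples Number of samples (default 120).
#' @param n_l1_probes LINE-1 (open sea) probes (default 200).
#' @param n_hmd_cgi_probes CpG-island probes inside HMDs (default 150).
#' @param n_shortpmd_promoter_probes Promoter CGI probes inside short PMDs
#'   (default 120).
#' @param n_genes Total genes (default 600).
#' @param n_immune_genes Immune-pathway genes planted inside short PMDs near
#'   HMD boundaries (default 60).
#' @param genome Chromosome geometry table (see [default_genome()]).
#' @param planted_hr Hazard ratio of the low- vs high-methylation group
#'   (default 2).
#' @param beta_noise_sd Gaussian noise SD on beta values (default 0.04);
#'   betas are clamped to \[0.001, 0.999\] afterwards.
#' @param demethylation_effect Open-sea beta drop per unit latent factor
#'   (default 0.25).
#' @param hyperme_gain_rate Per-probe hypermethylation probability per unit
#'   latent factor (default 0.35).
#' @param mutation_link Increase of the log mutation-burden mean over the
#'   latent range (default 1.5).
#' @param cna_link Logit-scale increase of the per-arm event probability over
#'   the latent range (default 2.5).
#' @param l1_base_beta Open-sea beta at `d = 0` (default 0.75).
#' @param base_hazard Daily hazard of the high-methylation group (default
#'   1/400).
#' @param censor_horizon_days Administrative censoring horizon (default 350,
#'   giving roughly 30% censoring at the default hazard).
#' @param rep_shift Replication-timing drop planted in cancer lines over the
#'   immune genes (default 1.5 z units).
#' @param rep_noise_sd Track noise SD (default 0.3).
#' @param rep_missing_rate Fraction of (window, cell line) values emitted
#'   missing (default 0.02).
#' @param seed Integer seed; one generator drives all randomness.
#' @return A validated list of class `methloss_config`.
#' @export
simulation_config <- function(n_samples = 120,
                              n_l1_probes = 200,
                              n_hmd_cgi_probes = 150,
                              n_shortpmd_promoter_probes = 120,
                              n_genes = 600,
                              n_immune_genes = 60,
                              genome = default_genome(),
                              planted_hr = 2,
                              beta_noise_sd = 0.04,
                              demethylation_effect = 0.25,
                              hyperme_gain_rate = 0.35,
                              mutation_link = 1.5,
                              cna_link = 2.5,
                              l1_base_beta = 0.75,
                              base_hazard = 1 / 400,
                              censor_horizon_days = 350,
                              rep_shift = 1.5,
                              rep_noise_sd = 0.3,
                              rep_missing_rate = 0.02,
                              seed = 1234) {
  cfg <- list(
    n_samples = n_samples, n_l1_probes = n_l1_probes,
    n_hmd_cgi_probes = n_hmd_cgi_probes,
    n_shortpmd_promoter_probes = n_shortpmd_promoter_probes,
    n_genes = n_genes, n_immune_genes = n_immune_genes,
    genome = as_tibble(genome), planted_hr = planted_hr,
    beta_noise_sd = beta_noise_sd, demethylation_effect = demethylation_effect,
    hyperme_gain_rate = hyperme_gain_rate, mutation_link = mutation_link,
    cna_link = cna_link, l1_base_beta = l1_base_beta,
    base_hazard = base_hazard, censor_horizon_days = censor_horizon_days,
    rep_shift = rep_shift, rep_noise_sd = rep_noise_sd,
    rep_missing_rate = rep_missing_rate, seed = seed
  )
  for (f in c("n_samples", "n_l1_probes", "n_hmd_cgi_probes",
              "n_shortpmd_promoter_probes", "n_genes", "n_immune_genes",
              "planted_hr", "base_hazard", "censor_horizon_days")) {
    check_positive(cfg[[f]], f)
  }
  for (f in c("beta_noise_sd", "demethylation_effect", "hyperme_gain_rate",
              "mutation_link", "cna_link", "rep_noise_sd", "rep_missing_rate")) {
    if (length(cfg[[f]]) != 1 || !is.finite(cfg[[f]]) || cfg[[f]] < 0) {
      abort(paste0("invalid configuration: `", f, "` must be a single non-negative number"))
    }
  }
  if (cfg$n_immune_genes >= cfg$n_genes) {
    abort("invalid configuration: `n_immune_genes` must be smaller than `n_genes`")
  }
  g <- cfg$genome
  if (!all(c("chrom", "length", "centromere") %in% names(g))) {
    abort("invalid configuration: `genome` needs chrom, length, centromere")
  }
  if (any(g$centromere <= 0) || any(g$length <= g$centromere)) {
    abort("invalid configuration: `genome` requires length > centromere > 0")
  }
  if (length(seed) != 1 || !is.finite(seed)) {
    abort("invalid configuration: `seed` must be a single integer")
  }
  structure(cfg, class = "methloss_config")
}

# 100-kb unit layout: alternating HMD / PMD blocks along each chromosome.
# Returns unit-level domain rows plus a hidden truth table of merged blocks.
simulate_domain_layout <- function(genome) {
  unit <- 1e5
  block_features <- list(
    HMD = list(var = 0.02, rt = 1.2),
    short = list(var = 0.05, rt = 0.6),
    mid = list(var = 0.09, rt = -0.3),
    long = list(var = 0.14, rt = -1.2)
  )
  units <- list()
  truth <- list()
  for (ci in seq_len(nrow(genome))) {
    chrom <- genome$chrom[ci]
    len <- genome$length[ci]
    pos <- 0
    hmd_turn <- TRUE
    while (pos < len - 5 * unit) {
      if (hmd_turn) {
        cls <- "HMD"
        n_units <- sample(8:20, 1)
      } else {
        cls <- sample(c("short", "mid", "long"), 1, prob = c(0.4, 0.35, 0.25))
        n_units <- switch(cls,
          short = sample(4:6, 1),
          mid = sample(8:12, 1),
          long = sample(15:30, 1)
        )
      }
      n_units <- min(n_units, floor((len - pos) / unit))
      if (n_units < 1) break
      start <- pos + unit * (seq_len(n_units) - 1)
      fb <- block_features[[cls]]
      block_var <- rnorm(1, fb$var, ifelse(cls == "HMD", 0.003, 0.004))
      block_rt <- rnorm(1, fb$rt, 0.08)
      units[[length(units) + 1]] <- tibble(
        chrom = chrom, start = start, end = start + unit,
        dtype = ifelse(cls == "HMD", "HMD", "PMD"),
        meth_variability = pmax(0.001, block_var + rnorm(n_units, 0, 0.002)),
        rep_timing = block_rt + rnorm(n_units, 0, 0.02)
      )
      truth[[length(truth) + 1]] <- tibble(
        chrom = chrom, start = pos, end = pos + n_units * unit, class = cls
      )
      pos <- pos + n_units * unit
      hmd_turn <- !hmd_turn
    }
  }
  list(units = bind_rows(units), truth = bind_rows(truth))
}

#' Simulate a full multi-omic cohort bundle
#'
#' Generates an internally consistent bundle — probe manifest, beta matrix,
#' domain table (100-kb units), copy-number segments, expression matrix, gene
#' models, replication-timing tracks, and a clinical table — all driven by the
#' planted latent demethylation factor described in [simulation_config()].
#' Output is deterministic given `cfg$seed`; all tables share one set of
#' sample identifiers.
#'
#' @param cfg A `methloss_config` from [simulation_config()].
#' @param include_tracks Also simulate replication-timing tracks (default
#'   `TRUE`; the tracks are the most expensive layer).
#' @return A list of class `methloss_cohort` with elements `config`, `latent`,
#'   `manifest`, `beta`, `domains`, `domain_truth`, `geometry`, `segments`,
#'   `expression`, `gene_models`, `gene_sets`, `clinical`, and `tracks`.
#' @export
simulate_cohort <- function(cfg = simulation_config(), include_tracks = TRUE) {
  if (!inherits(cfg, "methloss_config")) abort("cfg must come from simulation_config()")
  set.seed(cfg$seed)
  n <- cfg$n_samples
  samples <- sprintf("S%04d", seq_len(n))
  d <- runif(n)

  layout <- simulate_domain_layout(cfg$genome)
  units <- layout$units
  truth <- layout$truth
  hmd_blocks <- truth[truth$class == "HMD", ]
  short_blocks <- truth[truth$class == "short", ]
  pmd_blocks <- truth[truth$class != "HMD", ]

  place_in_blocks <- function(blocks, k) {
    idx <- sample.int(nrow(blocks), k, replace = TRUE)
    b <- blocks[idx, ]
    pos <- floor(b$start + runif(k) * (b$end - b$start - 1))
    tibble(chrom = b$chrom, pos = pos)
  }

  # --- probe manifest -------------------------------------------------------
  l1_pos <- place_in_blocks(truth, cfg$n_l1_probes)
  manifest_l1 <- tibble(
    probe_id = sprintf("L1_%04d", seq_len(cfg$n_l1_probes)),
    chrom = l1_pos$chrom, pos = l1_pos$pos,
    cgi_class = "opensea", promoter_flag = FALSE,
    repeat_family = sample(c("L1HS", "L1PA2", "L1PA3"), cfg$n_l1_probes, replace = TRUE),
    probe_len = 50L,
    mapped_len = sample(45:50, cfg$n_l1_probes, replace = TRUE)
  )
  hmd_pos <- place_in_blocks(hmd_blocks, cfg$n_hmd_cgi_probes)
  manifest_hmd <- tibble(
    probe_id = sprintf("HCGI_%04d", seq_len(cfg$n_hmd_cgi_probes)),
    chrom = hmd_pos$chrom, pos = hmd_pos$pos,
    cgi_class = "island",
    promoter_flag = seq_len(cfg$n_hmd_cgi_probes) %% 2 == 0,
    repeat_family = NA_character_, probe_len = 50L, mapped_len = 0L
  )
  sp_pos <- place_in_blocks(short_blocks, cfg$n_shortpmd_promoter_probes)
  manifest_sp <- tibble(
    probe_id = sprintf("SPCGI_%04d", seq_len(cfg$n_shortpmd_promoter_probes)),
    chrom = sp_pos$chrom, pos = sp_pos$pos,
    cgi_class = "island", promoter_flag = TRUE,
    repeat_family = NA_character_, probe_len = 50L, mapped_len = 0L
  )
  n_decoy <- 30L
  decoy_pos <- place_in_blocks(truth, n_decoy)
  manifest_decoy <- tibble(
    probe_id = sprintf("DEC_%04d", seq_len(n_decoy)),
    chrom = decoy_pos$chrom, pos = decoy_pos$pos,
    cgi_class = "opensea", promoter_flag = FALSE,
    repeat_family = rep(c("AluY", "L1PA4", "L1HS"), each = 10),
    probe_len = rep(c(50L, 50L, 60L), each = 10),
    mapped_len = c(rep(50L, 10), sample(20:44, 10, replace = TRUE),
                   sample(45:52, 10, replace = TRUE))
  )
  manifest <- bind_rows(manifest_l1, manifest_hmd, manifest_sp, manifest_decoy)

  # --- beta matrix ----------------------------------------------------------
  noise <- function(nr) matrix(rnorm(nr * n, 0, cfg$beta_noise_sd), nr, n)
  beta_l1 <- matrix(cfg$l1_base_beta - cfg$demethylation_effect * d,
                    cfg$n_l1_probes, n, byrow = TRUE) + noise(cfg$n_l1_probes)
  beta_hmd <- 0.08 + noise(cfg$n_hmd_cgi_probes)
  p_hyper <- clamp(cfg$hyperme_gain_rate * d, 0, 1)
  hyper <- matrix(
    rbinom(cfg$n_shortpmd_promoter_probes * n, 1,
           rep(p_hyper, each = cfg$n_shortpmd_promoter_probes)),
    cfg$n_shortpmd_promoter_probes, n
  )
  beta_sp <- ifelse(hyper == 1, 0.55, 0.08) + noise(cfg$n_shortpmd_promoter_probes)
  decoy_base <- runif(n_decoy, 0.2, 0.8)
  beta_decoy <- matrix(decoy_base, n_decoy, n) + noise(n_decoy)
  beta <- clamp(rbind(beta_l1, beta_hmd, beta_sp, beta_decoy), 0.001, 0.999)
  dimnames(beta) <- list(manifest$probe_id, samples)

  # --- gene models ----------------------------------------------------------
  imm_idx <- sample.int(nrow(short_blocks), cfg$n_immune_genes, replace = TRUE)
  imm_blocks <- short_blocks[imm_idx, ]
  imm_offset <- floor(runif(cfg$n_immune_genes, 2e4, 1.2e5))
  imm_len <- floor(runif(cfg$n_immune_genes, 5e3, 3e4))
  genes_imm <- tibble(
    gene_id = sprintf("IMM_%03d", seq_len(cfg$n_immune_genes)),
    chrom = imm_blocks$chrom,
    start = imm_blocks$start + imm_offset,
    end = pmin(imm_blocks$start + imm_offset + imm_len, imm_blocks$end - 1)
  )
  n_pmd_other <- min(180L, cfg$n_genes - cfg$n_immune_genes)
  deep_blocks <- truth[truth$class %in% c("mid", "long"), ]
  po_idx <- sample.int(nrow(deep_blocks), n_pmd_other, replace = TRUE)
  po_blocks <- deep_blocks[po_idx, ]
  po_len <- floor(runif(n_pmd_other, 5e3, 5e4))
  po_start <- floor(po_blocks$start +
                      runif(n_pmd_other) * (po_blocks$end - po_blocks$start - po_len - 1))
  genes_pmd <- tibble(
    gene_id = sprintf("PMDG_%03d", seq_len(n_pmd_other)),
    chrom = po_blocks$chrom, start = po_start, end = po_start + po_len
  )
  n_other <- cfg$n_genes - cfg$n_immune_genes - n_pmd_other
  ci <- sample.int(nrow(cfg$genome), n_other, replace = TRUE)
  o_len <- floor(runif(n_other, 5e3, 8e4))
  o_start <- floor(runif(n_other) * (cfg$genome$length[ci] - o_len - 1))
  genes_other <- tibble(
    gene_id = sprintf("G_%04d", seq_len(n_other)),
    chrom = cfg$genome$chrom[ci], start = o_start, end = o_start + o_len
  )
  gene_models <- bind_rows(genes_imm, genes_pmd, genes_other) |>
    arrange(.data$chrom, .data$start)
  in_pmd <- IRanges::overlapsAny(intervals_to_gr(gene_models),
                                 intervals_to_gr(pmd_blocks))
  gene_sets <- list(
    immune = genes_imm$gene_id,
    pmd_universe = gene_models$gene_id[in_pmd]
  )

  # --- expression -----------------------------------------------------------
  mu_g <- runif(cfg$n_genes, 4, 10)
  slope <- ifelse(gene_models$gene_id %in% gene_sets$immune, -2, 0)
  mu_order <- match(gene_models$gene_id, c(genes_imm$gene_id, genes_pmd$gene_id,
                                           genes_other$gene_id))
  mu_g <- mu_g[mu_order]
  expression <- matrix(mu_g, cfg$n_genes, n) +
    outer(slope, d) +
    matrix(rnorm(cfg$n_genes * n, 0, 0.5), cfg$n_genes, n)
  dimnames(expression) <- list(gene_models$gene_id, samples)

  # --- mutation burden, clinical covariates ---------------------------------
  mutation_burden <- rpois(n, exp(log(30) + cfg$mutation_link * d))
  purity <- runif(n, 0.3, 0.9)
  age <- round(runif(n, 40, 80))
  stage <- sample(1:4, n, replace = TRUE)

  # --- copy number segments -------------------------------------------------
  arms <- bind_rows(
    tibble(chrom = cfg$genome$chrom, start = 0, end = cfg$genome$centromere),
    tibble(chrom = cfg$genome$chrom, start = cfg$genome$centromere,
           end = cfg$genome$length)
  )
  # one candidate slot per (sample, arm): an arm-scale event with probability
  # increasing in d, otherwise (half the time) sub-threshold clutter that is
  # either too small or too flat to qualify; at most one segment per arm, so
  # segments never overlap within a sample
  p_event <- plogis(-2 + cfg$cna_link * d)
  na <- nrow(arms)
  nc <- n * na
  arm_len <- rep(arms$end - arms$start, times = n)
  arm_start <- rep(arms$start, times = n)
  is_event <- rbinom(nc, 1, rep(p_event, each = na)) == 1
  is_clutter <- !is_event & rbinom(nc, 1, 0.5) == 1
  small <- rbinom(nc, 1, 0.5) == 1
  seg_len <- ifelse(is_event, floor(runif(nc, 0.3, 0.9) * arm_len),
                    ifelse(small, floor(runif(nc, 2e5, 9e5)), floor(0.4 * arm_len)))
  sgn <- sample(c(-1, 1), nc, replace = TRUE)
  lr <- ifelse(is_event, sgn * runif(nc, 0.25, 0.7),
               ifelse(small, sgn * runif(nc, 0.25, 0.6),
                      sgn * runif(nc, 0.05, 0.15)))
  s0 <- arm_start + floor(runif(nc) * (arm_len - seg_len))
  keep <- is_event | is_clutter
  segments <- tibble(
    sample_id = rep(samples, each = na)[keep],
    chrom = rep(arms$chrom, times = n)[keep],
    start = s0[keep],
    end = (s0 + seg_len)[keep],
    log2_ratio = lr[keep]
  )

  # --- survival and response ------------------------------------------------
  score <- colMeans(beta[manifest_l1$probe_id, , drop = FALSE])
  group <- ifelse(score <= median(score), "low", "high")
  hazard <- cfg$base_hazard * ifelse(group == "low", cfg$planted_hr, 1)
  t_event <- rexp(n, hazard)
  pfs_time <- pmin(t_event, cfg$censor_horizon_days)
  event <- t_event <= cfg$censor_horizon_days

  p_dcb <- plogis(1.2 - 2.2 * d)
  dcb <- rbinom(n, 1, p_dcb) == 1
  pr_like <- rbinom(n, 1, 0.7) == 1
  best_response <- ifelse(dcb, ifelse(pr_like, "PR", "SD"),
                          ifelse(pr_like, "PD", "SD"))
  response_duration <- ifelse(best_response == "SD",
                              ifelse(dcb, runif(n, 7, 18), runif(n, 1, 6)),
                              NA_real_)
  response <- classify_response(best_response, response_duration)

  clinical <- tibble(
    sample_id = samples,
    pfs_time = pfs_time,
    event = event,
    best_response = best_response,
    response_duration_months = response_duration,
    response = response,
    mutation_burden = mutation_burden,
    purity = purity, age = age, stage = stage
  )

  tracks <- NULL
  if (include_tracks) {
    tracks <- simulate_replication_tracks(
      cfg, gene_models, late_genes = gene_sets$immune
    )
  }

  structure(
    list(
      config = cfg,
      latent = tibble(sample_id = samples, d = d, group = group),
      manifest = manifest,
      beta = beta,
      domains = units,
      domain_truth = truth,
      geometry = cfg$genome,
      segments = segments,
      expression = expression,
      gene_models = gene_models,
      gene_sets = gene_sets,
      clinical = clinical,
      tracks = tracks
    ),
    class = "methloss_cohort"
  )
}

#' Simulate replication-timing tracks for pseudo cell lines
#'
#' Emits wavelet-style smoothed replication-timing signal on a 5-kb grid for
#' `n_normal` normal and `n_cancer` cancer pseudo cell lines: a shared smooth
#' genomic profile plus line-specific noise. Windows overlapping `late_genes`
#' have their cancer signal shifted down by `shift` (later replication in
#' cancer); all other windows are null. A fraction of (window, cell line)
#' values is emitted as missing so that downstream exclusion of incomplete
#' windows is exercised.
#'
#' Note: this function draws from the R random number stream; seed it (or call
#' it inside [simulate_cohort()], which seeds everything once).
#'
#' @param cfg A `methloss_config`.
#' @param gene_models Gene models within `cfg$genome` (coordinate error
#'   otherwise).
#' @param late_genes Gene ids planted as later-replicating in cancer (default
#'   none).
#' @param shift Planted cancer-minus-normal signal shift (default
#'   `cfg$rep_shift`).
#' @param n_normal,n_cancer Number of cell lines per group (defaults 4).
#' @return A long tibble with `chrom`, `start`, `end`, `cell_line`, `group`,
#'   `signal` (`NA` = missing).
#' @export
simulate_replication_tracks <- function(cfg, gene_models, late_genes = character(),
                                        shift = cfg$rep_shift,
                                        n_normal = 4, n_cancer = 4) {
  check_intervals(gene_models, "gene models")
  gl <- cfg$genome$length[match(gene_models$chrom, cfg$genome$chrom)]
  if (anyNA(gl) || any(gene_models$end > gl)) {
    bad <- gene_models$gene_id[is.na(gl) | gene_models$end > gl]
    abort(paste0("gene(s) outside the configured genome: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  win <- 5e3
  windows <- bind_rows(lapply(seq_len(nrow(cfg$genome)), function(ci) {
    starts <- seq(0, cfg$genome$length[ci] - win, by = win)
    tibble(chrom = cfg$genome$chrom[ci], start = starts, end = starts + win)
  }))
  nw <- nrow(windows)
  base <- sin(2 * pi * windows$start / 1e7) +
    0.3 * sin(2 * pi * windows$start / 2.3e6)
  late_models <- gene_models[gene_models$gene_id %in% late_genes, , drop = FALSE]
  shifted <- if (nrow(late_models)) {
    IRanges::overlapsAny(intervals_to_gr(windows), intervals_to_gr(late_models))
  } else {
    rep(FALSE, nw)
  }
  lines <- c(sprintf("normal_%d", seq_len(n_normal)),
             sprintf("cancer_%d", seq_len(n_cancer)))
  groups <- rep(c("normal", "cancer"), c(n_normal, n_cancer))
  out <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    sig <- base + rnorm(nw, 0, cfg$rep_noise_sd)
    if (groups[k] == "cancer") sig <- sig - shift * shifted
    if (cfg$rep_missing_rate > 0) {
      sig[runif(nw) < cfg$rep_missing_rate] <- NA_real_
    }
    out[[k]] <- tibble(
      chrom = windows$chrom, start = windows$start, end = windows$end,
      cell_line = lines[k], group = groups[k], signal = sig
    )
  }
  bind_rows(out)
}

#' @export
print.methloss_cohort <- function(x, ...) {
  cat("Synthetic cohort: ", x$config$n_samples, " samples, ",
      nrow(x$manifest), " probes, ", nrow(x$gene_models), " genes, ",
      nrow(x$domains), " domain units (seed ", x$config$seed, ")\n", sep = "")
  invisible(x)
}
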