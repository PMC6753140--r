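# Readers and writers for the plain-text formats the pipeline consumes:
# TSV tables, BED-like domain/gene files and bedGraph tracks.
# All genomic coordinates are 0-based half-open on disk and in memory.

#' Read a beta-value matrix from TSV/CSV
#'
#' @param path File with a probe-id first column and one column per sample.
#' @param delim Field delimiter (default tab).
#' @return Probes x samples numeric matrix with probe ids as rownames.
#' @export
read_beta_matrix <- function(path, delim = "\t") {
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  check_beta_range(as_beta_matrix(df))
}

#' Read a probe manifest TSV
#' @param path File with columns `probe_id`, `chrom`, `pos`, `cgi_class`,
#'   `promoter_flag`, `repeat_family`, `mapped_len`, `probe_len`.
#' @return A tibble.
#' @export
read_probe_manifest <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Read a BED6+2 domain file (name column = dtype, then variability, timing)
#' @param path BED-like file: chrom, start, end, dtype, meth_variability,
#'   rep_timing (no header).
#' @return A tibble usable by [merge_domains()].
#' @export
read_domains_bed <- function(path) {
  readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "dtype", "meth_variability", "rep_timing"),
    show_col_types = FALSE
  )
}

#' Read gene models from BED4
#' @param path BED file: chrom, start, end, gene_id (no header).
#' @return A tibble with `gene_id`, `chrom`, `start`, `end`.
#' @export
read_gene_models_bed <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end", "gene_id"),
                  show_col_types = FALSE)[, c("gene_id", "chrom", "start", "end")]
}

#' Read a SEG-like copy number segment table
#' @param path TSV with header: sample_id, chrom, start, end, log2_ratio.
#' @return A tibble.
#' @export
read_segments <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Read a clinical TSV
#'
#' Expected columns: `sample_id`, `pfs_time` (days), `event` (0/1 or logical)
#' and optionally `best_response`, `response_duration_months`, `response`,
#' `mutation_burden`, `purity`, `age`, `stage`.
#' @param path TSV path.
#' @return A tibble.
#' @export
read_clinical <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Read replication-timing bedGraph files, one per cell line
#'
#' @param paths Named character vector of bedGraph paths; names are cell-line
#'   labels.
#' @param groups Named character vector mapping cell-line labels to
#'   `"normal"`/`"cancer"`.
#' @return Long tibble for [normalize_tracks()].
#' @export
read_bedgraph_tracks <- function(paths, groups) {
  miss <- setdiff(names(paths), names(groups))
  if (length(miss)) abort(paste0("no group for cell line(s): ", paste(miss, collapse = ", ")))
  bind_rows(lapply(names(paths), function(line) {
    df <- readr::read_tsv(paths[[line]],
                          col_names = c("chrom", "start", "end", "signal"),
                          show_col_types = FALSE)
    df$cell_line <- line
    df$group <- unname(groups[[line]])
    df
  }))
}

#' Write a simulated cohort bundle to plain-text files
#'
#' Emits the manifest (TSV), beta matrix (TSV, probes x samples), domains
#' (BED6+2), segments (SEG-like TSV), gene models (BED4), expression (TSV),
#' clinical table (TSV), genome geometry (TSV) and one bedGraph per cell
#' line. Coordinates are 0-based half-open.
#'
#' @param bundle A `methloss_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(bundle, dir) {
  if (!inherits(bundle, "methloss_cohort")) abort("bundle must come from simulate_cohort()")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(name) file.path(dir, name)
  written <- character()
  w <- function(x, name, ...) {
    readr::write_tsv(x, fp(name), ...)
    written <<- c(written, fp(name))
  }
  w(bundle$manifest, "probe_manifest.tsv")
  beta_df <- bind_cols(tibble(probe_id = rownames(bundle$beta)),
                       as_tibble(bundle$beta))
  w(beta_df, "beta_matrix.tsv")
  w(bundle$domains[, c("chrom", "start", "end", "dtype",
                       "meth_variability", "rep_timing")],
    "domains.bed", col_names = FALSE)
  w(bundle$segments, "segments.seg")
  w(bundle$gene_models[, c("chrom", "start", "end", "gene_id")],
    "gene_models.bed", col_names = FALSE)
  expr_df <- bind_cols(tibble(gene_id = rownames(bundle$expression)),
                       as_tibble(bundle$expression))
  w(expr_df, "expression.tsv")
  w(bundle$clinical, "clinical.tsv")
  w(bundle$geometry, "genome.tsv")
  readr::write_lines(bundle$gene_sets$immune, fp("immune_genes.txt"))
  written <- c(written, fp("immune_genes.txt"))
  if (!is.null(bundle$tracks)) {
    for (line in unique(bundle$tracks$cell_line)) {
      tr <- bundle$tracks[bundle$tracks$cell_line == line,
                          c("chrom", "start", "end", "signal")]
      w(tr, paste0("repliseq_", line, ".bedGraph"), col_names = FALSE)
    }
  }
  invisible(written)
}
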