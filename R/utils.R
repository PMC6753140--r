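# Internal helpers shared across modules.

# Coerce a beta-value container to a numeric matrix (probes x samples).
# Accepts a matrix with rownames, or a data frame whose first column (or a
# column named `probe_id`) holds probe identifiers.
as_beta_matrix <- function(beta) {
  if (is.matrix(beta)) {
    if (is.null(rownames(beta))) {
      abort("beta matrix must carry probe ids as rownames")
    }
    storage.mode(beta) <- "double"
    return(beta)
  }
  if (is.data.frame(beta)) {
    id_col <- if ("probe_id" %in% names(beta)) "probe_id" else names(beta)[1]
    ids <- as.character(beta[[id_col]])
    m <- as.matrix(beta[setdiff(names(beta), id_col)])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    return(m)
  }
  abort("beta must be a matrix or a data frame")
}

# Same idea for expression matrices (genes x samples).
as_expr_matrix <- function(expr) {
  if (is.matrix(expr)) {
    if (is.null(rownames(expr))) abort("expression matrix must carry gene ids as rownames")
    storage.mode(expr) <- "double"
    return(expr)
  }
  if (is.data.frame(expr)) {
    id_col <- if ("gene_id" %in% names(expr)) "gene_id" else names(expr)[1]
    ids <- as.character(expr[[id_col]])
    m <- as.matrix(expr[setdiff(names(expr), id_col)])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    return(m)
  }
  abort("expression must be a matrix or a data frame")
}

check_beta_range <- function(m) {
  v <- m[!is.na(m)]
  if (length(v) && (min(v) < 0 || max(v) > 1)) {
    abort("beta values must lie in [0, 1]")
  }
  invisible(m)
}

# Validate a domain/gene interval table: 0-based half-open coordinates.
check_intervals <- function(df, what = "interval table", require_sorted = FALSE) {
  need <- c("chrom", "start", "end")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(paste0(what, " is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (any(df$end <= df$start)) abort(paste0(what, ": every interval must have end > start"))
  if (any(df$start < 0)) abort(paste0(what, ": starts must be >= 0"))
  invisible(df)
}

# GRanges from a 0-based half-open table.
intervals_to_gr <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Stop with a configuration error naming the offending field.
check_positive <- function(value, field) {
  if (length(value) != 1 || !is.finite(value) || value <= 0) {
    abort(paste0("invalid configuration: `", field, "` must be a single positive number"))
  }
  invisible(value)
}
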