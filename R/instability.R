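#' Flag copy-number segments that qualify as arm/chromosome-scale events
#'
#' A segment counts toward the aneuploidy level when its absolute log2 ratio
#' reaches `threshold` and it is large: covering at least `arm_frac` of some
#' chromosome arm, or at least `chrom_frac` of the whole chromosome. Arms are
#' split at the centromere given in the geometry table.
#'
#' @param segments Data frame with `sample_id`, `chrom`, `start`, `end`
#'   (0-based half-open) and `log2_ratio`.
#' @param geometry Data frame with `chrom`, `length`, `centromere`.
#' @param threshold Absolute log2-ratio cutoff (default 0.2).
#' @param arm_frac Minimum covered fraction of an arm (default 0.10).
#' @param chrom_frac Minimum segment length as a fraction of the chromosome
#'   (default 0.05).
#' @param inclusive Compare `|log2| >= threshold` (default) rather than `>`.
#'
#' @return The segment tibble with logical columns `amplitude_ok`, `size_ok`
#'   and `qualifies`.
#' @export
call_qualifying_segments <- function(segments, geometry, threshold = 0.2,
                                     arm_frac = 0.10, chrom_frac = 0.05,
                                     inclusive = TRUE) {
  check_intervals(segments, "segment table")
  if (!all(c("sample_id", "log2_ratio") %in% names(segments))) {
    abort("segment table needs sample_id and log2_ratio")
  }
  unknown <- setdiff(unique(segments$chrom), geometry$chrom)
  if (length(unknown)) {
    abort(paste0("segment chromosome(s) absent from geometry: ",
                 paste(unknown, collapse = ", ")))
  }
  if (any(geometry$centromere <= 0 | geometry$centromere >= geometry$length)) {
    abort("geometry: centromere must satisfy 0 < centromere < length")
  }
  geo <- geometry[match(segments$chrom, geometry$chrom), ]
  seg_len <- segments$end - segments$start
  # intersection of [start, end) with p arm [0, cen) and q arm [cen, length)
  p_ov <- pmax(0, pmin(segments$end, geo$centromere) - segments$start)
  q_ov <- pmax(0, segments$end - pmax(segments$start, geo$centromere))
  p_len <- geo$centromere
  q_len <- geo$length - geo$centromere
  amplitude_ok <- if (inclusive) abs(segments$log2_ratio) >= threshold else
    abs(segments$log2_ratio) > threshold
  size_ok <- (p_ov >= arm_frac * p_len) | (q_ov >= arm_frac * q_len) |
    (seg_len >= chrom_frac * geo$length)
  out <- as_tibble(segments)
  out$amplitude_ok <- amplitude_ok
  out$size_ok <- size_ok
  out$qualifies <- amplitude_ok & size_ok
  out
}

#' Length-weighted aneuploidy level per sample
#'
#' The aneuploidy level is the sum, over qualifying segments, of the absolute
#' segment log2 ratio weighted by segment length. Weights are normalized by
#' the total autosome length in the geometry so the score does not depend on
#' genome size; all downstream uses are rank- or threshold-based, so only the
#' scale changes. Sex chromosomes are excluded by default.
#'
#' @param flagged Output of [call_qualifying_segments()] (or any segment table
#'   with a logical `qualifies` column). Samples present in the table but with
#'   no qualifying segment get level 0.
#' @param geometry Chromosome geometry table.
#' @param exclude_chroms Chromosome names dropped from both the numerator and
#'   the normalizing length (default sex chromosomes).
#'
#' @return A tibble with `sample_id`, `level`, `n_qualifying_segments`.
#' @export
aneuploidy_level <- function(flagged, geometry,
                             exclude_chroms = c("chrX", "chrY", "X", "Y")) {
  if (!"qualifies" %in% names(flagged)) {
    abort("run call_qualifying_segments() first: `qualifies` column missing")
  }
  auto <- geometry[!geometry$chrom %in% exclude_chroms, , drop = FALSE]
  total_len <- sum(auto$length)
  if (total_len <= 0) abort("geometry has no autosomal length")
  keep <- flagged$qualifies & !flagged$chrom %in% exclude_chroms
  q <- flagged[keep, , drop = FALSE]
  contrib <- abs(q$log2_ratio) * (q$end - q$start) / total_len
  per <- tapply(contrib, q$sample_id, sum)
  cnt <- tapply(rep(1L, nrow(q)), q$sample_id, sum)
  all_samples <- unique(flagged$sample_id)
  tibble(
    sample_id = all_samples,
    level = as.numeric(ifelse(is.na(per[all_samples]), 0, per[all_samples])),
    n_qualifying_segments = as.integer(ifelse(is.na(cnt[all_samples]), 0L, cnt[all_samples]))
  )
}
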