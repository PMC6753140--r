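# ggplot2 displays for the main result types.

#' @method autoplot methloss_km
#' @export
autoplot.methloss_km <- function(object, ...) {
  curves <- object$curves |>
    group_by(.data$group) |>
    dplyr::group_modify(~ bind_rows(
      tibble(time = 0, surv = 1, n_censor = 0), .x[, c("time", "surv", "n_censor")]
    )) |>
    ungroup()
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$time, y = .data$surv,
                                       colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = dplyr::filter(curves, .data$n_censor > 0),
                        shape = 3, show.legend = FALSE) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Time (days)", y = "Progression-free survival",
      colour = "Global methylation",
      subtitle = sprintf("log-rank P = %.3g, HR (low vs high) = %.2f",
                         object$logrank_p, object$hr)
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot methloss_proximity
#' @export
autoplot.methloss_proximity <- function(object, ...) {
  ggplot2::ggplot(tibble(null = object$null_means / 1e3),
                  ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed_mean_distance / 1e3,
                        colour = "red") +
    ggplot2::labs(
      x = "Mean distance to nearest HMD (kb)", y = "Permutations",
      subtitle = sprintf("observed = %.0f kb, empirical P = %.3g",
                         object$observed_mean_distance / 1e3, object$p_empirical)
    ) +
    ggplot2::theme_minimal()
}

#' Running-sum plot for one gene set of an enrichment result
#'
#' @param object A `methloss_enrichment` result.
#' @param set_id Which set to draw (default the first).
#' @param ... Unused.
#' @method autoplot methloss_enrichment
#' @export
autoplot.methloss_enrichment <- function(object, set_id = object$set_id[1], ...) {
  s <- attr(object, "ranked_scores")
  genes <- attr(object, "sets")[[set_id]]
  in_set <- names(s) %in% genes
  n <- length(s)
  m <- sum(in_set)
  w <- abs(s)
  nr <- sum(w[in_set])
  running <- cumsum(ifelse(in_set, w / nr, -1 / max(n - m, 1)))
  df <- tibble(rank = seq_len(n), running = running)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$running)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_rug(data = df[in_set, ], sides = "b", length = ggplot2::unit(0.02, "npc")) +
    ggplot2::labs(
      x = "Gene rank", y = "Running enrichment score",
      subtitle = sprintf("%s: ES = %.2f, NES = %.2f, FDR = %.2g", set_id,
                         object$es[object$set_id == set_id],
                         object$nes[object$set_id == set_id],
                         object$fdr[object$set_id == set_id])
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot methloss_pmd_clusters
#' @export
autoplot.methloss_pmd_clusters <- function(object, ...) {
  df <- tidy(object)
  df$cluster <- factor(df$cluster)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$meth_variability, y = .data$rep_timing,
                                   colour = .data$cluster, size = .data$length / 1e6)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "Methylation variability", y = "Replication timing",
                  colour = "PMD subclass", size = "Length (Mb)") +
    ggplot2::theme_minimal()
}

#' Scatter of the global methylation score against another per-sample feature
#'
#' @param features Data frame with `global_methylation` and `feature` columns.
#' @param feature Column name to plot against the score.
#' @return A ggplot object.
#' @export
plot_score_association <- function(features, feature) {
  ggplot2::ggplot(features, ggplot2::aes(x = .data$global_methylation,
                                         y = .data[[feature]])) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "Global LINE-1 methylation", y = feature) +
    ggplot2::theme_minimal()
}
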