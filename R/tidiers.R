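# broom-style tidy()/glance() methods for the fitted-result classes.

#' @method tidy methloss_km
#' @export
tidy.methloss_km <- function(x, ...) x$curves

#' @method glance methloss_km
#' @export
glance.methloss_km <- function(x, ...) {
  tibble(
    n = x$n, n_events = x$n_events,
    logrank_chisq = x$logrank_chisq, logrank_p = x$logrank_p,
    hr_low_vs_high = x$hr, hr_conf_low = x$hr_ci[1], hr_conf_high = x$hr_ci[2]
  )
}

#' @method tidy methloss_cox
#' @export
tidy.methloss_cox <- function(x, ...) x$coefficients

#' @method glance methloss_cox
#' @export
glance.methloss_cox <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events,
         loglik_null = x$loglik[1], loglik = x$loglik[2])
}

#' @method tidy methloss_logistic
#' @export
tidy.methloss_logistic <- function(x, ...) x$coefficients

#' @method glance methloss_logistic
#' @export
glance.methloss_logistic <- function(x, ...) {
  tibble(n = x$n, n_dcb = x$n_dcb,
         deviance = x$fit$deviance, aic = x$fit$aic)
}

#' @method tidy methloss_enrichment
#' @export
tidy.methloss_enrichment <- function(x, ...) {
  as_tibble(x)
}

#' @method tidy methloss_proximity
#' @export
tidy.methloss_proximity <- function(x, ...) {
  tibble(
    observed_mean_distance = x$observed_mean_distance,
    null_mean = mean(x$null_means),
    p_empirical = x$p_empirical,
    n_perm = x$n_perm,
    n_genes = x$n_genes
  )
}

#' @method tidy methloss_gene_lm
#' @export
tidy.methloss_gene_lm <- function(x, ...) as_tibble(x)

#' @method glance methloss_gene_lm
#' @export
glance.methloss_gene_lm <- function(x, ...) {
  tibble(
    n_genes = length(unique(x$gene_id)),
    n_samples = attr(x, "n_samples"),
    terms = paste(attr(x, "terms"), collapse = "+")
  )
}

#' @method tidy methloss_pmd_clusters
#' @export
tidy.methloss_pmd_clusters <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "methloss_pmd_clusters")
  out
}

#' @method glance methloss_pmd_clusters
#' @export
glance.methloss_pmd_clusters <- function(x, ...) {
  med <- attr(x, "median_length")
  tibble(
    k = attr(x, "k"),
    short_cluster = attr(x, "short_cluster"),
    n_pmds = nrow(x),
    median_length_short = unname(min(med))
  )
}
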