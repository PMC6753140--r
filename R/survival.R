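#' Convert months to days
#'
#' Follow-up is kept internally in days; month-based cutoffs use the mean
#' Gregorian month of 30.44 days.
#' @param months Numeric vector.
#' @return Days.
#' @export
months_to_days <- function(months) months * 30.44

#' Classify best overall response into durable clinical benefit
#'
#' Maps RECIST best-response labels to durable clinical benefit (DCB) versus
#' no durable benefit (NDB): complete or partial response is DCB, stable
#' disease is DCB only when it lasted more than `cutoff_months`, progressive
#' disease is NDB.
#'
#' @param label Character vector with values in `CR`, `PR`, `SD`, `PD`.
#' @param duration_months Numeric vector; required (non-missing) for `SD`.
#' @param cutoff_months Durability cutoff for stable disease (default 6).
#' @return Character vector of `"DCB"` / `"NDB"`.
#' @export
classify_response <- function(label, duration_months = NA_real_, cutoff_months = 6) {
  duration_months <- rep_len(duration_months, length(label))
  unknown <- setdiff(unique(label), c("CR", "PR", "SD", "PD"))
  if (length(unknown)) {
    abort(paste0("unknown response label(s): ", paste(unknown, collapse = ", ")))
  }
  if (any(label == "SD" & is.na(duration_months))) {
    abort("duration_months required for every SD response")
  }
  ifelse(label %in% c("CR", "PR"), "DCB",
    ifelse(label == "PD", "NDB",
      ifelse(duration_months > cutoff_months, "DCB", "NDB")
    )
  )
}

#' Stratify samples by a per-sample score
#'
#' Median rule: samples at or below the median go to the low group, the rest
#' to the high group (ties at the median go low; configurable via
#' `ties`). Percentile rule: below the `p_low` percentile is low, above the
#' `p_high` percentile is high, the middle is excluded (`NA` group). Both
#' rules are rank-based and therefore invariant to strictly monotone
#' transforms of the score.
#'
#' @param scores Data frame with `sample_id` and a score column, or a named
#'   numeric vector.
#' @param rule `"median"` (default) or `"percentile"`.
#' @param score Name of the score column (default `"score"`).
#' @param p_low,p_high Percentile cuts for the percentile rule (defaults 30
#'   and 70).
#' @param ties For the median rule, whether scores exactly at the median go
#'   `"low"` (default) or `"high"`.
#' @return A tibble with `sample_id`, `score`, `group` (`low`/`high`/`NA`).
#' @export
stratify <- function(scores, rule = c("median", "percentile"), score = "score",
                     p_low = 30, p_high = 70, ties = c("low", "high")) {
  rule <- match.arg(rule)
  ties <- match.arg(ties)
  if (is.numeric(scores) && !is.null(names(scores))) {
    scores <- tibble(sample_id = names(scores), score = unname(scores))
    score <- "score"
  }
  s <- scores[[score]]
  if (length(s) < 2) abort("need at least 2 samples to stratify")
  if (sd(s) == 0) abort("degenerate split: all scores identical")
  if (rule == "median") {
    med <- median(s)
    g <- if (ties == "low") ifelse(s <= med, "low", "high") else
      ifelse(s < med, "low", "high")
  } else {
    lo <- quantile(s, p_low / 100)
    hi <- quantile(s, p_high / 100)
    g <- ifelse(s < lo, "low", ifelse(s > hi, "high", NA))
  }
  tibble(sample_id = scores$sample_id, score = s, group = g)
}

#' Kaplan-Meier curves and log-rank test for a two-group stratification
#'
#' Product-limit survival estimate per group and the two-group log-rank test
#' (1 degree of freedom); censored subjects contribute to risk sets up to
#' their last follow-up. A Cox model on the group indicator provides the
#' hazard ratio of the low relative to the high group with a Wald confidence
#' interval.
#'
#' @param clinical Data frame with `sample_id`, `pfs_time` (> 0) and `event`
#'   (logical or 0/1; `TRUE` = progressed/died).
#' @param groups Data frame with `sample_id`, `group` (`low`/`high`); samples
#'   with `NA` group are dropped.
#' @return An object of class `methloss_km` with the KM curve tibble, log-rank
#'   chi-square and P, and the low-vs-high hazard ratio with CI.
#' @export
km_logrank <- function(clinical, groups) {
  if (any(clinical$pfs_time <= 0)) abort("pfs_time must be > 0")
  dat <- inner_join(clinical, groups[c("sample_id", "group")], by = "sample_id") |>
    filter(!is.na(.data$group))
  if (!all(c("low", "high") %in% dat$group)) abort("both groups must be non-empty")
  dat$event <- as.integer(dat$event)
  if (!any(dat$event[dat$group == "low"] == 1) ||
      !any(dat$event[dat$group == "high"] == 1)) {
    abort("each group needs at least one event")
  }
  surv <- survival::Surv(dat$pfs_time, dat$event)
  sd_fit <- survival::survdiff(surv ~ group, data = dat)
  chisq <- unname(sd_fit$chisq)
  p <- pchisq(chisq, df = 1, lower.tail = FALSE)
  dat$group <- factor(dat$group, levels = c("high", "low"))  # high = reference
  # convenience HR alongside the log-rank test; full diagnostics via cox_fit()
  cox <- suppressWarnings(survival::coxph(surv ~ group, data = dat, ties = "efron"))
  hr <- unname(exp(coef(cox)))
  se <- sqrt(diag(vcov(cox)))[1]
  ci <- exp(coef(cox)[1] + c(-1, 1) * qnorm(0.975) * se)
  sf <- survival::survfit(surv ~ group, data = dat)
  strata_lab <- sub("^group=", "", rep(names(sf$strata), sf$strata))
  curves <- tibble(
    group = strata_lab,
    time = sf$time,
    n_risk = sf$n.risk,
    n_event = sf$n.event,
    n_censor = sf$n.censor,
    surv = sf$surv,
    lower = sf$lower,
    upper = sf$upper
  )
  structure(
    list(
      curves = curves,
      logrank_chisq = chisq,
      logrank_p = p,
      hr = hr, hr_ci = unname(ci),
      n = nrow(dat), n_events = sum(dat$event),
      observed = sd_fit$obs, expected = sd_fit$exp
    ),
    class = "methloss_km"
  )
}

#' @export
print.methloss_km <- function(x, ...) {
  cat("Kaplan-Meier / log-rank (n = ", x$n, ", events = ", x$n_events, ")\n", sep = "")
  cat("  log-rank chi-square = ", format(x$logrank_chisq, digits = 4),
      ", P = ", format(x$logrank_p, digits = 3), "\n", sep = "")
  cat("  HR (low vs high) = ", format(x$hr, digits = 3),
      " [", format(x$hr_ci[1], digits = 3), ", ",
      format(x$hr_ci[2], digits = 3), "]\n", sep = "")
  invisible(x)
}

#' Multivariable Cox proportional hazards model
#'
#' Cox partial-likelihood fit with the Efron tie correction over one or more
#' per-sample covariates. Monotone likelihood (perfect separation, detected
#' as extreme coefficients) is flagged; non-convergence is an error carrying
#' the iteration diagnostics.
#'
#' @param clinical Data frame with `sample_id`, `pfs_time`, `event`.
#' @param covariates Data frame with `sample_id` plus one column per
#'   covariate (numeric or 0/1 indicators).
#' @return An object of class `methloss_cox` with a per-covariate coefficient
#'   tibble (`term`, `estimate`, `hr`, `se`, `z`, `p`, CI bounds).
#' @export
cox_fit <- function(clinical, covariates) {
  dat <- inner_join(clinical, covariates, by = "sample_id")
  terms <- setdiff(names(covariates), "sample_id")
  dat$event <- as.integer(dat$event)
  if (sum(dat$event) < 2) abort("need at least 2 events")
  const <- terms[vapply(terms, function(tm) sd(dat[[tm]]) == 0, logical(1))]
  if (length(const)) abort(paste0("degenerate covariate(s): ", paste(const, collapse = ", ")))
  fml <- stats::as.formula(paste(
    "survival::Surv(pfs_time, event) ~",
    paste(sprintf("`%s`", terms), collapse = " + ")
  ))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "efron"),
    warning = function(w) {
      if (grepl("did not converge", conditionMessage(w))) {
        abort(paste0("Cox fit did not converge: ", conditionMessage(w)))
      }
      invokeRestart("muffleWarning")
    }
  )
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  # monotone likelihood shows up as a diverging standardized coefficient
  covar_sd <- vapply(names(est), function(tm) sd(dat[[tm]]), numeric(1))
  separation <- abs(est) * covar_sd > 15 | se * covar_sd > 100
  tab <- tibble(
    term = names(est),
    estimate = unname(est),
    hr = exp(unname(est)),
    se = unname(se),
    z = unname(est / se),
    p = 2 * pnorm(-abs(unname(est / se))),
    conf_low = exp(unname(est - qnorm(0.975) * se)),
    conf_high = exp(unname(est + qnorm(0.975) * se)),
    separation_flag = separation
  )
  if (any(separation)) {
    warn(paste0("possible monotone likelihood (separation) for: ",
                paste(tab$term[separation], collapse = ", ")))
  }
  structure(
    list(coefficients = tab, n = fit$n, n_events = fit$nevent,
         loglik = fit$loglik, fit = fit),
    class = "methloss_cox"
  )
}

#' @export
print.methloss_cox <- function(x, ...) {
  cat("Cox proportional hazards (Efron ties); n = ", x$n,
      ", events = ", x$n_events, "\n", sep = "")
  print(as.data.frame(x$coefficients[, c("term", "hr", "conf_low", "conf_high", "p")]),
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Multivariable logistic model of durable clinical benefit
#'
#' Maximum-likelihood logistic regression of the DCB/NDB response on
#' per-sample covariates; reports odds ratios with Wald P values. Complete
#' separation is flagged.
#'
#' @param response Data frame with `sample_id` and `response`
#'   (`"DCB"`/`"NDB"`, or logical with `TRUE` = DCB).
#' @param covariates Data frame with `sample_id` plus covariate columns.
#' @return An object of class `methloss_logistic` with a coefficient tibble.
#' @export
response_logistic <- function(response, covariates) {
  dat <- inner_join(response, covariates, by = "sample_id")
  y <- if (is.logical(dat$response)) dat$response else dat$response == "DCB"
  if (length(unique(y)) < 2) abort("response has a single class; model undefined")
  terms <- setdiff(names(covariates), "sample_id")
  X <- dat[terms]
  fit <- suppressWarnings(glm(y ~ ., data = X, family = binomial()))
  est <- coef(fit)[-1]
  se <- sqrt(diag(vcov(fit)))[-1]
  covar_sd <- vapply(names(est), function(tm) {
    v <- dat[[tm]]
    if (is.numeric(v)) sd(v) else 1
  }, numeric(1))
  separation <- !fit$converged | abs(est) * covar_sd > 15 | se * covar_sd > 100
  tab <- tibble(
    term = names(est),
    estimate = unname(est),
    or = exp(unname(est)),
    se = unname(se),
    z = unname(est / se),
    p = 2 * pnorm(-abs(unname(est / se))),
    separation_flag = unname(separation)
  )
  if (any(separation)) {
    warn(paste0("possible separation for: ", paste(tab$term[separation], collapse = ", ")))
  }
  structure(
    list(coefficients = tab, n = nrow(dat), n_dcb = sum(y), fit = fit),
    class = "methloss_logistic"
  )
}

#' @export
print.methloss_logistic <- function(x, ...) {
  cat("Logistic model of durable clinical benefit; n = ", x$n,
      " (DCB = ", x$n_dcb, ")\n", sep = "")
  print(as.data.frame(x$coefficients[, c("term", "or", "p")]),
        row.names = FALSE, digits = 3)
  invisible(x)
}
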