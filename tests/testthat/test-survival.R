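test_that("durable clinical benefit classification follows the 6-month rule", {
  expect_equal(classify_response(c("PR", "PD", "CR")), c("DCB", "NDB", "DCB"))
  expect_equal(classify_response("SD", 7), "DCB")
  expect_equal(classify_response("SD", 5), "NDB")
  expect_equal(classify_response("SD", 6), "NDB")  # "more than 6 months"
  expect_error(classify_response("XX"), "unknown")
  expect_error(classify_response("SD"), "duration")
})

test_that("stratification rules split as documented and are rank-invariant", {
  sc <- tibble::tibble(sample_id = letters[1:4], score = c(1, 2, 3, 4))
  out <- stratify(sc)
  expect_equal(out$group, c("low", "low", "high", "high"))
  # ties at the median go low by default, high on request
  sc5 <- tibble::tibble(sample_id = letters[1:5], score = c(1, 2, 3, 4, 5))
  expect_equal(sum(stratify(sc5)$group == "low"), 3)
  expect_equal(sum(stratify(sc5, ties = "high")$group == "low"), 2)

  p <- stratify(tibble::tibble(sample_id = letters[1:10], score = 1:10),
                rule = "percentile")
  expect_equal(sum(p$group == "low", na.rm = TRUE), 3)
  expect_equal(sum(p$group == "high", na.rm = TRUE), 3)
  expect_equal(sum(is.na(p$group)), 4)

  # monotone transform invariance
  out_t <- stratify(dplyr::mutate(sc, score = exp(score)))
  expect_equal(out_t$group, out$group)
  expect_error(stratify(dplyr::mutate(sc, score = 1)), "degenerate")
})

test_that("log-rank matches a textbook hand computation on a small cohort", {
  clin <- tibble::tibble(
    sample_id = paste0("p", 1:6),
    pfs_time = c(3, 5, 7, 2, 4, 6),
    event = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
  )
  grp <- tibble::tibble(sample_id = paste0("p", 1:6),
                        group = rep(c("low", "high"), each = 3))
  fit <- km_logrank(clin, grp)

  # independent textbook computation over the event times
  times <- sort(unique(clin$pfs_time[clin$event]))
  o_minus_e <- 0
  v <- 0
  for (tm in times) {
    at_risk <- clin$pfs_time >= tm
    n <- sum(at_risk)
    n1 <- sum(at_risk & grp$group == "low")
    d <- sum(clin$pfs_time == tm & clin$event)
    d1 <- sum(clin$pfs_time == tm & clin$event & grp$group == "low")
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  expect_equal(fit$logrank_chisq, o_minus_e^2 / v, tolerance = 1e-10)
  expect_equal(fit$logrank_p, pchisq(o_minus_e^2 / v, 1, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("KM estimate reduces to the empirical survival without censoring", {
  clin <- tibble::tibble(
    sample_id = paste0("p", 1:8),
    pfs_time = c(1, 2, 3, 4, 5, 6, 7, 8),
    event = TRUE
  )
  grp <- tibble::tibble(sample_id = paste0("p", 1:8),
                        group = rep(c("low", "high"), each = 4))
  fit <- km_logrank(clin, grp)
  low <- fit$curves[fit$curves$group == "low", ]
  expect_equal(low$surv, c(0.75, 0.5, 0.25, 0))
  expect_true(all(diff(fit$curves$surv[fit$curves$group == "high"]) <= 0))
  # identical data in both groups: no difference to detect
  clin2 <- dplyr::bind_rows(clin, dplyr::mutate(clin, sample_id = paste0("q", 1:8)))
  grp2 <- tibble::tibble(sample_id = clin2$sample_id,
                         group = rep(c("low", "high"), each = 8))
  clin2$pfs_time <- rep(clin$pfs_time[1:8], 2)
  fit2 <- km_logrank(clin2, grp2)
  expect_lt(fit2$logrank_chisq, 1e-10)
  expect_equal(fit2$hr, 1, tolerance = 1e-6)
})

test_that("Cox fit behaves at the null, under label swap, and matches Breslow without ties", {
  set.seed(21)
  n <- 400
  clin <- tibble::tibble(
    sample_id = sprintf("s%03d", 1:n),
    pfs_time = rexp(n, 1 / 300),
    event = TRUE
  )
  x <- rbinom(n, 1, 0.5)
  cov <- tibble::tibble(sample_id = clin$sample_id, x = x)
  fit <- cox_fit(clin, cov)
  expect_equal(tidy(fit)$hr, 1, tolerance = 0.3)

  # swapping the indicator inverts the hazard ratio exactly
  fit_sw <- cox_fit(clin, dplyr::mutate(cov, x = 1 - x))
  expect_equal(tidy(fit_sw)$estimate, -tidy(fit)$estimate, tolerance = 1e-8)

  # no tied event times: Efron and Breslow coincide
  ref <- survival::coxph(survival::Surv(pfs_time, event) ~ x,
                         data = dplyr::inner_join(clin, cov, by = "sample_id"),
                         ties = "breslow")
  expect_equal(tidy(fit)$estimate, unname(coef(ref)), tolerance = 1e-8)

  expect_error(cox_fit(clin, dplyr::mutate(cov, x = 0)), "degenerate")
})

test_that("logistic response model recovers planted effects and flags degeneracies", {
  set.seed(22)
  n <- 400
  x <- rnorm(n)
  p <- plogis(-0.3 + 0.8 * x)
  resp <- tibble::tibble(
    sample_id = sprintf("s%03d", 1:n),
    response = ifelse(rbinom(n, 1, p) == 1, "DCB", "NDB")
  )
  cov <- tibble::tibble(sample_id = resp$sample_id, x = x)
  fit <- response_logistic(resp, cov)
  tt <- tidy(fit)
  expect_true(abs(tt$estimate - 0.8) < 3 * tt$se)
  # null covariate: odds ratio near 1
  cov0 <- tibble::tibble(sample_id = resp$sample_id, x = rnorm(n))
  expect_equal(tidy(response_logistic(resp, cov0))$or, 1, tolerance = 0.3)
  # joint row permutation leaves estimates unchanged
  perm <- sample(n)
  fit_p <- response_logistic(resp[perm, ], cov)
  expect_equal(tidy(fit_p)$estimate, tt$estimate, tolerance = 1e-10)
  expect_error(
    response_logistic(dplyr::mutate(resp, response = "DCB"), cov),
    "single class"
  )
})

test_that("a single simulated cohort recovers the planted hazard ratio", {
  b <- simulate_cohort(simulation_config(n_samples = 400, seed = 77),
                       include_tracks = FALSE)
  probes <- select_l1_probes(b$manifest)
  gs <- global_methylation(b$beta, probes)
  strata <- stratify(gs |> dplyr::select(sample_id, score))
  fit <- cox_fit(b$clinical,
                 tibble::tibble(sample_id = strata$sample_id,
                                low = as.integer(strata$group == "low")))
  tt <- tidy(fit)
  expect_true(abs(tt$estimate - log(2)) < 3 * tt$se)
  km <- km_logrank(b$clinical, strata)
  expect_lt(km$logrank_p, 0.05)
})
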