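surv_df <- function(time, event, ids = sprintf("S%03d", seq_along(time))) {
  data.frame(sample_id = ids, time_years = time, event = as.integer(event))
}

test_that("the product-limit estimator matches hand computation", {
  km <- km_estimate(surv_df(1:4, rep(1, 4)))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(survival_at(km, 2.5)$surv, 0.5)     # right-continuous step
  expect_equal(survival_at(km, 0.5)$surv, 1)

  all_cens <- km_estimate(surv_df(c(2, 5, 9), c(0, 0, 0)))
  expect_true(all(all_cens$surv == 1))
  expect_false(attr(all_cens, "ci_defined"))
})

test_that("without censoring the KM curve equals the empirical survival exactly", {
  set.seed(31)
  t <- stats::rexp(200, 0.3)
  km <- km_estimate(surv_df(t, rep(1, 200)))
  for (q in stats::quantile(t, c(0.1, 0.5, 0.9))) {
    expect_equal(survival_at(km, q)$surv, mean(t > q), tolerance = 1e-12)
  }
})

test_that("Greenwood log(-log) intervals bracket the estimate within [0,1]", {
  set.seed(32)
  t <- stats::rexp(150, 0.2)
  ev <- as.integer(t < stats::rexp(150, 0.1))
  t <- pmin(t, 12)
  km <- km_estimate(surv_df(pmax(t, 1e-6), ev))
  ok <- !is.na(km$lower)
  expect_true(all(km$lower[ok] <= km$surv[ok] + 1e-12))
  expect_true(all(km$surv <= km$upper | is.na(km$upper)))
  expect_true(all(km$lower >= 0 & km$upper <= 1, na.rm = TRUE))
})

test_that("reverse-KM follow-up behaves at the limits and inverts censoring", {
  # everyone censored at 10y: median follow-up is 10y
  rev1 <- reverse_km_followup(surv_df(rep(10, 20), rep(0, 20)))
  expect_true(rev1$reached)
  expect_equal(rev1$median, 10)

  # everyone dies: no censoring events, median unreached
  rev2 <- reverse_km_followup(surv_df(1:20, rep(1, 20)))
  expect_false(rev2$reached)
  expect_equal(rev2$lower_bound, 20)

  # censoring-only data: reverse-KM equals the plain KM of the censoring times
  set.seed(33)
  ct <- stats::rexp(100, 0.15)
  plain <- km_estimate(surv_df(ct, rep(1, 100)))
  revkm <- reverse_km_followup(surv_df(ct, rep(0, 100)))
  med_plain <- min(plain$time[plain$surv <= 0.5])
  expect_equal(revkm$median, med_plain)
})

test_that("Cox fit on one binary covariate matches the partial-likelihood oracle", {
  set.seed(34)
  n <- 120
  z <- stats::rbinom(n, 1, 0.5)
  t <- stats::rexp(n, 0.1 * exp(0.7 * z))
  ev <- rep(1L, n)
  records <- surv_df(t, ev)
  asg <- phenogroup_assignment(stats::setNames(z + 1L, records$sample_id), k = 2)
  fit <- cox_fit(records, asg)
  beta_oracle <- oracle_cox_beta(t, ev, z)
  expect_equal(unname(fit$coefficients["phenogroup2"]), beta_oracle,
               tolerance = 1e-6)
  expect_equal(fit$hr$hr[1], exp(unname(fit$coefficients[1])), tolerance = 1e-12)
  expect_true(fit$hr$lower[1] <= fit$hr$hr[1] && fit$hr$hr[1] <= fit$hr$upper[1])
})

test_that("a covariate independent of survival recovers HR near 1", {
  co <- generate_cohort(cohort_config(
    n_samples = 2000, n_features = 10, n_modules = 1, module_size_range = c(3, 3),
    n_informative_modules = 0, hazard_scale_per_group = c(0.1, 0.1, 0.1),
    seed = 35))
  asg <- phenogroup_assignment(co$true_labels, k = 3)  # labels carry no hazard
  fit <- cox_fit(co$survival, asg)
  hrs <- fit$hr[fit$hr$term %in% c("phenogroup2", "phenogroup3"), ]
  expect_true(all(hrs$lower < 1 & hrs$upper > 1))
})

test_that("staged adjustment presets use the configured covariates", {
  co <- small_cohort(seed = 36, n = 400, p = 20, n_modules = 2, informative = 1)
  asg <- phenogroup_assignment(co$true_labels, k = 3)
  m1 <- cox_fit(co$survival, asg, co$clinical, preset = "M1")
  expect_setequal(setdiff(m1$hr$term, c("phenogroup2", "phenogroup3")),
                  c("age", "sex", "egfr"))
  m2 <- cox_fit(co$survival, asg, co$clinical, preset = "M2")
  expect_true(all(c("log_nt_probnp", "maggic") %in% m2$hr$term))
  m3 <- cox_fit(co$survival, asg, co$clinical, preset = "M3")
  expect_true("ef_lt40" %in% m3$hr$term)
  expect_error(cox_fit(co$survival, asg, preset = "M1"), "missing covariate")
})

test_that("the interaction LRT has the right df and detects a planted interaction", {
  co <- small_cohort(seed = 37, n = 500, p = 20, n_modules = 2, informative = 1)
  asg <- phenogroup_assignment(co$true_labels, k = 3)
  res <- interaction_test(co$survival, asg, co$clinical, "ef_lt40",
                          preset = "unadjusted")
  expect_equal(res$df, 2)                       # (k-1) x (levels-1) = 2 x 1
  expect_gte(res$p, 0)
  expect_lte(res$p, 1)
  expect_equal(nrow(res$wald), 2)

  # plant a strong interaction: group-3 hazard doubled where ef_lt40 == 1
  set.seed(38)
  n <- 2000
  g <- sample(1:3, n, replace = TRUE)
  ef <- stats::rbinom(n, 1, 0.4)
  lam <- c(0.08, 0.10, 0.12)[g] * ifelse(g == 3 & ef == 1, 2.5, 1)
  t <- pmax(pmin(stats::rexp(n, lam), 15), 1e-6)
  ev <- as.integer(t < 15)
  ids <- sprintf("S%04d", 1:n)
  rec <- data.frame(sample_id = ids, time_years = t, event = ev)
  clin <- data.frame(sample_id = ids, age = 70, sex = 1, egfr = 60,
                     nt_probnp = 1000, maggic = 20L, ef_lt40 = ef,
                     afib = 0L, hf_duration_ge18mo = 0L)
  asg2 <- phenogroup_assignment(stats::setNames(g, ids), k = 3)
  planted <- interaction_test(rec, asg2, clin, "ef_lt40", preset = "unadjusted")
  expect_lt(planted$p, 0.01)
})

test_that("stratified survival cells partition the cohort", {
  co <- small_cohort(seed = 39, n = 300, p = 20, n_modules = 2, informative = 1)
  asg <- phenogroup_assignment(co$true_labels, k = 3)
  ef <- stats::setNames(co$clinical$ef_lt40, co$clinical$sample_id)
  res <- survival_by_strata(co$survival, asg, ef, at = 5)
  expect_equal(sum(res$summary$n), 300)
  expect_equal(length(res$curves), nrow(res$summary))

  # constant stratum reduces to the per-phenogroup curves
  res1 <- survival_by_strata(co$survival, asg, stats::setNames(rep(1, 300),
                                                               co$clinical$sample_id))
  for (g in 1:3) {
    ids_g <- names(co$true_labels)[co$true_labels == g]
    plain <- km_estimate(co$survival[co$survival$sample_id %in% ids_g, ])
    expect_equal(res1$curves[[paste0("g", g, "|1")]]$surv, plain$surv)
  }
})
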