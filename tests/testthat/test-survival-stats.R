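test_that("event-count power formula reproduces its closed form and limits", {
  expect_identical(events_needed(0.05, 0.90, 2), 88L)
  expect_identical(events_needed(0.05, 0.90, 2), events_needed(0.05, 0.90, 0.5))
  # more power costs events; larger effects need fewer
  expect_gt(events_needed(0.05, 0.95, 2), events_needed(0.05, 0.80, 2))
  expect_lt(events_needed(0.05, 0.90, 4), events_needed(0.05, 0.90, 2))
  expect_identical(events_needed(0.05, 0.90, 1e6), 1L)
  expect_error(events_needed(0.05, 0.90, 1), "rr = 1")
})

test_that("Cox coefficient maximises the written-out Efron partial likelihood", {
  # 6-subject fixture with a tie, one binary covariate
  time <- c(1, 2, 2, 3, 4, 5)
  event <- c(1, 1, 1, 0, 1, 1)
  x <- c(1, 0, 1, 0, 1, 0)
  rec <- data.frame(time = time, event = event, exposure = x)
  fit <- fit_cox(rec, "exposure", zph = FALSE)
  beta_grid <- oracle_efron_coef(time, event, x)
  expect_lt(abs(fit$table$coef - beta_grid), 2e-4)
  expect_equal(fit$table$hr, exp(fit$table$coef))
  expect_equal(fit$table$lo95, exp(fit$table$coef - 1.96 * fit$table$se))
})

test_that("Cox estimates are consistent for a known two-group hazard ratio", {
  set.seed(71)
  n <- 2000
  grp <- rep(0:1, each = n / 2)
  t <- rexp(n, rate = 0.1 * 2^grp)   # group 1 hazard exactly doubled
  rec <- data.frame(time = t, event = 1, exposure = grp)
  fit <- fit_cox(rec, "exposure", zph = FALSE)
  expect_gt(fit$table$hr, 1.85)
  expect_lt(fit$table$hr, 2.15)
})

test_that("Cox fitting guards its preconditions", {
  rec <- data.frame(time = c(1, 2, 3), event = c(0, 0, 0), exposure = 1:3)
  expect_error(fit_cox(rec, "exposure"), "2 events")
  rec2 <- data.frame(time = c(1, 2, 3, 4), event = c(1, 1, 0, 1),
                     exposure = rep(1, 4))
  expect_error(fit_cox(rec2, "exposure"), "NA coefficients")
  expect_error(fit_cox(rec2, "absent"), "absent")
})

test_that("log-rank p agrees with the Cox score test for a clean binary split", {
  set.seed(73)
  n <- 120
  grp <- rep(0:1, each = n / 2)
  t <- rexp(n, 0.08 * 1.8^grp)       # continuous: no ties
  rec <- data.frame(time = t, event = 1, exposure = grp)
  fit <- survival::coxph(survival::Surv(time, event) ~ exposure, data = rec)
  p_score <- summary(fit)$sctest["pvalue"]
  km <- km_logrank(rec, grp)
  expect_equal(unname(km$p), unname(p_score), tolerance = 1e-6)
})

test_that("Kaplan-Meier and log-rank behave on degenerate and separated groups", {
  base <- data.frame(time = c(2, 4, 6, 8, 10), event = c(1, 1, 0, 1, 1))
  both <- rbind(base, base)
  km0 <- km_logrank(both, rep(c("a", "b"), each = 5))
  expect_equal(km0$chisq, 0, tolerance = 1e-12)
  expect_equal(km0$p, 1)
  # survival curves are proper non-increasing step functions from 1
  for (gcurve in split(km0$curves, km0$curves$group)) {
    expect_true(all(diff(gcurve$surv) <= 1e-12))
    expect_true(all(gcurve$surv <= 1))
  }

  set.seed(77)
  sep <- data.frame(time = c(runif(40, 1, 5), runif(40, 10, 20)),
                    event = 1)
  expect_lt(km_logrank(sep, rep(c("early", "late"), each = 40))$p, 0.001)

  expect_error(km_logrank(base, rep("a", 5)), "2 non-empty groups")
})

test_that("log-rank chi-square matches the hand observed-minus-expected tally", {
  toy <- data.frame(time = c(1, 3, 5, 7, 9, 2, 4, 6, 8, 10),
                    event = c(1, 1, 0, 1, 1, 1, 0, 1, 1, 0))
  grp <- rep(c("A", "B"), each = 5)
  km <- km_logrank(toy, grp)
  expect_equal(km$chisq, oracle_logrank_chisq(toy$time, toy$event, grp),
               tolerance = 1e-9)
})

test_that("proportionality diagnostics calibrate under PH and detect violations", {
  set.seed(79)
  # planted non-PH: effect reverses sign mid-follow-up
  rejections <- 0
  for (r in 1:10) {
    n <- 500
    x <- rnorm(n)
    t1 <- rexp(n, 0.05 * exp(0.8 * x))          # strong positive effect
    t2 <- 14 + rexp(n, 0.05 * exp(-0.8 * x))    # reversed after day 14
    t <- ifelse(t1 <= 14, t1, t2)
    rec <- data.frame(time = pmin(t, 28), event = as.integer(t <= 28),
                      exposure = x)
    fit <- fit_cox(rec, "exposure")
    sch <- schoenfeld_prop_test(fit)
    if (sch$table$p[sch$table$term == "exposure"] < 0.05) {
      rejections <- rejections + 1
    }
  }
  expect_gte(rejections, 7)

  # PH data usually pass (single draw; the calibration rate is checked
  # over many replicates in the acceptance suite)
  set.seed(80)
  x <- rnorm(400)
  t <- rexp(400, 0.05 * exp(0.5 * x))
  rec <- data.frame(time = pmin(t, 28), event = as.integer(t <= 28),
                    exposure = x)
  fit <- fit_cox(rec, "exposure")
  expect_true(is.data.frame(fit$zph))
  expect_true(all(c("exposure", "GLOBAL") %in% fit$zph$term))
})

test_that("AUC equals the all-pairs count and respects monotone transforms", {
  set.seed(83)
  for (case in 1:30) {
    n <- sample(20:60, 1)
    outcome <- rbinom(n, 1, 0.4)
    if (length(unique(outcome)) < 2) next
    score <- round(rnorm(n), sample(0:1, 1))   # rounding induces ties
    r <- roc_delong(score, outcome)
    expect_equal(r$auc, oracle_auc(score, outcome), tolerance = 1e-12)
    # strictly monotone transform leaves the AUC unchanged
    r2 <- roc_delong(exp(score / 2), outcome)
    expect_equal(r2$auc, r$auc, tolerance = 1e-12)
  }
  perfect <- roc_delong(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(perfect$auc, 1)
  expect_error(roc_delong(1:5, rep(1, 5)), "both classes")
})

test_that("DeLong comparison is null for self-comparison and sane for rivals", {
  set.seed(89)
  n <- 150
  outcome <- rbinom(n, 1, 0.35)
  s1 <- rnorm(n) + outcome
  s2 <- rnorm(n) + 0.2 * outcome
  self <- compare_rocs(s1, s1, outcome)
  expect_equal(self$diff, 0)
  expect_equal(self$p, 1)
  cmp <- compare_rocs(s1, s2, outcome)
  expect_lt(cmp$p, 0.05)
  expect_gt(cmp$auc1, cmp$auc2)
  ci <- roc_delong(s1, outcome)$ci
  expect_true(ci[1] >= 0 && ci[2] <= 1)
})

test_that("the association suite reproduces the stratified design and bookkeeping", {
  sim <- tiny_sim()
  sel <- select_mtdna_probes(sim$probes[c("probe_id", "sequence")],
                             sim$ref$refs, 2)
  ints <- sim$intensities$intensity[sel$selected$probe_id, ]
  est <- estimate_mtdna_pipeline(
    ints, setNames(sel$selected$gc_fraction, sel$selected$probe_id))
  suite <- run_association_suite(est$estimates, sim$cohort$cohort)
  expect_setequal(unique(suite$stratum), c("all", "non_ards", "ards"))
  crude <- suite[suite$model == "crude", ]
  expect_equal(crude$n[crude$stratum == "all"], 60)

  # complete-case bookkeeping: each row's n equals its complete cases
  merged <- merge(sim$cohort$cohort, est$estimates, by = "sample_id")
  ards <- merged[merged$ards == 1, ]
  n_saps <- sum(complete.cases(ards[c("time", "event", "saps")]))
  expect_equal(suite$n[suite$model == "adjusted_saps"], n_saps)
  n_age <- sum(complete.cases(ards[c("time", "event", "age")]))
  expect_equal(suite$n[suite$model == "adjusted_age"], n_age)

  # a missing covariate column skips its row and annotates why
  broken <- sim$cohort$cohort
  broken$saps <- NULL
  suite2 <- run_association_suite(est$estimates, broken)
  row <- suite2[suite2$model == "adjusted_saps", ]
  expect_true(is.na(row$hr))
  expect_match(row$note, "skipped")
})

test_that("adjusting for an independent covariate barely moves the hazard ratio", {
  set.seed(97)
  n <- 4000
  z <- rnorm(n)
  noise_cov <- rnorm(n)
  t <- rexp(n, 0.03 * exp(log(2) * z))
  rec <- data.frame(time = pmin(t, 28), event = as.integer(t <= 28),
                    exposure = z, w = noise_cov)
  crude <- fit_cox(rec, "exposure", zph = FALSE)$table$hr
  adj <- fit_cox(rec, c("exposure", "w"), zph = FALSE)
  hr_adj <- adj$table$hr[adj$table$term == "exposure"]
  expect_lt(abs(hr_adj - crude) / crude, 0.1)
})
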