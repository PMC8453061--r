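#' Fit a Cox proportional-hazards model
#'
#' Wraps [survival::coxph()] with Efron tie handling (Breslow by
#' option), a tight convergence tolerance, and complete-case handling of
#' missing covariates; returns a tidy coefficient table with hazard
#' ratios, Wald 95% CIs and p-values, plus Schoenfeld proportionality
#' diagnostics when the model has at least two events.
#'
#' @param records data.frame with columns `time` (> 0) and `event`
#'   (0/1) plus the covariates.
#' @param covariates character vector of covariate column names.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param zph_transform time transform for the proportionality test
#'   (`"identity"` default, `"km"` by option).
#' @param zph compute the Schoenfeld diagnostics (default TRUE; skip in
#'   tight simulation loops).
#' @return list of class `cox_fit`: `table` (term, coef, se, hr, lo95,
#'   hi95, p), `n`, `events`, `loglik`, `ties`, `zph` (per-covariate and
#'   GLOBAL p-values or NULL), `proportionality_held`, `unstable`.
#' @export
fit_cox <- function(records, covariates, ties = c("efron", "breslow"),
                    zph_transform = c("identity", "km"), zph = TRUE) {
  ties <- match.arg(ties)
  zph_transform <- match.arg(zph_transform)
  stopifnot(is.data.frame(records), all(c("time", "event") %in% names(records)))
  missing_cov <- setdiff(covariates, names(records))
  if (length(missing_cov)) {
    stop("covariate(s) absent from records: ", paste(missing_cov, collapse = ", "))
  }
  dat <- records[stats::complete.cases(records[c("time", "event", covariates)]),
                 c("time", "event", covariates), drop = FALSE]
  if (any(dat$time <= 0)) stop("all times must be > 0")
  if (sum(dat$event) < 2) stop("at least 2 events required")
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = ties,
                         control = survival::coxph.control(eps = 1e-9,
                                                           iter.max = 50))
  if (any(is.na(stats::coef(fit)))) {
    stop("Cox fit produced NA coefficients (degenerate covariate?)")
  }
  s <- summary(fit)
  tab <- data.frame(
    term = rownames(s$coefficients),
    coef = s$coefficients[, "coef"],
    se = s$coefficients[, "se(coef)"],
    hr = exp(s$coefficients[, "coef"]),
    lo95 = exp(s$coefficients[, "coef"] - 1.96 * s$coefficients[, "se(coef)"]),
    hi95 = exp(s$coefficients[, "coef"] + 1.96 * s$coefficients[, "se(coef)"]),
    p = s$coefficients[, "Pr(>|z|)"],
    row.names = NULL, stringsAsFactors = FALSE)
  zph_tab <- if (zph) {
    tryCatch({
      zt <- survival::cox.zph(fit, transform = zph_transform, global = TRUE)
      data.frame(term = rownames(zt$table), p = zt$table[, "p"],
                 row.names = NULL, stringsAsFactors = FALSE)
    }, error = function(e) NULL)
  } else NULL
  held <- if (is.null(zph_tab)) NA else all(zph_tab$p >= 0.05, na.rm = TRUE)
  structure(list(table = tab, n = nrow(dat), events = sum(dat$event),
                 loglik = fit$loglik[2], ties = ties, zph = zph_tab,
                 proportionality_held = held,
                 unstable = any(abs(tab$coef) > 10), fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("cox_fit (%s ties): n=%d, events=%d%s\n", x$ties, x$n, x$events,
              if (isTRUE(x$unstable)) " [UNSTABLE]" else ""))
  tab <- x$table
  tab$hr_ci <- sprintf("%.2f (%.2f-%.2f)", tab$hr, tab$lo95, tab$hi95)
  print(tab[c("term", "hr_ci", "p")], row.names = FALSE)
  if (!is.null(x$zph)) {
    cat(sprintf("proportionality %s (global Schoenfeld p = %.3g)\n",
                if (isTRUE(x$proportionality_held)) "held" else "violated",
                x$zph$p[x$zph$term == "GLOBAL"]))
  }
  invisible(x)
}

#' Schoenfeld proportionality test
#'
#' Grambsch-Therneau test of the proportional-hazards assumption:
#' correlation of the scaled Schoenfeld residuals with (transformed)
#' event time, per covariate and globally.
#'
#' @param fit a [fit_cox()] result.
#' @param transform `"identity"` (default) or `"km"`.
#' @return list with `table` (term, chisq, df, p) and `held`.
#' @export
schoenfeld_prop_test <- function(fit, transform = c("identity", "km")) {
  transform <- match.arg(transform)
  stopifnot(inherits(fit, "cox_fit"))
  if (fit$events < 2) stop("proportionality test needs at least 2 events")
  zt <- survival::cox.zph(fit$fit, transform = transform, global = TRUE)
  tab <- data.frame(term = rownames(zt$table),
                    chisq = zt$table[, "chisq"], df = zt$table[, "df"],
                    p = zt$table[, "p"], row.names = NULL,
                    stringsAsFactors = FALSE)
  list(table = tab, held = all(tab$p >= 0.05, na.rm = TRUE))
}

#' Kaplan-Meier curves and log-rank test
#'
#' Product-limit survival per group and the k-1 df log-rank chi-square.
#' A continuous exposure can be dichotomised first with
#' [median_split()].
#'
#' @param records data.frame with `time` and `event`.
#' @param group vector of group labels (length `nrow(records)`).
#' @return list of class `km_result`: `curves` (group, time, surv,
#'   n_risk, n_event), `chisq`, `df`, `p`.
#' @export
km_logrank <- function(records, group) {
  stopifnot(is.data.frame(records), all(c("time", "event") %in% names(records)))
  group <- as.factor(group)
  if (length(group) != nrow(records)) stop("group length mismatch")
  if (nlevels(droplevels(group)) < 2) stop("at least 2 non-empty groups required")
  if (any(table(group) == 0)) stop("every group needs at least one subject")
  dat <- data.frame(time = records$time, event = records$event, group = group)
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = dat)
  strata_id <- rep(names(sf$strata), sf$strata)
  curves <- data.frame(group = sub("^group=", "", strata_id),
                       time = sf$time, surv = sf$surv, n_risk = sf$n.risk,
                       n_event = sf$n.event, stringsAsFactors = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = dat)
  df <- length(sd$n) - 1
  p <- stats::pchisq(sd$chisq, df, lower.tail = FALSE)
  structure(list(curves = curves, chisq = unname(sd$chisq), df = df, p = p),
            class = "km_result")
}

#' Median split of a continuous exposure
#' @param x numeric vector.
#' @return factor with levels `low` / `high` (`x > median`).
#' @export
median_split <- function(x) {
  factor(ifelse(x > stats::median(x, na.rm = TRUE), "high", "low"),
         levels = c("low", "high"))
}

#' ROC curve with DeLong machinery
#'
#' AUC via the Mann-Whitney estimator (ties count one half), DeLong
#' variance from placement values, and a Wald 95% CI truncated to
#' [0, 1]. Higher scores are taken to predict the positive class;
#' the raw AUC is reported (not forced above 0.5).
#'
#' @param score numeric predictor.
#' @param outcome binary outcome (0/1).
#' @return list of class `roc_result`: `auc`, `var`, `se`, `ci` (lo,
#'   hi), `n_pos`, `n_neg`, and the underlying `pROC::roc` object.
#' @export
roc_delong <- function(score, outcome) {
  stopifnot(length(score) == length(outcome))
  ok <- !is.na(score) & !is.na(outcome)
  score <- score[ok]; outcome <- outcome[ok]
  if (length(unique(outcome)) < 2) stop("outcome must contain both classes")
  r <- pROC::roc(response = outcome, predictor = score,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  auc <- as.numeric(pROC::auc(r))
  # a degenerate (0 or 1) AUC has zero DeLong variance; pROC warns
  v <- suppressWarnings(as.numeric(pROC::var(r, method = "delong")))
  se <- sqrt(v)
  ci <- c(max(0, auc - 1.96 * se), min(1, auc + 1.96 * se))
  structure(list(auc = auc, var = v, se = se, ci = ci,
                 n_pos = sum(outcome == 1), n_neg = sum(outcome == 0),
                 roc = r),
            class = "roc_result")
}

#' DeLong test for two correlated ROC curves
#'
#' Paired z-test of two AUCs computed on the same subjects. Identical
#' scores give difference 0 and p = 1 by convention (the DeLong z is
#' 0/0 there).
#'
#' @param score1,score2 paired predictors.
#' @param outcome shared binary outcome (0/1).
#' @return list with `auc1`, `auc2`, `diff`, `p`.
#' @export
compare_rocs <- function(score1, score2, outcome) {
  stopifnot(length(score1) == length(score2),
            length(score1) == length(outcome))
  r1 <- roc_delong(score1, outcome)
  r2 <- roc_delong(score2, outcome)
  d <- r1$auc - r2$auc
  if (isTRUE(all.equal(score1, score2)) || abs(d) < .Machine$double.eps) {
    tt <- tryCatch(
      pROC::roc.test(r1$roc, r2$roc, method = "delong", paired = TRUE),
      error = function(e) NULL)
    p <- if (!is.null(tt) && is.finite(tt$p.value)) tt$p.value else 1
    if (d == 0) p <- 1
  } else {
    tt <- pROC::roc.test(r1$roc, r2$roc, method = "delong", paired = TRUE)
    p <- tt$p.value
  }
  list(auc1 = r1$auc, auc2 = r2$auc, diff = d, p = p)
}

#' Number of events needed for a survival study
#'
#' Event-count formula for a two-sided Wald test of a hazard ratio:
#' \deqn{n_{event} = \lceil 4 (Z_{\alpha} + Z_{\beta})^2 / \ln(RR)^2 \rceil}
#' with \eqn{Z_\alpha} the standard-normal quantile at
#' \eqn{1 - \alpha/2} and \eqn{Z_\beta} at the target power.
#'
#' @param alpha two-sided significance level.
#' @param power target power (1 - beta).
#' @param rr design hazard ratio (> 0, not 1).
#' @return smallest integer number of events satisfying the formula.
#' @export
events_needed <- function(alpha = 0.05, power = 0.90, rr = 2) {
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1, rr > 0)
  if (rr == 1) stop("rr = 1: log hazard ratio is 0, formula undefined")
  z_a <- stats::qnorm(1 - alpha / 2)
  z_b <- stats::qnorm(power)
  as.integer(max(1, ceiling(4 * (z_a + z_b)^2 / log(rr)^2)))
}

# one labelled row of the association table from a fit (exposure term)
suite_row <- function(model, stratum, records, covariates,
                      exposure = "exposure", ties = "efron") {
  out <- tryCatch({
    fit <- fit_cox(records, covariates, ties = ties)
    r <- fit$table[fit$table$term == exposure, ]
    zg <- if (!is.null(fit$zph)) fit$zph$p[fit$zph$term == "GLOBAL"] else NA
    data.frame(model = model, stratum = stratum, n = fit$n,
               events = fit$events, hr = r$hr, lo95 = r$lo95, hi95 = r$hi95,
               p = r$p, schoenfeld_global_p = zg,
               proportionality_held = fit$proportionality_held,
               note = "", stringsAsFactors = FALSE)
  }, error = function(e) {
    data.frame(model = model, stratum = stratum, n = NA_integer_,
               events = NA_integer_, hr = NA_real_, lo95 = NA_real_,
               hi95 = NA_real_, p = NA_real_, schoenfeld_global_p = NA_real_,
               proportionality_held = NA,
               note = paste("skipped:", conditionMessage(e)),
               stringsAsFactors = FALSE)
  })
  out
}

#' Crude and adjusted association suite
#'
#' Fits the full association ladder of the study design: the crude
#' (exposure-only) Cox model in the whole cohort and in the non-ARDS
#' and ARDS strata; then, within ARDS, models singly adjusted by age,
#' SAPS, APACHE II, each organ-dysfunction flag, hospital and ICU stay;
#' the multivariate age + APACHE II and age + APACHE II + organ
#' dysfunction models; and sensitivity fits adjusted by sex,
#' comorbidities, and genetic PCs when PC columns are present. Every
#' row reports the complete-case n, events, the exposure hazard ratio
#' with Wald 95% CI and p, and the global Schoenfeld proportionality
#' p (rows violating proportionality are the analogue of a footnoted
#' model). Missing covariate columns skip their row with a note; no
#' multiple-testing adjustment is applied across rows.
#'
#' @param estimates data.frame from [estimate_mtdna_pipeline()]
#'   (`$estimates`), or any data.frame with `sample_id` and
#'   `standardized_estimate`.
#' @param records phenotype data.frame with `sample_id`, `time`,
#'   `event`, `ards` and the clinical covariates.
#' @param ties passed to [fit_cox()].
#' @return data.frame, one row per model.
#' @export
run_association_suite <- function(estimates, records, ties = "efron") {
  stopifnot(all(c("sample_id", "standardized_estimate") %in% names(estimates)),
            all(c("sample_id", "time", "event", "ards") %in% names(records)))
  dat <- merge(records, estimates[c("sample_id", "standardized_estimate")],
               by = "sample_id")
  dat$exposure <- dat$standardized_estimate
  ards <- dat[dat$ards == 1, , drop = FALSE]
  organ_flags <- c("neuro_dysfunction", "coag_dysfunction",
                   "hepatic_dysfunction", "renal_dysfunction")
  rows <- list(
    suite_row("crude", "all", dat, "exposure", ties = ties),
    suite_row("crude", "non_ards", dat[dat$ards == 0, ], "exposure",
              ties = ties),
    suite_row("crude", "ards", ards, "exposure", ties = ties))
  single <- c(age = "age", saps = "saps", apache2 = "apache2",
              stats::setNames(organ_flags, organ_flags),
              days_in_hospital = "days_in_hospital",
              days_in_icu = "days_in_icu")
  for (nm in names(single)) {
    rows[[length(rows) + 1L]] <-
      suite_row(paste0("adjusted_", nm), "ards", ards,
                c("exposure", single[[nm]]), ties = ties)
  }
  rows[[length(rows) + 1L]] <-
    suite_row("adjusted_age_apache2", "ards", ards,
              c("exposure", "age", "apache2"), ties = ties)
  rows[[length(rows) + 1L]] <-
    suite_row("adjusted_age_apache2_organ", "ards", ards,
              c("exposure", "age", "apache2", organ_flags), ties = ties)
  sens <- list(sex = "sex", comorbidities = "comorbidities")
  pc_cols <- grep("^PC[0-9]+$", names(dat), value = TRUE)
  if (length(pc_cols)) sens$pcs <- pc_cols
  for (nm in names(sens)) {
    rows[[length(rows) + 1L]] <-
      suite_row(paste0("sensitivity_", nm), "ards", ards,
                c("exposure", sens[[nm]]), ties = ties)
  }
  do.call(rbind, rows)
}
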