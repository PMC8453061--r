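#' Estimator configuration
#'
#' @param outlier_k SD multiplier for probe outlier removal; a probe is
#'   removed when its mean corrected intensity lies beyond
#'   `outlier_k` SD of the mean of probe means (default 1.5).
#' @param gc_degree degree of the per-sample GC polynomial regression
#'   (1 or 2; default 2).
#' @param min_probes minimum number of probes that must survive outlier
#'   removal (default 5).
#' @param standardize z-score the per-sample estimates across the
#'   cohort (default TRUE).
#' @param lrr_center cohort reference for the log R ratio: per-probe
#'   `"median"` (robust default) or `"mean"`.
#' @return a validated list of class `estimator_config`.
#' @export
estimator_config <- function(outlier_k = 1.5, gc_degree = 2L,
                             min_probes = 5L, standardize = TRUE,
                             lrr_center = c("median", "mean")) {
  if (outlier_k <= 0) stop("outlier_k must be > 0")
  if (!gc_degree %in% 1:2) stop("gc_degree must be 1 or 2")
  if (min_probes < 1) stop("min_probes must be >= 1")
  lrr_center <- match.arg(lrr_center)
  structure(list(outlier_k = outlier_k, gc_degree = as.integer(gc_degree),
                 min_probes = as.integer(min_probes),
                 standardize = isTRUE(standardize), lrr_center = lrr_center),
            class = "estimator_config")
}

check_intensity_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("intensities must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("intensity matrix needs probe rownames and sample colnames")
  }
  if (anyDuplicated(rownames(x)) || anyDuplicated(colnames(x))) {
    stop("probe/sample ids must be unique")
  }
  if (anyNA(x)) stop("missing intensities are not supported")
  if (any(x <= 0)) stop("raw intensities must be strictly positive")
  invisible(x)
}

#' GC-content correction of probe intensities
#'
#' For each sample independently, ordinary least squares of its log2
#' probe intensities on probe GC fraction (and GC squared when
#' `gc_degree = 2`) across all supplied probes; the corrected value is
#' the residual plus the sample-wise intercept, so each sample's overall
#' level is preserved while its GC trend ("GC wave") is removed. The GC
#' covariates are mean-centered before the fit, so the intercept is the
#' fitted value at the average probe GC — the sample's mean log2 level —
#' rather than an extrapolation to GC = 0; this keeps the preserved
#' sample level numerically stable when probes span a narrow GC range.
#'
#' @param intensity probes x samples matrix of raw (positive)
#'   intensities.
#' @param gc named numeric vector of probe GC fractions covering every
#'   row of `intensity`.
#' @param config an [estimator_config()].
#' @return list with `corrected` (probes x samples, log2 scale),
#'   `coefficients` (samples x (gc_degree + 1)), and `skipped` (TRUE
#'   when the GC design was degenerate and correction was skipped).
#' @export
gc_correct <- function(intensity, gc, config = estimator_config()) {
  check_intensity_matrix(intensity)
  if (!all(rownames(intensity) %in% names(gc))) {
    stop("every probe needs a gc_fraction")
  }
  gc <- gc[rownames(intensity)]
  deg <- config$gc_degree
  if (length(unique(gc)) < deg + 2L) {
    warning("GC design degenerate (too few distinct GC values); correction skipped")
    return(list(corrected = log2(intensity), coefficients = NULL,
                skipped = TRUE))
  }
  y <- log2(intensity)
  P <- stats::poly(gc, degree = deg, raw = TRUE)
  X <- cbind(1, scale(P, center = TRUE, scale = FALSE))
  fit <- stats::lm.fit(X, y)
  coefs <- t(fit$coefficients)
  colnames(coefs) <- c("intercept", paste0("gc", seq_len(deg)))
  rownames(coefs) <- colnames(intensity)
  corrected <- fit$residuals + rep(coefs[, "intercept"], each = nrow(y))
  dimnames(corrected) <- dimnames(y)
  list(corrected = corrected, coefficients = coefs, skipped = FALSE)
}

#' Log R ratio across the cohort
#'
#' Normalises each probe's corrected intensity against a cohort
#' reference for that probe (per-probe median by default): positive
#' values mean more signal than the cohort-typical sample, i.e. elevated
#' copy number.
#'
#' @param corrected probes x samples matrix of corrected log2
#'   intensities.
#' @param config an [estimator_config()].
#' @return list with `lrr` (same shape) and `reference` (per-probe
#'   cohort reference).
#' @export
compute_lrr <- function(corrected, config = estimator_config()) {
  if (ncol(corrected) < 2L) stop("LRR needs at least 2 samples (cohort reference)")
  ref <- if (config$lrr_center == "median") {
    apply(corrected, 1, stats::median)
  } else {
    rowMeans(corrected)
  }
  list(lrr = corrected - ref, reference = ref)
}

#' Remove outlier probes
#'
#' Computes each probe's mean corrected intensity across samples and
#' removes probes whose mean lies beyond `outlier_k` standard deviations
#' of the mean of those probe means. A single pass; no re-iteration.
#' When the probe means have zero spread nothing is removed.
#'
#' @param corrected probes x samples matrix of corrected log2
#'   intensities (at least 3 probes).
#' @param config an [estimator_config()].
#' @return list with `retained`, `removed` (probe id vectors) and
#'   `distances` (|mean - grand mean| / SD per probe; NA when SD = 0).
#' @export
filter_outlier_probes <- function(corrected, config = estimator_config()) {
  if (nrow(corrected) < 3L) stop("outlier filtering needs at least 3 probes")
  m <- rowMeans(corrected)
  s <- stats::sd(m)
  if (s == 0) {
    removed <- character(0)
    dist <- rep(NA_real_, length(m))
  } else {
    dist <- abs(m - mean(m)) / s
    removed <- names(m)[dist > config$outlier_k]
  }
  retained <- setdiff(names(m), removed)
  if (length(retained) < config$min_probes) {
    stop(sprintf(
      "only %d probe(s) retained after outlier removal (min_probes = %d); relax outlier_k",
      length(retained), config$min_probes))
  }
  list(retained = retained, removed = removed,
       distances = stats::setNames(dist, names(m)))
}

#' Per-sample whole-blood mtDNA copy estimates
#'
#' The raw estimate is the mean log R ratio across retained probes; the
#' standardized estimate is its z-score across the cohort (so hazard
#' ratios downstream read "per SD of wb-mtDNA").
#'
#' @param lrr probes x samples LRR matrix.
#' @param retained probe ids to average over.
#' @param config an [estimator_config()].
#' @return data.frame with sample_id, raw_estimate_log2,
#'   standardized_estimate (NA column when `standardize = FALSE`).
#' @export
estimate_mtdna <- function(lrr, retained, config = estimator_config()) {
  if (length(retained) < config$min_probes) {
    stop(sprintf("%d retained probe(s) < min_probes = %d",
                 length(retained), config$min_probes))
  }
  if (!all(retained %in% rownames(lrr))) stop("retained probes missing from LRR matrix")
  raw <- colMeans(lrr[retained, , drop = FALSE])
  std <- rep(NA_real_, length(raw))
  if (config$standardize) {
    s <- stats::sd(raw)
    if (s == 0) stop("cohort SD of raw estimates is 0; cannot standardize")
    std <- (raw - mean(raw)) / s
  }
  data.frame(sample_id = colnames(lrr), raw_estimate_log2 = as.numeric(raw),
             standardized_estimate = as.numeric(std), stringsAsFactors = FALSE)
}

#' Full intensity-to-estimate pipeline
#'
#' GC correction, log R ratio normalisation, probe outlier removal and
#' per-sample averaging in the standard order.
#'
#' @param intensity probes x samples raw intensity matrix (typically
#'   restricted to the selected mitochondrial probes).
#' @param gc named probe GC fractions.
#' @param config an [estimator_config()].
#' @return list of class `mtdna_estimates`: `estimates` (data.frame),
#'   `retained`, `removed`, `gc_coefficients`, `lrr_reference`.
#' @export
estimate_mtdna_pipeline <- function(intensity, gc,
                                    config = estimator_config()) {
  corr <- gc_correct(intensity, gc, config)
  lrr <- compute_lrr(corr$corrected, config)
  filt <- filter_outlier_probes(corr$corrected, config)
  est <- estimate_mtdna(lrr$lrr, filt$retained, config)
  structure(list(estimates = est, retained = filt$retained,
                 removed = filt$removed, outlier_distances = filt$distances,
                 gc_coefficients = corr$coefficients,
                 gc_skipped = corr$skipped, lrr_reference = lrr$reference),
            class = "mtdna_estimates")
}

#' @export
print.mtdna_estimates <- function(x, ...) {
  cat(sprintf("mtdna_estimates: %d samples, %d probes retained (%d removed as outliers)\n",
              nrow(x$estimates), length(x$retained), length(x$removed)))
  invisible(x)
}
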