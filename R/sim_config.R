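#' Simulation configuration
#'
#' Parameters of the synthetic cohort generator. The defaults emulate a
#' GEN-SEP-like sepsis cohort: 687 patients of whom 264 develop ARDS,
#' an ARDS 28-day event fraction of 96/264 with a true hazard ratio of
#' 3.65 per SD of latent mtDNA copy number, and a null effect with an
#' 85/423 event fraction in the non-ARDS stratum.
#'
#' The latent per-sample mtDNA copy number is log2-scaled with mean 0
#' and SD `cn_log_sd`; mitochondrial probe intensities respond to it
#' one-to-one on the log2 scale while decoy probes do not respond at
#' all. Each sample carries its own GC-bias coefficients (b1, b2),
#' emulating the per-sample "GC wave" artifact the intensity correction
#' removes.
#'
#' @param seed integer master seed; stage seeds are derived from it so
#'   each generator is reproducible independently.
#' @param n_samples number of patients.
#' @param n_mito_probes number of probes copied from the mitochondrial
#'   reference (true mtDNA probes).
#' @param n_decoy_probes number of non-mitochondrial probes.
#' @param probe_length probe length in bases.
#' @param mito_length,n_nuclear_seqs,nuclear_length reference geometry.
#' @param numt_k integer vector; one NUMT-like nuclear near-copy of a
#'   mitochondrial segment is planted per element, with exactly that
#'   many substitutions (all falling inside the first `probe_length`
#'   bases of the segment so the planted distance is checkable).
#' @param numt_length length of each planted NUMT segment.
#' @param gc_bias_sd length-2 SDs of the per-sample GC coefficients
#'   (b1 linear, b2 quadratic); `c(0, 0)` disables GC bias.
#' @param noise_sd SD of the probe-level log2-intensity noise.
#' @param cn_log_sd SD of the latent log2 copy number.
#' @param n_outlier_probes number of mitochondrial probes planted as
#'   outliers; `outlier_shift` is added to their log2 mean.
#' @param outlier_shift log2 mean shift of planted outlier probes.
#' @param true_log_hr log hazard ratio per SD of latent copy number in
#'   the ARDS stratum (the whole cohort when `ards_fraction` is 0 or 1).
#' @param nonards_log_hr log hazard ratio in the non-ARDS stratum.
#' @param target_event_fraction expected pre-censoring event fraction by
#'   `censor_day` in the ARDS stratum (whole cohort if unstratified).
#' @param nonards_event_fraction event fraction in the non-ARDS stratum.
#' @param censor_day administrative censoring horizon in days.
#' @param ards_fraction proportion of patients labelled ARDS.
#' @param weibull_shape shape of the Weibull baseline hazard; 1 gives
#'   the exponential default.
#' @param n_snps,maf_range genotype panel size and allele-frequency law.
#' @param n_low_maf,n_monomorphic,n_all_het planted SNP pathologies
#'   (MAF 0.005 SNPs, monomorphic SNPs, all-heterozygote HWE violators).
#' @param n_duplicate_pairs,n_parent_child planted related sample pairs.
#' @param sample_missing_rate,snp_missing_rate background missingness;
#'   one planted bad sample / bad SNP block is added on top.
#' @param pop_split fraction of samples assigned to a second population
#'   (0 disables population structure).
#' @param pop_delta allele-frequency shift of the second population.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_samples = 687L,
                       n_mito_probes = 19L,
                       n_decoy_probes = 81L,
                       probe_length = 30L,
                       mito_length = 16569L,
                       n_nuclear_seqs = 8L,
                       nuclear_length = 5000L,
                       numt_k = c(0L, 1L, 3L),
                       numt_length = 90L,
                       gc_bias_sd = c(0.4, 0.4),
                       noise_sd = 0.2,
                       cn_log_sd = 0.5,
                       n_outlier_probes = 2L,
                       outlier_shift = 3,
                       true_log_hr = log(3.65),
                       nonards_log_hr = 0,
                       target_event_fraction = 96 / 264,
                       nonards_event_fraction = 85 / 423,
                       censor_day = 28,
                       ards_fraction = 264 / 687,
                       weibull_shape = 1,
                       n_snps = 2000L,
                       maf_range = c(0.05, 0.5),
                       n_low_maf = 5L,
                       n_monomorphic = 3L,
                       n_all_het = 2L,
                       n_duplicate_pairs = 1L,
                       n_parent_child = 1L,
                       sample_missing_rate = 0.01,
                       snp_missing_rate = 0.01,
                       pop_split = 0,
                       pop_delta = 0.15) {
  cfg <- as.list(environment())
  counts <- c("n_samples", "n_mito_probes", "n_decoy_probes", "probe_length",
              "mito_length", "n_nuclear_seqs", "nuclear_length", "n_snps")
  for (nm in counts) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] < 1) {
      stop(sprintf("'%s' must be a count >= 1", nm), call. = FALSE)
    }
  }
  if (probe_length > mito_length) {
    stop("probe_length exceeds mito_length", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (!(target_event_fraction > 0 && target_event_fraction < 1)) {
    stop("target_event_fraction must lie in (0, 1)", call. = FALSE)
  }
  if (censor_day <= 0) stop("censor_day must be > 0", call. = FALSE)
  if (ards_fraction < 0 || ards_fraction > 1) {
    stop("ards_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (length(gc_bias_sd) != 2 || any(gc_bias_sd < 0)) {
    stop("gc_bias_sd must be two nonnegative SDs", call. = FALSE)
  }
  if (any(numt_k < 0) || any(numt_k > probe_length)) {
    stop("numt_k values must lie in [0, probe_length]", call. = FALSE)
  }
  if (numt_length < probe_length) {
    stop("numt_length must be >= probe_length", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# per-stage seed so each generator is reproducible in isolation;
# kept below 2^31 - 1
derive_seed <- function(seed, stage) {
  offs <- c(references = 11L, probes = 23L, cn = 37L, intensities = 41L,
            cohort = 53L, genotypes = 67L)
  if (!stage %in% names(offs)) stop("unknown stage: ", stage)
  as.integer((as.numeric(seed) * 7919 + offs[[stage]]) %% 2147483647)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "sim_config: n=%d (ARDS fraction %.3f), %d mito + %d decoy probes,\n",
    "  noise_sd=%.2f, cn_log_sd=%.2f, ARDS log-HR=%.3f, event fraction %.3f,\n",
    "  censoring at day %g, %d SNPs, seed %d\n"),
    x$n_samples, x$ards_fraction, x$n_mito_probes, x$n_decoy_probes,
    x$noise_sd, x$cn_log_sd, x$true_log_hr, x$target_event_fraction,
    x$censor_day, x$n_snps, x$seed))
  invisible(x)
}
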