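#' Generate reference sequences with planted NUMTs
#'
#' Draws one random mitochondrial sequence (treated as circular
#' downstream) and a panel of nuclear sequences. For each element of
#' `config$numt_k` a NUMT-like near-copy of a mitochondrial segment is
#' planted into a nuclear sequence with exactly that many substitutions;
#' the substitutions fall inside the first `probe_length` bases of the
#' segment, so a probe taken at the segment start has a known minimum
#' nuclear mismatch distance equal to k.
#'
#' @param config a [sim_config()].
#' @return list with `refs` (a [reference_set()]) and `numts`
#'   (data.frame recording nuclear id, positions, mitochondrial origin,
#'   planted k and substitution positions).
#' @export
generate_references <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "references"))
  mito <- random_dna(config$mito_length)
  nuclear <- vapply(seq_len(config$n_nuclear_seqs),
                    function(i) random_dna(config$nuclear_length),
                    character(1))
  names(nuclear) <- sprintf("nuc%02d", seq_len(config$n_nuclear_seqs))

  ks <- as.integer(config$numt_k)
  numts <- data.frame(nuclear_id = character(0), nuc_start = integer(0),
                      mito_start = integer(0), length = integer(0),
                      k = integer(0), sub_positions = character(0),
                      stringsAsFactors = FALSE)
  if (length(ks)) {
    len <- config$numt_length
    # disjoint mito source segments, away from the origin so the wrap
    # probe and NUMT probes never collide
    lo <- config$probe_length + 1L
    hi <- config$mito_length - len - config$probe_length
    if (hi - lo < length(ks) * 2L * len) {
      stop("mito_length too small for the requested NUMT plan", call. = FALSE)
    }
    starts <- lo + (seq_along(ks) - 1L) * 2L * len +
      sample.int(len, length(ks), replace = TRUE)
    for (j in seq_along(ks)) {
      seg <- substr(mito, starts[j], starts[j] + len - 1L)
      subs <- integer(0)
      if (ks[j] > 0) {
        s <- substitute_bases(seg, ks[j], at = seq_len(config$probe_length))
        seg <- s$sequence
        subs <- s$positions
      }
      tgt <- 1L + (j - 1L) %% config$n_nuclear_seqs
      pos <- sample.int(config$nuclear_length - len + 1L, 1L)
      nuclear[tgt] <- paste0(substr(nuclear[tgt], 1L, pos - 1L), seg,
                             substr(nuclear[tgt], pos + len,
                                    config$nuclear_length))
      numts <- rbind(numts, data.frame(
        nuclear_id = names(nuclear)[tgt], nuc_start = pos,
        mito_start = starts[j], length = len, k = ks[j],
        sub_positions = paste(subs, collapse = ","),
        stringsAsFactors = FALSE))
    }
  }
  list(refs = reference_set(mito, nuclear), numts = numts)
}

#' Generate array probes with known provenance
#'
#' Mitochondrial probes are copied from the mitochondrial reference
#' (about half on the reverse strand; the first one wraps the origin to
#' exercise circular matching). One mitochondrial probe is placed at the
#' start of each planted NUMT source segment, so its minimum nuclear
#' mismatch equals the planted k. Decoy probes are either copies of
#' nuclear windows with a small number of substitutions (nuclear
#' homologs, recorded) or random sequences. Planted outlier probes are
#' flagged among the clean mitochondrial probes; the intensity generator
#' shifts their mean.
#'
#' @param ref a list as returned by [generate_references()].
#' @param config a [sim_config()].
#' @return data.frame with probe_id, sequence, gc_fraction, source,
#'   strand, mito_start, numt_k, is_outlier.
#' @export
generate_probes <- function(ref, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "probes"))
  w <- config$probe_length
  L <- config$mito_length
  mito <- ref$refs$mito
  doubled <- paste0(mito, substr(mito, 1L, w - 1L))

  n_numt <- nrow(ref$numts)
  if (config$n_mito_probes < n_numt + 1L) {
    stop("n_mito_probes must exceed the number of planted NUMTs", call. = FALSE)
  }
  # forbidden zone: NUMT source segments (a clean probe must not overlap)
  forbid <- unlist(lapply(seq_len(n_numt), function(j) {
    s <- ref$numts$mito_start[j]
    seq(max(1L, s - w + 1L), s + ref$numts$length[j] - 1L)
  }))
  n_clean <- config$n_mito_probes - n_numt
  # first clean probe wraps the origin
  starts <- L - (w %/% 3L) + 1L
  pool <- setdiff(seq_len(L - w + 1L), c(forbid, seq(L - w, L)))
  starts <- c(starts, sample(pool, n_clean - 1L))
  mito_df <- data.frame(
    mito_start = c(starts, ref$numts$mito_start),
    source = c(rep("mito", n_clean), rep("mito_numt", n_numt)),
    numt_k = c(rep(NA_integer_, n_clean), ref$numts$k),
    stringsAsFactors = FALSE)
  mito_df$sequence <- substr(rep(doubled, nrow(mito_df)), mito_df$mito_start,
                             mito_df$mito_start + w - 1L)
  mito_df$strand <- sample(c("+", "-"), nrow(mito_df), replace = TRUE)
  flip <- mito_df$strand == "-"
  mito_df$sequence[flip] <- vapply(mito_df$sequence[flip], revcomp,
                                   character(1), USE.NAMES = FALSE)

  # decoys: some nuclear near-copies, the rest random
  n_dec <- config$n_decoy_probes
  n_homolog <- min(10L, n_dec)
  dec_seq <- character(n_dec)
  dec_k <- rep(NA_integer_, n_dec)
  for (i in seq_len(n_homolog)) {
    src <- sample(ref$refs$nuclear, 1L)
    pos <- sample.int(nchar(src) - w + 1L, 1L)
    s <- substr(src, pos, pos + w - 1L)
    k <- sample(0:3, 1L)
    if (k > 0) s <- substitute_bases(s, k)$sequence
    dec_seq[i] <- s
    dec_k[i] <- k
  }
  for (i in seq_len(n_dec)[-seq_len(n_homolog)]) dec_seq[i] <- random_dna(w)
  dec_df <- data.frame(
    mito_start = NA_integer_,
    source = c(rep("decoy_nuclear", n_homolog),
               rep("decoy_random", n_dec - n_homolog)),
    numt_k = dec_k, sequence = dec_seq, strand = "+",
    stringsAsFactors = FALSE)

  probes <- rbind(mito_df[names(dec_df)], dec_df)
  probes <- data.frame(probe_id = sprintf("P%03d", seq_len(nrow(probes))),
                       probes, stringsAsFactors = FALSE)
  probes$gc_fraction <- vapply(probes$sequence, gc_fraction, numeric(1),
                               USE.NAMES = FALSE)
  probes$is_outlier <- FALSE
  clean_idx <- which(probes$source == "mito")
  n_out <- min(config$n_outlier_probes, length(clean_idx))
  if (n_out > 0) probes$is_outlier[sample(clean_idx, n_out)] <- TRUE
  rownames(probes) <- NULL
  probes[c("probe_id", "sequence", "gc_fraction", "source", "strand",
           "mito_start", "numt_k", "is_outlier")]
}

#' Draw the latent per-sample mtDNA copy number
#'
#' Log2-scale latent copy number, mean 0, SD `cn_log_sd`. This is the
#' quantity all downstream estimates try to recover.
#'
#' @param config a [sim_config()].
#' @return named numeric vector (names are sample ids).
#' @export
generate_latent_cn <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "cn"))
  cn <- stats::rnorm(config$n_samples, 0, config$cn_log_sd)
  names(cn) <- sprintf("S%04d", seq_len(config$n_samples))
  cn
}

#' Generate the raw probe-by-sample intensity matrix
#'
#' Signal model on the log2 scale:
#' \deqn{\log_2 I_{p,i} = \mu_p + a_p \, cn_i + b_{1,i}\,gc_p +
#'   b_{2,i}\,gc_p^2 + s_p + \varepsilon_{p,i}}
#' where \eqn{a_p = 1} for mitochondrial probes and 0 for decoys,
#' \eqn{(b_{1,i}, b_{2,i})} are per-sample GC-wave coefficients,
#' \eqn{s_p} is the outlier mean shift for planted outlier probes, and
#' \eqn{\varepsilon \sim N(0, \mathrm{noise\_sd}^2)}. Returned on the
#' raw \eqn{2^x} scale (strictly positive).
#'
#' @param probes data.frame from [generate_probes()].
#' @param cn latent copy-number vector from [generate_latent_cn()].
#' @param config a [sim_config()].
#' @return list with `intensity` (probes x samples matrix, raw scale),
#'   `probe_mu` and `gc_bias` (per-sample b1, b2).
#' @export
generate_intensities <- function(probes, cn, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "intensities"))
  n <- length(cn)
  p <- nrow(probes)
  mu <- stats::rnorm(p, 10, 0.5)
  a <- as.numeric(probes$source %in% c("mito", "mito_numt"))
  shift <- ifelse(probes$is_outlier, config$outlier_shift, 0)
  b1 <- stats::rnorm(n, 0, config$gc_bias_sd[1])
  b2 <- stats::rnorm(n, 0, config$gc_bias_sd[2])
  gc <- probes$gc_fraction
  log2i <- outer(mu + shift, rep(1, n)) +
    outer(a, cn) +
    outer(gc, b1) + outer(gc^2, b2) +
    matrix(stats::rnorm(p * n, 0, config$noise_sd), p, n)
  dimnames(log2i) <- list(probes$probe_id, names(cn))
  list(intensity = 2^log2i, probe_mu = mu,
       gc_bias = data.frame(sample_id = names(cn), b1 = b1, b2 = b2,
                            stringsAsFactors = FALSE))
}

# Solve for the baseline hazard h0 (cumulative hazard h0 * t^shape) such
# that the expected pre-censoring event fraction by `censor` over the
# supplied linear predictors equals `target`; monotone in h0, bisection
# on log h0.
calibrate_baseline_hazard <- function(eta, target, censor, shape = 1,
                                      tol = 1e-10, max_iter = 200) {
  frac <- function(log_h0) {
    mean(1 - exp(-exp(log_h0) * censor^shape * exp(eta))) - target
  }
  lo <- -40; hi <- 20
  if (frac(lo) > 0 || frac(hi) < 0) {
    stop("baseline hazard calibration failed: target event fraction unreachable",
         call. = FALSE)
  }
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (frac(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  exp((lo + hi) / 2)
}

#' Generate a survival cohort under proportional hazards
#'
#' Event times follow a Weibull proportional-hazards model (exponential
#' by default, `weibull_shape = 1`) with linear predictor
#' `log_hr * z`, where `z` is the standardized latent copy number. The
#' baseline hazard of each stratum (ARDS / non-ARDS when
#' `ards_fraction` is strictly between 0 and 1) is calibrated by
#' bisection so the expected pre-censoring event fraction by
#' `censor_day` matches the stratum target. Administrative censoring is
#' applied at `censor_day`. Demographic and clinical covariates are
#' drawn from distributions matching a severe-sepsis ICU cohort and are
#' independent of the hazard; SAPS carries ~50% missingness and hospital
#' stay ~14%, mirroring the incomplete clinical records such cohorts
#' typically have.
#'
#' @param cn latent copy-number vector from [generate_latent_cn()].
#' @param config a [sim_config()].
#' @return list with `cohort` (one row per patient: covariates, `time`
#'   in (0, censor_day], `event` 0/1), `uncensored_time`, and the
#'   calibrated baseline hazards.
#' @export
generate_cohort <- function(cn, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.finite(config$true_log_hr)) stop("true_log_hr must be finite")
  set.seed(derive_seed(config$seed, "cohort"))
  n <- length(cn)
  z <- as.numeric(scale(cn))
  n_ards <- round(n * config$ards_fraction)
  ards <- rep(FALSE, n)
  if (n_ards > 0) ards[sample.int(n, n_ards)] <- TRUE

  log_hr <- ifelse(ards, config$true_log_hr, config$nonards_log_hr)
  eta <- log_hr * z
  h0 <- c(ards = NA_real_, nonards = NA_real_)
  tgt <- c(ards = config$target_event_fraction,
           nonards = config$nonards_event_fraction)
  stratified <- n_ards > 0 && n_ards < n
  shape <- config$weibull_shape
  cens <- config$censor_day
  t_unc <- numeric(n)
  if (stratified) {
    for (grp in c("ards", "nonards")) {
      idx <- if (grp == "ards") which(ards) else which(!ards)
      h0[grp] <- calibrate_baseline_hazard(eta[idx], tgt[grp], cens, shape)
      e <- stats::rexp(length(idx))
      t_unc[idx] <- (e / (h0[grp] * exp(eta[idx])))^(1 / shape)
    }
  } else {
    h <- calibrate_baseline_hazard(eta, config$target_event_fraction, cens, shape)
    h0[] <- h
    e <- stats::rexp(n)
    t_unc <- (e / (h * exp(eta)))^(1 / shape)
  }
  event <- as.integer(t_unc <= cens)
  time <- pmin(t_unc, cens)

  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  age <- clamp(round(stats::rnorm(n, 63, 14)), 18, 95)
  bmi <- round(clamp(stats::rnorm(n, 28, 6), 15, 60), 1)
  apache2 <- clamp(round(stats::rnorm(n, 22, 7)), 2, 50)
  saps <- clamp(round(stats::rnorm(n, 49, 14)), 10, 110)
  saps[stats::runif(n) < 0.5] <- NA_integer_
  apache2[stats::runif(n) < 0.025] <- NA_integer_
  sex <- ifelse(stats::runif(n) < 0.66, "male", "female")
  comorbidities <- as.integer(stats::runif(n) < 0.39)
  organ <- function(rate) as.integer(stats::runif(n) < rate)
  days_icu <- ifelse(event == 1,
                     pmax(1, ceiling(time) + stats::rpois(n, 1)),
                     pmax(1, round(stats::rnorm(n, 29, 15))))
  days_hospital <- days_icu + stats::rpois(n, ifelse(event == 1, 4, 20))
  days_hospital[stats::runif(n) < 0.136] <- NA_integer_

  cohort <- data.frame(
    sample_id = names(cn), age = age, sex = sex, bmi = bmi,
    apache2 = apache2, saps = saps, comorbidities = comorbidities,
    neuro_dysfunction = organ(0.25), coag_dysfunction = organ(0.27),
    hepatic_dysfunction = organ(0.16), renal_dysfunction = organ(0.39),
    ards = as.integer(ards), days_in_hospital = days_hospital,
    days_in_icu = days_icu, time = time, event = event,
    stringsAsFactors = FALSE)
  list(cohort = cohort, uncensored_time = stats::setNames(t_unc, names(cn)),
       h0 = h0)
}

#' Generate a genotype matrix with planted QC pathologies
#'
#' SNPs are drawn under Hardy-Weinberg equilibrium at uniform random
#' allele frequencies, except planted violators: low-MAF SNPs
#' (MAF 0.005), monomorphic SNPs, and all-heterozygote SNPs. Planted
#' duplicate and parent-child sample pairs provide relatedness targets,
#' and one deliberately bad sample (90% missing) plus two bad SNPs (10%
#' missing) exercise the call-rate filters. Optional two-population
#' structure shifts allele frequencies for a subset of samples.
#'
#' @param config a [sim_config()].
#' @return list with `genotypes` (SNPs x samples integer matrix with
#'   NA for missing) and `truth` (planted facts, queryable by tests).
#' @export
generate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "genotypes"))
  n <- config$n_samples
  m <- config$n_snps
  sample_ids <- sprintf("S%04d", seq_len(n))
  snp_ids <- sprintf("rs%05d", seq_len(m))
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])

  pop <- rep(1L, n)
  if (config$pop_split > 0) {
    pop[sample.int(n, round(n * config$pop_split))] <- 2L
  }
  G <- matrix(NA_integer_, m, n, dimnames = list(snp_ids, sample_ids))
  for (j in seq_len(m)) {
    p1 <- maf[j]
    p2 <- if (any(pop == 2L)) clamp01(maf[j] + sample(c(-1, 1), 1) * config$pop_delta) else p1
    p <- ifelse(pop == 2L, p2, p1)
    G[j, ] <- stats::rbinom(n, 2L, p)
  }

  # planted pathologies occupy the first SNP rows, in blocks
  i <- 0L
  take <- function(k) {
    idx <- i + seq_len(k); i <<- i + k
    if (i > m) stop("n_snps too small for the planted pathologies")
    idx
  }
  low_idx <- take(config$n_low_maf)
  # exact allele counts, so the planted SNPs sit below the 1% MAF
  # threshold deterministically even in small cohorts
  k_alt <- max(1L, round(0.005 * 2 * n))
  for (j in low_idx) {
    G[j, ] <- 0L
    G[j, sample.int(n, k_alt)] <- 1L
    maf[j] <- k_alt / (2 * n)
  }
  mono_idx <- take(config$n_monomorphic)
  G[mono_idx, ] <- 0L
  maf[mono_idx] <- 0
  het_idx <- take(config$n_all_het)
  G[het_idx, ] <- 1L

  # related pairs: the last samples are rewritten as copies/children
  dup_pairs <- data.frame(a = character(0), b = character(0))
  pc_pairs <- data.frame(parent = character(0), child = character(0))
  tail_pool <- n
  for (k in seq_len(config$n_duplicate_pairs)) {
    a <- tail_pool - 1L; b <- tail_pool; tail_pool <- tail_pool - 2L
    G[, b] <- G[, a]
    dup_pairs <- rbind(dup_pairs, data.frame(a = sample_ids[a],
                                             b = sample_ids[b]))
  }
  for (k in seq_len(config$n_parent_child)) {
    a <- tail_pool - 1L; b <- tail_pool; tail_pool <- tail_pool - 2L
    transmitted <- stats::rbinom(m, 1L, G[, a] / 2)
    G[, b] <- transmitted + stats::rbinom(m, 1L, maf)
    pc_pairs <- rbind(pc_pairs, data.frame(parent = sample_ids[a],
                                           child = sample_ids[b]))
  }

  # background missingness, then planted bad sample / bad SNPs
  miss <- matrix(stats::runif(m * n) < config$snp_missing_rate, m, n) |
    matrix(stats::runif(m * n) < config$sample_missing_rate, m, n)
  G[miss] <- NA_integer_
  bad_sample <- sample_ids[1L]
  G[stats::runif(m) < 0.9, 1L] <- NA_integer_
  bad_snps <- snp_ids[i + 1:2]
  for (j in i + 1:2) G[j, stats::runif(n) < 0.1] <- NA_integer_

  list(genotypes = G,
       truth = list(maf = stats::setNames(maf, snp_ids),
                    low_maf_snps = snp_ids[low_idx],
                    monomorphic_snps = snp_ids[mono_idx],
                    all_het_snps = snp_ids[het_idx],
                    duplicate_pairs = dup_pairs,
                    parent_child_pairs = pc_pairs,
                    bad_sample = bad_sample, bad_snps = bad_snps,
                    population = stats::setNames(pop, sample_ids)))
}

clamp01 <- function(x) pmin(pmax(x, 0.01), 0.99)

#' Simulate a complete synthetic study
#'
#' Orchestrates the generators: references with planted NUMTs, probes,
#' latent copy number, intensities, survival cohort and genotypes. The
#' result carries every planted ground-truth fact so each downstream
#' stage has a recovery target.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_dataset` with elements `config`, `ref`,
#'   `probes`, `cn`, `intensities`, `cohort`, `genotypes`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  ref <- generate_references(config)
  probes <- generate_probes(ref, config)
  cn <- generate_latent_cn(config)
  ints <- generate_intensities(probes, cn, config)
  coh <- generate_cohort(cn, config)
  gt <- generate_genotypes(config)
  structure(list(config = config, ref = ref, probes = probes, cn = cn,
                 intensities = ints, cohort = coh, genotypes = gt),
            class = "sim_dataset")
}
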