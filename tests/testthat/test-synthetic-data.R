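test_that("identical configs give byte-identical outputs", {
  cfg <- tiny_config(seed = 21)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$ref$refs$mito, b$ref$refs$mito)
  expect_identical(a$ref$refs$nuclear, b$ref$refs$nuclear)
  expect_identical(a$probes, b$probes)
  expect_identical(a$intensities$intensity, b$intensities$intensity)
  expect_identical(a$cohort$cohort, b$cohort$cohort)
  expect_identical(a$genotypes$genotypes, b$genotypes$genotypes)

  # and FASTA serialisation is byte-identical too
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_fasta(c(mito = a$ref$refs$mito, a$ref$refs$nuclear), f1)
  write_fasta(c(mito = b$ref$refs$mito, b$ref$refs$nuclear), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("planted NUMTs sit at their recorded mismatch distance", {
  sim <- tiny_sim()
  numts <- sim$ref$numts
  w <- sim$config$probe_length
  for (j in seq_len(nrow(numts))) {
    probe <- substr_of(sim$ref$refs$mito, numts$mito_start[j], w)
    # the planted substitutions are confined to the first probe-length
    # bases, so the probe over the segment start sees exactly k
    expect_identical(min_mismatch_to_nuclear(probe, sim$ref$refs),
                     numts$k[j])
    expect_identical(oracle_min_mismatch(probe, sim$ref$refs$nuclear),
                     numts$k[j])
  }
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(probe_length = 50, mito_length = 40), "mito_length")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(target_event_fraction = 1.2), "target_event_fraction")
  expect_error(sim_config(censor_day = 0), "censor_day")
  expect_error(sim_config(n_samples = 0), "count")
})

test_that("intensity signal model is exact in the noiseless case", {
  cfg <- tiny_config(seed = 3, noise_sd = 0, gc_bias_sd = c(0, 0))
  ref <- generate_references(cfg)
  probes <- generate_probes(ref, cfg)
  cn <- c(s1 = 1, s2 = 0, s3 = -1)
  ints <- generate_intensities(probes, cn, cfg)
  l2 <- log2(ints$intensity)
  mito_rows <- which(probes$source == "mito" & !probes$is_outlier)
  for (p in mito_rows) {
    expect_equal(unname(l2[p, ] - ints$probe_mu[p]), unname(cn),
                 tolerance = 1e-12)
  }
  decoy_rows <- which(probes$source == "decoy_random")
  for (p in decoy_rows[1:3]) {
    expect_equal(unname(diff(l2[p, ])), c(0, 0), tolerance = 1e-12)
  }
  # planted outliers carry the configured mean shift
  out_rows <- which(probes$is_outlier)
  expect_true(length(out_rows) > 0)
  expect_equal(unname(l2[out_rows[1], ] - ints$probe_mu[out_rows[1]]),
               unname(cn) + cfg$outlier_shift, tolerance = 1e-12)
})

test_that("mean mito intensity tracks latent copy number under noise", {
  cfg <- sim_config(seed = 9, n_samples = 200, noise_sd = 0.1,
                    gc_bias_sd = c(0, 0), mito_length = 3000,
                    nuclear_length = 1000, n_snps = 12)
  ref <- generate_references(cfg)
  probes <- generate_probes(ref, cfg)
  cn <- generate_latent_cn(cfg)
  ints <- generate_intensities(probes, cn, cfg)
  rows <- probes$source == "mito" & !probes$is_outlier
  m <- colMeans(log2(ints$intensity[rows, ]))
  expect_gt(cor(m, cn), 0.95)
})

test_that("cohort generation calibrates the event fraction and censors at the horizon", {
  cfg <- sim_config(seed = 31, n_samples = 1500, ards_fraction = 1,
                    true_log_hr = 0, target_event_fraction = 0.36,
                    n_snps = 12, mito_length = 3000, nuclear_length = 1000)
  cn <- generate_latent_cn(cfg)
  coh <- generate_cohort(cn, cfg)
  d <- coh$cohort
  expect_true(all(d$time > 0))
  expect_true(all(d$time <= 28))
  expect_identical(max(d$time), 28)
  expect_true(all(d$event %in% 0:1))
  # null model: binomial 99% band around the target
  band <- qbinom(c(0.005, 0.995), nrow(d), 0.36) / nrow(d)
  expect_gte(mean(d$event), band[1])
  expect_lte(mean(d$event), band[2])
  expect_true(all(coh$uncensored_time > 0))
})

test_that("stratified cohorts get stratum-specific hazards and event rates", {
  cfg <- sim_config(seed = 41, n_samples = 3000, n_snps = 12,
                    mito_length = 3000, nuclear_length = 1000)
  cn <- generate_latent_cn(cfg)
  coh <- generate_cohort(cn, cfg)
  d <- coh$cohort
  expect_equal(sum(d$ards), round(3000 * 264 / 687))
  f_ards <- mean(d$event[d$ards == 1])
  f_non <- mean(d$event[d$ards == 0])
  expect_lt(abs(f_ards - 96 / 264), 0.04)
  expect_lt(abs(f_non - 85 / 423), 0.04)
  # the planted log-HR acts in the ARDS stratum only
  z <- as.numeric(scale(cn))
  fit_a <- fit_cox(cbind(d, exposure = z)[d$ards == 1, ], "exposure",
                   zph = FALSE)
  fit_n <- fit_cox(cbind(d, exposure = z)[d$ards == 0, ], "exposure",
                   zph = FALSE)
  expect_gt(fit_a$table$hr, 2)
  expect_lt(abs(fit_n$table$coef), 0.25)
})

test_that("Weibull baseline keeps the calibrated event fraction", {
  cfg <- sim_config(seed = 43, n_samples = 1200, ards_fraction = 1,
                    weibull_shape = 2, target_event_fraction = 0.3,
                    n_snps = 12, mito_length = 3000, nuclear_length = 1000)
  cn <- generate_latent_cn(cfg)
  coh <- generate_cohort(cn, cfg)
  expect_lt(abs(mean(coh$cohort$event) - 0.3), 0.05)
})

test_that("genotype generator plants queryable QC pathologies", {
  sim <- tiny_sim()
  g <- sim$genotypes$genotypes
  tr <- sim$genotypes$truth

  dup <- tr$duplicate_pairs[1, ]
  expect_equal(pihat(g, dup$a, dup$b)$pihat, 1)

  # planted low-MAF SNPs fall below the 1% filter threshold
  maf <- snp_maf(g)
  expect_true(all(maf[tr$low_maf_snps] < 0.01, na.rm = TRUE))
  expect_true(all(maf[tr$monomorphic_snps] == 0))

  # all-heterozygote SNPs are extreme HWE violations
  for (s in tr$all_het_snps) {
    row <- g[s, ]
    row <- row[!is.na(row)]
    expect_lt(hwe_exact_test(sum(row == 0), sum(row == 1), sum(row == 2)),
              1e-6)
  }
  expect_lt(colMeans(!is.na(g))[tr$bad_sample], 0.95)
})
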