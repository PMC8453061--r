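# fixture builder: intensity matrix from an explicit log2 signal model
make_ints <- function(mu, cn, gc, b1 = 0, b2 = 0, noise = 0, seed = 1) {
  set.seed(seed)
  p <- length(mu); n <- length(cn)
  if (length(b1) == 1) b1 <- rep(b1, n)
  if (length(b2) == 1) b2 <- rep(b2, n)
  l2 <- outer(mu, rep(1, n)) + outer(rep(1, p), cn) +
    gc %o% b1 + (gc^2) %o% b2 +
    matrix(rnorm(p * n, 0, noise), p, n)
  dimnames(l2) <- list(sprintf("P%02d", 1:p), sprintf("S%02d", 1:n))
  2^l2
}

test_that("GC correction removes exactly the trend it models", {
  gc <- seq(0.2, 0.8, length.out = 12)
  mu <- rep(8, 12)
  cn <- c(0.5, 0, -0.5, 1)
  # per-sample linear bias, no noise
  ints <- make_ints(mu, cn, gc, b1 = c(0.8, -0.3, 0.4, 0), b2 = rep(0, 4))
  corr <- gc_correct(ints, setNames(gc, rownames(ints)),
                     estimator_config(gc_degree = 2))
  expect_false(corr$skipped)
  for (i in 1:4) {
    slope <- coef(lm(corr$corrected[, i] ~ gc))[2]
    expect_lt(abs(slope), 1e-8)
  }
  # with no injected bias and no noise the input is returned exactly
  ints0 <- make_ints(mu, cn, gc)
  corr0 <- gc_correct(ints0, setNames(gc, rownames(ints0)))
  expect_equal(corr0$corrected, log2(ints0), tolerance = 1e-12)
})

test_that("degenerate GC designs skip correction with a warning", {
  gc <- rep(0.5, 6)
  ints <- make_ints(rep(8, 6), c(0, 1), gc)
  expect_warning(corr <- gc_correct(ints, setNames(gc, rownames(ints))),
                 "degenerate")
  expect_true(corr$skipped)
  expect_equal(corr$corrected, log2(ints))
})

test_that("per-sample quadratic GC waves are suppressed under noise", {
  set.seed(33)
  n <- 100; p <- 40
  gc <- runif(p, 0.25, 0.75)
  ints <- make_ints(rnorm(p, 8, 0.3), rnorm(n, 0, 0.5), gc,
                    b1 = rnorm(n, 0, 0.5), b2 = rnorm(n, 0, 0.5),
                    noise = 0.05, seed = 34)
  corr <- gc_correct(ints, setNames(gc, rownames(ints)))
  cors <- apply(corr$corrected, 2, function(y) cor(y, gc))
  expect_lt(mean(abs(cors)), 0.05)
})

test_that("log R ratio is centred on the per-probe cohort reference", {
  gc <- seq(0.3, 0.7, length.out = 8)
  mu <- rnorm(8, 8, 0.4)
  # identical samples: LRR must vanish
  same <- make_ints(mu, rep(0, 5), gc)
  lrr0 <- compute_lrr(log2(same))
  expect_true(all(abs(lrr0$lrr) < 1e-12))

  # doubling one sample's intensities lifts its LRR by exactly 1 (odd n)
  cn <- c(1, 0, 0, 0, 0)
  ints <- make_ints(mu, cn, gc)
  lrr <- compute_lrr(log2(ints))
  expect_equal(unname(lrr$lrr[, 1]), rep(1, 8), tolerance = 1e-12)

  # per-probe median of LRR is exactly zero for odd cohorts
  set.seed(8)
  r <- matrix(rnorm(7 * 9), 7, 9,
              dimnames = list(paste0("P", 1:7), paste0("S", 1:9)))
  lrr_r <- compute_lrr(r)
  expect_equal(unname(apply(lrr_r$lrr, 1, median)), rep(0, 7))
  expect_equal(lrr_r$reference, apply(r, 1, median))

  expect_error(compute_lrr(r[, 1, drop = FALSE]), "2 samples")
})

test_that("outlier probe rule matches its hand-computed restatement", {
  set.seed(12)
  n <- 6
  means <- c(rnorm(18, 8, 0.3), 11, 12)  # 20 probes, two gross outliers
  names(means) <- sprintf("P%02d", 1:20)
  corrected <- outer(means, rep(0, n), `+`) +
    matrix(0, 20, n, dimnames = list(names(means), paste0("S", 1:n)))
  corrected <- corrected + 0  # exact probe means = `means`
  filt <- filter_outlier_probes(corrected, estimator_config())
  expect_setequal(filt$removed, oracle_outlier_ids(means, 1.5))
  expect_true(all(c("P19", "P20") %in% filt$removed))

  # equal probe means: zero spread, nothing removed
  flat <- matrix(5, 10, 4, dimnames = list(paste0("P", 1:10),
                                           paste0("S", 1:4)))
  expect_identical(filter_outlier_probes(flat)$removed, character(0))

  # refusing to continue below min_probes
  tight <- estimator_config(outlier_k = 0.1, min_probes = 18)
  expect_error(filter_outlier_probes(corrected, tight), "relax outlier_k")
})

test_that("estimates recover the latent signal and standardize exactly", {
  gc <- seq(0.3, 0.7, length.out = 9)
  cn <- rnorm(11, 0, 0.5)
  ints <- make_ints(rnorm(9, 8, 0.4), cn, gc)
  res <- estimate_mtdna_pipeline(ints, setNames(gc, rownames(ints)))
  est <- res$estimates
  # noiseless, bias-free: perfect affine recovery
  expect_equal(cor(est$raw_estimate_log2, cn), 1, tolerance = 1e-12)
  expect_equal(mean(est$standardized_estimate), 0, tolerance = 1e-9)
  expect_equal(sd(est$standardized_estimate), 1, tolerance = 1e-9)

  flat <- make_ints(rep(8, 9), rep(0, 5), gc)
  expect_error(
    estimate_mtdna(compute_lrr(log2(flat))$lrr, rownames(flat),
                   estimator_config()),
    "SD.*0|0.*standardize")
})

test_that("scaling one sample's raw intensities shifts its estimate by log2(c)", {
  gc <- seq(0.25, 0.75, length.out = 10)
  cn <- rnorm(7, 0, 0.5)
  ints <- make_ints(rnorm(10, 8, 0.3), cn, gc, seed = 3)
  base <- estimate_mtdna_pipeline(ints, setNames(gc, rownames(ints)))
  scaled <- ints
  scaled[, 3] <- scaled[, 3] * 8
  shifted <- estimate_mtdna_pipeline(scaled, setNames(gc, rownames(ints)))
  delta <- shifted$estimates$raw_estimate_log2 -
    base$estimates$raw_estimate_log2
  # sample 3 moves by +3 = log2(8); the cohort reference shift is shared
  expect_equal(delta[3] - mean(delta[-3]), 3, tolerance = 1e-9)
})

test_that("estimates are invariant under probe reordering", {
  gc <- seq(0.3, 0.7, length.out = 8)
  ints <- make_ints(rnorm(8, 8, 0.3), rnorm(6, 0, 0.5), gc,
                    noise = 0.1, seed = 5)
  gcv <- setNames(gc, rownames(ints))
  a <- estimate_mtdna_pipeline(ints, gcv)
  perm <- sample(nrow(ints))
  b <- estimate_mtdna_pipeline(ints[perm, ], gcv[perm])
  expect_equal(a$estimates$raw_estimate_log2, b$estimates$raw_estimate_log2,
               tolerance = 1e-12)
})

test_that("estimator recovers the latent copy number through the full synthetic path", {
  cfg <- sim_config(seed = 55, n_samples = 500, noise_sd = 0.1,
                    gc_bias_sd = c(0, 0), mito_length = 3000,
                    nuclear_length = 1000, n_snps = 12)
  ref <- generate_references(cfg)
  probes <- generate_probes(ref, cfg)
  cn <- generate_latent_cn(cfg)
  ints <- generate_intensities(probes, cn, cfg)
  sel <- select_mtdna_probes(probes[c("probe_id", "sequence")], ref$refs, 2)
  m <- ints$intensity[sel$selected$probe_id, ]
  res <- estimate_mtdna_pipeline(m, setNames(sel$selected$gc_fraction,
                                             sel$selected$probe_id))
  expect_gt(cor(res$estimates$raw_estimate_log2,
                cn[res$estimates$sample_id]), 0.9)
})
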