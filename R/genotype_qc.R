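#' Genotype QC configuration
#'
#' Thresholds of the standard array-QC cascade: sample call rate, SNP
#' call rate, minor allele frequency, Hardy-Weinberg exact test,
#' relatedness (PIHAT), and the LD-pruned PCA used for ancestry
#' adjustment.
#'
#' @param sample_call_rate_min,snp_call_rate_min minimum non-missing
#'   fraction (default 0.95; removal is strict `<`).
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param hwe_p_min exact-test p-value threshold (default 1e-6).
#' @param pihat_max relatedness threshold (default 0.2).
#' @param n_pcs number of principal components returned (default 5).
#' @param prune_r2 LD pruning r-squared threshold (default 0.2).
#' @param prune_window,prune_step sliding window size and step in SNPs
#'   (defaults 50 and 5).
#' @param min_pair_overlap minimum overlapping non-missing SNPs for a
#'   reliable PIHAT (default 50).
#' @return list of class `qc_config`.
#' @export
qc_config <- function(sample_call_rate_min = 0.95, snp_call_rate_min = 0.95,
                      maf_min = 0.01, hwe_p_min = 1e-6, pihat_max = 0.2,
                      n_pcs = 5L, prune_r2 = 0.2, prune_window = 50L,
                      prune_step = 5L, min_pair_overlap = 50L) {
  stopifnot(sample_call_rate_min > 0, sample_call_rate_min <= 1,
            snp_call_rate_min > 0, snp_call_rate_min <= 1,
            maf_min >= 0, maf_min < 0.5, hwe_p_min > 0, hwe_p_min < 1,
            pihat_max > 0, n_pcs >= 1, prune_r2 > 0, prune_r2 <= 1,
            prune_window >= 2, prune_step >= 1)
  structure(as.list(environment()), class = "qc_config")
}

check_genotypes <- function(g) {
  if (!is.matrix(g)) stop("genotypes must be a matrix (SNPs x samples)")
  if (is.null(rownames(g)) || is.null(colnames(g))) {
    stop("genotype matrix needs SNP rownames and sample colnames")
  }
  vals <- g[!is.na(g)]
  if (length(vals) && !all(vals %in% 0:2)) {
    stop("genotype calls must be 0, 1, 2 or NA")
  }
  invisible(g)
}

#' Call-rate filtering
#'
#' Removes samples whose non-missing fraction is below the sample
#' threshold, then (recomputing rates on the surviving samples) SNPs
#' below the SNP threshold. Boundary values are retained (removal is
#' strict `<`).
#'
#' @param g SNPs x samples matrix with calls in \{0, 1, 2, NA\}.
#' @param config a [qc_config()].
#' @return list with `genotypes` (filtered), `removed_samples`,
#'   `removed_snps` (data.frames with id, call_rate, reason).
#' @export
call_rate_filter <- function(g, config = qc_config()) {
  check_genotypes(g)
  sample_cr <- colMeans(!is.na(g))
  drop_s <- sample_cr < config$sample_call_rate_min
  if (all(drop_s)) stop("call-rate filter removed every sample")
  g2 <- g[, !drop_s, drop = FALSE]
  snp_cr <- rowMeans(!is.na(g2))
  drop_p <- snp_cr < config$snp_call_rate_min
  list(genotypes = g2[!drop_p, , drop = FALSE],
       removed_samples = data.frame(sample_id = colnames(g)[drop_s],
                                    call_rate = unname(sample_cr[drop_s]),
                                    reason = rep("sample_call_rate", sum(drop_s)),
                                    stringsAsFactors = FALSE),
       removed_snps = data.frame(snp_id = rownames(g2)[drop_p],
                                 call_rate = unname(snp_cr[drop_p]),
                                 reason = rep("snp_call_rate", sum(drop_p)),
                                 stringsAsFactors = FALSE))
}

#' Minor allele frequency per SNP
#' @param g SNPs x samples matrix.
#' @return named vector of `min(p, 1 - p)`; NA for SNPs with no calls.
#' @export
snp_maf <- function(g) {
  nn <- rowSums(!is.na(g))
  p <- rowSums(g, na.rm = TRUE) / (2 * nn)
  ifelse(nn == 0, NA_real_, pmin(p, 1 - p))
}

#' MAF filtering
#'
#' Removes SNPs with minor allele frequency below `maf_min`
#' (monomorphic SNPs have MAF 0 and are always removed); SNPs with no
#' non-missing calls are removed under a distinct reason code.
#'
#' @inheritParams call_rate_filter
#' @return list with `genotypes` and `removed_snps`.
#' @export
maf_filter <- function(g, config = qc_config()) {
  check_genotypes(g)
  maf <- snp_maf(g)
  no_calls <- is.na(maf)
  low <- !no_calls & maf < config$maf_min
  removed <- data.frame(
    snp_id = rownames(g)[no_calls | low],
    maf = unname(maf[no_calls | low]),
    reason = ifelse(no_calls[no_calls | low], "no_calls", "low_maf"),
    stringsAsFactors = FALSE)
  list(genotypes = g[!(no_calls | low), , drop = FALSE],
       removed_snps = removed)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact p-value conditional on the observed allele counts: the
#' probability of every heterozygote count whose conditional probability
#' does not exceed that of the observed count is summed (standard exact
#' definition, no mid-p). Computed in log space for stability.
#'
#' @param hom_ref,het,hom_alt genotype counts.
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(hom_ref, het, hom_alt) {
  stopifnot(hom_ref >= 0, het >= 0, hom_alt >= 0)
  n <- hom_ref + het + hom_alt
  if (n < 1) stop("total genotype count must be >= 1")
  n_a <- 2 * hom_ref + het          # reference allele count
  n_b <- 2 * hom_alt + het
  n_minor <- min(n_a, n_b)
  # possible het counts share the parity of the minor allele count
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  # log P(het = h | n, n_a) up to a constant:
  #   h*log(2) - lgamma terms of the genotype multinomial
  logp <- vapply(hets, function(h) {
    aa <- (n_a - h) / 2
    bb <- (n_b - h) / 2
    h * log(2) - lgamma(h + 1) - lgamma(aa + 1) - lgamma(bb + 1)
  }, numeric(1))
  logp <- logp - max(logp)
  pr <- exp(logp) / sum(exp(logp))
  obs <- pr[match(het, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}

#' HWE filtering
#'
#' @inheritParams call_rate_filter
#' @return list with `genotypes`, `removed_snps` and the per-SNP exact
#'   p-values.
#' @export
hwe_filter <- function(g, config = qc_config()) {
  check_genotypes(g)
  p <- apply(g, 1, function(row) {
    row <- row[!is.na(row)]
    if (!length(row)) return(NA_real_)
    hwe_exact_test(sum(row == 0), sum(row == 1), sum(row == 2))
  })
  drop <- !is.na(p) & p < config$hwe_p_min
  list(genotypes = g[!drop, , drop = FALSE],
       removed_snps = data.frame(snp_id = rownames(g)[drop],
                                 hwe_p = unname(p[drop]),
                                 reason = rep("hwe", sum(drop)),
                                 stringsAsFactors = FALSE),
       hwe_p = p)
}

#' Method-of-moments PIHAT between two samples
#'
#' PLINK-style IBD estimation: over the SNPs observed in both samples,
#' the counts of identity-by-state 0/1/2 loci are compared with their
#' expectations given the allele frequencies; the IBD-state proportions
#' are solved by the standard cascade (IBS0 only arises under IBD 0,
#' etc.), truncated into [0, 1], and PIHAT = P(IBD=1)/2 + P(IBD=2).
#'
#' @param g SNPs x samples matrix (allele frequencies are estimated from
#'   all samples in `g`).
#' @param a,b sample ids or column indices.
#' @param config a [qc_config()] (supplies `min_pair_overlap`).
#' @return list with `pihat`, IBD-state proportions `k0`, `k1`, `k2`,
#'   overlap `n`, and `reliable` flag.
#' @export
pihat <- function(g, a, b, config = qc_config()) {
  check_genotypes(g)
  ga <- g[, a]
  gb <- g[, b]
  ok <- !is.na(ga) & !is.na(gb)
  nn <- sum(ok)
  if (nn < config$min_pair_overlap) {
    warning(sprintf("only %d overlapping SNPs for pair (%s, %s); PIHAT unreliable",
                    nn, a, b))
    return(list(pihat = NA_real_, k0 = NA_real_, k1 = NA_real_,
                k2 = NA_real_, n = nn, reliable = FALSE))
  }
  ga <- ga[ok]; gb <- gb[ok]
  p <- rowSums(g[ok, , drop = FALSE], na.rm = TRUE) /
    (2 * rowSums(!is.na(g[ok, , drop = FALSE])))
  q <- 1 - p
  ibs <- 2 - abs(ga - gb)
  # both-homozygous-opposite is IBS 0; het vs opposite hom is IBS 1 by
  # the |dosage difference| coding above, which matches allele sharing
  n_ibs <- c(sum(ibs == 0), sum(ibs == 1), sum(ibs == 2))
  e0_ibd0 <- sum(2 * p^2 * q^2)
  e1_ibd0 <- sum(4 * p^3 * q + 4 * p * q^3)
  e1_ibd1 <- sum(2 * p * q)
  # raw cascade (no intermediate truncation, which would bias the
  # estimate upward for unrelated pairs); truncate PIHAT at the end
  k0 <- n_ibs[1] / e0_ibd0
  k1 <- (n_ibs[2] - k0 * e1_ibd0) / e1_ibd1
  k2 <- 1 - k0 - k1
  ph <- min(max(k1 / 2 + k2, 0), 1)
  list(pihat = ph, k0 = min(max(k0, 0), 1), k1 = min(max(k1, 0), 1),
       k2 = min(max(k2, 0), 1), n = nn, reliable = TRUE)
}

#' All-pairs PIHAT matrix
#'
#' Vectorised method-of-moments PIHAT for every sample pair, computed
#' with the same per-locus expectations as [pihat()] (the two agree
#' exactly). IBS counts and per-pair expectations are accumulated over
#' co-observed loci via indicator-matrix cross-products, so the cost is
#' a handful of matrix multiplications rather than a loop over pairs.
#'
#' @param g SNPs x samples matrix.
#' @return list with `pihat` (samples x samples symmetric matrix, NA on
#'   the diagonal and for pairs with insufficient overlap) and
#'   `overlap` (co-observed locus counts).
#' @param config a [qc_config()].
#' @export
pihat_matrix <- function(g, config = qc_config()) {
  check_genotypes(g)
  p <- rowSums(g, na.rm = TRUE) / (2 * rowSums(!is.na(g)))
  q <- 1 - p
  O <- !is.na(g); storage.mode(O) <- "double"
  I0 <- (!is.na(g) & g == 0L); storage.mode(I0) <- "double"
  I1 <- (!is.na(g) & g == 1L); storage.mode(I1) <- "double"
  I2 <- (!is.na(g) & g == 2L); storage.mode(I2) <- "double"
  n_obs <- crossprod(O)
  n_ibs2 <- crossprod(I0) + crossprod(I1) + crossprod(I2)
  x02 <- crossprod(I0, I2)
  n_ibs0 <- x02 + t(x02)
  n_ibs1 <- n_obs - n_ibs2 - n_ibs0
  e0_ibd0 <- crossprod(O, (2 * p^2 * q^2) * O)
  e1_ibd0 <- crossprod(O, (4 * p^3 * q + 4 * p * q^3) * O)
  e1_ibd1 <- crossprod(O, (2 * p * q) * O)
  k0 <- n_ibs0 / e0_ibd0
  k1 <- (n_ibs1 - k0 * e1_ibd0) / e1_ibd1
  ph <- pmin(pmax(k1 / 2 + (1 - k0 - k1), 0), 1)
  ph[n_obs < config$min_pair_overlap] <- NA_real_
  diag(ph) <- NA_real_
  list(pihat = ph, overlap = n_obs)
}

#' Relatedness filtering
#'
#' Computes PIHAT for every sample pair, flags pairs above
#' `pihat_max`, and removes the member with the lower call rate from
#' each flagged pair (ties: the later column). Pairs with fewer than
#' `min_pair_overlap` co-observed SNPs are skipped with a warning.
#'
#' @inheritParams call_rate_filter
#' @return list with `genotypes`, `removed_samples`, and `pairs` (all
#'   flagged pairs with their PIHAT).
#' @export
relatedness_filter <- function(g, config = qc_config()) {
  check_genotypes(g)
  ids <- colnames(g)
  pm <- pihat_matrix(g, config)
  skipped <- sum(pm$overlap[upper.tri(pm$overlap)] < config$min_pair_overlap)
  if (skipped > 0) {
    warning(sprintf("%d pair(s) skipped: fewer than %d overlapping SNPs",
                    skipped, config$min_pair_overlap))
  }
  hit <- which(upper.tri(pm$pihat) & !is.na(pm$pihat) &
                 pm$pihat > config$pihat_max, arr.ind = TRUE)
  flagged <- data.frame(a = ids[hit[, 1]], b = ids[hit[, 2]],
                        pihat = pm$pihat[hit], stringsAsFactors = FALSE)
  removed <- character(0)
  if (nrow(flagged)) {
    cr <- colMeans(!is.na(g))
    for (k in order(-flagged$pihat)) {
      a <- flagged$a[k]; b <- flagged$b[k]
      if (a %in% removed || b %in% removed) next
      removed <- c(removed, if (cr[a] < cr[b]) a else b)
    }
  }
  list(genotypes = g[, setdiff(ids, removed), drop = FALSE],
       removed_samples = data.frame(sample_id = removed,
                                    reason = rep("relatedness",
                                                 length(removed)),
                                    stringsAsFactors = FALSE),
       pairs = flagged)
}

#' Greedy sliding-window LD pruning
#'
#' Within each window of `prune_window` SNPs (advanced by `prune_step`),
#' for every pair with squared dosage correlation above `prune_r2` the
#' later SNP is dropped; surviving SNPs are returned in matrix order.
#'
#' @inheritParams call_rate_filter
#' @return character vector of retained SNP ids.
#' @export
ld_prune <- function(g, config = qc_config()) {
  check_genotypes(g)
  ids <- rownames(g)
  alive <- rep(TRUE, length(ids))
  start <- 1L
  m <- length(ids)
  repeat {
    end <- min(start + config$prune_window - 1L, m)
    idx <- seq(start, end)
    idx <- idx[alive[idx]]
    if (length(idx) > 1L) {
      r <- suppressWarnings(stats::cor(t(g[idx, , drop = FALSE]),
                                       use = "pairwise.complete.obs"))
      r[is.na(r)] <- 0
      for (ii in seq_along(idx)[-length(idx)]) {
        if (!alive[idx[ii]]) next
        for (jj in (ii + 1L):length(idx)) {
          if (alive[idx[jj]] && r[ii, jj]^2 > config$prune_r2) {
            alive[idx[jj]] <- FALSE
          }
        }
      }
    }
    if (end == m) break
    start <- start + config$prune_step
  }
  ids[alive]
}

#' Genotype principal components
#'
#' Genotypes are standardized per SNP as `(g - 2p) / sqrt(2p(1-p))`
#' with missing values set to 0 after standardization; the leading
#' eigenvectors of the sample covariance give the PC scores, each
#' rescaled to unit variance. Sign convention: the largest-magnitude
#' loading of each component is positive.
#'
#' @param g SNPs x samples matrix (after filtering/pruning).
#' @param n_pcs number of components.
#' @return samples x n_pcs matrix of scores (columns PC1..).
#' @export
genotype_pca <- function(g, n_pcs = 5L) {
  check_genotypes(g)
  if (nrow(g) < n_pcs) stop("fewer SNPs than requested PCs")
  p <- rowSums(g, na.rm = TRUE) / (2 * rowSums(!is.na(g)))
  keep <- p > 0 & p < 1
  g <- g[keep, , drop = FALSE]
  p <- p[keep]
  if (nrow(g) < n_pcs) stop("fewer polymorphic SNPs than requested PCs")
  Z <- (g - 2 * p) / sqrt(2 * p * (1 - p))
  Z[is.na(Z)] <- 0
  sv <- svd(t(Z), nu = n_pcs, nv = n_pcs)   # samples x SNPs
  scores <- sv$u[, seq_len(n_pcs), drop = FALSE]
  for (k in seq_len(n_pcs)) {
    load <- sv$v[, k]
    if (load[which.max(abs(load))] < 0) scores[, k] <- -scores[, k]
    sk <- stats::sd(scores[, k])
    if (sk > 0) scores[, k] <- scores[, k] / sk
  }
  dimnames(scores) <- list(colnames(g), paste0("PC", seq_len(n_pcs)))
  scores
}

#' Full genotype QC cascade
#'
#' Order: sample call rate, SNP call rate, MAF, HWE, relatedness, then
#' LD pruning and PCA on the clean matrix.
#'
#' @inheritParams call_rate_filter
#' @param pca compute PCs (default TRUE).
#' @return list of class `qc_report`: `genotypes` (clean matrix),
#'   `removed_samples`, `removed_snps`, `related_pairs`, `pruned_snps`
#'   (retained ids), `pcs` (scores matrix or NULL).
#' @export
run_genotype_qc <- function(g, config = qc_config(), pca = TRUE) {
  cr <- call_rate_filter(g, config)
  mf <- maf_filter(cr$genotypes, config)
  hw <- hwe_filter(mf$genotypes, config)
  rel <- relatedness_filter(hw$genotypes, config)
  removed_snps <- rbind(
    cr$removed_snps[c("snp_id", "reason")],
    mf$removed_snps[c("snp_id", "reason")],
    hw$removed_snps[c("snp_id", "reason")])
  removed_samples <- rbind(cr$removed_samples[c("sample_id", "reason")],
                           rel$removed_samples[c("sample_id", "reason")])
  pruned <- ld_prune(rel$genotypes, config)
  pcs <- NULL
  if (pca) {
    pcs <- genotype_pca(rel$genotypes[pruned, , drop = FALSE], config$n_pcs)
  }
  structure(list(genotypes = rel$genotypes,
                 removed_samples = removed_samples,
                 removed_snps = removed_snps,
                 related_pairs = rel$pairs,
                 pruned_snps = pruned, pcs = pcs),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0("qc_report: %d SNPs x %d samples retained; ",
                     "%d samples and %d SNPs removed; %d SNPs after pruning\n"),
              nrow(x$genotypes), ncol(x$genotypes),
              nrow(x$removed_samples), nrow(x$removed_snps),
              length(x$pruned_snps)))
  invisible(x)
}
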