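# Independent oracles, deliberately written as naive double loops /
# direct enumerations so they share no code with the implementation.

# minimum Hamming distance of `probe` to any window of any sequence in
# `seqs`, both strands, by explicit per-offset character comparison
oracle_min_mismatch <- function(probe, seqs) {
  rc <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  pv_f <- strsplit(probe, "")[[1]]
  pv_r <- strsplit(rc(probe), "")[[1]]
  w <- length(pv_f)
  best <- w
  for (s in seqs) {
    sv <- strsplit(s, "")[[1]]
    if (length(sv) < w) next
    for (off in 1:(length(sv) - w + 1)) {
      win <- sv[off:(off + w - 1)]
      best <- min(best, sum(win != pv_f), sum(win != pv_r))
    }
  }
  best
}

# exact HWE p-value by direct enumeration using the factorial formula
# (probability of each heterozygote count given allele counts)
oracle_hwe_p <- function(aa, ab, bb) {
  n <- aa + ab + bb
  na <- 2 * aa + ab
  nb <- 2 * bb + ab
  hets <- seq(min(na, nb) %% 2, min(na, nb), by = 2)
  pr <- sapply(hets, function(h) {
    naa <- (na - h) / 2
    nbb <- (nb - h) / 2
    exp(lfactorial(n) - lfactorial(naa) - lfactorial(h) - lfactorial(nbb) +
          lfactorial(na) + lfactorial(nb) - lfactorial(2 * n) + h * log(2))
  })
  p_obs <- pr[hets == ab]
  sum(pr[pr <= p_obs * (1 + 1e-9)])
}

# Mann-Whitney AUC by brute-force all-pairs count (ties count 1/2)
oracle_auc <- function(score, outcome) {
  pos <- score[outcome == 1]
  neg <- score[outcome == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(pos) * length(neg))
}

# two-group log-rank chi-square by the observed-minus-expected tally at
# each distinct event time
oracle_logrank_chisq <- function(time, event, group) {
  g <- as.integer(as.factor(group))
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Efron partial log-likelihood for a single covariate, written out
# term by term; `oracle_efron_coef` maximises it on a grid
oracle_efron_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    d_idx <- which(time == t & event == 1)
    r_idx <- which(time >= t)
    d <- length(d_idx)
    sum_r <- sum(exp(beta * x[r_idx]))
    sum_d <- sum(exp(beta * x[d_idx]))
    ll <- ll + sum(beta * x[d_idx])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(sum_r - (l / d) * sum_d)
    }
  }
  ll
}

oracle_efron_coef <- function(time, event, x, grid = seq(-5, 5, by = 1e-4)) {
  ll <- vapply(grid, oracle_efron_loglik, numeric(1),
               time = time, event = event, x = x)
  grid[which.max(ll)]
}

# the probe outlier rule restated directly on a vector of probe means
oracle_outlier_ids <- function(means, k = 1.5) {
  names(means)[abs(means - mean(means)) > k * sd(means)]
}
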