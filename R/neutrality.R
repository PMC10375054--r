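# Tajima's (1989) normalising constants as functions of sample size
tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

# segregating sites of an alignment subset (unambiguous bases only)
count_segregating <- function(aln) {
  tot <- site_summary(classify_sites(aln))
  unname(tot["S"])
}

#' Tajima's D
#'
#' The normalised difference between the pairwise-difference estimator
#' of theta (\eqn{\hat k}) and Watterson's segregating-sites estimator
#' (\eqn{S/a_1}):
#' \eqn{D = (\hat k - S/a_1)/\sqrt{e_1 S + e_2 S(S-1)}}.
#' Negative values indicate an excess of rare variants, as expected
#' after a population expansion or under purifying selection.
#'
#' @param aln A [hap_alignment()].
#' @param population Population label or `"all"`.
#' @return One-row tibble: `population`, `n`, `S`, `k_hat`, `D`
#'   (`D = NaN` with a warning when `S = 0`).
#' @export
tajimas_d <- function(aln, population = "all") {
  sub <- aln_subset(aln, population)
  n <- nrow(sub)
  if (n < 4L) abort("Tajima's D requires n >= 4", class = "haplopop_input_error")
  S <- count_segregating(sub)
  k_hat <- nucleotide_diversity(sub)$k_hat
  if (S == 0) {
    warn("no segregating sites: Tajima's D undefined")
    D <- NaN
  } else {
    cst <- tajima_constants(n)
    D <- (k_hat - S / cst$a1) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
  }
  tibble(population = population, n = n, S = as.integer(S), k_hat = k_hat, D = D)
}

#' Coalescent p-value for Tajima's D
#'
#' Simulates `n_sims` neutral constant-size coalescent samples of size
#' `n` with theta fixed at Watterson's estimate \eqn{S/a_1}, computes
#' D for each, and reports a two-tailed p-value:
#' twice the smaller of the lower-tail fraction (\eqn{D^* \le D}) and
#' the upper-tail fraction, capped at 1. Replicates with undefined D
#' (no segregating sites) are counted in neither tail's favour by
#' treating their D as 0.
#'
#' @param D Observed Tajima's D.
#' @param n Sample size.
#' @param S Observed number of segregating sites (sets the null theta).
#' @param n_sims Number of coalescent replicates (default 1000).
#' @param seed RNG seed.
#' @return Two-tailed p-value in (0, 1].
#' @export
tajima_d_pvalue <- function(D, n, S, n_sims = 1000, seed = NULL) {
  if (is.nan(D)) abort("D is undefined", class = "haplopop_input_error")
  if (n_sims < 100) warn("fewer than 100 simulations: p-value will be coarse")
  theta_w <- S / tajima_constants(n)$a1
  sims <- with_seed(seed, {
    vapply(seq_len(n_sims), function(b) {
      st <- sim_summary_stats(n, theta_w)
      if (st$S == 0) return(0)
      cst <- tajima_constants(n)
      (st$k_hat - st$S / cst$a1) / sqrt(cst$e1 * st$S + cst$e2 * st$S * (st$S - 1))
    }, numeric(1))
  })
  lower <- mean(sims <= D)
  upper <- mean(sims >= D)
  min(1, 2 * min(lower, upper))
}

# log unsigned Stirling numbers of the first kind, rows up to n:
# |s(n+1, k)| = n |s(n, k)| + |s(n, k-1)|, computed in log space
log_stirling_first <- function(n) {
  logS <- matrix(-Inf, nrow = n, ncol = n)
  logS[1, 1] <- 0
  if (n > 1L) {
    for (m in 1:(n - 1L)) {
      for (k in 1:(m + 1L)) {
        terms <- c(
          if (k <= m) log(m) + logS[m, k] else -Inf,
          if (k >= 2L) logS[m, k - 1L] else -Inf
        )
        logS[m + 1L, k] <- logsumexp(terms)
      }
    }
  }
  logS
}

# log P(K = k | n, theta) for k = 1..n under the Ewens sampling formula
ewens_log_pmf <- function(n, theta) {
  logS <- log_stirling_first(n)
  log_rising <- sum(log(theta + 0:(n - 1)))
  logS[n, ] + (1:n) * log(theta) - log_rising
}

#' Fu's Fs
#'
#' Under the Ewens sampling formula with theta estimated from mean
#' pairwise differences, \eqn{S'} is the probability of observing at
#' least as many distinct alleles (haplotypes) as sampled;
#' \eqn{F_s = \ln(S'/(1-S'))}. Large negative values (an excess of
#' alleles relative to theta) indicate population growth.
#'
#' @param n Sample size (>= 2).
#' @param k_obs Observed number of distinct haplotypes (1..n).
#' @param theta Positive theta estimate, conventionally \eqn{\hat k}
#'   (mean pairwise differences).
#' @return Fs; `+Inf` when `k_obs = 1` (the tail probability is 1).
#' @export
fus_fs <- function(n, k_obs, theta) {
  if (n < 2L || k_obs < 1L || k_obs > n) {
    abort("need n >= 2 and 1 <= k_obs <= n", class = "haplopop_input_error")
  }
  if (theta <= 0) abort("theta must be > 0", class = "haplopop_input_error")
  if (k_obs == 1L) return(Inf)
  lp <- ewens_log_pmf(n, theta)
  log_upper <- logsumexp(lp[k_obs:n])       # log P(K >= k_obs)
  log_lower <- logsumexp(lp[1:(k_obs - 1L)])  # log P(K < k_obs)
  # Fs = log(S') - log(1 - S'), each tail computed directly in log space
  log_upper - log_lower
}

#' Coalescent p-value for Fu's Fs
#'
#' Simulates neutral constant-size samples with the given theta,
#' computes each replicate's Fs from its own haplotype count and mean
#' pairwise differences, and reports the lower-tail fraction
#' \eqn{P(F_s^* \le F_s^{obs})}. By Fu's convention the test is called
#' significant at the nominal 5% level when p < 0.02.
#'
#' @param Fs_obs Observed Fs.
#' @param n Sample size.
#' @param theta Theta for the neutral null (the observed \eqn{\hat k}).
#' @param n_sims Number of replicates (default 1000).
#' @param seed RNG seed.
#' @return Lower-tail p-value in (0, 1].
#' @export
fs_pvalue <- function(Fs_obs, n, theta, n_sims = 1000, seed = NULL) {
  sims <- with_seed(seed, {
    vapply(seq_len(n_sims), function(b) {
      st <- sim_summary_stats(n, theta)
      th <- if (st$k_hat > 0) st$k_hat else NA_real_
      if (is.na(th)) Inf else fus_fs(n, st$K, th)
    }, numeric(1))
  })
  mean(sims <= Fs_obs)
}

#' Neutrality-test summary per population
#'
#' @param aln A [hap_alignment()].
#' @param n_sims Coalescent replicates for both p-values (default 1000).
#' @param seed RNG seed (per-population streams derived deterministically).
#' @param populations Populations to test (default: all in `aln`).
#' @return Tibble: `population`, `n`, `S`, `k_hat`, `D`, `D_pvalue`,
#'   `Fs`, `Fs_pvalue`.
#' @export
neutrality_tests <- function(aln, n_sims = 1000, seed = NULL,
                             populations = NULL) {
  populations <- populations %||% unique(aln$population)
  rows <- purrr::map(populations, function(p) {
    td <- tajimas_d(aln, p)
    sub <- aln_subset(aln, p)
    k_obs <- length(unique(sub$sequence))
    fs <- if (td$k_hat > 0) fus_fs(td$n, k_obs, td$k_hat) else NA_real_
    sd1 <- if (is.null(seed)) NULL else derive_seed(seed, paste0("tajima_", p))
    sd2 <- if (is.null(seed)) NULL else derive_seed(seed, paste0("fs_", p))
    dp <- if (!is.nan(td$D)) tajima_d_pvalue(td$D, td$n, td$S, n_sims, sd1) else NA_real_
    fp <- if (!is.na(fs) && is.finite(fs)) fs_pvalue(fs, td$n, td$k_hat, n_sims, sd2) else NA_real_
    mutate(td, D_pvalue = dp, Fs = fs, Fs_pvalue = fp)
  })
  bind_rows(rows)
}
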