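test_that("Tajima's D matches a hand-evaluated toy", {
  # n = 5, S = 3, k_hat = 1.4; D frozen from an independent exact
  # rational-arithmetic evaluation of the constants
  aln <- hap_alignment(paste0("s", 1:5), rep("X", 5),
                       c("AAAAAAAAAA", "AAAAAAAAAT", "AAAAAAAATT",
                         "AAAAAAAAAA", "AAAAATAAAA"))
  td <- tajimas_d(aln)
  expect_equal(td$S, 3L)
  expect_equal(td$k_hat, 1.4)
  expect_equal(td$D, -0.17474884742461846, tolerance = 1e-12)
})

test_that("Tajima's D edge cases behave as defined", {
  mono <- hap_alignment(paste0("s", 1:5), rep("X", 5), rep("ACGT", 5))
  expect_warning(td <- tajimas_d(mono), "undefined")
  expect_true(is.nan(td$D))
  small <- hap_alignment(paste0("s", 1:3), rep("X", 3),
                         c("AAT", "ATT", "AAA"))
  expect_error(tajimas_d(small), class = "haplopop_input_error")
})

test_that("Tajima's D p-value is central for D = 0 and reproducible", {
  p0 <- tajima_d_pvalue(0, n = 20, S = 10, n_sims = 400, seed = 21)
  expect_gt(p0, 0.5)
  p1 <- tajima_d_pvalue(-1.8, n = 30, S = 12, n_sims = 300, seed = 8)
  p2 <- tajima_d_pvalue(-1.8, n = 30, S = 12, n_sims = 300, seed = 8)
  expect_identical(p1, p2)
  expect_warning(tajima_d_pvalue(0, 10, 5, n_sims = 50, seed = 1), "coarse")
})

test_that("Fu's Fs agrees with exhaustive Ewens enumeration on toys", {
  expect_identical(fus_fs(10, 1, 2), Inf)
  # n = 4, theta = 1: |s(4,k)| = (6, 11, 6, 1), rising factorial 24
  expect_equal(fus_fs(4, 3, 1), log((7 / 24) / (17 / 24)), tolerance = 1e-12)
  expect_equal(fus_fs(4, 2, 1), log((18 / 24) / (6 / 24)), tolerance = 1e-12)
  expect_error(fus_fs(4, 2, 0), class = "haplopop_input_error")
  expect_error(fus_fs(1, 1, 1), class = "haplopop_input_error")
})

test_that("Ewens probabilities from the log-Stirling recursion match the
           polynomial-expansion oracle", {
  for (n in c(4, 6, 8)) {
    for (theta in c(0.1, 1, 10)) {
      got <- exp(haplopop:::ewens_log_pmf(n, theta))
      expect_equal(got, oracle_ewens_pmf(n, theta), tolerance = 1e-10)
      expect_equal(sum(got), 1, tolerance = 1e-10)
    }
  }
})

test_that("Fs p-value is reproducible and detects expansion fixtures", {
  p1 <- fs_pvalue(-3, n = 30, theta = 1.5, n_sims = 200, seed = 31)
  p2 <- fs_pvalue(-3, n = 30, theta = 1.5, n_sims = 200, seed = 31)
  expect_identical(p1, p2)
  # a strongly star-like expansion sample: many haplotypes, low k_hat
  sim <- simulate_coalescent(60, theta = 8,
                             demography = demography_expansion(0.15, 100),
                             seed = 17)
  nd <- nucleotide_diversity(sim$alignment)
  k_obs <- length(unique(sim$alignment$sequence))
  fs <- fus_fs(60, k_obs, nd$k_hat)
  expect_lt(fs, 0)
  expect_lt(fs_pvalue(fs, 60, nd$k_hat, n_sims = 300, seed = 5), 0.02)
})

test_that("observed mismatch distribution matches pair enumeration", {
  mono <- hap_alignment(paste0("s", 1:4), rep("X", 4), rep("ACGT", 4))
  expect_equal(mismatch_observed(mono), 1)
  two <- hap_alignment(c("a", "b"), c("X", "X"), c("AAAAA", "ATTTA"))
  expect_equal(mismatch_observed(two), c(0, 0, 0, 1))
  for (s in 1:5) {
    aln <- rand_alignment(n = 7, L = 12, seed = s + 600)
    obs <- mismatch_observed(aln)
    d <- oracle_dist(aln$sequence)
    dv <- d[upper.tri(d)]
    expect_equal(obs, as.vector(table(factor(dv, levels = 0:max(dv)))) /
                   length(dv))
  }
})

test_that("expected mismatch reduces to the geometric equilibrium", {
  th <- 1.7
  e <- mismatch_expected(0, th, th, 12, renormalize = FALSE)
  expect_equal(e, th^(0:12) / (1 + th)^(1:13), tolerance = 1e-12)
  e2 <- mismatch_expected(3, 0.4, 80, 25)
  expect_equal(sum(e2), 1, tolerance = 1e-12)
  expect_true(all(e2 >= 0))
})

test_that("expected mismatch matches independent numerical integration", {
  cases <- list(c(1.5, 0.5, 100), c(0.8, 1, 10), c(4, 0.2, 50))
  for (cs in cases) {
    got <- mismatch_expected(cs[1], cs[2], cs[3], 15, renormalize = FALSE)
    ora <- oracle_mismatch_expected(cs[1], cs[2], cs[3], 15)
    expect_equal(got, ora, tolerance = 1e-7)
  }
})

test_that("SSD is invariant to appending zero-frequency classes", {
  obs <- mismatch_expected(1.2, 0.3, 60, 10)
  f1 <- fit_sudden_expansion(obs)
  f2 <- fit_sudden_expansion(c(obs, 0, 0, 0) / sum(c(obs, 0, 0, 0)))
  expect_equal(f1$SSD, f2$SSD, tolerance = 1e-6)
})

test_that("sudden-expansion fit recovers generating parameters", {
  obs <- mismatch_expected(1.0, 0.5, 50, 20)
  fit <- fit_sudden_expansion(obs, n = 50)
  expect_lt(fit$SSD, 1e-8)
  expect_equal(fit$tau, 1.0, tolerance = 0.1)
})

test_that("degenerate single-class distributions hit the tau = 0 boundary", {
  expect_warning(fit <- fit_sudden_expansion(1), "degenerate")
  expect_equal(fit$tau, 0)
  expect_equal(fit$SSD, 0)
})

test_that("raggedness follows its defining sum of squared steps", {
  expect_equal(raggedness(c(1)), 1)        # (0-1)^2 with trailing zero
  expect_equal(raggedness(c(0.5, 0.3, 0.2)),
               (0.3 - 0.5)^2 + (0.2 - 0.3)^2 + (0 - 0.2)^2)
})

test_that("goodness-of-fit bootstrap is calibrated and reproducible", {
  set.seed(77)
  ok <- 0
  n_trials <- 20
  for (i in seq_len(n_trials)) {
    obs <- haplopop:::sim_mismatch_vector(50, 50, demography_expansion(0.02, 100))
    fit <- fit_sudden_expansion(obs, n = 50)
    fit <- gof_bootstrap(fit, n_boot = 60, seed = 1000 + i)
    if (fit$SSD_pvalue > 0.05) ok <- ok + 1
  }
  expect_gte(ok, 16)  # ~ uniform p under the generating model
  obs <- mismatch_expected(1, 0.5, 50, 12)
  f1 <- gof_bootstrap(fit_sudden_expansion(obs, n = 40), n_boot = 60, seed = 3)
  f2 <- gof_bootstrap(fit_sudden_expansion(obs, n = 40), n_boot = 60, seed = 3)
  expect_identical(f1$SSD_pvalue, f2$SSD_pvalue)
})

test_that("grossly bimodal distributions are rejected by the bootstrap", {
  obs <- c(0.35, 0.05, 0.02, 0.02, 0.05, 0.28, 0.15, 0.05, 0.02, 0.01)
  fit <- fit_sudden_expansion(obs, n = 60)
  fit <- gof_bootstrap(fit, n_boot = 100, seed = 12)
  expect_lt(fit$raggedness_pvalue, 0.1)
})

test_that("expansion-time arithmetic follows tau = 2ut", {
  expect_equal(expansion_time(0, "3.1%/Myr", 683)$t_years, 0)
  et <- expansion_time(1.0, 3.1e-8, 683, 1)
  expect_equal(et$t_years, 1 / (2 * 683 * 3.1e-8), tolerance = 1e-12)
  expect_equal(et$t_years, 23614.98, tolerance = 1e-4)
  # doubling L halves t at fixed tau
  expect_equal(expansion_time(1, 3.1e-8, 2 * 683)$t_years, et$t_years / 2)
  # the divergence-rate convention doubles the time
  expect_equal(expansion_time(1, "3.1%/Myr", 683,
                              convention = "divergence")$t_years,
               2 * et$t_years)
  expect_equal(parse_rate("3.1%/Myr"), 3.1e-8)
  expect_error(parse_rate("fast"), class = "haplopop_config_error")
  expect_error(expansion_time(1, 0, 683), class = "haplopop_undefined_error")
})
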