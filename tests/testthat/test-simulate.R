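test_that("simulations are bit-identical under a fixed seed", {
  s1 <- simulate_coalescent(c(5, 5), theta = 2,
                            demography = demography_island(Nm = 2),
                            L = 100, seed = 42)
  s2 <- simulate_coalescent(c(5, 5), theta = 2,
                            demography = demography_island(Nm = 2),
                            L = 100, seed = 42)
  expect_identical(s1$alignment$sequence, s2$alignment$sequence)
  expect_identical(s1$genealogy$time, s2$genealogy$time)
  s3 <- simulate_fujian_like(seed = 3)
  s4 <- simulate_fujian_like(seed = 3)
  expect_identical(s3$alignment$sequence, s4$alignment$sequence)
})

test_that("mean segregating sites match the Watterson expectation", {
  set.seed(7)
  S <- replicate(2000, haplopop:::sim_summary_stats(10, 5)$S)
  expect_equal(mean(S), 5 * sum(1 / (1:9)), tolerance = 0.05 * 5 * sum(1 / (1:9)))
})

test_that("infinite-sites output is homoplasy-free (four-gamete test)", {
  for (s in 1:5) {
    sim <- simulate_coalescent(12, theta = 6, L = 300, seed = 700 + s)
    m <- do.call(rbind, strsplit(sim$alignment$sequence, ""))
    var_cols <- which(apply(m, 2, function(x) length(unique(x)) > 1))
    if (length(var_cols) < 2) next
    for (a in head(var_cols, 15)) {
      for (b in var_cols[var_cols > a]) {
        gametes <- unique(paste(m[, a], m[, b]))
        expect_lte(length(gametes), 3)
      }
    }
  }
})

test_that("finite-sites mode produces valid alignments consistent with L", {
  sim <- simulate_coalescent(8, theta = 3, L = 50,
                             mutation_model = "finite_sites_JC", seed = 99)
  expect_equal(aln_length(sim$alignment), 50L)
  expect_true(all(grepl("^[ACGT]+$", sim$alignment$sequence)))
})

test_that("the simulated tree is a valid ultrametric-by-construction phylo", {
  sim <- simulate_coalescent(10, theta = 1, seed = 5)
  phy <- sim$tree
  expect_s3_class(phy, "phylo")
  expect_equal(ape::Ntip(phy), 10L)
  expect_true(ape::is.ultrametric(phy, tol = 1e-8))
})

test_that("island-model differentiation decreases with migration", {
  set.seed(13)
  mean_phi <- vapply(c(0.5, 5, 50), function(nm) {
    phis <- replicate(200, {
      sim <- simulate_coalescent(c(8, 8), theta = 3,
                                 demography = demography_island(Nm = nm),
                                 L = 150)
      am <- suppressWarnings(
        amova(pairwise_difference_matrix(sim$alignment),
              sim$alignment$population, n_perm = 0))
      am$phi_st
    })
    mean(phis, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(mean_phi) < 0))
  expect_gt(mean_phi[1], 0.2)    # strong structure at Nm = 0.5
  expect_lt(mean_phi[3], 0.05)   # near panmixia at Nm = 50
})

test_that("the study-like simulator matches the survey design", {
  sim <- simulate_fujian_like(seed = 8)
  aln <- sim$alignment
  expect_equal(nrow(aln), 390L)
  expect_equal(aln_length(aln), 683L)
  expect_equal(as.integer(table(aln$population)), rep(65L, 6))
})

test_that("study-like simulations show weak structure and expansion signals", {
  set.seed(55)
  seeds <- 1:8
  phi_means <- numeric(0)
  d_means <- numeric(0)
  unimodal <- logical(0)
  for (s in seeds) {
    sim <- simulate_fujian_like(seed = 100 + s)
    aln <- sim$alignment
    d <- pairwise_difference_matrix(aln)
    pw <- pairwise_phist(d, aln$population, n_perm = 0)
    phi_means <- c(phi_means, mean(pw$phi_st[upper.tri(pw$phi_st)], na.rm = TRUE))
    d_means <- c(d_means, suppressWarnings(mean(vapply(unique(aln$population),
      function(p) tajimas_d(aln, p)$D, numeric(1)), na.rm = TRUE)))
    obs <- mismatch_observed(aln)
    big <- which(obs > 0.02)
    interior_modes <- sum(vapply(seq_along(obs), function(i) {
      obs[i] > 0.02 &&
        (i == 1 || obs[i] >= obs[i - 1]) &&
        (i == length(obs) || obs[i] > obs[i + 1])
    }, logical(1)))
    unimodal <- c(unimodal, interior_modes <= 1)
  }
  expect_lt(abs(mean(phi_means)), 0.03)
  expect_true(all(d_means < 0))
  expect_gte(mean(unimodal), 0.8)
})

test_that("simulated datasets round-trip through FASTA output", {
  sim <- simulate_coalescent(c(4, 4), theta = 2, L = 60, seed = 11)
  fa <- withr::local_tempfile(fileext = ".fasta")
  pm <- withr::local_tempfile(fileext = ".tsv")
  pr <- withr::local_tempfile(fileext = ".tsv")
  write_sim_dataset(sim, fa, pm, pr)
  back <- read_fasta(fa, pm)
  expect_equal(back$sequence, sim$alignment$sequence)
  expect_equal(back$population, sim$alignment$population)
  expect_true(file.exists(pr))
})

test_that("invalid simulator configurations are rejected", {
  expect_error(simulate_coalescent(0, 1), class = "haplopop_config_error")
  expect_error(simulate_coalescent(5, -1), class = "haplopop_config_error")
  expect_error(demography_expansion(-1, 2), class = "haplopop_config_error")
  expect_error(demography_island(-3), class = "haplopop_config_error")
  # two isolated demes can never find a common ancestor
  expect_error(simulate_coalescent(c(3, 3), 1,
                                   demography = demography_island(Nm = 0),
                                   seed = 1),
               class = "haplopop_config_error")
})
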