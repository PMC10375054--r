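test_that("pairwise difference matrix matches the brute-force double loop", {
  expect_equal(unname(pairwise_difference_matrix(
    hap_alignment(c("a", "b"), c("X", "X"), c("AAAA", "AAAA")))[1, 2]), 0)
  expect_equal(unname(pairwise_difference_matrix(
    hap_alignment(c("a", "b"), c("X", "X"), c("AAAA", "AATT")))[1, 2]), 2)
  for (s in 1:8) {
    aln <- rand_alignment(n = 8, L = 20, p_ambig = 0.05, seed = s + 400)
    expect_equal(unname(pairwise_difference_matrix(aln)),
                 oracle_dist(aln$sequence))
  }
})

test_that("AMOVA reproduces hand-computed sums of squares", {
  # two populations of three; within-pop squared distances sum to 2 each,
  # between-pop to 56: SS_total = 10, SS_within = 4/3, Vb = 1/3,
  # n_bar = 3, Va = 25/9, Phi_ST = 25/28
  aln <- hap_alignment(paste0("s", 1:6), rep(c("P1", "P2"), each = 3),
                       c("AAAA", "AAAT", "AAAA", "TTAA", "TTAT", "TTAA"))
  am <- amova(pairwise_difference_matrix(aln), aln$population, n_perm = 0)
  expect_equal(am$ss_total, 10)
  expect_equal(am$ss_within, 4 / 3)
  expect_equal(am$ss_among, 26 / 3)
  expect_equal(am$vb, 1 / 3)
  expect_equal(am$va, 25 / 9)
  expect_equal(am$phi_st, 25 / 28)
  td <- tidy(am)
  expect_equal(sum(td$percent[1:2]), 100, tolerance = 0.01)
  expect_equal(td$df[1:2], c(1L, 4L))
})

test_that("fixed difference between populations gives Phi_ST = 1", {
  aln <- hap_alignment(paste0("s", 1:4), c("A", "A", "B", "B"),
                       c("AAAA", "AAAA", "TAAA", "TAAA"))
  am <- amova(pairwise_difference_matrix(aln), aln$population, n_perm = 99,
              seed = 1)
  expect_equal(am$phi_st, 1)
  expect_equal(tidy(am)$percent[1], 100)
})

test_that("all-zero distances yield an undefined Phi_ST with a warning", {
  aln <- hap_alignment(paste0("s", 1:4), c("A", "A", "B", "B"),
                       rep("AAAA", 4))
  expect_warning(am <- amova(pairwise_difference_matrix(aln),
                             aln$population, n_perm = 10, seed = 1),
                 "undefined")
  expect_true(is.nan(am$phi_st))
})

test_that("permutation p-values are reproducible given the seed", {
  aln <- rand_alignment(n = 12, L = 30, n_pop = 2, seed = 11)
  d <- pairwise_difference_matrix(aln)
  p1 <- amova(d, aln$population, n_perm = 200, seed = 5)$p_value
  p2 <- amova(d, aln$population, n_perm = 200, seed = 5)$p_value
  expect_identical(p1, p2)
  pw1 <- pairwise_phist(d, aln$population, n_perm = 100, seed = 7)
  pw2 <- pairwise_phist(d, aln$population, n_perm = 100, seed = 7)
  expect_identical(pw1$p_value, pw2$p_value)
})

test_that("random labelling of one panmictic pool gives mean Phi_ST near 0", {
  set.seed(99)
  phis <- replicate(500, {
    sim <- simulate_coalescent(16, theta = 3, L = 200)
    d <- pairwise_difference_matrix(sim$alignment)
    labs <- sample(rep(c("A", "B"), 8))
    am <- suppressWarnings(amova(d, labs, n_perm = 0))
    am$phi_st
  })
  expect_lt(abs(mean(phis, na.rm = TRUE)), 0.03)
})

test_that("pairwise Phi_ST handles identical and fixed-difference pops", {
  # same composition in both populations: Phi_ST ~ 0, p large
  seqs <- c("AAAA", "AAAT", "AAAA", "AAAT")
  aln <- hap_alignment(paste0("s", 1:4), c("A", "A", "B", "B"), seqs)
  pw <- pairwise_phist(pairwise_difference_matrix(aln), aln$population,
                       n_perm = 99, seed = 2)
  expect_lt(pw$phi_st["A", "B"], 0.01)
  expect_gt(pw$p_value["A", "B"], 0.2)
  # fixed difference: Phi_ST = 1
  aln2 <- hap_alignment(paste0("s", 1:4), c("A", "A", "B", "B"),
                        c("GAAA", "GAAA", "TAAA", "TAAA"))
  pw2 <- pairwise_phist(pairwise_difference_matrix(aln2), aln2$population,
                        n_perm = 0)
  expect_equal(pw2$phi_st["A", "B"], 1)
  expect_true(all(tidy(pw2)$p_holm >= tidy(pw2)$p_value, na.rm = TRUE))
})

test_that("d_xy matches direct expectations and the brute-force oracle", {
  aln <- hap_alignment(paste0("s", 1:4), c("A", "A", "B", "B"),
                       rep("ACGTACGTAC", 4))
  expect_equal(dxy(aln, "A", "B"), 0)
  aln2 <- hap_alignment(paste0("s", 1:4), c("A", "A", "B", "B"),
                        c(rep("AAAAAAAAAA", 2), rep("AAAAAAAAAT", 2)))
  expect_equal(dxy(aln2, "A", "B"), 0.1)
  for (s in 1:5) {
    aln3 <- rand_alignment(n = 8, L = 15, n_pop = 2, p_ambig = 0.05,
                           seed = s + 500)
    a <- aln3$sequence[aln3$population == "pop1"]
    b <- aln3$sequence[aln3$population == "pop2"]
    acc <- 0
    for (x in a) for (y in b) {
      cx <- strsplit(x, "")[[1]]; cy <- strsplit(y, "")[[1]]
      ok <- cx %in% BASES & cy %in% BASES
      acc <- acc + sum(cx[ok] != cy[ok]) / sum(ok)
    }
    expect_equal(dxy(aln3, "pop1", "pop2"), acc / (length(a) * length(b)))
  }
})

test_that("NJ recovers additive four-taxon trees exactly", {
  set.seed(123)
  for (rep in 1:10) {
    x <- runif(5, 0.5, 3)   # pendant a,b,c,d + internal edge
    d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
    d["a", "b"] <- d["b", "a"] <- x[1] + x[2]
    d["c", "d"] <- d["d", "c"] <- x[3] + x[4]
    d["a", "c"] <- d["c", "a"] <- x[1] + x[5] + x[3]
    d["a", "d"] <- d["d", "a"] <- x[1] + x[5] + x[4]
    d["b", "c"] <- d["c", "b"] <- x[2] + x[5] + x[3]
    d["b", "d"] <- d["d", "b"] <- x[2] + x[5] + x[4]
    phy <- nj_tree(d)
    path <- ape::cophenetic.phylo(phy)[letters[1:4], letters[1:4]]
    expect_equal(path, d, tolerance = 1e-9)
  }
})

test_that("NJ handles two taxa and rejects asymmetric input", {
  d <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  phy <- nj_tree(d)
  expect_equal(sum(phy$edge.length), 3)
  d2 <- matrix(c(0, 1, 2, 0), 2)
  expect_error(nj_tree(d2), class = "haplopop_input_error")
})

test_that("bootstrap support separates well-differentiated clusters", {
  base <- strrep("A", 30)
  far <- paste0(strrep("T", 10), strrep("A", 20))
  mut <- function(s, pos, to) { substr(s, pos, pos) <- to; s }
  seqs <- c(base, mut(base, 15, "G"), far, mut(far, 25, "C"))
  aln <- hap_alignment(paste0("s", 1:4), rep("X", 4), seqs)
  bs <- bootstrap_support(aln, n_reps = 99, seed = 4, collapse = FALSE)
  expect_gte(max(bs$support), 95)
  one <- bootstrap_support(aln, n_reps = 1, seed = 4, collapse = FALSE)
  expect_true(all(one$support %in% c(0, 100)))
})

test_that("star-like simulated haplotypes give shallow NJ trees", {
  sim <- simulate_coalescent(40, theta = 3,
                             demography = demography_expansion(0.2, 50),
                             seed = 12)
  tab <- collapse_haplotypes(sim$alignment)
  d <- haplopop:::hap_dist_matrix(tab$sequence)
  dimnames(d) <- list(tab$haplotype, tab$haplotype)
  phy <- nj_tree(d)
  # internal branches should be tiny relative to total tree depth
  internal <- phy$edge[, 2] > ape::Ntip(phy)
  expect_lt(mean(phy$edge.length[internal]), 1.5)
})
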