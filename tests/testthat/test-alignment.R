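test_that("FASTA + popmap round-trips through read/write", {
  aln <- hap_alignment(c("s1", "s2"), c("A", "B"), c("acgtt", "ACGTA"))
  expect_equal(nrow(aln), 2L)
  expect_equal(aln_length(aln), 5L)
  expect_equal(aln$sequence[1], "ACGTT")  # upper-cased on input

  fa <- withr::local_tempfile(fileext = ".fasta")
  pm <- withr::local_tempfile(fileext = ".tsv")
  write_fasta(aln, fa, popmap_path = pm)
  back <- read_fasta(fa, pm)
  expect_equal(back$sequence, aln$sequence)
  expect_equal(back$population, aln$population)
})

test_that("alignment validation rejects malformed input", {
  expect_error(hap_alignment(c("a", "b"), c("X", "X"), c("ACGTA", "ACGTAA")),
               class = "haplopop_alignment_error")
  expect_error(hap_alignment(c("a", "a"), c("X", "X"), c("ACG", "ACG")),
               class = "haplopop_input_error")
  fa <- withr::local_tempfile(fileext = ".fasta")
  pm <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(">s1", "ACGT", ">s2", "ACGA"), fa)
  writeLines("s1\tA", pm)
  expect_error(read_fasta(fa, pm), class = "haplopop_mapping_error")
  writeLines(character(0), fa)
  expect_error(read_fasta(fa, pm), class = "haplopop_input_error")
})

test_that("IUPAC ambiguity codes other than N are degraded to N", {
  aln <- hap_alignment("s1", "X", "ARYGT-N")
  expect_equal(aln$sequence, "ANNGT-N")
})

test_that("base composition masks ambiguity and matches a hand tally", {
  expect_equal(base_composition(hap_alignment("a", "X", "AT"))$proportion,
               c(0.5, 0, 0, 0.5))
  expect_equal(base_composition(hap_alignment("a", "X", "AANN"))$proportion,
               c(1, 0, 0, 0))
  # 3 x 4 toy with hand-counted bases: A=3, C=2, G=2, T=3 over 10
  aln <- hap_alignment(paste0("s", 1:3), rep("X", 3),
                       c("ACGT", "AC-T", "AGNT"))
  expect_equal(base_composition(aln)$proportion, c(3, 2, 2, 3) / 10)
  expect_error(base_composition(hap_alignment("a", "X", "NN--")),
               class = "haplopop_composition_error")
})

test_that("site classification follows the singleton/informative rules", {
  aln <- hap_alignment(paste0("s", 1:4), rep("X", 4),
                       c("AAAC", "AAAC", "ATAC", "TTNC"))
  # col1 A,A,A,T singleton; col2 A,A,T,T informative; col3 A,A,A,N
  # invariant; col4 invariant
  cats <- classify_sites(aln)$category
  expect_equal(cats, c("singleton", "parsimony_informative",
                       "invariant", "invariant"))
  tot <- site_summary(classify_sites(aln))
  expect_equal(unname(tot["S"]), 2)
  # columns observable in < 2 sequences are excluded
  aln2 <- hap_alignment(c("a", "b"), c("X", "X"), c("AN", "AN"))
  expect_equal(classify_sites(aln2)$category, c("invariant", "excluded"))
})

test_that("site totals satisfy S = singletons + informative on random alignments", {
  for (s in 1:20) {
    aln <- rand_alignment(n = 8, L = 30, p_ambig = 0.05, seed = s)
    tot <- site_summary(classify_sites(aln))
    expect_equal(unname(tot["S"]), unname(tot["n_singleton"] + tot["n_pi"]))
    expect_equal(unname(sum(tot[c("S", "n_invariant", "n_excluded")])), 30)
    # brute-force per-column recount
    m <- do.call(rbind, strsplit(aln$sequence, ""))
    S_brute <- sum(vapply(seq_len(ncol(m)), function(j) {
      b <- m[, j][m[, j] %in% BASES]
      length(b) >= 2 && length(unique(b)) >= 2
    }, logical(1)))
    expect_equal(unname(tot["S"]), S_brute)
  }
})

test_that("base composition sums to one whenever defined", {
  for (s in 1:10) {
    aln <- rand_alignment(n = 5, L = 40, p_ambig = 0.1, seed = s + 100)
    expect_equal(sum(base_composition(aln)$proportion), 1, tolerance = 1e-12)
  }
})

test_that("ORF screening flags premature stops under the right code", {
  # TAA mid-sequence in frame 0 is premature under any supported code
  aln <- hap_alignment("s1", "X", "ATGTAACCAGGG")
  res <- check_orf(aln, frame = 0)
  expect_equal(res$stop_codons[[1]], 2L)
  # AGA codes for serine in invertebrate mitochondria but is a stop in
  # vertebrate mitochondria
  aln2 <- hap_alignment("s1", "X", "ATGAGACCAGGG")
  expect_equal(check_orf(aln2, frame = 0)$n_stops, 0L)
  expect_equal(check_orf(aln2, frame = 0,
                         code = "vertebrate_mitochondrial")$n_stops, 1L)
  expect_error(check_orf(aln2, code = "nope"), class = "haplopop_config_error")
})

test_that("the reconstructed count-table fixture is ORF-clean", {
  orf <- check_orf(table1_fixture())
  expect_true(all(orf$n_stops == 0L))
})
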