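# Published haplotype-by-locality count matrix for the six Fujian
# localities (ND, FZ, PT, QZ, XM, ZZ): 84 haplotypes x 6 populations,
# column sums 65, grand total 390. Used by the fixture generator below.
fujian_hap_counts <- function() {
  m <- matrix(c(
    1L, 0L, 0L, 3L, 3L, 2L,
    30L, 42L, 32L, 36L, 47L, 37L,
    0L, 0L, 0L, 0L, 0L, 2L,
    0L, 0L, 0L, 0L, 0L, 2L,
    1L, 2L, 2L, 3L, 0L, 2L,
    0L, 0L, 0L, 2L, 0L, 5L,
    0L, 0L, 0L, 0L, 0L, 1L,
    1L, 0L, 0L, 0L, 0L, 1L,
    2L, 2L, 4L, 4L, 0L, 5L,
    0L, 1L, 0L, 0L, 0L, 1L,
    0L, 0L, 0L, 0L, 0L, 1L,
    0L, 0L, 0L, 0L, 0L, 1L,
    2L, 0L, 0L, 0L, 2L, 1L,
    0L, 0L, 0L, 0L, 0L, 1L,
    0L, 0L, 0L, 0L, 0L, 1L,
    0L, 1L, 2L, 0L, 0L, 1L,
    1L, 0L, 0L, 0L, 3L, 1L,
    0L, 0L, 0L, 0L, 1L, 0L,
    1L, 0L, 0L, 1L, 3L, 0L,
    0L, 0L, 0L, 0L, 1L, 0L,
    0L, 0L, 0L, 0L, 1L, 0L,
    0L, 0L, 0L, 0L, 1L, 0L,
    0L, 0L, 0L, 0L, 1L, 0L,
    0L, 0L, 0L, 0L, 1L, 0L,
    0L, 0L, 0L, 0L, 1L, 0L,
    2L, 3L, 3L, 4L, 0L, 0L,
    0L, 0L, 0L, 1L, 0L, 0L,
    0L, 0L, 0L, 1L, 0L, 0L,
    2L, 0L, 0L, 1L, 0L, 0L,
    0L, 0L, 0L, 1L, 0L, 0L,
    0L, 0L, 0L, 1L, 0L, 0L,
    0L, 0L, 0L, 1L, 0L, 0L,
    0L, 0L, 0L, 1L, 0L, 0L,
    0L, 0L, 0L, 1L, 0L, 0L,
    0L, 0L, 0L, 1L, 0L, 0L,
    0L, 0L, 0L, 1L, 0L, 0L,
    0L, 0L, 0L, 1L, 0L, 0L,
    0L, 0L, 0L, 1L, 0L, 0L,
    1L, 0L, 1L, 0L, 0L, 0L,
    0L, 0L, 1L, 0L, 0L, 0L,
    0L, 0L, 1L, 0L, 0L, 0L,
    0L, 0L, 1L, 0L, 0L, 0L,
    0L, 0L, 1L, 0L, 0L, 0L,
    0L, 0L, 1L, 0L, 0L, 0L,
    0L, 0L, 1L, 0L, 0L, 0L,
    0L, 0L, 1L, 0L, 0L, 0L,
    1L, 0L, 1L, 0L, 0L, 0L,
    0L, 0L, 1L, 0L, 0L, 0L,
    0L, 0L, 1L, 0L, 0L, 0L,
    0L, 0L, 1L, 0L, 0L, 0L,
    0L, 1L, 1L, 0L, 0L, 0L,
    0L, 1L, 1L, 0L, 0L, 0L,
    0L, 1L, 1L, 0L, 0L, 0L,
    0L, 1L, 1L, 0L, 0L, 0L,
    0L, 1L, 1L, 0L, 0L, 0L,
    0L, 1L, 1L, 0L, 0L, 0L,
    0L, 1L, 1L, 0L, 0L, 0L,
    0L, 1L, 1L, 0L, 0L, 0L,
    0L, 1L, 1L, 0L, 0L, 0L,
    0L, 1L, 1L, 0L, 0L, 0L,
    1L, 0L, 0L, 0L, 0L, 0L,
    1L, 0L, 0L, 0L, 0L, 0L,
    1L, 0L, 0L, 0L, 0L, 0L,
    1L, 0L, 0L, 0L, 0L, 0L,
    1L, 0L, 0L, 0L, 0L, 0L,
    1L, 0L, 0L, 0L, 0L, 0L,
    1L, 0L, 0L, 0L, 0L, 0L,
    1L, 0L, 0L, 0L, 0L, 0L,
    1L, 0L, 0L, 0L, 0L, 0L,
    1L, 0L, 0L, 0L, 0L, 0L,
    1L, 0L, 0L, 0L, 0L, 0L,
    1L, 0L, 0L, 0L, 0L, 0L,
    1L, 0L, 0L, 0L, 0L, 0L,
    1L, 0L, 0L, 0L, 0L, 0L,
    1L, 0L, 0L, 0L, 0L, 0L,
    1L, 0L, 0L, 0L, 0L, 0L,
    1L, 0L, 0L, 0L, 0L, 0L,
    1L, 0L, 0L, 0L, 0L, 0L,
    1L, 0L, 0L, 0L, 0L, 0L,
    1L, 0L, 0L, 0L, 0L, 0L,
    0L, 1L, 0L, 0L, 0L, 0L,
    0L, 1L, 0L, 0L, 0L, 0L,
    0L, 1L, 0L, 0L, 0L, 0L,
    0L, 1L, 0L, 0L, 0L, 0L
  ), nrow = 84L, ncol = 6L, byrow = TRUE,
  dimnames = list(paste0("H", 1:84), c("ND", "FZ", "PT", "QZ", "XM", "ZZ")))
  m
}

#' Reconstructed study-design fixture alignment
#'
#' Builds an alignment exactly consistent with the published
#' haplotype-by-locality count table of the six-locality Fujian survey:
#' 84 distinct 683-bp sequences, each replicated according to its count
#' in each locality (column sums 65, grand total 390; the dominant
#' haplotype totals 224). The haplotype sequences themselves are not
#' published, so the fixture assigns arbitrary but fixed sequences that
#' differ pairwise within the first 21 columns and are stop-free in
#' frame 0 under the invertebrate mitochondrial code; every count-based
#' statistic (haplotype diversity, sharing, dominance, AMOVA inputs) is
#' unaffected by that choice, while sequence-based statistics (pi,
#' mismatch) are synthetic.
#'
#' Records are ordered haplotype-major so that [collapse_haplotypes()]
#' reassigns the names `H1`...`H84` in table order.
#'
#' @return A [hap_alignment()] of 390 sequences in 6 populations.
#' @export
table1_fixture <- function() {
  counts <- fujian_hap_counts()
  seqs <- vapply(1:84, fixture_sequence, character(1))
  pops <- colnames(counts)
  id <- character(0); popv <- character(0); sq <- character(0)
  for (h in 1:84) {
    for (p in seq_along(pops)) {
      k <- counts[h, p]
      if (k > 0L) {
        id <- c(id, paste0(pops[p], "_H", h, "_", seq_len(k)))
        popv <- c(popv, rep(pops[p], k))
        sq <- c(sq, rep(seqs[h], k))
      }
    }
  }
  hap_alignment(id, popv, sq)
}

# deterministic 683-bp sequence for fixture haplotype i: a proline
# homopolymer codon backbone (stop-free under all supported codes) with
# third-codon-position substitutions encoding i in binary over the
# first 7 codons
fixture_sequence <- function(i) {
  codons <- rep("CCA", 227L)
  for (j in 0:6) {
    if (bitwAnd(i, bitwShiftL(1L, j)) != 0L) {
      substr(codons[j + 1L], 3L, 3L) <- "G"
    }
  }
  paste0(paste(codons, collapse = ""), "CC")
}
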