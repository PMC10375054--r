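#' Collapse an alignment into haplotypes
#'
#' Two sequences share a haplotype iff their strings are identical
#' (exact match after normalisation). Sequences containing ambiguous
#' bases are therefore never merged into a partially matching haplotype:
#' this is deterministic and conservative, since wildcard merging is
#' order-dependent. Haplotypes are named `H1`, `H2`, ... in order of
#' first appearance in the input.
#'
#' @param aln A [hap_alignment()].
#' @return A `haplotype_table` tibble with columns `haplotype`,
#'   `sequence`, one count column per population (input population
#'   order), and `Total`.
#' @examples
#' aln <- hap_alignment(paste0("s", 1:3), c("A", "A", "B"),
#'                      c("ACG", "ACG", "ACT"))
#' collapse_haplotypes(aln)
#' @export
collapse_haplotypes <- function(aln) {
  pops <- unique(aln$population)
  useq <- unique(aln$sequence)                      # first-appearance order
  idx <- match(aln$sequence, useq)
  counts <- matrix(0L, nrow = length(useq), ncol = length(pops),
                   dimnames = list(NULL, pops))
  tab <- table(factor(idx, levels = seq_along(useq)),
               factor(aln$population, levels = pops))
  counts[] <- as.integer(tab)
  out <- tibble(haplotype = paste0("H", seq_along(useq)), sequence = useq)
  for (p in pops) out[[p]] <- counts[, p]
  out$Total <- as.integer(rowSums(counts))
  attr(out, "populations") <- pops
  attr(out, "L") <- aln_length(aln)
  class(out) <- c("haplotype_table", class(out))
  out
}

#' Populations of a haplotype table
#' @param table A `haplotype_table`.
#' @return Character vector of population labels (column order).
#' @export
hap_populations <- function(table) {
  attr(table, "populations") %||%
    setdiff(names(table), c("haplotype", "sequence", "Total"))
}

hap_counts <- function(table) {
  m <- as.matrix(table[, hap_populations(table), drop = FALSE])
  rownames(m) <- table$haplotype
  storage.mode(m) <- "integer"
  m
}

#' Private/shared haplotype profile
#'
#' For each haplotype, the number of populations in which it occurs, and
#' the overall partition into private (exactly one population) and
#' shared (two or more) haplotypes.
#'
#' @param table A `haplotype_table` from [collapse_haplotypes()].
#' @return Tibble with columns `haplotype`, `total`, `n_populations`,
#'   `status` (`"private"`/`"shared"`); attributes `n_private`,
#'   `n_shared`.
#' @export
sharing_profile <- function(table) {
  m <- hap_counts(table)
  npop <- rowSums(m > 0L)
  out <- tibble(haplotype = table$haplotype,
                total = as.integer(rowSums(m)),
                n_populations = as.integer(npop),
                status = ifelse(npop >= 2L, "shared", "private"))
  attr(out, "n_private") <- sum(npop == 1L)
  attr(out, "n_shared") <- sum(npop >= 2L)
  out
}

#' Most frequent haplotype
#'
#' @param table A `haplotype_table`.
#' @return One-row tibble: `haplotype`, `total`, `frequency_pct`
#'   (percentage of all individuals), `n_populations`. Ties are broken by
#'   haplotype order (first appearance).
#' @export
dominant_haplotype <- function(table) {
  m <- hap_counts(table)
  tot <- rowSums(m)
  i <- which.max(tot)                                # first max wins ties
  tibble(haplotype = table$haplotype[i],
         total = as.integer(tot[i]),
         frequency_pct = unname(100 * tot[i] / sum(tot)),
         n_populations = as.integer(sum(m[i, ] > 0L)))
}

#' Per-population sample sizes and haplotype richness
#'
#' @param table A `haplotype_table`.
#' @return Tibble with columns `population`, `n` (sample size) and
#'   `n_haplotypes` (haplotypes observed in that population).
#' @export
per_population_haplotype_counts <- function(table) {
  m <- hap_counts(table)
  n <- colSums(m)
  if (any(n == 0L)) {
    abort(paste0("population with zero samples: ",
                 paste(colnames(m)[n == 0L], collapse = ", ")),
          class = "haplopop_input_error")
  }
  tibble(population = colnames(m), n = as.integer(n),
         n_haplotypes = as.integer(colSums(m > 0L)))
}

#' Re-expand a haplotype table into an alignment
#'
#' Repeats every haplotype sequence according to its per-population
#' counts; the multiset of sequences equals that of the alignment the
#' table was built from (ids are regenerated).
#'
#' @param table A `haplotype_table`.
#' @return A [hap_alignment()].
#' @export
expand_haplotypes <- function(table) {
  m <- hap_counts(table)
  pops <- colnames(m)
  ids <- character(0); popv <- character(0); seqs <- character(0)
  for (p in pops) {
    for (i in seq_len(nrow(m))) {
      k <- m[i, p]
      if (k > 0L) {
        ids <- c(ids, paste0(p, "_", table$haplotype[i], "_", seq_len(k)))
        popv <- c(popv, rep(p, k))
        seqs <- c(seqs, rep(table$sequence[i], k))
      }
    }
  }
  hap_alignment(ids, popv, seqs)
}

#' Write a haplotype count table as TSV (and haplotype sequences as FASTA)
#' @param table A `haplotype_table`.
#' @param path Output TSV path (columns: haplotype, populations, Total).
#' @param fasta_path Optional FASTA path for the haplotype sequences.
#' @return `path`, invisibly.
#' @export
write_haplotype_table <- function(table, path, fasta_path = NULL) {
  readr::write_tsv(table[, c("haplotype", hap_populations(table), "Total")], path)
  if (!is.null(fasta_path)) {
    dna <- ape::as.DNAbin(strsplit(setNames(table$sequence, table$haplotype), ""))
    ape::write.FASTA(dna, fasta_path)
  }
  invisible(path)
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("<haplotype_table> %d haplotypes, %d individuals, %d population(s)\n",
              nrow(x), sum(x$Total), length(hap_populations(x))))
  NextMethod()
}
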