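#' Haplotype (gene) diversity
#'
#' Nei's unbiased estimator \eqn{h = n(1 - \sum_i (c_i/n)^2)/(n-1)}: the
#' probability that two sequences drawn without replacement carry
#' different haplotypes.
#'
#' @param counts Vector of positive haplotype counts (one population).
#' @return `h` in `[0, 1]`.
#' @examples
#' haplotype_diversity(c(30, rep(2, 4), rep(1, 27)))  # 0.789
#' @export
haplotype_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) {
    abort("haplotype diversity undefined for n < 2", class = "haplopop_undefined_error")
  }
  n / (n - 1) * (1 - sum((counts / n)^2))
}

# pairwise difference / comparable-site statistics over unique sequences.
# Returns sums over all unordered pairs of the full sample:
#   sum_d   = total differing sites, sum_frac = total per-pair (d / comparable)
#   n_pairs = choose(n, 2)
pair_sums <- function(seqs, mult) {
  m <- t(vapply(strsplit(seqs, "", fixed = TRUE), identity,
                character(nchar(seqs[1]))))
  if (length(seqs) == 1L) m <- matrix(strsplit(seqs, "")[[1]], nrow = 1)
  ok <- is_base(m)
  k <- nrow(m)
  sum_d <- 0; sum_frac <- 0
  if (k > 1L) {
    for (i in 1:(k - 1L)) {
      for (j in (i + 1L):k) {
        both <- ok[i, ] & ok[j, ]
        comp <- sum(both)
        d <- sum(m[i, both] != m[j, both])
        w <- mult[i] * mult[j]
        sum_d <- sum_d + w * d
        if (comp > 0L) sum_frac <- sum_frac + w * d / comp
      }
    }
  }
  n <- sum(mult)
  list(sum_d = sum_d, sum_frac = sum_frac, n_pairs = n * (n - 1) / 2)
}

#' Nucleotide diversity and mean pairwise differences
#'
#' \eqn{\hat{k}} is the mean, over all unordered sequence pairs, of the
#' number of sites at which both sequences are unambiguous and differ;
#' \eqn{\pi} is the mean of the per-pair fraction (differences divided by
#' the pair's comparable sites). Ambiguity and gaps are masked per pair
#' (pairwise deletion), not by removing whole columns.
#'
#' @param aln A [hap_alignment()].
#' @param population A population label, or `"all"` (default) for the
#'   pooled sample.
#' @return One-row tibble: `population`, `n`, `pi`, `k_hat`.
#' @export
nucleotide_diversity <- function(aln, population = "all") {
  sub <- aln_subset(aln, population)
  if (nrow(sub) < 2L) {
    abort("nucleotide diversity undefined for fewer than 2 sequences",
          class = "haplopop_undefined_error")
  }
  useq <- unique(sub$sequence)
  mult <- as.integer(table(factor(sub$sequence, levels = useq)))
  ps <- pair_sums(useq, mult)
  tibble(population = population, n = nrow(sub),
         pi = ps$sum_frac / ps$n_pairs, k_hat = ps$sum_d / ps$n_pairs)
}

#' Per-population diversity summary
#'
#' One row per population (sample size, haplotype richness, haplotype
#' diversity, nucleotide diversity, mean pairwise differences) plus a
#' final `"mean"` row holding the unweighted arithmetic mean of the
#' per-population `h` and `pi` — the convention used when a study quotes
#' a single "average diversity" across localities.
#'
#' @param aln A [hap_alignment()].
#' @param table Optional `haplotype_table`; computed from `aln` if missing.
#' @return Tibble: `population`, `n`, `n_haplotypes`, `h`, `pi`, `k_hat`.
#' @export
summarize_diversity <- function(aln, table = NULL) {
  table <- table %||% collapse_haplotypes(aln)
  m <- hap_counts(table)
  pops <- colnames(m)
  rows <- purrr::map(pops, function(p) {
    nd <- nucleotide_diversity(aln, p)
    tibble(population = p, n = as.integer(sum(m[, p])),
           n_haplotypes = as.integer(sum(m[, p] > 0L)),
           h = haplotype_diversity(m[, p]),
           pi = nd$pi, k_hat = nd$k_hat)
  })
  out <- bind_rows(rows)
  bind_rows(out, tibble(population = "mean", n = NA_integer_,
                        n_haplotypes = NA_integer_,
                        h = mean(out$h), pi = mean(out$pi),
                        k_hat = mean(out$k_hat)))
}

#' Write a per-population diversity table as TSV
#' @param div Result of [summarize_diversity()].
#' @param path Output path.
#' @return `path`, invisibly. `h` is rounded to 3 decimals and `pi` to 5,
#'   the conventional reporting precision; full precision is kept in R.
#' @export
write_diversity_table <- function(div, path) {
  out <- div
  out$h <- round(out$h, 3)
  out$pi <- round(out$pi, 5)
  readr::write_tsv(out, path)
  invisible(path)
}
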