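#' Construct a haploid sequence alignment
#'
#' A `hap_alignment` is a tibble with one row per sequence and columns
#' `id`, `population` and `sequence`, all sequences of identical length.
#' Lower-case input is upper-cased and IUPAC ambiguity codes other than
#' `N` are recoded to `N`: every downstream statistic is defined on the
#' unambiguous bases `A`, `C`, `G`, `T`, with `N` and the gap character
#' `-` masked per site rather than by deleting whole columns, so the
#' original site coordinate frame (1-based in all outputs) is preserved.
#'
#' @param ids Character vector of unique sequence identifiers.
#' @param populations Character vector of population labels, one per
#'   sequence.
#' @param sequences Character vector of aligned sequences (equal lengths).
#' @return A `hap_alignment` tibble with attribute `L` (alignment length).
#' @examples
#' hap_alignment(c("s1", "s2"), c("A", "A"), c("ACGTT", "ACGTA"))
#' @export
hap_alignment <- function(ids, populations, sequences) {
  if (length(ids) == 0L) {
    abort("alignment must contain at least one sequence", class = "haplopop_input_error")
  }
  if (length(populations) != length(ids) || length(sequences) != length(ids)) {
    abort("ids, populations and sequences must have equal length",
          class = "haplopop_input_error")
  }
  if (anyDuplicated(ids)) {
    abort("sequence ids must be unique", class = "haplopop_input_error")
  }
  sequences <- toupper(sequences)
  L <- unique(nchar(sequences))
  if (length(L) != 1L) {
    abort(
      paste0("all sequences must have identical length; found lengths: ",
             paste(sort(L), collapse = ", ")),
      class = "haplopop_alignment_error"
    )
  }
  # IUPAC ambiguity codes other than N are accepted but degraded to N
  sequences <- gsub("[^ACGTN-]", "N", sequences)
  out <- tibble(id = unname(as.character(ids)),
                population = unname(as.character(populations)),
                sequence = unname(sequences))
  attr(out, "L") <- as.integer(L)
  class(out) <- c("hap_alignment", class(out))
  out
}

#' Alignment length (number of sites)
#' @param aln A `hap_alignment`.
#' @return Integer number of columns.
#' @export
aln_length <- function(aln) {
  L <- attr(aln, "L")
  if (is.null(L)) L <- unique(nchar(aln$sequence))
  as.integer(L)
}

#' Read an aligned FASTA file with a population map
#'
#' The population map is a two-column TSV (id, population) without a
#' header; lines starting with `#` are ignored. Every FASTA record must
#' have a mapping entry.
#'
#' @param path Path to an aligned FASTA file (wrapped or single-line).
#' @param popmap Path to the two-column TSV population map.
#' @return A [hap_alignment()].
#' @export
read_fasta <- function(path, popmap) {
  if (!file.exists(path)) abort(paste0("no such file: ", path), class = "haplopop_input_error")
  dna <- suppressWarnings(ape::read.FASTA(path))
  if (is.null(dna) || length(dna) == 0L) {
    abort("empty FASTA file", class = "haplopop_input_error")
  }
  seqs <- vapply(as.character(dna), function(x) paste(x, collapse = ""), character(1))
  pm <- read_popmap(popmap)
  ids <- names(seqs)
  missing <- setdiff(ids, pm$id)
  if (length(missing) > 0L) {
    abort(paste0("ids missing from population map: ",
                 paste(head(missing, 5L), collapse = ", ")),
          class = "haplopop_mapping_error")
  }
  pops <- pm$population[match(ids, pm$id)]
  hap_alignment(ids, pops, seqs)
}

#' Read a two-column (id, population) TSV population map
#' @param path File path; `#` comment lines allowed, no header.
#' @return Tibble with columns `id`, `population`.
#' @export
read_popmap <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path), class = "haplopop_input_error")
  pm <- readr::read_tsv(path, col_names = c("id", "population"),
                        comment = "#", col_types = "cc", progress = FALSE)
  if (nrow(pm) == 0L) abort("empty population map", class = "haplopop_input_error")
  if (anyDuplicated(pm$id)) abort("duplicate ids in population map", class = "haplopop_input_error")
  pm
}

#' Write an alignment (and optionally its population map) to disk
#' @param aln A [hap_alignment()].
#' @param path Output FASTA path.
#' @param popmap_path Optional TSV path for the id-to-population map.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path, popmap_path = NULL) {
  dna <- ape::as.DNAbin(strsplit(setNames(aln$sequence, aln$id), ""))
  ape::write.FASTA(dna, path)
  if (!is.null(popmap_path)) {
    readr::write_tsv(tibble(id = aln$id, population = aln$population),
                     popmap_path, col_names = FALSE)
  }
  invisible(path)
}

#' Base composition of an alignment
#'
#' Proportions of A, C, G and T over all pooled unambiguous bases;
#' `N` and gaps are ignored.
#'
#' @param aln A [hap_alignment()].
#' @return Tibble with columns `base` and `proportion` (sums to 1).
#' @export
base_composition <- function(aln) {
  chars <- unlist(strsplit(aln$sequence, "", fixed = TRUE), use.names = FALSE)
  counts <- c(A = sum(chars == "A"), C = sum(chars == "C"),
              G = sum(chars == "G"), T = sum(chars == "T"))
  total <- sum(counts)
  if (total == 0L) {
    abort("base composition undefined: alignment contains only N/gap characters",
          class = "haplopop_composition_error")
  }
  tibble(base = names(counts), proportion = as.numeric(counts) / total)
}

#' Classify alignment sites
#'
#' Each site is classified on its unambiguous bases only: a site with at
#' least two distinct bases is variable; a variable site is
#' parsimony-informative if at least two bases each occur in at least two
#' sequences, otherwise it is a singleton site. Sites at which fewer than
#' two sequences carry an unambiguous base are `excluded`; the remainder
#' are `invariant`.
#'
#' @param aln A [hap_alignment()].
#' @return Tibble with one row per site: `site` (1-based), `category`;
#'   attributes `S`, `n_singleton`, `n_pi`, `n_invariant`, `n_excluded`
#'   carry the totals, also available via [site_summary()].
#' @export
classify_sites <- function(aln) {
  m <- seq_matrix(aln)
  cats <- character(ncol(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    col <- col[col %in% c("A", "C", "G", "T")]
    if (length(col) < 2L) {
      cats[j] <- "excluded"
    } else {
      tab <- table(col)
      if (length(tab) < 2L) {
        cats[j] <- "invariant"
      } else if (sum(tab >= 2L) >= 2L) {
        cats[j] <- "parsimony_informative"
      } else {
        cats[j] <- "singleton"
      }
    }
  }
  out <- tibble(site = seq_len(ncol(m)), category = cats)
  attr(out, "totals") <- c(
    S = sum(cats %in% c("singleton", "parsimony_informative")),
    n_singleton = sum(cats == "singleton"),
    n_pi = sum(cats == "parsimony_informative"),
    n_invariant = sum(cats == "invariant"),
    n_excluded = sum(cats == "excluded")
  )
  class(out) <- c("site_classification", class(out))
  out
}

#' Totals from a site classification
#' @param sites Result of [classify_sites()].
#' @return Named integer vector `S`, `n_singleton`, `n_pi`,
#'   `n_invariant`, `n_excluded`.
#' @export
site_summary <- function(sites) attr(sites, "totals")

# genetic codes supported for ORF screening; values are deviations from
# the standard code at the relevant codons
.stop_codons <- list(
  standard = c("TAA", "TAG", "TGA"),
  invertebrate_mitochondrial = c("TAA", "TAG"),
  vertebrate_mitochondrial = c("TAA", "TAG", "AGA", "AGG")
)

#' Screen sequences for premature stop codons
#'
#' Translates each ungapped sequence in a fixed reading frame and reports
#' the positions (codon indices) of stop codons occurring before the final
#' codon. Protein-coding mtDNA fragments free of premature stops and
#' indels are the expected input for all downstream statistics.
#'
#' @param aln A [hap_alignment()].
#' @param frame Reading-frame offset 0, 1, 2, or `"auto"` (default): the
#'   frame minimising the total number of stop codons across sequences.
#' @param code Genetic code: `"invertebrate_mitochondrial"` (default),
#'   `"vertebrate_mitochondrial"` or `"standard"`.
#' @return Tibble with columns `id`, `frame`, `n_stops`, `stop_codons`
#'   (list column of 1-based codon indices). All `n_stops == 0` means the
#'   alignment passes.
#' @export
check_orf <- function(aln, frame = "auto", code = "invertebrate_mitochondrial") {
  if (!code %in% names(.stop_codons)) {
    abort(paste0("unsupported genetic code: ", code), class = "haplopop_config_error")
  }
  stops <- .stop_codons[[code]]
  scan_frame <- function(fr) {
    lapply(aln$sequence, function(s) {
      s <- gsub("-", "", s, fixed = TRUE)
      s <- substring(s, fr + 1L)
      ncod <- nchar(s) %/% 3L
      if (ncod < 2L) return(integer(0))
      starts <- seq(1L, by = 3L, length.out = ncod)
      codons <- substring(s, starts, starts + 2L)
      # stops before the final codon count as premature
      which(codons[-ncod] %in% stops)
    })
  }
  if (identical(frame, "auto")) {
    totals <- vapply(0:2, function(fr) sum(lengths(scan_frame(fr))), numeric(1))
    frame <- (0:2)[which.min(totals)]
  }
  if (!frame %in% 0:2) abort("frame must be 0, 1, 2 or 'auto'", class = "haplopop_config_error")
  pos <- scan_frame(as.integer(frame))
  tibble(id = aln$id, frame = as.integer(frame),
         n_stops = lengths(pos), stop_codons = pos)
}

#' @export
print.hap_alignment <- function(x, ...) {
  cat(sprintf("<hap_alignment> %d sequences x %d sites, %d population(s)\n",
              nrow(x), aln_length(x), dplyr::n_distinct(x$population)))
  NextMethod()
}

# subset an alignment to one population ("all" keeps everything)
aln_subset <- function(aln, population = "all") {
  if (identical(population, "all")) return(aln)
  keep <- aln$population %in% population
  if (!any(keep)) {
    abort(paste0("no sequences in population: ", population),
          class = "haplopop_input_error")
  }
  out <- aln[keep, ]
  attr(out, "L") <- aln_length(aln)
  class(out) <- unique(c("hap_alignment", class(out)))
  out
}
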