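#' Neighbour-joining tree from a distance matrix
#'
#' Saitou–Nei neighbour joining (Studier–Keppler form, via \pkg{ape}).
#' Negative branch lengths, which NJ can produce when the matrix is not
#' additive, are clamped to zero with the negative excess transferred to
#' the sister branch at the same junction so that path lengths between
#' the joined neighbours and the rest of the tree are preserved
#' (Kuhner–Felsenstein convention).
#'
#' @param dist Symmetric distance matrix with labels.
#' @return An unrooted `phylo` tree with branch lengths.
#' @export
nj_tree <- function(dist) {
  dist <- as.matrix(dist)
  if (nrow(dist) < 2L) abort("need at least 2 taxa", class = "haplopop_input_error")
  if (max(abs(dist - t(dist))) > 1e-8) {
    abort("distance matrix must be symmetric", class = "haplopop_input_error")
  }
  if (is.null(rownames(dist))) {
    rownames(dist) <- colnames(dist) <- paste0("t", seq_len(nrow(dist)))
  }
  if (nrow(dist) == 2L) {
    txt <- sprintf("(%s:%f,%s:%f);", rownames(dist)[1], dist[1, 2] / 2,
                   rownames(dist)[2], dist[1, 2] / 2)
    return(ape::read.tree(text = txt))
  }
  phy <- ape::nj(stats::as.dist(dist))
  clamp_negative_branches(phy)
}

# set negative branch lengths to 0, moving the excess onto a sister
# branch at the same parent node
clamp_negative_branches <- function(phy, tol = 1e-12) {
  for (iter in 1:20) {
    neg <- which(phy$edge.length < -tol)
    if (length(neg) == 0L) break
    e <- neg[1]
    parent <- phy$edge[e, 1]
    sisters <- setdiff(which(phy$edge[, 1] == parent), e)
    if (length(sisters) > 0L) {
      phy$edge.length[sisters[1]] <- phy$edge.length[sisters[1]] + phy$edge.length[e]
    }
    phy$edge.length[e] <- 0
  }
  phy$edge.length[phy$edge.length < 0] <- 0
  phy
}

#' Bootstrap support for neighbour-joining splits
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree
#' from the pairwise difference matrix of each pseudo-alignment, and
#' reports for each internal node of the reference tree the percentage
#' of replicate trees containing the same split.
#'
#' @param aln A [hap_alignment()]. Typically the haplotype sequences
#'   (one per haplotype) rather than all individuals; use
#'   `collapse = TRUE` for that.
#' @param n_reps Number of bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @param collapse If `TRUE` (default), collapse to unique haplotypes
#'   first and label tips by haplotype name.
#' @return List with `tree` (reference `phylo`, `node.label` = support
#'   in percent) and `support` (numeric vector over internal nodes).
#' @export
bootstrap_support <- function(aln, n_reps = 1000, seed = NULL, collapse = TRUE) {
  if (n_reps < 1) abort("n_reps must be >= 1", class = "haplopop_input_error")
  if (collapse) {
    tab <- collapse_haplotypes(aln)
    aln <- hap_alignment(tab$haplotype, rep("all", nrow(tab)), tab$sequence)
  }
  m <- seq_matrix(aln)
  dist_from <- function(cols) {
    mm <- m[, cols, drop = FALSE]
    ok <- is_base(mm)
    k <- nrow(mm)
    d <- matrix(0, k, k, dimnames = list(rownames(m), rownames(m)))
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        both <- ok[i, ] & ok[j, ]
        d[i, j] <- d[j, i] <- sum(mm[i, both] != mm[j, both])
      }
    }
    d
  }
  ref <- nj_tree(dist_from(seq_len(ncol(m))))
  boots <- with_seed(seed, {
    lapply(seq_len(n_reps), function(b) {
      nj_tree(dist_from(sample.int(ncol(m), replace = TRUE)))
    })
  })
  counts <- ape::prop.clades(ref, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- 100 * counts / n_reps
  ref$node.label <- format(round(support, 1), trim = TRUE)
  list(tree = ref, support = support)
}

#' Write a tree to a Newick file
#' @param tree A `phylo` object (e.g. from [nj_tree()] or
#'   [bootstrap_support()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
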