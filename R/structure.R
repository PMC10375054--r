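#' Pairwise difference matrix
#'
#' Entry (i, j) is the number of sites at which sequences i and j are
#' both unambiguous and differ. Computed on the unique sequences and
#' expanded, so cost scales with the number of haplotypes, not samples.
#'
#' @param aln A [hap_alignment()].
#' @return Symmetric numeric matrix with zero diagonal, dimnames = ids.
#' @export
pairwise_difference_matrix <- function(aln) {
  useq <- unique(aln$sequence)
  idx <- match(aln$sequence, useq)
  hd <- hap_dist_matrix(useq)
  out <- hd[idx, idx, drop = FALSE]
  dimnames(out) <- list(aln$id, aln$id)
  out
}

# Hamming distances (with pairwise N/gap masking) among unique sequences
hap_dist_matrix <- function(seqs) {
  k <- length(seqs)
  if (all(nchar(seqs) == 0L)) return(matrix(0, k, k))
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = k, byrow = TRUE)
  ok <- is_base(m)
  d <- matrix(0, k, k)
  if (k > 1L) {
    for (i in 1:(k - 1L)) {
      for (j in (i + 1L):k) {
        both <- ok[i, ] & ok[j, ]
        d[i, j] <- d[j, i] <- sum(m[i, both] != m[j, both])
      }
    }
  }
  d
}

# AMOVA variance components from a squared-distance matrix and a grouping
# factor; the Excoffier two-level decomposition on squared molecular
# distances.
amova_components <- function(d2, groups) {
  groups <- as.factor(groups)
  N <- nrow(d2)
  P <- nlevels(groups)
  n_g <- as.integer(table(groups))
  ss_total <- sum(d2[upper.tri(d2)]) / N
  ss_within <- 0
  for (g in levels(groups)) {
    i <- which(groups == g)
    ss_within <- ss_within + sum(d2[i, i]) / (2 * length(i))
  }
  ss_among <- ss_total - ss_within
  df_among <- P - 1L
  df_within <- N - P
  vb <- ss_within / df_within
  nbar <- (N - sum(n_g^2) / N) / (P - 1)
  va <- (ss_among / df_among - vb) / nbar
  phi <- if ((va + vb) > 0) va / (va + vb) else NaN
  list(N = N, P = P, df_among = df_among, df_within = df_within,
       ss_among = ss_among, ss_within = ss_within, ss_total = ss_total,
       va = va, vb = vb, phi_st = phi)
}

#' Two-level analysis of molecular variance (AMOVA)
#'
#' Partitions squared pairwise molecular distances into among- and
#' within-population variance components Va and Vb, with
#' \eqn{\Phi_{ST} = Va/(Va+Vb)}. Significance is assessed by permuting
#' individuals among populations; the p-value is the proportion of
#' permuted \eqn{\Phi_{ST}} values at least as large as the observed one,
#' with the (b+1)/(m+1) correction so p is never exactly zero.
#'
#' @param dist Symmetric matrix of pairwise molecular distances
#'   (e.g. [pairwise_difference_matrix()]); raw pairwise differences, not
#'   model-corrected distances, are the conventional choice at low
#'   divergence.
#' @param populations Vector of population labels, one per row of `dist`.
#' @param n_perm Number of label permutations (default 10000).
#' @param seed RNG seed for the permutations.
#' @return A `hap_amova` object; see [tidy.hap_amova()].
#' @export
amova <- function(dist, populations, n_perm = 10000, seed = NULL) {
  dist <- as.matrix(dist)
  if (nrow(dist) != length(populations)) {
    abort("populations must match the distance matrix rows", class = "haplopop_input_error")
  }
  if (length(unique(populations)) < 2L) {
    abort("AMOVA needs at least 2 populations", class = "haplopop_input_error")
  }
  if (max(abs(dist - t(dist))) > 1e-8) {
    abort("distance matrix must be symmetric", class = "haplopop_input_error")
  }
  d2 <- dist^2
  obs <- amova_components(d2, populations)
  if (is.nan(obs$phi_st)) {
    warn("all distances are zero: Phi_ST undefined")
    p <- NA_real_
  } else if (n_perm > 0) {
    groups <- as.factor(populations)
    hits <- with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(b) {
        gp <- sample(groups)
        cb <- amova_components(d2, gp)
        !is.nan(cb$phi_st) && cb$phi_st >= obs$phi_st
      }, logical(1)))
    })
    p <- (hits + 1) / (n_perm + 1)
  } else {
    p <- NA_real_
  }
  structure(c(obs, list(p_value = p, n_perm = n_perm)), class = "hap_amova")
}

#' @export
print.hap_amova <- function(x, ...) {
  cat("Two-level AMOVA\n")
  print(tidy(x))
  cat(sprintf("Phi_ST = %.5f, permutation p = %s (%d permutations)\n",
              x$phi_st, format(x$p_value, digits = 3), x$n_perm))
  invisible(x)
}

#' Tidy an AMOVA fit into its variance-decomposition table
#' @param x A `hap_amova` object.
#' @param ... Unused.
#' @return Tibble with rows among/within/total: d.f., sums of squares,
#'   variance components and percentage of variation.
#' @export
tidy.hap_amova <- function(x, ...) {
  total_v <- x$va + x$vb
  tibble(source = c("Among populations", "Within populations", "Total"),
         df = c(x$df_among, x$df_within, x$df_among + x$df_within),
         sum_sq = c(x$ss_among, x$ss_within, x$ss_total),
         variance = c(x$va, x$vb, total_v),
         percent = c(100 * x$va / total_v, 100 * x$vb / total_v, NA_real_))
}

#' One-line AMOVA summary
#' @param x A `hap_amova` object.
#' @param ... Unused.
#' @return One-row tibble: `phi_st`, `p_value`, `n_perm`, `n`, `n_populations`.
#' @export
glance.hap_amova <- function(x, ...) {
  tibble(phi_st = x$phi_st, p_value = x$p_value, n_perm = x$n_perm,
         n = x$N, n_populations = x$P)
}

#' Pairwise Phi-ST between all population pairs
#'
#' Runs a two-population AMOVA for every pair; negative estimates are
#' reported as computed (they arise when within-population variance
#' exceeds the total and indicate no differentiation).
#'
#' @inheritParams amova
#' @return A `pairwise_structure` object: symmetric `phi_st` and `p_value`
#'   matrices plus a long-format tibble accessor via [tidy.pairwise_structure()].
#' @export
pairwise_phist <- function(dist, populations, n_perm = 10000, seed = NULL) {
  dist <- as.matrix(dist)
  pops <- unique(populations)
  P <- length(pops)
  if (P < 2L) abort("need at least 2 populations", class = "haplopop_input_error")
  phi <- matrix(NA_real_, P, P, dimnames = list(pops, pops))
  pv <- matrix(NA_real_, P, P, dimnames = list(pops, pops))
  diag(phi) <- 0
  pair_id <- 0L
  for (a in 1:(P - 1L)) {
    for (b in (a + 1L):P) {
      pair_id <- pair_id + 1L
      i <- which(populations %in% c(pops[a], pops[b]))
      sub_seed <- if (is.null(seed)) NULL else derive_seed(seed, paste0("pair", pair_id))
      fit <- amova(dist[i, i, drop = FALSE], populations[i],
                   n_perm = n_perm, seed = sub_seed)
      phi[a, b] <- phi[b, a] <- fit$phi_st
      pv[a, b] <- pv[b, a] <- fit$p_value
    }
  }
  structure(list(phi_st = phi, p_value = pv, populations = pops,
                 n_perm = n_perm),
            class = "pairwise_structure")
}

#' @export
print.pairwise_structure <- function(x, ...) {
  cat("Pairwise Phi_ST (lower triangle) / permutation p (upper):\n")
  m <- x$phi_st
  m[upper.tri(m)] <- x$p_value[upper.tri(m)]
  print(round(m, 5))
  invisible(x)
}

#' Tidy pairwise structure results to long format
#' @param x A `pairwise_structure` object.
#' @param ... Unused.
#' @return Tibble: `pop1`, `pop2`, `phi_st`, `p_value`, `p_holm`
#'   (sequential-Bonferroni adjusted).
#' @export
tidy.pairwise_structure <- function(x, ...) {
  pops <- x$populations
  pr <- t(combn(seq_along(pops), 2))
  out <- tibble(pop1 = pops[pr[, 1]], pop2 = pops[pr[, 2]],
                phi_st = x$phi_st[pr], p_value = x$p_value[pr])
  out$p_holm <- stats::p.adjust(out$p_value, method = "holm")
  out
}

#' Between-population average divergence (d_xy)
#'
#' Mean over all inter-population sequence pairs of the per-site
#' difference fraction (differences / comparable sites, with pairwise
#' masking of ambiguous bases and gaps).
#'
#' @param aln A [hap_alignment()].
#' @param popA,popB Population labels.
#' @return Scalar d_xy (per site).
#' @export
dxy <- function(aln, popA, popB) {
  a <- aln_subset(aln, popA)
  b <- aln_subset(aln, popB)
  ua <- unique(a$sequence); ca <- as.integer(table(factor(a$sequence, levels = ua)))
  ub <- unique(b$sequence); cb <- as.integer(table(factor(b$sequence, levels = ub)))
  ma <- matrix(unlist(strsplit(ua, "", fixed = TRUE)), nrow = length(ua), byrow = TRUE)
  mb <- matrix(unlist(strsplit(ub, "", fixed = TRUE)), nrow = length(ub), byrow = TRUE)
  oka <- is_base(ma); okb <- is_base(mb)
  tot <- 0
  for (i in seq_along(ua)) {
    for (j in seq_along(ub)) {
      both <- oka[i, ] & okb[j, ]
      comp <- sum(both)
      if (comp > 0L) {
        tot <- tot + ca[i] * cb[j] * sum(ma[i, both] != mb[j, both]) / comp
      }
    }
  }
  tot / (nrow(a) * nrow(b))
}

#' Matrix of between-population divergences
#' @param aln A [hap_alignment()].
#' @return Symmetric matrix of [dxy()] values (zero diagonal).
#' @export
dxy_matrix <- function(aln) {
  pops <- unique(aln$population)
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  if (length(pops) > 1L) {
    for (a in 1:(length(pops) - 1L)) {
      for (b in (a + 1L):length(pops)) {
        m[a, b] <- m[b, a] <- dxy(aln, pops[a], pops[b])
      }
    }
  }
  m
}
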