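# Independent oracle implementations: deliberately naive routes
# (double loops, numerical integration, polynomial expansion,
# exhaustive search) against which the package's implementations are
# checked.

BASES <- c("A", "C", "G", "T")

# all-pairs diversity by plain double loop with per-pair masking
oracle_pair_stats <- function(seqs) {
  n <- length(seqs)
  sm <- strsplit(seqs, "")
  sum_d <- 0; sum_frac <- 0; np <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      a <- sm[[i]]; b <- sm[[j]]
      ok <- a %in% BASES & b %in% BASES
      d <- sum(a[ok] != b[ok])
      np <- np + 1
      sum_d <- sum_d + d
      if (sum(ok) > 0) sum_frac <- sum_frac + d / sum(ok)
    }
  }
  list(k_hat = sum_d / np, pi = sum_frac / np)
}

# brute-force pairwise difference matrix
oracle_dist <- function(seqs) {
  n <- length(seqs)
  sm <- strsplit(seqs, "")
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      ok <- sm[[i]] %in% BASES & sm[[j]] %in% BASES
      d[i, j] <- sum(sm[[i]][ok] != sm[[j]][ok])
    }
  }
  d
}

# sudden-expansion mismatch probabilities by numerical integration of
# the pair coalescence-time density (requires theta0, theta1 > 0)
oracle_mismatch_expected <- function(tau, th0, th1, d_max) {
  vapply(0:d_max, function(i) {
    recent <- stats::integrate(function(s) stats::dpois(i, s) * exp(-s / th1) / th1,
                               0, tau, rel.tol = 1e-12, abs.tol = 0)$value
    old <- exp(-tau / th1) *
      stats::integrate(function(v) stats::dpois(i, tau + v) * exp(-v / th0) / th0,
                       0, Inf, rel.tol = 1e-12, abs.tol = 0)$value
    recent + old
  }, numeric(1))
}

# Ewens P(K = k) via polynomial expansion of the rising factorial
# theta (theta+1) ... (theta+n-1): coefficient k is |s(n, k)|
oracle_ewens_pmf <- function(n, theta) {
  p <- 1
  for (m in 0:(n - 1)) p <- c(0, p) + m * c(p, 0)
  stirling <- p[2:(n + 1)]
  probs <- stirling * theta^(1:n) / prod(theta + 0:(n - 1))
  probs
}

plain_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

mst_length <- function(seqs) {
  k <- length(seqs)
  if (k <= 1) return(0)
  d <- outer(seqs, seqs, Vectorize(plain_hamming))
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected", weighted = TRUE)
  sum(igraph::E(igraph::mst(g, weights = igraph::E(g)$weight))$weight)
}

# exhaustive Steiner minimal tree length for a small haplotype set:
# candidate Steiner points are all strings over the observed states at
# each variable column; up to length(seqs) - 2 of them may be added
oracle_steiner_length <- function(seqs) {
  stopifnot(length(seqs) <= 4)
  cols <- strsplit(seqs, "")
  L <- length(cols[[1]])
  opts <- lapply(seq_len(L), function(j) unique(vapply(cols, `[`, "", j)))
  cands <- do.call(expand.grid, c(opts, stringsAsFactors = FALSE))
  cands <- apply(cands, 1, paste, collapse = "")
  cands <- setdiff(cands, seqs)
  best <- mst_length(seqs)
  max_add <- max(length(seqs) - 2, 0)
  if (max_add >= 1) {
    for (m in cands) best <- min(best, mst_length(c(seqs, m)))
  }
  if (max_add >= 2 && length(cands) >= 2) {
    cmb <- utils::combn(cands, 2)
    for (cc in seq_len(ncol(cmb))) {
      best <- min(best, mst_length(c(seqs, cmb[, cc])))
    }
  }
  best
}

# all minimum spanning trees of a small complete graph, as lists of
# sorted "i-j" edge keys, by exhaustive enumeration of edge subsets
oracle_all_msts <- function(d) {
  k <- nrow(d)
  pairs <- t(utils::combn(k, 2))
  w <- d[pairs]
  trees <- list()
  best <- Inf
  for (sel in utils::combn(nrow(pairs), k - 1, simplify = FALSE)) {
    g <- igraph::graph_from_edgelist(pairs[sel, , drop = FALSE], directed = FALSE)
    if (igraph::vcount(g) < k) g <- igraph::add_vertices(g, k - igraph::vcount(g))
    if (!igraph::is_connected(g)) next
    tw <- sum(w[sel])
    key <- paste(pairs[sel, 1], pairs[sel, 2], sep = "-")
    if (tw < best - 1e-9) {
      best <- tw; trees <- list(key)
    } else if (abs(tw - best) <= 1e-9) {
      trees <- c(trees, list(key))
    }
  }
  trees
}

# random alignment generator for property tests
rand_alignment <- function(n, L, n_pop = 1, p_ambig = 0.02, seed = NULL) {
  withr::with_seed(seed %||% sample.int(1e6, 1), {
    m <- matrix(sample(BASES, n * L, replace = TRUE,
                       prob = c(0.3, 0.25, 0.25, 0.2)), n, L)
    # make most columns invariant so alignments look sequence-like
    for (j in seq_len(L)) {
      if (stats::runif(1) < 0.7) m[, j] <- m[1, j]
    }
    amb <- stats::runif(n * L) < p_ambig
    m[amb] <- sample(c("N", "-"), sum(amb), replace = TRUE)
    hap_alignment(paste0("s", seq_len(n)),
                  paste0("pop", rep_len(seq_len(n_pop), n)),
                  apply(m, 1, paste, collapse = ""))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
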