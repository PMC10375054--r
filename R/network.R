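# --- haplotype-network machinery -------------------------------------------
#
# Networks are built on the variable columns only (invariant columns carry
# no information for connections) with uniform site weights. Distances are
# Hamming distances with pairwise masking of ambiguous bases; tie-breaking
# everywhere is lexicographic in node name so results are deterministic.

# accept a haplotype_table or a named character vector of sequences
hap_set <- function(x) {
  if (inherits(x, "haplotype_table")) {
    list(names = x$haplotype, seqs = x$sequence,
         freq = as.integer(x$Total), counts = hap_counts(x))
  } else {
    nm <- names(x) %||% paste0("H", seq_along(x))
    list(names = nm, seqs = toupper(unname(x)),
         freq = rep(1L, length(x)), counts = NULL)
  }
}

# paste matrix rows back into strings (zero-column safe)
collapse_rows <- function(m, n) {
  if (is.null(dim(m)) || ncol(m) == 0L) return(rep("", n))
  apply(m, 1L, paste, collapse = "")
}

# network code is alphabet-agnostic: any character state is valid except
# the ambiguity/gap markers N and '-'
net_ok <- function(m) m != "N" & m != "-"

# columns with >= 2 distinct unambiguous states
variable_columns <- function(seqs) {
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = length(seqs), byrow = TRUE)
  keep <- vapply(seq_len(ncol(m)), function(j) {
    b <- m[, j][net_ok(m[, j, drop = FALSE])]
    length(unique(b)) >= 2L
  }, logical(1))
  m[, keep, drop = FALSE]
}

# Hamming distances over unambiguous states (pairwise masking of N/-)
state_dist_matrix <- function(seqs) {
  k <- length(seqs)
  if (all(nchar(seqs) == 0L)) return(matrix(0, k, k))
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = k, byrow = TRUE)
  ok <- net_ok(m)
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

# pair connection thresholds: weight at which each pair first becomes
# connected when edges are inserted in ascending weight order (minimax
# path weight). Used for the (epsilon-relaxed) minimum spanning network.
connection_thresholds <- function(d) {
  k <- nrow(d)
  t_conn <- matrix(Inf, k, k)
  comp <- seq_len(k)
  for (w in sort(unique(d[upper.tri(d)]))) {
    merged <- TRUE
    while (merged) {       # transitive closure at this weight level
      merged <- FALSE
      for (i in seq_len(k - 1L)) {
        for (j in (i + 1L):k) {
          if (d[i, j] <= w && comp[i] != comp[j]) {
            newly <- comp == comp[j]
            comp[newly] <- comp[i]
            merged <- TRUE
          }
        }
      }
    }
    t_conn[outer(comp, comp, "==") & !is.finite(t_conn)] <- w
    diag(t_conn) <- 0
  }
  t_conn
}

# edges of the epsilon-relaxed minimum spanning network: (i, j) is kept
# iff d_ij <= t_ij + epsilon; for epsilon = 0 this is the union of all
# minimum spanning trees
msn_edges <- function(d, epsilon = 0) {
  t_conn <- connection_thresholds(d)
  k <- nrow(d)
  out <- NULL
  for (i in seq_len(max(k - 1L, 0L))) {
    for (j in (i + 1L):k) {
      if (d[i, j] <= t_conn[i, j] + epsilon) {
        out <- rbind(out, c(i, j, d[i, j]))
      }
    }
  }
  out
}

make_network <- function(hs, node_seq_var, is_median, edges_idx) {
  nodes <- tibble(name = hs$names, is_median = is_median,
                  frequency = hs$freq, sequence = node_seq_var)
  if (!is.null(hs$counts)) {
    for (p in colnames(hs$counts)) {
      nodes[[p]] <- c(hs$counts[, p], rep(0L, nrow(nodes) - nrow(hs$counts)))
    }
  }
  edges <- if (is.null(edges_idx) || nrow(edges_idx) == 0L) {
    tibble(from = character(0), to = character(0), steps = numeric(0))
  } else {
    tibble(from = hs$names[edges_idx[, 1]], to = hs$names[edges_idx[, 2]],
           steps = edges_idx[, 3])
  }
  structure(list(nodes = nodes, edges = edges), class = "haplo_network")
}

#' Minimum spanning network of haplotypes
#'
#' The union of all minimum spanning trees over the masked Hamming
#' distance graph: an edge is retained exactly when its endpoints are
#' not connected by any path of strictly smaller edge weights (Kruskal
#' with inclusion of equal-weight ties). `epsilon > 0` additionally
#' admits edges up to `epsilon` steps longer than the connection
#' threshold.
#'
#' @param x A `haplotype_table` (from [collapse_haplotypes()]) or a
#'   named character vector of haplotype sequences.
#' @param epsilon Non-negative weight tolerance (default 0).
#' @return A `haplo_network`: `$nodes` (name, is_median, frequency,
#'   per-population counts when available) and `$edges` (from, to,
#'   steps).
#' @export
minimum_spanning_network <- function(x, epsilon = 0) {
  hs <- hap_set(x)
  seq_var <- collapse_rows(variable_columns(hs$seqs), length(hs$seqs))
  d <- state_dist_matrix(hs$seqs)
  make_network(hs, seq_var, rep(FALSE, length(hs$seqs)), msn_edges(d, epsilon))
}

# all quasi-medians of a sequence triple (majority state per column;
# columns with three distinct states branch into each of them)
quasi_medians <- function(a, b, c, max_combo = 81L) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]; cc <- strsplit(c, "")[[1]]
  opts <- vector("list", length(ca))
  for (j in seq_along(ca)) {
    v <- c(ca[j], cb[j], cc[j])
    tab <- table(v)
    opts[[j]] <- if (max(tab) >= 2L) names(tab)[which.max(tab)] else unique(v)
  }
  n_comb <- prod(lengths(opts))
  if (n_comb > max_combo) return(character(0))
  out <- ""
  for (j in seq_along(opts)) {
    out <- as.vector(outer(out, opts[[j]], paste0))
  }
  out
}

#' Median-joining haplotype network
#'
#' The iterative median-joining construction: build the
#' epsilon-relaxed minimum spanning network, then for every connected
#' triple of nodes (at least two of its three pairs linked) generate
#' quasi-median (Steiner) vectors and add those that strictly shorten
#' the triple's local connection (\eqn{\sum_x d(x,m)} less than the sum
#' of the two smallest pairwise distances); repeat until no median is
#' added, then prune superfluous medians (unlinked ones, and degree-2
#' medians lying exactly on a geodesic between their two neighbours).
#' Median vectors have frequency 0 and names `MV1`, `MV2`, ...
#'
#' Haplotypes carrying ambiguous bases at variable sites remain nodes
#' but are excluded from median generation (with a warning).
#'
#' @inheritParams minimum_spanning_network
#' @return A `haplo_network`; see [minimum_spanning_network()].
#' @export
median_joining <- function(x, epsilon = 0) {
  if (epsilon < 0) abort("epsilon must be >= 0", class = "haplopop_config_error")
  hs <- hap_set(x)
  n_obs <- length(hs$seqs)
  seqs <- collapse_rows(variable_columns(hs$seqs), n_obs)
  names <- hs$names
  ambiguous <- grepl("[N-]", seqs)
  if (any(ambiguous)) {
    warn(paste0(sum(ambiguous),
                " haplotype(s) with ambiguous bases at variable sites",
                " excluded from median computation"))
  }
  mv_id <- 0L
  repeat {
    d <- state_dist_matrix(seqs)
    edges <- msn_edges(d, epsilon)
    adj <- matrix(FALSE, length(seqs), length(seqs))
    if (!is.null(edges)) adj[edges[, 1:2, drop = FALSE]] <- TRUE
    adj <- adj | t(adj)
    amb_all <- c(ambiguous, rep(FALSE, length(seqs) - n_obs))
    elig <- which(!amb_all)
    new_seqs <- character(0)
    if (length(elig) >= 3L) {
      trip <- combn(sort(elig), 3L)
      for (tt in seq_len(ncol(trip))) {
        u <- trip[1, tt]; v <- trip[2, tt]; w <- trip[3, tt]
        n_linked <- adj[u, v] + adj[u, w] + adj[v, w]
        if (n_linked < 2L) next
        pd <- sort(c(d[u, v], d[u, w], d[v, w]))
        local_cost <- pd[1] + pd[2]
        for (m in quasi_medians(seqs[u], seqs[v], seqs[w])) {
          if (m %in% seqs || m %in% new_seqs) next
          cm <- strsplit(m, "")[[1]]
          dm <- vapply(c(u, v, w), function(i) {
            ci <- strsplit(seqs[i], "")[[1]]
            sum(ci != cm)
          }, numeric(1))
          if (sum(dm) < local_cost) new_seqs <- c(new_seqs, m)
        }
      }
    }
    if (length(new_seqs) == 0L) break
    new_seqs <- sort(unique(new_seqs))
    for (m in new_seqs) {
      mv_id <- mv_id + 1L
      names <- c(names, paste0("MV", mv_id))
    }
    seqs <- c(seqs, new_seqs)
  }
  # prune superfluous medians
  repeat {
    d <- state_dist_matrix(seqs)
    edges <- msn_edges(d, epsilon)
    deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = length(seqs))
    drop <- integer(0)
    for (i in seq_along(seqs)) {
      if (i <= n_obs) next
      if (deg[i] <= 1L) { drop <- c(drop, i); next }
      if (deg[i] == 2L) {
        nb <- c(edges[edges[, 1] == i, 2], edges[edges[, 2] == i, 1])
        if (d[nb[1], nb[2]] == d[nb[1], i] + d[i, nb[2]]) drop <- c(drop, i)
      }
    }
    if (length(drop) == 0L) break
    keep <- setdiff(seq_along(seqs), drop[1])
    seqs <- seqs[keep]; names <- names[keep]
  }
  d <- state_dist_matrix(seqs)
  hs$names <- names
  hs$freq <- c(hs$freq, rep(0L, length(seqs) - n_obs))
  make_network(hs, seqs, c(rep(FALSE, n_obs), rep(TRUE, length(seqs) - n_obs)),
               msn_edges(d, epsilon))
}

#' Total edge length of a haplotype network's spanning structure
#' @param net A `haplo_network`.
#' @param spanning If `TRUE` (default) the minimum spanning tree length
#'   over the network's nodes; otherwise the sum of all edge weights.
#' @return Total mutational steps.
#' @export
network_length <- function(net, spanning = TRUE) {
  if (nrow(net$edges) == 0L) return(0)
  if (!spanning) return(sum(net$edges$steps))
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes$name)
  sum(igraph::E(igraph::mst(g, weights = igraph::E(g)$steps))$steps)
}

#' Is a haplotype network connected?
#' @param net A `haplo_network`.
#' @return Logical.
#' @export
network_connected <- function(net) {
  if (nrow(net$nodes) <= 1L) return(TRUE)
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes$name)
  igraph::is_connected(g)
}

#' @export
print.haplo_network <- function(x, ...) {
  cat(sprintf("<haplo_network> %d nodes (%d median vectors), %d edges\n",
              nrow(x$nodes), sum(x$nodes$is_median), nrow(x$edges)))
  invisible(x)
}

#' Write a haplotype network as node/edge TSVs (optionally GraphML)
#' @param net A `haplo_network`.
#' @param nodes_path,edges_path Output TSV paths.
#' @param graphml_path Optional GraphML export path.
#' @return `nodes_path`, invisibly.
#' @export
write_network <- function(net, nodes_path, edges_path, graphml_path = NULL) {
  readr::write_tsv(net$nodes, nodes_path)
  readr::write_tsv(net$edges, edges_path)
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = net$nodes)
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(nodes_path)
}
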