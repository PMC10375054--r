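#' Demographic models for the coalescent simulator
#'
#' Time is measured in coalescent units of N generations for a haploid
#' population of size N, so that the scaled mutation rate is
#' \eqn{\theta = 2Nu} per sequence and a pair of lineages in one deme
#' coalesces at rate 1 (times a history-dependent multiplier). Looking
#' back in time, `demography_expansion(tau_event, growth_factor)` makes
#' the population `growth_factor` times smaller than at present beyond
#' time `tau_event` (i.e. an instantaneous `growth_factor`-fold expansion
#' happened `tau_event` time units ago); in mutational units the
#' expansion time is \eqn{\tau = \theta \cdot tau\_event}.
#' `demography_island(Nm)` adds symmetric migration among equally sized
#' demes at per-lineage scaled rate `Nm`; it may be combined with an
#' expansion (all demes rescale together).
#'
#' @param tau_event Scaled time of the instantaneous size change (>= 0).
#' @param growth_factor Ratio of present to ancestral size (>= 1 for an
#'   expansion).
#' @param Nm Scaled migration rate (expected migrants per deme per
#'   coalescent time unit).
#' @return A demography description used by [simulate_coalescent()].
#' @name demography
NULL

#' @rdname demography
#' @export
demography_constant <- function() {
  list(type = "constant", tau_event = 0, growth_factor = 1, Nm = 0)
}

#' @rdname demography
#' @export
demography_expansion <- function(tau_event, growth_factor) {
  if (tau_event < 0 || growth_factor <= 0) {
    abort("tau_event must be >= 0 and growth_factor > 0", class = "haplopop_config_error")
  }
  list(type = "expansion", tau_event = tau_event,
       growth_factor = growth_factor, Nm = 0)
}

#' @rdname demography
#' @export
demography_island <- function(Nm, tau_event = 0, growth_factor = 1) {
  if (Nm < 0) abort("Nm must be >= 0", class = "haplopop_config_error")
  list(type = "island", tau_event = tau_event,
       growth_factor = growth_factor, Nm = Nm)
}

# simulate a (possibly structured) coalescent genealogy.
# Returns parent/time vectors over nodes 1..(2n-1); tips are 1..n.
sim_genealogy <- function(n_per_deme, demography) {
  n <- sum(n_per_deme)
  D <- length(n_per_deme)
  parent <- rep(NA_integer_, 2L * n - 1L)
  node_time <- numeric(2L * n - 1L)
  active <- seq_len(n)
  deme <- rep(seq_len(D), n_per_deme)
  lin_deme <- deme
  mig <- if (D > 1L) demography$Nm else 0
  g_anc <- demography$growth_factor
  tau_ev <- demography$tau_event
  t <- 0
  nxt <- n
  while (length(active) > 1L) {
    g <- if (t >= tau_ev) g_anc else 1
    k_d <- tabulate(lin_deme, nbins = D)
    coal_d <- g * k_d * (k_d - 1) / 2
    mig_rate <- mig * length(active) * (D > 1L)
    R <- sum(coal_d) + mig_rate
    if (R <= 0) {
      # isolated lineages with no migration cannot coalesce
      abort("coalescent cannot proceed: zero event rate (Nm = 0 with >1 deme)",
            class = "haplopop_config_error")
    }
    dt <- rexp(1L, R)
    if (t < tau_ev && t + dt > tau_ev && g_anc != 1) {
      t <- tau_ev   # rate changes at the event; redraw beyond it
      next
    }
    t <- t + dt
    if (runif(1L) * R < sum(coal_d)) {
      d <- sample.int(D, 1L, prob = coal_d)
      in_d <- which(lin_deme == d)
      pick <- if (length(in_d) == 2L) in_d else sample(in_d, 2L)
      nxt <- nxt + 1L
      parent[active[pick]] <- nxt
      node_time[nxt] <- t
      active <- c(active[-pick], nxt)
      lin_deme <- c(lin_deme[-pick], d)
    } else {
      i <- sample.int(length(active), 1L)
      lin_deme[i] <- sample(setdiff(seq_len(D), lin_deme[i]), 1L)
    }
  }
  list(n = n, parent = parent, time = node_time, tip_deme = deme)
}

# branch length above each non-root node
branch_lengths <- function(gen) {
  len <- numeric(length(gen$parent))
  has_parent <- !is.na(gen$parent)
  len[has_parent] <- gen$time[gen$parent[has_parent]] - gen$time[which(has_parent)]
  len
}

# number of tip descendants below each node
descendant_counts <- function(gen) {
  n_nodes <- length(gen$parent)
  desc <- integer(n_nodes)
  desc[seq_len(gen$n)] <- 1L
  ord <- order(gen$time[(gen$n + 1L):n_nodes])
  for (v in (gen$n + ord)) {
    desc[v] <- sum(desc[which(gen$parent == v)])
  }
  desc
}

# convert to an ape "phylo" (root renumbered to n+1 as ape requires)
genealogy_to_phylo <- function(gen, tip_labels = NULL) {
  n <- gen$n
  n_nodes <- 2L * n - 1L
  remap <- seq_len(n_nodes)
  internal <- (n + 1L):n_nodes
  remap[internal] <- n + 1L + (n_nodes - internal)
  kids <- which(!is.na(gen$parent))
  edge <- cbind(remap[gen$parent[kids]], remap[kids])
  lens <- gen$time[gen$parent[kids]] - gen$time[kids]
  phy <- list(edge = edge, edge.length = lens,
              tip.label = tip_labels %||% paste0("t", seq_len(n)),
              Nnode = n - 1L)
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

#' Simulate sequence data under the coalescent
#'
#' Draws a genealogy (standard Kingman coalescent; time-rescaled under a
#' sudden size change; structured with migration under the island
#' model), drops mutations on branches as a Poisson process at rate
#' \eqn{\theta/2} per unit scaled time, and emits an aligned sample.
#' Under `infinite_sites` every mutation occupies a new alignment
#' column (positions drawn without replacement from `1..L`); under
#' `finite_sites_JC` mutations hit uniformly chosen sites and substitute
#' a uniformly chosen different base (Jukes–Cantor).
#'
#' @param n_per_deme Integer vector of sample sizes; one deme per entry
#'   (multiple entries without an island demography are labels on a
#'   panmictic population).
#' @param theta Scaled mutation rate 2Nu per sequence (> 0).
#' @param demography See [demography_constant()], [demography_expansion()],
#'   [demography_island()].
#' @param L Alignment length in sites.
#' @param mutation_model `"infinite_sites"` (default) or `"finite_sites_JC"`.
#' @param seed RNG seed; fixed seed gives bit-identical output.
#' @param pop_labels Optional deme labels (default `pop1`, `pop2`, ...).
#' @return A `sim_dataset`: list with `alignment` ([hap_alignment()]),
#'   `genealogy` (internal node times/topology), `tree` (`phylo`),
#'   `mutations` (tibble: node, position), and `params`.
#' @export
simulate_coalescent <- function(n_per_deme, theta,
                                demography = demography_constant(),
                                L = 683,
                                mutation_model = c("infinite_sites", "finite_sites_JC"),
                                seed = NULL, pop_labels = NULL) {
  mutation_model <- match.arg(mutation_model)
  n_per_deme <- as.integer(n_per_deme)
  if (any(n_per_deme <= 0L) || theta <= 0 || L <= 0) {
    abort("sample sizes, theta and L must be positive", class = "haplopop_config_error")
  }
  n <- sum(n_per_deme)
  pop_labels <- pop_labels %||% paste0("pop", seq_along(n_per_deme))
  with_seed(seed, {
    # multiple entries without an island demography are panmictic labels
    gen_demes <- if (demography$type == "island") n_per_deme else n
    gen <- sim_genealogy(gen_demes, demography)
    if (demography$type != "island") {
      gen$tip_deme <- rep(seq_along(n_per_deme), n_per_deme)
    }
    blen <- branch_lengths(gen)
    n_mut <- rpois(length(blen), theta / 2 * blen)
    bases <- c("A", "C", "G", "T")
    anc <- sample(bases, L, replace = TRUE)
    seqs <- matrix(rep(anc, each = n), nrow = n)
    mut_nodes <- integer(0); mut_pos <- integer(0)
    if (mutation_model == "infinite_sites") {
      S <- sum(n_mut)
      if (S > L) {
        abort(sprintf("infinite-sites simulation needs %d columns but L = %d", S, L),
              class = "haplopop_config_error")
      }
      if (S > 0L) {
        pos <- sample.int(L, S)
        mut_nodes <- rep(seq_along(n_mut), n_mut)
        mut_pos <- pos
        below <- tips_below(gen)
        for (k in seq_len(S)) {
          tips <- below[[mut_nodes[k]]]
          old <- anc[mut_pos[k]]
          seqs[tips, mut_pos[k]] <- sample(setdiff(bases, old), 1L)
        }
      }
    } else {
      # evolve sequences down the tree from the root
      node_seq <- vector("list", length(gen$parent))
      root <- which(is.na(gen$parent))
      node_seq[[root]] <- anc
      ord <- order(gen$time, decreasing = TRUE)
      for (v in setdiff(ord, root)) {
        s <- node_seq[[gen$parent[v]]]
        if (n_mut[v] > 0L) {
          for (j in seq_len(n_mut[v])) {
            p <- sample.int(L, 1L)
            s[p] <- sample(setdiff(bases, s[p]), 1L)
            mut_nodes <- c(mut_nodes, v); mut_pos <- c(mut_pos, p)
          }
        }
        node_seq[[v]] <- s
      }
      for (i in seq_len(n)) seqs[i, ] <- node_seq[[i]]
    }
    pops <- pop_labels[gen$tip_deme]
    ids <- paste0(pops, "_", unlist(lapply(n_per_deme, seq_len)))
    aln <- hap_alignment(ids, pops, apply(seqs, 1L, paste, collapse = ""))
    structure(list(
      alignment = aln,
      genealogy = gen,
      tree = genealogy_to_phylo(gen, ids),
      mutations = tibble(node = mut_nodes, position = mut_pos),
      params = list(n_per_deme = n_per_deme, theta = theta,
                    demography = demography, L = L,
                    mutation_model = mutation_model, seed = seed)
    ), class = "sim_dataset")
  })
}

# list of tip ids below each node
tips_below <- function(gen) {
  n_nodes <- length(gen$parent)
  below <- vector("list", n_nodes)
  for (i in seq_len(gen$n)) below[[i]] <- i
  ord <- order(gen$time[(gen$n + 1L):n_nodes])
  for (v in (gen$n + ord)) {
    below[[v]] <- unlist(below[which(gen$parent == v)], use.names = FALSE)
  }
  below
}

# Fast path for null distributions: summary statistics (S, k_hat, K
# distinct mutational haplotypes) from a genealogy without building
# sequence strings. Infinite-sites mutation process.
sim_summary_stats <- function(n, theta, demography = demography_constant()) {
  gen <- sim_genealogy(n, demography)
  blen <- branch_lengths(gen)
  n_mut <- rpois(length(blen), theta / 2 * blen)
  S <- sum(n_mut)
  desc <- descendant_counts(gen)
  npairs <- n * (n - 1) / 2
  k_hat <- sum(n_mut * desc * (n - desc)) / npairs
  # distinct haplotypes: partition tips by the set of mutated branches
  # on their root path
  mutated <- which(n_mut > 0L)
  if (length(mutated) == 0L) {
    K <- 1L
  } else {
    key <- character(length(gen$parent))
    root <- which(is.na(gen$parent))
    ord <- order(gen$time, decreasing = TRUE)
    for (v in setdiff(ord, root)) {
      key[v] <- if (n_mut[v] > 0L) {
        paste0(key[gen$parent[v]], ",", v)
      } else {
        key[gen$parent[v]]
      }
    }
    K <- length(unique(key[seq_len(n)]))
  }
  list(S = S, k_hat = k_hat, K = K)
}

#' Simulate a six-locality study-like dataset
#'
#' Emulates the sampling design and genetic signal of a coastal
#' barnacle COI survey: 6 demes of 65 haploid individuals each, a 683-bp
#' locus, high gene flow (island model, Nm = 100) and a recent 50-fold
#' sudden expansion, giving star-like genealogies with one dominant
#' haplotype, per-deme haplotype diversity roughly 0.4–0.85 and
#' nucleotide diversity in the low 1e-3 range.
#'
#' @param seed RNG seed.
#' @return A `sim_dataset` (see [simulate_coalescent()]); populations are
#'   labelled `P1`...`P6`.
#' @export
simulate_fujian_like <- function(seed = NULL) {
  simulate_coalescent(
    n_per_deme = rep(65L, 6L), theta = 4,
    demography = demography_island(Nm = 100, tau_event = 0.2,
                                   growth_factor = 50),
    L = 683L, mutation_model = "infinite_sites", seed = seed,
    pop_labels = paste0("P", 1:6)
  )
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %d sequences (%s), L = %d, theta = %g, demography: %s\n",
              nrow(x$alignment),
              paste(x$params$n_per_deme, collapse = "+"),
              x$params$L, x$params$theta, x$params$demography$type))
  invisible(x)
}

#' Write a simulated dataset to FASTA + popmap (+ parameter sidecar)
#' @param sim A `sim_dataset`.
#' @param fasta,popmap,params Output paths (params optional).
#' @return `fasta`, invisibly.
#' @export
write_sim_dataset <- function(sim, fasta, popmap, params = NULL) {
  write_fasta(sim$alignment, fasta, popmap_path = popmap)
  if (!is.null(params)) {
    p <- sim$params
    readr::write_tsv(tibble(
      key = c("theta", "L", "mutation_model", "demography", "tau_event",
              "growth_factor", "Nm", "n_per_deme"),
      value = c(p$theta, p$L, p$mutation_model, p$demography$type,
                p$demography$tau_event, p$demography$growth_factor,
                p$demography$Nm, paste(p$n_per_deme, collapse = ","))
    ), params)
  }
  invisible(fasta)
}
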