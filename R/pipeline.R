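#' Analysis configuration for the full pipeline
#'
#' @param n_perm Permutations for AMOVA / pairwise Phi-ST (default 10000).
#' @param n_boot Bootstrap replicates for NJ support and the mismatch
#'   goodness-of-fit (default 1000).
#' @param n_null Coalescent replicates for neutrality-test p-values
#'   (default 1000).
#' @param rate Substitution rate for expansion dating (string such as
#'   `"3.1%/Myr"` or a per-site per-year number).
#' @param rate_convention `"lineage"` or `"divergence"`; see [parse_rate()].
#' @param generation_years Generation time in years (default 1).
#' @param seed Master seed; per-stage seeds are derived deterministically
#'   from it so adding a stage does not perturb earlier stages.
#' @param epsilon Median-joining tolerance (default 0).
#' @return A list of validated settings for [run_full_analysis()].
#' @export
analysis_config <- function(n_perm = 10000, n_boot = 1000, n_null = 1000,
                            rate = "3.1%/Myr",
                            rate_convention = "lineage",
                            generation_years = 1, seed = 20230713,
                            epsilon = 0) {
  if (n_perm < 1 || n_boot < 1 || n_null < 1) {
    abort("replicate counts must be >= 1", class = "haplopop_config_error")
  }
  list(n_perm = n_perm, n_boot = n_boot, n_null = n_null, rate = rate,
       rate_convention = rate_convention,
       generation_years = generation_years, seed = as.integer(seed),
       epsilon = epsilon)
}

#' Run the full single-locus analysis pipeline
#'
#' Executes the complete workflow on an aligned haploid dataset:
#' haplotype table, per-population diversity, AMOVA, pairwise Phi-ST and
#' between-population divergence, NJ tree with bootstrap support,
#' neutrality tests, per-population mismatch fits with expansion-time
#' dating, and the median-joining network — writing one TSV (or Newick)
#' per result into `out_dir` plus a run log recording parameters and
#' seeds.
#'
#' @param aln A [hap_alignment()] (or use `fasta` + `popmap` paths).
#' @param out_dir Output directory (created if needed).
#' @param config See [analysis_config()].
#' @param fasta,popmap Optional input paths used when `aln` is `NULL`.
#' @return Invisibly, a list with every result object:
#'   `haplotypes`, `diversity`, `amova`, `pairwise`, `dxy`, `tree`,
#'   `neutrality`, `mismatch`, `expansion`, `network`.
#' @export
run_full_analysis <- function(aln = NULL, out_dir, config = analysis_config(),
                              fasta = NULL, popmap = NULL) {
  if (is.null(aln)) {
    if (is.null(fasta) || is.null(popmap)) {
      abort("provide either aln or fasta + popmap", class = "haplopop_input_error")
    }
    aln <- read_fasta(fasta, popmap)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run_log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("haplopop %s | seed %d | n_perm %d | n_boot %d | n_null %d | rate %s | generation %g y",
       as.character(utils::packageVersion("haplopop")), config$seed,
       config$n_perm, config$n_boot, config$n_null,
       as.character(config$rate), config$generation_years)
  logf("input: %d sequences x %d sites, populations: %s", nrow(aln),
       aln_length(aln), paste(unique(aln$population), collapse = ", "))

  stage <- function(name) derive_seed(config$seed, name)

  tab <- collapse_haplotypes(aln)
  write_haplotype_table(tab, file.path(out_dir, "table1_haplotypes.tsv"),
                        fasta_path = file.path(out_dir, "haplotypes.fasta"))
  comp <- base_composition(aln)
  readr::write_tsv(comp, file.path(out_dir, "base_composition.tsv"))
  sites <- classify_sites(aln)
  readr::write_tsv(sites, file.path(out_dir, "site_classification.tsv"))
  logf("haplotypes: %d; variable sites: %d", nrow(tab), site_summary(sites)["S"])

  div <- summarize_diversity(aln, tab)
  write_diversity_table(div, file.path(out_dir, "table2_diversity.tsv"))

  dist <- pairwise_difference_matrix(aln)
  am <- amova(dist, aln$population, n_perm = config$n_perm, seed = stage("amova"))
  am_tab <- tidy(am)
  am_tab$phi_st <- c(am$phi_st, NA, NA)
  am_tab$p_value <- c(am$p_value, NA, NA)
  readr::write_tsv(am_tab, file.path(out_dir, "table3_amova.tsv"))
  logf("AMOVA: Phi_ST = %.5f, p = %.4g", am$phi_st, am$p_value)

  pw <- pairwise_phist(dist, aln$population, n_perm = config$n_perm,
                       seed = stage("pairwise"))
  dx <- dxy_matrix(aln)
  # conventional combined matrix: Phi_ST below the diagonal, d_xy above
  comb <- pw$phi_st
  comb[upper.tri(comb)] <- dx[upper.tri(dx)]
  readr::write_tsv(as_tibble(comb, rownames = "locality"),
                   file.path(out_dir, "table4_pairwise.tsv"))
  readr::write_tsv(tidy(pw), file.path(out_dir, "table4_pairwise_long.tsv"))

  bs <- bootstrap_support(aln, n_reps = config$n_boot, seed = stage("njboot"),
                          collapse = TRUE)
  write_newick(bs$tree, file.path(out_dir, "nj_tree.nwk"))

  neut <- neutrality_tests(aln, n_sims = config$n_null, seed = stage("neutrality"))
  fits <- mismatch_analysis(aln, n_boot = config$n_boot, seed = stage("mismatch"))
  mm <- bind_rows(purrr::imap(fits, function(f, p) {
    mutate(glance(f), population = p, .before = 1)
  }))
  tab5 <- left_join(neut, mm, by = "population")
  readr::write_tsv(tab5, file.path(out_dir, "table5_demography.tsv"))
  hist_tab <- bind_rows(purrr::imap(fits, function(f, p) {
    mutate(tidy(f), population = p, .before = 1)
  }))
  readr::write_tsv(hist_tab, file.path(out_dir, "mismatch_histograms.tsv"))

  exp_tab <- bind_rows(purrr::imap(fits, function(f, p) {
    mutate(expansion_time(f$tau, config$rate, aln_length(aln),
                          config$generation_years,
                          convention = config$rate_convention),
           population = p, .before = 1)
  }))
  readr::write_tsv(exp_tab, file.path(out_dir, "expansion_times.tsv"))

  net <- median_joining(tab, epsilon = config$epsilon)
  write_network(net, file.path(out_dir, "network_nodes.tsv"),
                file.path(out_dir, "network_edges.tsv"))
  logf("network: %d nodes (%d medians), %d edges",
       nrow(net$nodes), sum(net$nodes$is_median), nrow(net$edges))
  logf("done")

  invisible(list(alignment = aln, haplotypes = tab, diversity = div,
                 amova = am, pairwise = pw, dxy = dx, tree = bs,
                 neutrality = neut, mismatch = fits, expansion = exp_tab,
                 network = net, config = config))
}
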