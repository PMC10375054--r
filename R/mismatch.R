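#' Observed mismatch distribution
#'
#' Relative frequencies, over all unordered sequence pairs, of the
#' number of pairwise differences (classes `0..d_max`, where `d_max` is
#' the largest observed difference).
#'
#' @param aln A [hap_alignment()].
#' @param population Population label or `"all"` (pooled).
#' @return Numeric vector of frequencies summing to 1; element `i`
#'   corresponds to `i - 1` differences.
#' @export
mismatch_observed <- function(aln, population = "all") {
  sub <- aln_subset(aln, population)
  if (nrow(sub) < 2L) {
    abort("mismatch distribution needs at least 2 sequences", class = "haplopop_input_error")
  }
  useq <- unique(sub$sequence)
  mult <- as.integer(table(factor(sub$sequence, levels = useq)))
  d <- hap_dist_matrix(useq)
  dmax <- max(d)
  counts <- numeric(dmax + 1L)
  counts[1L] <- sum(mult * (mult - 1) / 2)          # within-haplotype pairs
  if (length(useq) > 1L) {
    for (i in 1:(length(useq) - 1L)) {
      for (j in (i + 1L):length(useq)) {
        counts[d[i, j] + 1L] <- counts[d[i, j] + 1L] + mult[i] * mult[j]
      }
    }
  }
  counts / sum(counts)
}

# log of the equilibrium geometric mismatch term theta^i / (1+theta)^(i+1)
log_feq <- function(i, theta) {
  if (theta <= 0) return(ifelse(i == 0, 0, -Inf))
  i * log(theta) - (i + 1) * log1p(theta)
}

#' Expected mismatch distribution under the sudden-expansion model
#'
#' Pairwise-difference class probabilities for a population that changed
#' instantaneously from mutation-scaled size `theta0` to `theta1` at
#' mutational time `tau = 2ut` before present. At equilibrium
#' (`tau = 0` or `theta0 = theta1 = theta`) this reduces to the
#' geometric \eqn{F_i = \theta^i/(1+\theta)^{i+1}}; in general
#' \deqn{F_i = \hat F_i(\theta_1)\,P[\mathrm{Pois}(a\tau) > i] +
#'   e^{-\tau/\theta_1} \sum_{j=0}^{i} \mathrm{dpois}(j;\tau)\,
#'   \hat F_{i-j}(\theta_0),\quad a = (\theta_1+1)/\theta_1,}
#' the exact closed form of the coalescent pair-time mixture.
#'
#' @param tau Mutational time since the size change (>= 0).
#' @param theta0,theta1 Pre- and post-change theta (>= 0).
#' @param d_max Largest difference class to return.
#' @param renormalize Rescale the truncated vector to sum to 1 (default
#'   `TRUE`).
#' @return Numeric vector of length `d_max + 1`.
#' @export
mismatch_expected <- function(tau, theta0, theta1, d_max, renormalize = TRUE) {
  if (tau < 0 || theta0 < 0 || theta1 < 0) {
    abort("tau, theta0, theta1 must be >= 0", class = "haplopop_config_error")
  }
  i <- 0:d_max
  feq <- function(th) {
    if (th <= 0) return(as.numeric(i == 0))
    exp(i * log(th) - (i + 1) * log1p(th))
  }
  if (theta1 > 0) {
    a_tau <- tau * (theta1 + 1) / theta1
    recent <- feq(theta1) * stats::ppois(i, a_tau, lower.tail = FALSE)
    scale_old <- exp(-tau / theta1)
  } else {
    recent <- rep(0, d_max + 1L)   # the old/boundary terms carry the mass
    scale_old <- if (tau > 0) 0 else 1
  }
  feq0 <- feq(theta0)
  pois <- stats::dpois(i, tau)
  old <- scale_old * vapply(i, function(ii) {
    sum(pois[1:(ii + 1L)] * feq0[(ii + 1L):1L])
  }, numeric(1))
  out <- recent + old
  if (theta1 <= 0 && tau > 0) out[1L] <- 1  # instantaneous recent coalescence
  if (renormalize) {
    s <- sum(out)
    if (s > 0) out <- out / s
  }
  out
}

#' Harpending's raggedness index
#'
#' \eqn{r = \sum_{i=1}^{d+1} (x_i - x_{i-1})^2} over the frequency
#' vector `x_0..x_d` with `x_{d+1} = 0`; small for the smooth unimodal
#' distributions produced by demographic expansions.
#'
#' @param observed Frequency vector over classes `0..d`.
#' @return Scalar raggedness.
#' @export
raggedness <- function(observed) {
  sum(diff(c(observed, 0))^2)
}

#' Fit the sudden-expansion model to a mismatch distribution
#'
#' Minimises the sum of squared deviations
#' \eqn{SSD = \sum_i (obs_i - exp_i)^2} over
#' \eqn{\tau \in [0, 25]}, \eqn{\theta_0 \in [0, 50]},
#' \eqn{\theta_1 \in [\theta_0, 5000]} by a coarse grid search refined
#' with Nelder–Mead on a smooth reparameterisation. The expected vector
#' is truncated at the observed `d_max` and renormalised.
#'
#' @param observed Frequency vector (classes `0..d_max`, sums to 1).
#' @param n Optional sample size the distribution came from (stored for
#'   the parametric bootstrap).
#' @param tau_max,theta0_max,theta1_max Search bounds.
#' @param refine_starts Number of grid basins to refine by Nelder–Mead
#'   (default 5; the parametric bootstrap uses 1 for speed).
#' @param maxit Nelder–Mead iteration cap per start.
#' @return A `mismatch_fit` object: `tau`, `theta0`, `theta1`, `SSD`,
#'   `raggedness`, `observed`, `expected`. See [tidy.mismatch_fit()],
#'   [glance.mismatch_fit()], [gof_bootstrap()].
#' @export
fit_sudden_expansion <- function(observed, n = NULL, tau_max = 25,
                                 theta0_max = 50, theta1_max = 5000,
                                 refine_starts = 5L, maxit = 600L) {
  if (abs(sum(observed) - 1) > 1e-6) {
    abort("observed must be a frequency vector summing to 1", class = "haplopop_input_error")
  }
  d_max <- length(observed) - 1L
  if (d_max == 0L) {
    warn("degenerate mismatch distribution (single class): returning tau = 0 boundary")
    fit <- list(tau = 0, theta0 = 0, theta1 = 0, SSD = 0,
                raggedness = raggedness(observed),
                observed = observed, expected = observed,
                d_max = d_max, n = n)
    class(fit) <- "mismatch_fit"
    return(fit)
  }
  ssd_for <- function(tau, th0, th1) {
    e <- mismatch_expected(tau, th0, th1, d_max)
    sum((observed - e)^2)
  }
  # coarse grid; the observed mean anchors plausible tau values, since
  # the model's mean is close to tau + theta0 for large theta1
  obs_mean <- sum((0:d_max) * observed)
  taus <- sort(unique(c(0, obs_mean * c(0.25, 0.5, 0.75, 1, 1.25, 1.5),
                        seq(0.1, tau_max, length.out = 12))))
  taus <- taus[taus <= tau_max]
  th0s <- c(0, 0.05, 0.1, 0.25, 0.5, 1, 2, 5, 15, theta0_max)
  th1s <- c(0.5, 2, 10, 50, 200, 1000, theta1_max)
  grid <- NULL
  for (tv in taus) for (t0 in th0s) for (t1 in th1s) {
    if (t1 < t0) next
    grid <- rbind(grid, c(tv, t0, t1, ssd_for(tv, t0, t1)))
  }
  grid <- grid[order(grid[, 4]), , drop = FALSE]
  # smooth refinement from several starting basins: logistic box
  # transforms keep the search inside the bounds and theta1 >= theta0
  unpack <- function(p) {
    tau <- tau_max * stats::plogis(p[1])
    th0 <- theta0_max * stats::plogis(p[2])
    th1 <- th0 + (theta1_max - th0) * stats::plogis(p[3])
    c(tau, th0, th1)
  }
  pack1 <- function(x, mx) stats::qlogis(pmin(pmax(x / mx, 1e-6), 1 - 1e-6))
  best_val <- grid[1, 4]
  pars <- grid[1, 1:3]
  for (s in seq_len(min(refine_starts, nrow(grid)))) {
    st <- grid[s, ]
    p0 <- c(pack1(st[1], tau_max), pack1(st[2], theta0_max),
            pack1(max(st[3] - st[2], 1e-4), theta1_max - st[2]))
    opt <- stats::optim(p0, function(p) {
      q <- unpack(p); ssd_for(q[1], q[2], q[3])
    }, method = "Nelder-Mead", control = list(maxit = maxit, reltol = 1e-12))
    if (opt$value < best_val) {
      best_val <- opt$value
      pars <- unpack(opt$par)
    }
  }
  ssd <- best_val
  fit <- list(tau = pars[1], theta0 = pars[2], theta1 = pars[3],
              SSD = ssd,
              raggedness = raggedness(observed),
              observed = observed,
              expected = mismatch_expected(pars[1], pars[2], pars[3], d_max),
              d_max = d_max, n = n)
  class(fit) <- "mismatch_fit"
  fit
}

#' @export
print.mismatch_fit <- function(x, ...) {
  cat(sprintf(paste0("Sudden-expansion mismatch fit: tau = %.3f, theta0 = %.3f, ",
                     "theta1 = %.1f\nSSD = %.5f, raggedness = %.4f (%d classes)\n"),
              x$tau, x$theta0, x$theta1, x$SSD, x$raggedness, x$d_max + 1L))
  if (!is.null(x$SSD_pvalue)) {
    cat(sprintf("bootstrap p: SSD %.3f, raggedness %.3f\n",
                x$SSD_pvalue, x$raggedness_pvalue))
  }
  invisible(x)
}

#' Tidy a mismatch fit into observed/expected class frequencies
#' @param x A `mismatch_fit`.
#' @param ... Unused.
#' @return Tibble: `differences`, `observed`, `expected`.
#' @export
tidy.mismatch_fit <- function(x, ...) {
  tibble(differences = 0:x$d_max, observed = x$observed, expected = x$expected)
}

#' One-row mismatch-fit summary
#' @param x A `mismatch_fit`.
#' @param ... Unused.
#' @return Tibble: `tau`, `theta0`, `theta1`, `SSD`, `raggedness` and,
#'   when [gof_bootstrap()] has been run, their bootstrap p-values.
#' @export
glance.mismatch_fit <- function(x, ...) {
  tibble(tau = x$tau, theta0 = x$theta0, theta1 = x$theta1,
         SSD = x$SSD, raggedness = x$raggedness,
         SSD_pvalue = x$SSD_pvalue %||% NA_real_,
         raggedness_pvalue = x$raggedness_pvalue %||% NA_real_)
}

# pairwise mismatch frequency vector straight from a simulated genealogy
# (sum of mutations on the path between each tip pair)
sim_mismatch_vector <- function(n, theta, demography) {
  gen <- sim_genealogy(n, demography)
  n_mut <- rpois(length(gen$parent), theta / 2 * branch_lengths(gen))
  D <- matrix(0, n, n)
  below <- tips_below(gen)
  for (v in which(n_mut > 0L)) {
    tips <- below[[v]]
    D[tips, -tips] <- D[tips, -tips] + n_mut[v]
  }
  d <- D[upper.tri(D)] + t(D)[upper.tri(D)]
  tabulate(d + 1L, nbins = max(d) + 1L) / length(d)
}

#' Parametric bootstrap goodness-of-fit for a mismatch fit
#'
#' Simulates `n_boot` coalescent samples of size `n` under the fitted
#' sudden-expansion model, refits each simulated mismatch distribution,
#' and reports `p = P(SSD* >= SSD_obs)` and the analogous raggedness
#' p-value (raggedness of the simulated observed vectors). Large p means
#' the expansion model cannot be rejected.
#'
#' @param fit A `mismatch_fit`.
#' @param n Sample size (defaults to the `n` stored in the fit).
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @return The fit with `SSD_pvalue` and `raggedness_pvalue` filled in.
#' @export
gof_bootstrap <- function(fit, n = NULL, n_boot = 1000, seed = NULL) {
  n <- n %||% fit$n
  if (is.null(n)) abort("sample size n required", class = "haplopop_input_error")
  if (n_boot < 50) warn("fewer than 50 bootstrap replicates: p-values will be coarse")
  th1 <- max(fit$theta1, 1e-3)
  th0 <- fit$theta0
  growth <- th1 / max(th0, th1 / 1000)   # cap at 1000x when theta0 ~ 0
  demog <- if (fit$tau > 0 && growth > 1) {
    demography_expansion(tau_event = fit$tau / th1, growth_factor = growth)
  } else {
    demography_constant()
  }
  theta_sim <- if (fit$tau > 0) th1 else max(th0, 1e-3)
  stats_boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      obs_b <- sim_mismatch_vector(n, theta_sim, demog)
      fit_b <- fit_sudden_expansion(obs_b, n = n, refine_starts = 1L,
                                    maxit = 200L)
      c(fit_b$SSD, raggedness(obs_b))
    }, numeric(2))
  })
  fit$SSD_pvalue <- mean(stats_boot[1, ] >= fit$SSD)
  fit$raggedness_pvalue <- mean(stats_boot[2, ] >= fit$raggedness)
  fit$n <- n
  fit$n_boot <- n_boot
  fit
}

#' Convert a rate string like "3.1%/Myr" to substitutions/site/year
#'
#' @param rate A number (already per site per year) or a string
#'   `"<percent>%/Myr"`.
#' @param convention `"lineage"` (default; the rate applies to each
#'   lineage) or `"divergence"` (the quoted rate is between-lineage
#'   divergence, i.e. twice the lineage rate).
#' @return Rate per site per year on the per-lineage scale.
#' @export
parse_rate <- function(rate, convention = c("lineage", "divergence")) {
  convention <- match.arg(convention)
  if (is.character(rate)) {
    m <- stringr::str_match(rate, "^\\s*([0-9.eE+-]+)\\s*%\\s*/\\s*M(?:yr|a)\\s*$")
    if (is.na(m[1, 2])) {
      abort(paste0("cannot parse rate string: ", rate), class = "haplopop_config_error")
    }
    rate <- as.numeric(m[1, 2]) / 100 / 1e6
  }
  if (convention == "divergence") rate <- rate / 2
  rate
}

#' Expansion time from tau
#'
#' With the sudden-expansion relation \eqn{\tau = 2ut}, where
#' \eqn{u = rate \times L \times generation} is the per-sequence,
#' per-generation mutation rate, the expansion happened
#' \eqn{t = \tau/(2u)} years ago (generation time in years).
#'
#' @param tau Fitted tau (mutational units).
#' @param rate Per-site per-year substitution rate, or a string such as
#'   `"3.1%/Myr"`; see [parse_rate()] for the lineage/divergence
#'   convention.
#' @param L Sequence length in sites.
#' @param generation_years Generation time in years (default 1).
#' @param convention Passed to [parse_rate()].
#' @return One-row tibble: `tau`, `rate_per_site_per_year`, `L`,
#'   `generation_years`, `u`, `t_years`.
#' @export
expansion_time <- function(tau, rate, L, generation_years = 1,
                           convention = c("lineage", "divergence")) {
  rate <- parse_rate(rate, match.arg(convention))
  if (tau < 0 || rate < 0 || L <= 0 || generation_years < 0) {
    abort("inputs must be non-negative (L positive)", class = "haplopop_input_error")
  }
  u <- rate * L * generation_years
  if (u == 0 && tau > 0) {
    abort("expansion time undefined: zero mutation rate with tau > 0",
          class = "haplopop_undefined_error")
  }
  t_years <- if (tau == 0) 0 else tau / (2 * u)
  tibble(tau = tau, rate_per_site_per_year = rate, L = L,
         generation_years = generation_years, u = u, t_years = t_years)
}

#' Per-population mismatch analysis
#'
#' Observed mismatch distribution, sudden-expansion fit and (optional)
#' parametric-bootstrap goodness of fit for each population.
#'
#' @param aln A [hap_alignment()].
#' @param populations Populations (default all; `"all"` may be included
#'   for the pooled sample).
#' @param n_boot Bootstrap replicates (0 to skip the goodness-of-fit).
#' @param seed RNG seed.
#' @return Named list of `mismatch_fit` objects.
#' @export
mismatch_analysis <- function(aln, populations = NULL, n_boot = 1000,
                              seed = NULL) {
  populations <- populations %||% unique(aln$population)
  fits <- purrr::map(populations, function(p) {
    obs <- mismatch_observed(aln, p)
    n_p <- if (identical(p, "all")) nrow(aln) else sum(aln$population == p)
    fit <- fit_sudden_expansion(obs, n = n_p)
    if (n_boot > 0 && fit$d_max > 0L) {
      sd_p <- if (is.null(seed)) NULL else derive_seed(seed, paste0("gof_", p))
      fit <- gof_bootstrap(fit, n = n_p, n_boot = n_boot, seed = sd_p)
    }
    fit
  })
  names(fits) <- populations
  fits
}
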