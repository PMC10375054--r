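---
title: "Models and methods in haplopop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in haplopop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

haplopop implements the classical single-locus analysis applied to
non-recombining haploid markers such as mitochondrial COI fragments:
haplotype identification, diversity indices, AMOVA-based population
structure, neutrality tests, mismatch-distribution demographic
inference, and median-joining haplotype networks, together with a
coalescent simulator that provides ground truth for every estimator.
This vignette records the statistical models, the conventions chosen
where the literature allows several, and the limits of what the
package's own tests demonstrate.

## Data model and ambiguity handling

An alignment is a tibble of equal-length sequences with a population
label per record. All statistics are defined on the unambiguous bases
A, C, G, T. `N` and the gap character are masked *per site and per
pair* (pairwise deletion), never by removing whole columns, so the
1-based site coordinate frame of the input alignment is preserved in
every report. IUPAC ambiguity codes other than `N` are accepted on
input but degraded to `N`: partial information at a polymorphic
position cannot enter estimators defined on the four-letter alphabet
without introducing a merging rule, and any such rule would be
order-dependent.

The same reasoning fixes the haplotyping rule: two sequences share a
haplotype if and only if their strings match exactly. A sequence with
an `N` therefore never merges into a "compatible" haplotype. This is
conservative — it can split one true haplotype into two when sequencing
quality is poor — but it is deterministic and reproducible, which we
judged more important for a reference implementation. Haplotypes are
named `H1`, `H2`, ... in order of first appearance in the input, so
the numbering is a property of the dataset, not of frequency ranking.

## Diversity

Haplotype diversity uses the unbiased estimator
$h = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)$ with $p_i$ the sample
haplotype frequencies. Nucleotide diversity $\pi$ is the mean over all
unordered pairs of the per-pair fraction of differing comparable sites;
$\hat k$ is the mean raw count of differences. When a single "average"
diversity is quoted across localities it is the *unweighted arithmetic
mean* of the per-locality values, the convention used in survey tables
with equal sample sizes; a pooled-sample estimate would differ and is
available by passing `population = "all"`. Tabular output rounds $h$
to 3 decimals and $\pi$ to 5, matching conventional reporting; full
precision is retained in R.

## AMOVA and pairwise $\Phi_{ST}$

The two-level analysis of molecular variance partitions squared
pairwise molecular distances: with $N$ individuals in $P$ populations,

$$SS_{total} = \tfrac{1}{N}\sum_{i<j} d_{ij}^2,\qquad
  SS_{within} = \sum_p \tfrac{1}{n_p}\sum_{i<j \in p} d_{ij}^2,$$

$V_b = SS_{within}/(N-P)$, $V_a = (SS_{among}/(P-1) - V_b)/\bar n$ with
$\bar n = (N - \sum_p n_p^2/N)/(P-1)$, and
$\Phi_{ST} = V_a/(V_a+V_b)$. The distance is the raw count of pairwise
differences rather than a model-corrected distance: at the divergence
levels this package targets ($\pi$ of order $10^{-3}$) multiple-hit
corrections are far below sampling noise. Significance comes from
permuting individuals among populations (default 10,000 permutations)
with the $(b+1)/(m+1)$ estimator, so a p-value is never exactly zero.
Negative $\Phi_{ST}$ estimates are reported as computed; they are the
expected behaviour of an unbiased variance-component estimator near
zero differentiation, and truncating them would bias averages upward.
Pairwise values are reported raw and with a Holm (sequential
Bonferroni) adjustment, since survey papers are frequently silent about
multiple-testing policy; readers can apply either. Between-population
divergence $d_{xy}$ is the uncorrected mean per-site difference
fraction over inter-population pairs, the natural companion to a
within-population $\pi$ of the same units.

## Neutrality tests

Tajima's $D$ follows the standard normalisation of
$\hat k - S/a_1$ by $\sqrt{e_1 S + e_2 S(S-1)}$ with the usual
$n$-dependent constants. Its p-value is obtained by simulating neutral
constant-size coalescent samples *conditioned on the sample size* with
$\theta$ fixed at Watterson's estimate $S/a_1$, and doubling the
smaller tail (capped at 1) — the practice of the established AMOVA
software lineage — rather than using the beta approximation, which is
known to be anticonservative in the tails. The default is 1000
replicates; the per-replicate statistics are computed directly from the
simulated genealogy and Poisson mutation counts without materialising
sequences, which keeps the null cheap.

Fu's $F_s$ uses the Ewens sampling formula: with
$S' = P(K \ge k_{obs} \mid \theta, n)$,
$F_s = \ln(S'/(1-S'))$, where $P(K=k) \propto |s(n,k)|\,\theta^k$ and
$|s(n,k)|$ are unsigned Stirling numbers of the first kind computed by
the triangular recursion in log space (a polynomial-expansion route is
kept in the test suite as an independent oracle). $\theta$ is the
pairwise estimator $\hat k$, following the statistic's original
definition. One observed allele gives $S'=1$ and a $+\infty$ sentinel.
The p-value is the lower-tail fraction of simulated $F_s^*$, and we
document the convention that significance at the nominal 5% level is
declared at $p < 0.02$, because the null distribution of $F_s$
concentrates probability near its extremes.

## Mismatch distributions and sudden expansion

The sudden-expansion model describes a population whose
mutation-scaled size changed instantaneously from $\theta_0$ to
$\theta_1$ at mutational time $\tau = 2ut$ before present. The
expected pairwise-difference distribution is evaluated in the exact
closed form

$$F_i = \hat F_i(\theta_1)\,P[\mathrm{Pois}(a\tau) > i]
      + e^{-\tau/\theta_1}\sum_{j=0}^{i}
        \mathrm{dpois}(j;\tau)\,\hat F_{i-j}(\theta_0),
  \qquad a = \tfrac{\theta_1+1}{\theta_1},$$

where $\hat F_i(\theta) = \theta^i/(1+\theta)^{i+1}$ is the
equilibrium geometric distribution; the formula follows from
integrating the Poisson mutation count over the piecewise-exponential
pair coalescence time, and the test suite checks it against direct
numerical integration. Parameters are fitted by minimising
$SSD = \sum_i (obs_i - exp_i)^2$ over $\tau \in [0,25]$,
$\theta_0 \in [0,50]$, $\theta_1 \in [\theta_0, 5000]$, using a coarse
grid (anchored at the observed mean, since the model mean is close to
$\tau + \theta_0$ for large $\theta_1$) followed by Nelder–Mead from
the best few basins under a smooth logistic reparameterisation that
enforces the box and the ordering $\theta_1 \ge \theta_0$. The
expected vector is truncated at the largest observed difference class
and renormalised; the exact per-class weighting used by the
established software is unpublished, so plain SSD over the observed
support is our documented choice. Harpending's raggedness
$r = \sum (x_i - x_{i-1})^2$ is computed on the observed vector with a
trailing zero class.

Goodness of fit uses a parametric bootstrap: samples of the original
size are simulated under the fitted expansion (the fitted
$(\tau, \theta_0, \theta_1)$ mapped to a coalescent sudden-expansion
demography), each simulated mismatch distribution is refitted, and
$p = P(SSD^* \ge SSD_{obs})$; the bootstrap refits use a single-start
refinement because their role is to reproduce the null spread of the
statistic, not to polish each replicate. Expansion dating applies
$t = \tau/(2u)$ with $u = \text{rate} \times L \times \text{generation}$.
Clock rates quoted as "percent per million years" are ambiguous between
a per-lineage and a pairwise-divergence convention (a factor of two in
$t$); both are exposed (`convention = "lineage"` is the default) and
neither is hard-coded into any reported constant.

## Haplotype networks

The minimum spanning network is the union of all minimum spanning
trees of the Hamming-distance graph, computed by the connection-
threshold rule (an edge survives exactly when its endpoints are not
joined by strictly shorter edges). Median joining extends it
iteratively: for every connected triple, quasi-median vectors
(majority state per column; three-state columns branch) are added when
they strictly shorten the triple's local connection; after
convergence, superfluous median vectors — unlinked ones and degree-2
medians lying exactly on a geodesic between their neighbours — are
pruned. The tolerance `epsilon` defaults to 0, the default of the
widely used desktop implementation. Only variable columns enter the
construction, with uniform site weights; tie-breaks are lexicographic
in node name, so the output is deterministic for a given input order.
Haplotypes with ambiguity at variable sites remain network nodes but
are excluded from median generation, because a quasi-median through an
`N` is undefined.

## The coalescent simulator

The simulator is first-class, tested code: it supplies the neutrality
nulls, the goodness-of-fit bootstrap, and all synthetic test data.
Time is scaled in units of $N$ generations for a haploid population,
so $\theta = 2Nu$ per sequence and mutations fall on branches at rate
$\theta/2$ — users comparing with diploid-scaled tools should note the
factor of two. Demographies: constant size; sudden expansion
(coalescence rate multiplied by the growth factor beyond the event
time, the time-rescaling equivalent of an instantaneous size change);
and an island model with symmetric per-lineage migration rate $Nm$,
optionally combined with an expansion. Mutation models: infinite
sites (each mutation a fresh column — homoplasy-free by construction,
which the four-gamete property test verifies) and finite-sites
Jukes–Cantor, sufficient at the sub-percent divergences targeted here.
Fixed seeds give bit-identical output.

`simulate_fujian_like()` emulates a six-locality coastal survey
design: 6 demes × 65 haploid samples, a 683-site locus, high gene flow
($Nm = 100$) and a recent 50-fold expansion. The remaining free
parameters were set once to $\theta = 4$ and event time 0.2 (mutational
expansion time $\tau = \theta \times 0.2 = 0.8$), which places
simulated datasets in the empirically typical regime for such surveys:
one dominant haplotype, per-deme $h$ roughly 0.4–0.85, per-deme $\pi$
in the low $10^{-3}$ range, and a unimodal mismatch distribution.

What the simulator does *not* emulate: sequencing error, base-
compositional bias (simulated ancestral bases are uniform), rate
heterogeneity among sites, selection, and recombination. Tests passing
on simulated data therefore demonstrate correctness of the estimators
under their own model assumptions, not robustness to these real-data
features.

## The reconstructed count-table fixture

`table1_fixture()` rebuilds a 390-sequence, six-locality alignment
whose haplotype-by-locality counts equal a published survey table
exactly (84 haplotypes, 65 samples per locality, the dominant
haplotype at 224 copies, 59 single-locality haplotypes). The haplotype
*sequences* are not published, so the fixture assigns synthetic,
internally consistent sequences: a proline-codon backbone with
third-position substitutions encoding each haplotype index in binary
within the first 21 columns, stop-free under the invertebrate
mitochondrial code. Every count-based statistic (haplotype diversity,
dominance, sharing, richness) is exactly reproducible from such a
fixture; sequence-based statistics computed on it ($\pi$, base
composition, site counts, AMOVA variance components, mismatch shapes)
reflect the synthetic sequences and are *not* estimates of any real
quantity. The per-locality haplotype diversities the fixture
reproduces (0.789, 0.584, 0.756, 0.688, 0.475, 0.668; unweighted mean
0.660) are recomputed by the test suite and the acceptance script, not
asserted as constants.

## Numerical and degenerate-input conventions

* Sites observable in fewer than two sequences are `excluded` from the
  variable/invariant classification rather than silently invariant.
* Diversity statistics require $n \ge 2$, Tajima's $D$ requires
  $n \ge 4$ and $S \ge 1$ (else `NaN` with a warning), Fu's $F_s$
  returns $+\infty$ at $k_{obs} = 1$.
* An all-zero distance matrix makes $\Phi_{ST}$ undefined; the AMOVA
  reports `NaN` with a warning instead of 0.
* Neighbour joining clamps negative branch lengths to zero, moving the
  excess onto the sister branch at the same junction so adjacent path
  lengths are preserved.
* A single-class mismatch distribution returns the $\tau = 0$ boundary
  fit with a warning.
* All permutation and bootstrap p-values use add-one corrections or
  report exact fractions, and every stochastic routine takes an
  explicit seed; the pipeline derives per-stage seeds from one master
  seed by stage-name hashing, so inserting a stage leaves the streams
  of other stages untouched.

## Problem sizes used in the shipped checks

The package's own test suite runs everything at reduced but
statistically meaningful sizes, chosen so the whole suite completes in
a few minutes on a single core: 2000 replicates for the neutral
Tajima's-$D$ calibration ($n = 30$, $\theta = 5$), 500 for the
expansion direction and the random-labelling $\Phi_{ST}$ centring, 200
fitted replicates for $\tau$ recovery (truth $\tau = 3$, tolerance
25% on the median), 200 island-model replicates per migration level,
and bootstrap/permutation counts of 50–300 in pipeline smoke tests.
The analysis defaults remain at the conventional published sizes
(10,000 permutations, 1000 bootstraps, 1000 coalescent nulls).

## Known limitations

* AMOVA is two-level only; hierarchical designs with groups of
  populations are out of scope.
* The mismatch fit minimises unweighted SSD; standard errors for
  $\tau$ are available only through the parametric bootstrap, not
  analytically.
* The median-joining implementation targets the moderate haplotype
  counts of single-locus surveys (hundreds); its triple enumeration is
  cubic in the number of nodes.
* Fu's $F_s$ at very large $n$ (thousands) would need the Stirling
  triangle in higher precision than double-log arithmetic provides;
  at survey scales ($n \le$ a few hundred) it is exact to double
  precision.
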