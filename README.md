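# haplopop

Single-locus population genetics for haploid alignments: the complete
analysis a molecular-ecology study applies to a mitochondrial COI
survey, as one tested R package. Given an aligned set of haploid
sequences and a sample-to-population map, haplopop identifies
haplotypes and builds the haplotype-by-locality count table, computes
haplotype diversity $h$ and nucleotide diversity $\pi$, partitions
variance within and among populations by AMOVA with permutation tests
($\Phi_{ST} = V_a/(V_a+V_b)$), runs Tajima's $D$ and Fu's $F_s$
neutrality tests against coalescent-simulated nulls, fits the
Rogers–Harpending sudden-expansion model to the mismatch distribution
($\tau$, $\theta_0$, $\theta_1$, SSD, raggedness, parametric-bootstrap
goodness of fit) and converts $\tau = 2ut$ into an expansion date,
builds median-joining haplotype networks and neighbour-joining trees
with bootstrap support, and ships a coalescent simulator
(constant-size, sudden-expansion, island demographies; infinite-sites
and Jukes–Cantor mutation) that provides ground truth for all of it.

It is aimed at population geneticists and molecular ecologists who
want the classical DnaSP/Arlequin-style pipeline as scriptable,
seed-reproducible R functions returning tibbles, with broom-style
`tidy()`/`glance()` methods and `autoplot()` figures.

## Worked example

A bundled generator reconstructs a six-locality barnacle COI survey
dataset (390 sequences of 683 bp in localities ND, FZ, PT, QZ, XM, ZZ)
from its published haplotype-by-locality count table; the haplotype
sequences themselves are synthetic, so count-based statistics are
exact while sequence-based ones are illustrative.

```r
library(haplopop)

aln <- table1_fixture()
tab <- collapse_haplotypes(aln)
tab
#> <haplotype_table> 84 haplotypes, 390 individuals, 6 population(s)

dominant_haplotype(tab)
#> # A tibble: 1 × 4
#>   haplotype total frequency_pct n_populations
#> 1 H2          224          57.4             6

summarize_diversity(aln, tab)[, c("population", "n", "n_haplotypes", "h")]
#> # A tibble: 7 × 4
#>   population     n n_haplotypes     h
#> 1 ND            65           32 0.789
#> 2 QZ            65           19 0.688
#> 3 XM            65           12 0.475
#> 4 ZZ            65           17 0.668
#> 5 FZ            65           20 0.584
#> 6 PT            65           27 0.756
#> 7 mean          NA           NA 0.660
```

The dominant haplotype H2 accounts for 224/390 = 57.4% of individuals
and occurs in all six localities; 59 of the 84 haplotypes are private
to one locality (`sharing_profile(tab)`), and the unweighted mean
haplotype diversity across localities is 0.660.

Demographic inference on a simulated survey-like dataset (6 demes ×
65 samples, high gene flow, recent 50-fold expansion):

```r
sim <- simulate_fujian_like(seed = 42)
d <- tajimas_d(sim$alignment, "P1")
d
#> # A tibble: 1 × 5
#>   population     n     S k_hat     D
#> 1 P1            65    19  1.09 -2.22
tajima_d_pvalue(d$D, d$n, d$S, n_sims = 1000, seed = 1)
#> [1] 0.004

fit <- fit_sudden_expansion(mismatch_observed(sim$alignment), n = 390)
fit
#> Sudden-expansion mismatch fit: tau = 1.537, theta0 = 0.000, theta1 = 5000.0
#> SSD = 0.00495, raggedness = 0.0843 (7 classes)
expansion_time(fit$tau, "3.1%/Myr", 683)$t_years
#> [1] 36293
```

The strongly negative Tajima's $D$ with a small simulated-null p-value
and the smooth unimodal mismatch fit are the signature of the recent
expansion the simulator imposed; the last line converts the fitted
$\tau$ into years under a 3.1%/Myr per-lineage clock and a one-year
generation time.

The whole workflow — count table, diversity, AMOVA, pairwise
$\Phi_{ST}$/$d_{xy}$, NJ tree, neutrality and mismatch tables,
network TSVs, run log — is orchestrated by
`run_full_analysis(aln, out_dir, analysis_config(seed = ...))`, and a
thin command-line wrapper lives in `inst/cli/run_analysis.R`. Networks
and fits plot via `autoplot()`.

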