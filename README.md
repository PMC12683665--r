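# germscreen

Salinity-tolerance screening of seed germination and early seedling
development, for plant scientists running petri-dish and germination-box
trials. The package covers the full statistical workflow of a
three-stage screen:

1. **Germination dynamics** under a salt gradient, analysed as
   interval-censored time-to-event data: germination is only observed
   between scheduled inspections, and seeds that never germinate are
   right censored. The cumulative germination curve is estimated by the
   Turnbull nonparametric MLE — masses $w_j$ on the maximal-intersection
   intervals maximising
   $\prod_i \big(\sum_{j:(q_j,p_j]\subseteq(L_i,R_i]} w_j\big)^{n_i}$
   via the self-consistency EM — from which T50 (with bootstrap SE),
   generalized Wilcoxon scores $u = \hat S(L)+\hat S(R)-1$ against the
   pooled curve, and a permutation test of curve equality are derived.
2. **Stress tolerance index (STI) screening** of an accession panel:
   the six classical germination indices (TG, VC, GI, MGT, GSI, NR) per
   dish, their stress/control ratios $STI_x = X_{stress}/X_{control}$
   per accession, PCA of the STI matrix, and reproducible hierarchical
   k-means clustering (Ward initialization + Lloyd refinement).
3. **Seedling morphometry**: per-box vigor index
   $SVI = \text{germinability}\times(\text{shoot}+\text{main root}+
   \text{lateral root})$, trait STIs, and Kruskal–Wallis/Dunn contrasts
   across the germination-stage clusters.

A configurable simulator (`simulate_panel()`, `simulate_seedlings()`)
generates panels with known delay, viability, synchrony and morphometry
parameters, so every stage is testable end-to-end without any external
data. See the vignette in `vignettes/germination-screening.Rmd` for the
models and design decisions.

## Worked example

One dish of 50 seeds inspected at 1, 2, 3 and 6 days after sowing (DAS),
with 10/20/5/0 newly germinated seeds and 3 abnormal seedlings at the
final count:

```r
library(germscreen)
library(dplyr)

counts <- tibble::tibble(
  accession = "CAM-01", treatment_mM = 0, replicate = "r1",
  day = c(1, 2, 3, 6), new_germinated = c(10L, 20L, 5L, 0L),
  n_sown = 50L, abnormal_final = c(NA, NA, NA, 3L)
)

fit <- fit_npmle(counts_to_intervals(counts))
fit
#> Turnbull NPMLE fit: 50 seeds, 4 support interval(s)
#> log-likelihood: -63.99271 | EM iterations: 2
#> # A tibble: 4 × 4
#>    left right  mass   cdf
#>   <dbl> <dbl> <dbl> <dbl>
#> 1     0     1   0.2   0.2
#> 2     1     2   0.4   0.6
#> 3     2     3   0.1   0.7
#> 4     6   Inf   0.3   1
```

The counts align with the schedule, so the masses are the empirical
proportions: 20% of seeds germinated in (0,1], 40% in (1,2], and 30%
(the `(6, Inf)` row) never germinated. T50 interpolates the curve across
the crossing interval — F(1) = 0.2, F(2) = 0.6, so half the sown seeds
are reached at 1 + (0.5 − 0.2)/0.4 = 1.75 DAS:

```r
quantile_time(fit, 0.5)
#> # A tibble: 1 × 3
#>       p  time defined
#>   <dbl> <dbl> <lgl>
#> 1   0.5  1.75 TRUE

germination_indices(counts) %>% select(tg, vc, gi, mgt, gsi, nr)
#> # A tibble: 1 × 6
#>      tg    vc    gi   mgt   gsi    nr
#>   <dbl> <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1    70 0.538  21.7   1.3 0.412  91.4
```

70% total germination, mean germination time 1.3 DAS (sown-seed
denominator, so MGT × VC = G6/Ntot holds exactly), synchrony 0.41, and
91.4% of germinated seedlings morphologically normal.

A full screening run on a simulated 55-accession panel (three built-in
phenotype archetypes, 2 treatments × 3 dishes × 50 seeds):

```r
sim <- simulate_panel(seed = 1)
res <- run_experiment2(sim$counts, k = 3, seed = 1)
res
#> STI screening of 55 accessions
#> PC1/PC2 variance (%): 41.2/34
#> cluster sizes: 32/14/9

joined <- left_join(tidy(res$clusters), sim$truth, by = "accession")
rand_index(joined$cluster, joined$archetype)
#> [1] 1
```

The clustering recovers the generator's three archetypes exactly
(Rand index 1), with the slow-but-complete archetype (32 accessions)
separated from the fast-but-frail (14) and salt-sensitive (9) ones.

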