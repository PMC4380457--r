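# yuledist

Statistics of pairwise evolutionary time distances between the observed
leaves of a random Yule (birth–death) tree with incomplete sampling.

## The problem

In phylogenetics one often has only a matrix of pairwise time distances
between sampled species — not a reliable tree, and never the unsampled
species.  Under the Yule model (each lineage splits at rate λ, dies at
rate μ, the tree has age *T*, and each extant leaf is observed with
probability σ), the expected histogram of pairwise distances and of
several neighbour statistics have exact closed forms, all depending on
the parameters only through three identifiable combinations:

    r = λ − μ,    q = λσ,    A = σ·e^{rT}.

With g(t) = (e^{rt/2} − 1)/r, the package evaluates on [0, 2T]:

| statistic | expected density |
|---|---|
| pairwise distance | (qA/2)·e^{rt/2} |
| n-th nearest neighbour | n(n+1)/2 · qA·(qg)^{n−1}·e^{rt/2}/(1+qg)^{n+2} |
| cherry (reciprocal nearest) | (qA/2)·e^{rt/2}/(1+qg)^4 |
| pairwise min of nearest distances | 2λ²σ³e^{r(T+t)}·G(T−t/2)/(1+qg)^5 + cherry term |

The pairwise density is a pure exponential — a one-line test of
Yule-ness for empirical data.  The neighbour statistics carry more: each
develops an interior maximum only when sampling is sparse (σ below 1/3,
1/4 and 1/5 respectively at μ = 0), so a maximum in an empirical
histogram *bounds the sampling fraction* with no rate assumptions.
Fitting the curves yields (r, q, A); since μ ≥ 0, the ratio q/r is an
upper bound for σ, and assuming a ratio μ/λ gives σ = (q/r)(1 − μ/λ).

The package provides: the exact laws (`pairwise_density`,
`nth_min_density`, `cherry_density`, `min2_density`, `leaf_count_pmf`,
moments, narrow-bin occupancy laws); a compiled Kinetic Monte Carlo
simulator with full genealogy retention (`simulate_yule_tree`,
`ensemble_histograms`); tree-free statistics from distance matrices or
Newick trees (`pairwise_list`, `nth_nearest_list`, `cherry_list`,
`min2_list`); and robust IRLS fitting with sampling-fraction bounds
(`fit_densities`, `sigma_upper_bound`, `implied_sigma`,
`maximum_based_sigma_bound`).

## Worked example

Simulate 10,000 trees at λ = 6, μ = 3, σ = 0.1, T = 1 (so r = 3,
q = 0.6, A = 0.1·e³ ≈ 2.009), pool their histograms, and recover the
identifiable combinations:

```r
library(yuledist)
p <- yule_params(lambda = 6, mu = 3, sigma = 0.1, height = 1)
mean_leaves(p)   # 2.008554  : expected observed leaves, sigma*e^{rT}
mean_pairs(p)    # 7.666865  : expected observed pairs

h <- ensemble_histograms(p, s = 10000, bins = 40, seed = 42,
                         kinds = c("pairwise", "nth_min", "cherry"))
fit <- fit_densities(list(h$pairwise, h$nth_min1, h$cherry))
fit
#> Yule density fit (identifiable combinations):
#>   r = lambda - mu     : 2.95273 (se 0.0174)
#>   q = lambda * sigma  : 0.612991 (se 0.00552)
#>   A = sigma * exp(rT) : 1.98208 (se 0.0134)
#>   converged: TRUE (28 IRLS iterations)
#>   sigma upper bound q/r (mu = 0): 0.2076
```

The fit recovers r ≈ 3, q ≈ 0.6, A ≈ 2.0.  The σ bound q/r ≈ 0.21 is an
upper bound because extinction was assumed absent; the true σ = 0.1
corresponds to the actual ratio μ/λ = 0.5:

```r
implied_sigma(fit, 0.5)
#> 0.1038007
maximum_based_sigma_bound(h$nth_min1, fit)
#> $bound 0.333..., $t_max 0.438, "upper bound assumes mu >= 0"
```

The fitted nearest-neighbour curve has an interior maximum, which alone
certifies σ < 1/3 for this data.

A command-line wrapper over the same functions ships in
`inst/cli/yuledist.R` (subcommands `simulate`, `density`, `stats`,
`fit`, `fixtures`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/yuledist.R", package="yuledist"))')" \
  density --kind nmin --n 1 --lambda 6 --sigma 0.1 --height 1 --grid 0:2:200
```

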