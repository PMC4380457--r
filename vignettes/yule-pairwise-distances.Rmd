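---
title: "Pairwise distance statistics on Yule trees: models, methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pairwise distance statistics on Yule trees: models, methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yuledist)
```

## The model

A Yule (birth--death) tree starts from a single lineage at time 0.  Each
lineage independently splits at rate $\lambda$ and dies at rate $\mu$; the
tree is observed at a fixed height (age) $T$, and each extant leaf is
retained in the data independently with sampling fraction $\sigma \in
[0,1]$.  Incomplete sampling and a recent random mass extinction are
equivalent under this model, which is why $\sigma$ can be read either way.
The data this package targets are not trees but **pairwise time
distances**: the distance between two leaves is $2(T - t_{\mathrm{MRCA}})$,
twice the time back to their most recent common ancestor, so all distances
live on $[0, 2T]$.

Throughout, closed forms are written in the three combinations
$$r = \lambda - \mu, \qquad q = \lambda\sigma, \qquad A = \sigma e^{rT},$$
because every distance statistic depends on the parameters only through
them: the four raw parameters are not identifiable from distances alone.

### The observed leaf-count law

The number $M$ of observed leaves is zero-inflated geometric.  With the
growth integral $G(\tau) = (e^{r\tau}-1)/r$,
$$P(0) = 1 - \frac{\sigma e^{rT}}{1 + qG(T)},\qquad
  P(m \ge 1) = (1-P(0))\,(1-\eta)\,\eta^{m-1},\qquad
  \eta = \frac{qG(T)}{1 + qG(T)}.$$
This form is exactly equivalent to the usual expressions with
$(\lambda-\mu)$ denominators but remains finite and accurate through the
critical case $\lambda = \mu$ (where $G \to T$).  From it follow the
moments $\langle M\rangle = \sigma e^{rT} = A$ and
$\langle M(M-1)/2\rangle = \sigma^2\lambda\, e^{rT} G(T)$, and the tail
$P(M > k) = (1-P(0))\eta^k$.

### Expected distance densities

With $g(t) = (e^{rt/2}-1)/r$, the package evaluates, on $[0, 2T]$ and zero
outside:

* **pairwise**: $N(t) = \tfrac{1}{2}qA\, e^{rt/2}$ — a pure increasing
  exponential, cut off at $2T$.  Its integral over the support equals the
  expected pair count exactly, which pins down the $\lambda/2$ prefactor.
* **$n$-th nearest neighbour**:
  $N_n(t) = \tfrac{n(n+1)}{2}\, qA\,(qg)^{n-1} e^{rt/2}/(1+qg)^{n+2}$.
  Each observed leaf with at least $n$ other observed leaves contributes
  one value; ties count with multiplicity.
* **cherries** (reciprocal nearest neighbours):
  $N_\Lambda(t) = \tfrac{1}{2} qA\, e^{rt/2}/(1+qg)^4$.
* **pairwise minimum of nearest-neighbour distances** ("min2"): for every
  unordered pair, the smaller of the two members' nearest-neighbour
  distances,
  $$N_{\min2}(t) = 2\lambda^2\sigma^3 e^{r(T+t)}
    \frac{G(T - t/2)}{(1+qg)^5} \;+\; N_\Lambda(t).$$

These forms were derived by solving the branching recursions of the model
with a Laplace transform and verified three independent ways: against
literal transcriptions of the published algebra (in the test suite's
oracle helpers), against the branch-point construction (the density of
branch points at depth $t/2$ times the expected "payoff" of observed
descendants on both sides), and against Kinetic Monte Carlo simulation.

The second, additive term of $N_{\min 2}$ deserves a note.  The natural
recursion for the min2 statistic counts cross-subtree pairs in which one
member has nearest-neighbour distance $t$ and the other a larger one.
That bookkeeping misses pairs that are *reciprocal* nearest neighbours —
for a cherry, both members attain the minimum on each other, so neither
has a neighbour "further than $t$".  These pairs contribute exactly the
cherry density.  The corrected sum is validated by an exact identity the
statistic must satisfy — every pair of observed leaves has exactly one
min2 value, so $\int_0^{2T} N_{\min2}\,dt$ must equal the expected pair
count — and by ensemble simulation, both of which fail for the bare
cross-pair term alone.

### Maxima as sampling diagnostics

The nearest-neighbour, cherry and min2 densities are increasing on their
support when sampling is dense, but develop an interior maximum when
$\sigma$ falls below $(1-\mu/\lambda)/3$, $(1-\mu/\lambda)/4$ and
$(1-\mu/\lambda)/5$ respectively (the min2 threshold holds for tree
heights large enough that the support cutoff does not interfere).  Since
$\mu \ge 0$, *observing* such a maximum bounds the sampling fraction by
$1/3$, $1/4$ or $1/5$ without knowing any rate.  The maximum locations for
the first two are closed forms,
$t^{\max}_1 = \tfrac{2}{r}\ln\frac{\lambda(1-\sigma)-\mu}{2\lambda\sigma}$
and the cherry analogue with $3\lambda\sigma$ in the denominator; the min2
maximum is located numerically.

### Single trees: the conditional density

For one tree and a narrow bin $[t, t+dt)$, the expected bin count
$N(t)\,dt$ is misleading: the count distribution is almost all mass at
zero plus a wide positive part, because a bin is non-empty only when a
branch point happens to sit at depth $t/2$.  The empty-bin probability and
the full count distribution (a divisor sum over factorizations of the
count into two subtree leaf counts) are implemented directly, and the
conditional density
$\tilde N(t) = N(t)/[1 - \Pr(\text{empty})] = (1+qg)^2/dt$
is the right target when fitting a single sparse tree, with zero bins
ignored.  The identity $N\,dt = \tilde N\,dt\,(1-\Pr(\text{empty}))$ holds
by construction and is asserted in the tests.

## Numerical design

All expressions are computed through two scalar kernels,
$\mathrm{expm1}(x)/x$ and $\mathrm{log1p}(x)/x$, with short Taylor series
below $|x| < 10^{-5}$.  No formula divides by $\lambda-\mu$, so no branch
switching is needed anywhere near the critical case; a continuity test
compares $|\lambda-\mu| = 10^{-10}$ against $10^{-6}$ across every
operation.  The `near_critical` flag on parameter objects is informational
only.

Probabilities use the geometric form of the leaf-count law rather than
the raw published algebra (whose $(\cdot)^{M+1}$ powers overflow for large
$M$); the two agree to $10^{-10}$ relative on moderate parameters, which
the oracle tests check explicitly.

## The simulator

Trees are grown by Kinetic Monte Carlo: waiting times are exponential with
mean $1/(M(\lambda+\mu))$ for $M$ alive lineages, a uniformly chosen
lineage then splits or dies with odds $\lambda : \mu$, and the event whose
waiting time overshoots $T$ is discarded.  The complete genealogy is kept;
Bernoulli($\sigma$) marks are applied to the extant leaves at the end.  A
lineage cap (default $10^6$ alive) turns runaway growth
($e^{(\lambda-\mu)T}$ can be astronomical) into a typed error.

The hot loop is compiled (Rcpp) and draws all randomness from R's RNG, so
`set.seed()` makes every tree and every ensemble reproducible; this
replaces per-tree counter substreams, which buy nothing in a single-stream
R session.  Statistic extraction works directly on the genealogy: pairwise
counts come from per-split products of observed-descendant counts,
nearest-neighbour orders from a climb up the parent links (split times are
monotone along root paths, so the sorted distance multiset of a leaf is
its ancestor sequence), cherries are splits with exactly one observed leaf
on each side, and min2 histograms follow from the sorted nearest-neighbour
distances.  The tests verify that genealogy-walk statistics equal
matrix-based statistics on the same trees exactly.

Ensembles accumulate, per bin: pooled counts, squared per-tree counts (for
empirical standard errors), non-empty-tree counts (for the conditional
mean) and per-tree totals.  One statistical subtlety matters for
validation: all bins of an ensemble histogram share the same trees, so
per-bin deviations are positively correlated and per-tree pair counts are
heavy-tailed.  Comparisons in the test suite therefore combine a single
exact total-count test with per-bin checks under an explicit multiplicity
allowance, rather than pretending bins are independent.

## Fitting

`fit_densities()` fits the pairwise, nearest-neighbour and cherry curves
jointly in $(r, q, A)$ (log-parameterized for positivity) by iteratively
reweighted least squares with bisquare weights (tuning constant 4.685,
the standard choice for that weight family), a damped Gauss--Newton inner
step, and convergence at relative parameter change below $10^{-8}$ or 100
iterations.  Starting values come from a log-linear regression of the
positive pairwise bins (slope $r/2$, intercept $\log(qA/2)$) plus a coarse
grid for $q$.  Degenerate inputs (all-zero histograms, empty windows)
return a flagged non-converged result instead of an error.  The min2
curve is excluded from fitting because it depends on $T$ beyond the three
identifiable combinations; for maximum detection its large-$T$ shape
$e^{rt/2}/(1+qg)^5$ is used.

Reported standard errors use a heteroscedasticity-robust (sandwich)
covariance, valid when bin noise is independent (for example Poisson
noise).  For histograms pooled over one batch of trees the bins are
correlated through the trees they share, and the within-fit standard
errors understate the batch-level sampling uncertainty — the parameter
recovery test therefore judges the estimator against the spread across
replicate ensembles.  When uncertainty matters for pooled simulated data,
fit replicate batches.

From a fit, `sigma_upper_bound()` returns $q/r$ (the $\sigma$ bound at
$\mu = 0$, capped at 1) and `implied_sigma()` returns
$(q/r)(1-\mu/\lambda)$ for any assumed extinction-to-speciation ratio.

## What the generator emulates, and what it does not

The synthetic ensembles realize the model assumptions exactly: constant
rates, independent lineages, uniform random sampling of leaves, exact
time distances.  Real phylogenetic data violate several of these —
rate variation over time and across clades, radiation or mass-extinction
episodes, taxonomically biased sampling, and molecular-clock error in the
distance estimates.  Passing the simulation-versus-theory suite therefore
demonstrates the mathematics and the implementation, not that any given
empirical tree is Yule-like; on real data, systematic departures of the
histograms from a fitted exponential (particularly at large $t$) are
themselves the interesting signal, and fit windows exist precisely to
exclude regimes where the model visibly breaks down.

## Problem sizes and defaults

Validation ensembles use $10^4$ trees per configuration for the four
standard panels ($T = 1$, $\lambda = 6$, $\mu \in \{0, 3\}$,
$\sigma \in \{1, 0.1\}$) and $10^5$ trees for the sparse-sampling
protocols ($\lambda = 11$, $\mu = 5$, $\sigma = 0.01$, bin width $0.005$;
narrow-bin occupancy at $t = 1.5$, $dt = 10^{-5}$), sizes at which the
per-bin standard errors are a few percent and every law is exercised well
into its tail.  Histograms default to uniform bins over the full support
$[0, 2T]$, half-open with a closed last bin.  Matrix inputs are validated
for symmetry ($10^{-9}$ relative), zero diagonal and non-negativity, but
ultrametricity is deliberately *not* enforced: empirical matrices are
noisy, and distances are used as given.  When no height is supplied with
a bare matrix, $T = \max(d)/2$ is inferred from the support.  Cherry ties
(exactly equidistant nearest neighbours, common in rounded empirical
matrices) are resolved greedily by ascending distance then lexicographic
label, each leaf used at most once, so results are deterministic.

## Limitations

* Constant-rate, single-regime model only; no time-varying or
  clade-specific rates, no conditioning on survival or on a fixed leaf
  count.
* The fitter estimates the three identifiable combinations, never the
  four raw parameters; all $\sigma$ statements are bounds or
  ratio-conditional values.
* Within-fit standard errors assume independent bin noise (see above).
* The min2 maximum criterion is asymptotic in $T$; for short trees the
  support cutoff can suppress an otherwise-present maximum.
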