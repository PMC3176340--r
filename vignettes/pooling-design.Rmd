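---
title: "Models and methods behind pooldesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pooldesign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pooldesign)
```

## The design problem

Sequencing pooled DNA is a cost-effective way to discover rare variants:
one lane sequences a pool of $k$ individuals instead of one. The design
question is how many individuals to pool, and how many independent lanes to
run, so that a variant of minor allele frequency (MAF) $p$ is detected with
a desired power at coverage depth $C$ — where "detected" means at least $T$
reads carrying the variant at the site.

Two opposing forces create an interior optimum in $k$. A larger pool is
more likely to contain a carrier chromosome at all; but each carrier
chromosome then contributes a smaller fraction of reads, so the threshold
$T$ becomes harder to reach. Neither force alone decides the design — the
calculator quantifies their balance.

## Detection probability under equal contributions

A pool of $k$ diploid individuals contains $2k$ chromosomes. The number of
carrier chromosomes is $N \sim \mathrm{Binomial}(2k, p)$ — each chromosome
carries the variant independently with probability $p$. Given $N = n$ and
equal individual contributions, every read covering the site originates
from a carrier chromosome with probability $n/(2k)$, so the variant read
count is $\mathrm{Binomial}(C, n/(2k))$ and

$$
P(\text{detect} \mid p)
  \;=\; \sum_{n=0}^{2k} \binom{2k}{n} p^n (1-p)^{2k-n}\;
        P\!\left(\mathrm{Binomial}\!\left(C, \tfrac{n}{2k}\right) \ge T\right).
$$

This is `detection_prob_equal()`. Two modelling commitments deserve
spelling out, because the formula alone does not force them: carrier
chromosomes are sampled independently at frequency $p$ (no
population-structure correction), and reads are drawn with replacement
from the chromosome pool. Both are the standard idealisations for design
calculations, and together they reproduce all published reference numbers
we checked the implementation against.

For rare variants the sum is dominated by its $n = 1$ term
(`rare_variant_approx()`). The approximation error scales with the
expected carrier count $2kp$: within the test suite we verify a relative
gap below 10% whenever $2kp \le 0.06$, and the gap grows to tens of
percent once $2kp$ approaches 0.2, so the full mixture is always what the
design functions use.

With $L$ independent lanes (one pool each) the power is
$1 - (1 - P)^L$ (`power_with_lanes()`), and `lanes_for_power()` inverts
this for the smallest sufficient integer $L$. Because the inversion runs
through logarithms, the implementation re-checks the two candidate lane
counts around the analytic ceiling and accepts $L$ when the target is met
within $10^{-12}$, so a table entry can never be off by one through
floating-point rounding alone. Tabulated probabilities are rounded to 4
decimals for display only; lane searches always use full precision. Ties
in the pool-size search break towards the smaller $k$: at equal power the
cheaper design wins. The default search range $k \in [1, 50]$ covers every
optimum arising at the coverages (20–50×) and MAFs (0.005–0.025) the
package tabulates.

## Unequal contributions and the Dirichlet prior

Pool construction and capture are imperfect: individual $i$ contributes a
fraction $w_i$ of the reads, with $\mathbf{w}$ on the $k$-simplex and
assumed constant across genome positions. With genotypes
$g_i \in \{0, 1, 2\}$ (copies of the minor allele), a read carries the
variant with probability

$$
q \;=\; \sum_{i=1}^k w_i\, \frac{g_i}{2},
$$

and detection is again a $\mathrm{Binomial}(C, q)$ tail
(`read_variant_fraction()`, `detection_prob_given_w()`). Genotypes are
modelled as $g_i \sim \mathrm{Binomial}(2, p)$ independently per
individual — equivalent to independent carrier status per chromosome, and
the unique choice that collapses exactly to the equal-contribution formula
at uniform $\mathbf{w}$ (a reduction the tests verify to $10^{-10}$).

For fixed $\mathbf{w}$ the genotype expectation is computed exactly by
enumerating configurations. The enumeration is complete (all carrier
counts up to $2k$) while $3^k \le 2\times 10^4$, i.e. pools of up to nine;
beyond that it is truncated at the smallest carrier count retaining all
but $10^{-8}$ of the carrier-count mass — for the tabulated designs this
keeps at most six carriers and a per-call error below $10^{-8}$. When even
the truncated enumeration exceeds a two-million-configuration budget the
function refuses and points at its Monte-Carlo mode rather than running
for hours.

Uncertainty about $\mathbf{w}$ is expressed through an exchangeable
symmetric Dirichlet prior with concentration $\alpha$: large $\alpha$
pushes contributions towards equality, small $\alpha$ makes them erratic.
`average_detection_prob()` averages the fixed-$\mathbf{w}$ probability
over $n_w$ prior draws. Its inner expectation exploits exchangeability:
grouping genotype configurations into strata of $h$ heterozygotes and $m$
homozygotes, the read fraction $q = U/2 + V$ depends on the draw only
through the aggregate contributions $(U, V)$ of $h + m$ coordinates, so
each stratum can use the draw's leading coordinates. Each draw still
yields a deterministic, exactly genotype-weighted value; only
$\mathbf{w}$ is sampled. This keeps the Monte-Carlo variance in the one
place it cannot be removed and makes a full design-table search a matter
of seconds. The default $n_w = 20{,}000$ keeps the standard error below
about $10^{-3}$ on every tabulated design; the reported `se` makes the
attained precision explicit, and a seed is a required argument — there are
no silently irreproducible numbers in the package.

The pool-size search under the prior (`optimal_pool_size_dirichlet()`)
evaluates every candidate $k$ with the same seed. These common random
numbers stabilise the argmax: comparisons between neighbouring $k$ share
their draws, so the selected optimum does not flicker with independent
noise.

**A flat ridge at high coverage.** At $C = 50$ the average detection
probability is nearly constant across two or three neighbouring pool
sizes (differences of a few $10^{-4}$, smaller than any practical
Monte-Carlo resolution). Published reference optima at such cells are
themselves one-off Monte-Carlo picks — published tables disagree with each
other by one to two individuals there — so the package documents the
behaviour instead of chasing a label: the search returns a deterministic,
seeded argmax, the tests require it to sit within one of the reference
optimum at flat cells while losing no more than 0.003 detection
probability, and at low-to-moderate coverage (where the optimum is sharp)
the reference optima are reproduced exactly.

Degenerate Dirichlet draws with an underflowed zero coordinate (possible
at very small $\alpha$) are clamped to $10^{-12}$ before normalisation so
$q$ stays well defined.

## Estimating the contribution vector and its concentration

With individual genotypes known at a panel of sites and pooled read counts
observed, the expected pooled alternate-allele fraction at a site is
$\sum_i w_i g_{si}/2$. `estimate_w()` fits $\mathbf{w}$ by depth-weighted
least squares on the observed fractions, constrained to the simplex. The
equality-constrained weighted normal equations have a closed-form
solution; nonnegativity is enforced by an active-set loop that pins
violating coordinates to zero and re-solves (at most $k$ rounds). The
estimator is deterministic given data, and unidentifiable inputs — e.g.
two individuals with identical genotypes at every site, whose
contributions only enter through their sum — are rejected with an explicit
error rather than silently resolved. Weighting by site depth $r_s + a_s$
gives each read equal say, which is the right weighting when read counts
are binomial at their site fraction; zero-depth sites carry no
information and are dropped with a warning.

A single estimated $\hat{\mathbf{w}}$ then calibrates $\alpha$ two ways:

* **Pseudo maximum likelihood** (`pmle_alpha()`): maximize the symmetric
  Dirichlet log-density of the one observation. The score equation
  $\psi(k\alpha) - \psi(\alpha) = -\tfrac1k \sum_i \log \hat w_i$ (with
  $\psi$ the digamma function) has a strictly decreasing left side with
  range $(\log k, \infty)$, so a unique root exists exactly when
  $\hat{\mathbf{w}}$ is not uniform; the root is bracketed on
  $[10^{-6}, 10^{6}]$ and polished to $|{\rm score}| < 10^{-10}$. Uniform
  input is a genuine boundary case ($\hat\alpha \to \infty$) and raises a
  dedicated degeneracy error.
* **Pseudo method of moments** (`pmme_alpha()`): match the Dirichlet
  coordinate variance $\tfrac1k(1-\tfrac1k)/(k\alpha+1)$ to the sample
  variance of the $\hat w_i$ with divisor $k - 1$. The divisor matters:
  it is the convention under which the estimator reproduces the published
  reference value from the published vector.

Both accept vectors within $10^{-3}$ of the simplex, because estimated
vectors are routinely reported rounded (the published 8-vector sums to
0.9999), and both use the values as given rather than renormalising.

## Sequencing-error calibration of the threshold

At an error-free site the read counts are
$(\mathrm{correct}, b_1, b_2, b_3) \sim
\mathrm{Multinomial}(C;\, 1-e,\, e/3,\, e/3,\, e/3)$: an erred base is
each wrong base with probability $e/3$. A false variant call occurs when
*any* wrong base reaches $T$, so the relevant statistic is
$M = \max(b_1, b_2, b_3)$, whose three counts are negatively dependent
through the shared total. `misdetection_prob_multinomial()` computes
$P(M \ge T)$ exactly by inclusion–exclusion with nested conditional
binomial sums; the tests confirm it against an independent brute-force
multinomial summation to $10^{-12}$ (absolute). The per-base Poisson model
(`misdetection_prob_poisson()`, tail of $\mathrm{Poisson}(Ce)$) pools the
wrong bases into one count; it is kept as a comparator only — it
overstates the false-call rate of the maximum statistic at every grid
point we test — and is never used for design. The default error rate
$e = 0.01$ reflects the upper end of the 0.5–1% range typical of current
short-read platforms; at $T = 3$ the false-call probability stays below
0.2% for all coverages 20–50×.

Because $M$ is integer-valued, no deterministic threshold achieves a
prescribed false-call rate exactly. `randomized_threshold()` uses the
standard randomized-test construction: with survival $S(t) = P(M \ge t)$,
pick $T$ with $S(T) \le \gamma_0 < S(T-1)$ and call with probability
$\gamma = (\gamma_0 - S(T)) / (S(T-1) - S(T))$ when $M = T - 1$. The
achieved size equals the target identically; the suite checks the
identity to $10^{-12}$ and the empirical rate over simulated error-only
sites to within four standard errors.

## The forward simulator

`simulate_detection()`, `simulate_site_data()` and
`simulate_error_sites()` implement the generative model literally —
contributions, genotypes, then reads — with no shared code path into the
analytic formulas, which is what qualifies them as oracles: agreement
between the two routes (asserted throughout the test suite at four
standard errors) checks the mathematics, not the code against itself.
Every simulator takes a mandatory seed, returns it alongside the result,
and restores the caller's RNG state.

The synthetic site generator draws per-site MAFs uniformly on
$[0.05, 0.5]$ by default: contribution estimation in practice uses
*common* polymorphic sites (rare sites barely separate individuals), and
this default keeps the genotype design well conditioned at a few hundred
sites. What the generator deliberately omits: position-varying
contributions, quality- or strand-dependent error rates, alignment
artefacts, and genotyping error in the individual panel. Passing recovery
tests therefore demonstrate statistical correctness of the estimator
under its stated model, not robustness to those real-data effects.

## Problem sizes used in the tests

The suite runs the full equal-contribution table at $k \le 50$ exactly;
Dirichlet averages at $n_w = 20{,}000$ draws (standard errors below
$10^{-3}$) with pool-size searches over $k \in [2, 12{-}16]$; simulation
oracles at $2{-}4 \times 10^5$ replicates (four-standard-error
agreement bands of a few $10^{-3}$); and estimator-consistency checks at
up to 1,000 sites × depth 400 over 20 seeds. These sizes make every
stochastic assertion decisive at its stated tolerance while keeping the
whole suite around twenty seconds on one core.

## Known limitations

* The detection and false-call analyses are separate, as is conventional
  for threshold-based design: true-variant reads and error reads at the
  same site are not modelled jointly. At $e \le 1\%$ the interaction is
  negligible relative to the design quantities tabulated here.
* Coverage is a fixed design parameter; per-site coverage variation
  (capture bias, mappability) is out of scope.
* Only a symmetric Dirichlet prior is supported, with $\alpha$ estimated
  empirically from one pool; hyperpriors over $\alpha$ and joint
  estimation across pools are not implemented.
* The contribution estimator assumes genotypes in the panel are correct;
  genotyping error propagates directly into $\hat{\mathbf{w}}$.
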