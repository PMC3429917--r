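---
title: "Location-dependent permutation thresholds for QTL genome scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Location-dependent permutation thresholds for QTL genome scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldtqtl)
```

## The problem

A genome scan for quantitative trait loci (QTL) computes a LOD score at
every marker and asks which scores are large enough to call. Because
hundreds of correlated tests are run at once, the conventional remedy is a
permutation threshold: shuffle the phenotypes many times, record the
genome-wide *maximum* LOD of each shuffled scan, and take the upper
$(1-\gamma)$ quantile of those maxima as a constant threshold. This
controls the genome-wide error rate (GWER) — the probability of at least
one false call anywhere — at level $\gamma$.

What the constant threshold does *not* control is where the false calls
land. Write the scan maximum as the pair $M = (\delta, \lambda)$: $\delta$
its magnitude and $\lambda$ the index of the marker attaining it. Whenever
the distribution of $\lambda$ is not uniform — and linkage structure alone
is enough to make it non-uniform — the per-marker (local) false-positive
rate of the constant threshold varies along the genome. Dense marker
clusters split their chances of carrying the maximum across many nearby
markers; isolated markers absorb theirs alone. We call this *location
bias*.

## The location-dependent threshold

Let $n_m$ be the number of markers and $p_i = P\{\lambda = i\}$ the
location distribution of the maximum under permutation. Define the bias
factors
$$\alpha_i = \frac{1}{n_m\,p_i},$$
so $\alpha_i = 1$ means marker $i$ attains the maximum exactly at its
uniform share, $\alpha_i > 1$ that it is under-represented.

The location-dependent threshold (LDT) $T_{\mathrm{LDT}}$ is built from
the *conditional* distributions of $\delta$ given $\lambda = i$: marker
$i$'s threshold is the conditional quantile at exceedance level
$\gamma\,\alpha_i$. Multiplying through by $p_i$ shows what this buys:
$$P\{\delta > T_{\mathrm{LDT},i},\ \lambda = i\}
  = (\gamma \alpha_i)\, p_i = \frac{\gamma}{n_m}
  \quad\text{for every } i,$$
so the joint error mass is the same at every marker (a constant local
rate) and its genome-wide sum is $\gamma$ (GWER control). Where
$\alpha_i > 1$ the threshold is pulled *down* relative to the
constant-local-rate threshold $T_\lambda$ (the plain conditional
$\gamma$-quantile), and pushed up where $\alpha_i < 1$.

The construction exists only while every conditional target
$\gamma\alpha_i$ stays below 1, i.e. for
$$\gamma < \min_i \{1/\alpha_i\} = n_m \min_i p_i .$$
`ldt_threshold()` refuses a $\gamma$ at or above this bound and reports
it; `validity_range()` exposes it. (One could also read the equivalence
of thresholds as extending *above* that range, but the existence
condition is the binding constraint and is what the package enforces.)
Near the bound, location-adjusted P-values are driven almost entirely by
*where* a peak sits rather than how high it is —
`adjust_scan()` therefore also reports each marker's attainable maximum,
$\approx 1/\alpha_i$.

When the conditional distributions are identical and $\lambda$ is uniform
(mutually unlinked, balanced markers), every $\alpha_i = 1$ and the LDT
collapses onto the constant threshold; the package's test suite asserts
this equivalence within Monte-Carlo error, and the calibration
experiments in `scripts/acceptance.R` measure both methods' realised
rates out of sample.

## Estimation and sampling depth

Everything is estimated from one permutation sample: `sample_max_lod()`
shuffles the phenotype vector (uniform random permutation, genotypes
fixed), rescans, and stores each $(\delta, \lambda)$ pair. The raw pair
list is retained — conditional quantiles at arbitrary levels
$\gamma\alpha_i$ need the raw strata, not histograms.

Conditioning is data-hungry: each marker needs its own tail, so the
sampling depth rule is $n_p\,p_i \gtrsim 1000$ draws per marker.
`required_permutations()` implements both forms: with a pilot estimate of
$p$, $\lceil 1000/\min_i p_i\rceil$; without one, the rule of thumb
$5000\,n_m$ for moderate bias (170,000 draws for a 34-marker scan —
orders of magnitude above the ~1000 permutations that suffice for the
constant threshold).

A marker with *zero* recorded maxima is flagged, never smoothed silently:
threshold construction stops with a pointer to the depth rule. An
explicit `smooth = TRUE` (add-one counts) exists for exploration only.

## The LOD statistic

Single-marker regression with Gaussian likelihood:
$$\mathrm{LOD} = \frac{n}{2}\log_{10}\frac{RSS_0}{RSS_1}
             = -\frac{n}{2}\log_{10}(1 - R^2),$$
with $RSS_0$ the residual sum of squares about the grand mean and
$RSS_1$ that of the two-group-mean fit. Only permutation *ranks* of the
scan maxima enter the thresholds, so any monotone variant of the
single-marker statistic would give identical thresholds; the absolute
LOD scale matters only when comparing against scans produced by other
software. `marker_lod()` computes the group-mean form directly; the bulk
permutation kernel uses the algebraically identical correlation form as
one standardized cross-product per chunk of permutations, which is what
makes $10^5$-permutation runs take seconds rather than hours.

## Numerical conventions

* **Quantile convention.** Thresholds are order statistics of the
  sampled values: the smallest sampled $t$ with strict exceedance
  $\#\{v > t\}/n \le$ target. The realised error rate therefore never
  exceeds the nominal one; with ties it can sit below it (conservative).
* **Adjusted P-values** use the $(r+1)/(n_p+1)$ permutation convention
  with $\ge$ for the observed score: valid P-values, never exactly zero.
  The location-adjusted P-value is the linear transform
  $n_m (r_i + 1)/(n_p + 1)$ of the conditional count $r_i$ at the
  marker, capped at 1 for reporting (the uncapped value is exposed).
* **Tie-breaking for $\lambda$.** Exact LOD ties are measure-zero for
  continuous phenotypes but real in code (degenerate permutations).
  The default breaks ties uniformly at random (seeded): a fixed
  "first-marker" rule would itself inject location bias toward low
  indices. `tie_rule = "first"` is available for strict reproducibility
  across tie-handling conventions.
* **Degenerate scores.** Monomorphic marker columns and constant
  phenotypes score LOD 0 rather than erroring, so permuted data sets
  always yield a full scan; near-perfect fits are floored at machine
  precision to keep scores finite.
* **Seeding.** Every stochastic function takes one root seed.
  `sample_max_lod()` processes permutations in fixed-size chunks, each
  chunk drawing from a seed derived as
  $(\mathrm{seed} + 1000003\,k) \bmod (2^{31}-1)$, so results are
  independent of scheduling and a long run can be split across calls
  (`chunk_offset`) and concatenated bit-for-bit.

## What the simulator does and does not emulate

`sim_geno()` generates each chromosome as a two-state Markov chain per
individual: equifrequent genotypes at the chromosome-initial marker, and
a state flip between adjacent markers with probability equal to the
interval's recombination fraction (given directly, or through the
Haldane map function from cM spacing). This is the standard
no-interference model of a backcross or doubled-haploid genome, and both
designs are treated identically — two genotype classes coded 0/1.

It deliberately does **not** emulate: crossover interference, segregation
distortion, genotyping error, missing genotypes (the methodology assumes
complete data and the reader enforces it), multi-allelic or dominant
systems (F2), or non-Gaussian trait distributions. Calibration results
on these simulations therefore show that the estimator does what its
construction promises under its own assumptions; they do not show
robustness to artefacts real data may carry.

Default study conditions used by the calibration experiments (chosen to
match typical linkage-population practice and kept fixed): doubled
haploid, 150 individuals, 20 markers on 2 chromosomes mixing 2 cM
clusters with 25 cM gaps (`example_map_20()`), $\gamma = 0.20$,
$n_p = 5000 \times 20 = 10^5$; exchangeability checks use 10 unlinked
balanced markers and $n_p = 5\times10^4$; the bundled 34-marker
dense/sparse map (`example_map_34()`) mirrors a single-chromosome layout
with pronounced location bias.

## Linkage drives location bias

`recombination_sweep()` runs the diagnostic experiment: 10 equally
spaced markers, 200 backcross individuals, recombination rates
$0.01, 0.04, \ldots, 0.31$, 300 genotype replicates per rate (the test
suite runs 30), each tested for uniformity of the $\lambda$ counts with
a $\chi^2$ goodness-of-fit test on 9 degrees of freedom
(`chisq_uniformity()`, 2000 permutation draws per replicate so expected
counts are 200 per marker). Tight linkage concentrates the maximum and
inflates the statistic far above the $\chi^2_9$ 95th percentile; as
$r$ grows toward independence the medians fall to the null level. The
per-replicate permutation depth and the 30-replicate test scale are the
package's own choices; the 95th-percentile reference is computed from
`qchisq(0.95, df)`, not hard-coded.

## Known limitations

* Marker-based only: no interval mapping or on-grid pseudomarkers,
  though nothing in the construction is specific to markers — any finite
  set of test positions works.
* The validity ceiling $\gamma < n_m \min_i p_i$ can be low in heavily
  biased genomes; for markers that rarely attain the maximum, comparing
  an observed score to the *maximum's* conditional distribution is
  itself debatable (a mixture of order statistics is the natural
  alternative, out of scope here).
* Conditional estimation multiplies the permutation cost by roughly
  $5 n_m$ relative to the constant-threshold workflow.
* P-values below $n_m/(n_p+1)$ are unobtainable by construction;
  plan $n_p$ around the smallest P-value that matters.

## Test and experiment scales

The shipped test suite runs the full calibration at the documented
conditions: $2\times10^5$ permutations for the GWER check,
$5\times10^4$ for the exchangeability check, $11\times30\times2000$
permutation draws for the sweep — about a minute in total on one core,
thanks to the vectorized scan kernel. `scripts/acceptance.R --seed S
--out f.json` reruns all of it from scratch and writes the measured
rates as JSON.
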