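---
title: "Predicting recombination frequency from additive map distance"
author: "recfreq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting recombination frequency from additive map distance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recfreq)
```

## The problem

On a high-density linkage map the distance between adjacent markers is so
short that every mapping function reduces to `r = d`: map distances are
estimated interval by interval and summed. Over intermediate and long
intervals, however, that additive distance no longer has a fixed relation to
recombination frequency. The inverse Haldane and Kosambi functions assume a
particular (or absent) model of crossover interference and systematically
underpredict `r` over such intervals, while the capped linear function
`r = min(d, 1/2)` overpredicts it on chromosomes with more than one
crossover. `recfreq` implements a structural alternative: predict the
probability that *no* crossover falls between the two markers, and convert
that to recombination frequency.

## The model

Two biological assumptions carry the whole method:

1. **No chromatid interference.** Each bivalent crossover involves two of
   the four chromatids, so a random meiotic product carries each crossover
   independently with probability 1/2. Consequently a pair of loci with at
   least one bivalent crossover between them yields recombinant and
   non-recombinant gametes in equal proportion, and

   $$r = \tfrac{1}{2}\,(1 - p_0),$$

   where $p_0$ is the probability of no bivalent crossover between the loci.

2. **Structural crossover interference.** Given $k$ crossovers in the
   bivalent, the chromosome of map length $d$ (Morgans) is divided into $k$
   non-overlapping regions of equal width $d/k$, one crossover per region,
   placed uniformly and independently within its region. Interference is
   thus represented by construction — crossovers cannot crowd into one
   region — rather than through a renewal-process model.

For markers at map positions $m_i \le m_j$, with region indices
$\lceil m\,k/d \rceil$ and region upper boundaries $b = \lceil m\,k/d\rceil
\cdot d/k$, the conditional no-crossover probability is piecewise:

$$
p_0(k) = \begin{cases}
1 & k = 0\\[2pt]
1 - \dfrac{m_j - m_i}{d/k} & \text{same region}\\[6pt]
\left(1 - \dfrac{b_i - m_i}{d/k}\right)\dfrac{b_j - m_j}{d/k} & \text{adjacent regions}\\[6pt]
0 & \text{regions further apart.}
\end{cases}
$$

Because the number of bivalent crossovers varies between meioses, $p_0(k)$
is marginalised over a multinomial distribution $p_k$ of bivalent crossover
counts, $p_0 = \sum_k p_k\, p_0(k)$, and $r = (1-p_0)/2$. The distribution
$p_k$ is the extra biological input this predictor needs and the inverse
mapping functions do not.

### Boundary conventions

Two conventions make the piecewise function total and reproducible:

* A marker exactly on a region boundary belongs to the *lower*-index
  region (the ceiling is left-continuous), and $m = 0$ is assigned region 1.
  A relative tolerance of `1e-9` is applied to $m\,k/d$ before the ceiling
  so a marker analytically on a boundary cannot jump regions through
  floating-point rounding.
* Crossovers are counted between markers over the half-open interval
  $(m_i, m_j]$: a crossover exactly at a marker position separates loci
  above it. The empirical estimator (`empiricalPairR`) uses the same
  convention, so model and estimator agree on degenerate placements.

The adjacent-regions branch is used exactly as written: $(b_j - m_j)/(d/k)$
is the probability that the upper region's crossover falls *above* $m_j$.
The Monte-Carlo oracle in the test suite validates this reading of the
formula against brute-force placement draws.

### The chromosome length `d` is a model parameter

Region widths are $d/k$, so `d` must be the map length of the *whole*
chromosome. When a map is subsampled (`subsampleMarkers`), the result keeps
the full map's `d` even though the retained markers span less; predictions
on a thinned marker set therefore use the same placement model as the full
map. Supplying a span-derived `d` would silently change the model.

## Inferring the bivalent distribution

Observed gametic crossover counts are a binomial thinning of the bivalent
counts: $P(k \mid n) = \binom{n}{k}(1/2)^n$. `emFit` maximises the
resulting mixture likelihood of the gametic count histogram over the
multinomial $p_n$ by expectation-maximization. With maximum observed count
$N$, support $0..2N-1$ suffices and is the default; initialisation is
uniform over the support (avoiding lock-in at the $p_0 = 0$ boundary), the
tolerance is `1e-10` on the log-likelihood increment, and the iteration cap
is 10,000 (hitting it flags `converged = FALSE` rather than failing — near
a simplex boundary EM converges only geometrically while the likelihood is
already flat to machine precision).

### The obligate-crossover test

The obligate crossover (every bivalent gets at least one) is taken as the
null hypothesis. `obligateCrossoverTest` fits the restricted model by
running EM over support $1..2N-1$ — the constrained MLE is *not* a
renormalisation of the unrestricted fit — and then draws parametric
bootstrap histograms of the observed size from that restricted fit,
refitting the unrestricted EM on each. The p-value is the proportion of
bootstrap $\hat p_0^*$ at least as large as the observed $\hat p_0$. Only
when this rejects (p < `alpha`, default 0.05, strict) does
`selectDistribution` keep the unrestricted distribution; otherwise the
restricted one is used. The bootstrap's resampling scheme is this package's
documented design (seeded, 1000 replicates by default), validated by its
type-I-error and power properties in the test suite rather than against an
external reference. An EM estimate $\hat p_0 \le 10^{-8}$ is treated as
exactly zero (the boundary is reached only in the limit) and short-circuits
to p = 1.

All bootstrap refits run through one vectorised EM over the whole replicate
ensemble, which keeps a 1000-replicate test around a second.

## The simulator as oracle

`simulateBivalent` / `sampleGamete` / `simulateGameteSet` generate meioses
under exactly the model above: count drawn from the supplied distribution,
one uniform crossover per equal region, per-crossover inclusion with
probability 1/2. Per-crossover independent thinning is the natural
position-level reading of "no chromatid interference"; at the count level
it is exactly the binomial sampling model. The simulator is both the
synthetic-data generator and the package's brute-force oracle: the analytic
$p_0(k)$ and the marginal predictions are required (in the acceptance
tests) to agree with Monte-Carlo estimates within four binomial standard
errors across random configurations.

What the generator emulates: configurable chromosome map length,
sex-specific multinomial bivalent count distributions, uniform placement
within equal regions, binomial chromatid sampling. What it does *not*
emulate: physical-to-genetic distance heterogeneity along the chromosome,
genotyping error, gene conversion, selection on crossover count, or any
interference structure other than the equal-regions model. Tests passing on
simulated data therefore show the implementation is faithful to the model
and self-consistent — they cannot show the model fits any particular
organism; that assessment needs empirical maps and gamete data supplied in
the TSV formats.

## Evaluation and genetic shuffling

`empiricalPairR` estimates a pair's recombination frequency as the
proportion of meiotic products with an odd crossover count in $(m_i, m_j]$;
it is deliberately not clipped at 0.5. `compareFunctions` subsamples
markers (default fraction 0.015, `ceiling` per chromosome so small
chromosomes keep a marker; default seed 2021), forms all within-chromosome
pairs and reports each predictor's mean absolute error
$\frac{1}{n}\sum|r_e - r_p|$.

The intra-chromosomal component of genetic shuffling is the mean pairwise
recombination frequency, $\bar r = \sum_{i<j} r_{ij} / \binom{\Lambda}{2}$
(`rbarIntra`). For a genome-level figure, per-chromosome values are
aggregated weighted by pair count by default — each marker pair counts once,
which is what the definition suggests when chromosomes differ in marker
number — with an unweighted chromosome mean available via
`aggregate = "chromosomes"` since the choice is genuinely open.

## Units and file formats

Every file value is centimorgans; every in-memory value is Morgans; the
conversion factor is exactly 100. All I/O is tab-separated UTF-8 with one
header row and `#` comment lines (the CLI writes a header recording
version, command line and seed, and no timestamp, so outputs are
byte-reproducible). Physical bp positions are carried as metadata only and
never enter computation; disagreement between bp order and cM order is a
warning, not an error, because empirical maps contain local ordering noise.
Markers with identical map positions are retained (co-segregating markers
are normal in dense maps); such pairs predict r = 0 by construction.

## Problem sizes

The shipped tests exercise the method at the scales it is designed for
while staying quick: 200 random configurations at $10^5$ placement draws
for the conditional-probability oracle, 50 configurations at $10^5$ gametes
for the end-to-end oracle, EM recovery at $5\times 10^4$ simulated gametes
(total-variation distance below 0.02, decreasing over $10^3/10^4/10^5$),
20 seeded replicates of the bootstrap test at 1000 draws for size and
power, and a 50-marker, $10^4$-meiosis study for the predictor comparison.
These sizes were chosen as the smallest at which the statistical assertions
have comfortable margins.

## Known limitations

* The equal-regions model is a deliberate simplification; real interference
  does not impose hard region boundaries, and the model's own authorship of
  the breakpoints is arbitrary. `probAllCrossoversVisible` quantifies how
  much of the bivalent a gamete with a given count can reveal.
* Chromosomes dominated by a single obligate crossover are predicted
  slightly better by the plain linear function (the structural model divides
  by the full map length); the evaluation harness makes this visible rather
  than hiding it.
* Inter-chromosomal shuffling and variance of genetic relatedness are
  downstream of $\bar r$ and out of scope.
* Inference from gametic counts assumes the gametes are an unbiased sample
  of the bivalent (no meiotic drive, no selection on crossover count).
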