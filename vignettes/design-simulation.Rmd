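---
title: "Design-based simulation of household-survey cluster sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design-based simulation of household-survey cluster sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svysim)
```

## The problem

Large national household interview surveys in Japan have traditionally drawn
a *constant* number of census enumeration areas (clusters of roughly 50
households) from every prefecture, enumerating all households in the selected
clusters. Equal allocation equalizes precision across prefectures, but the
sample no longer mirrors the population distribution: prefectures differ in
size by an order of magnitude, so national estimates built from such samples
carry avoidable sampling error. The probabilistic alternative is two-stage
cluster sampling of households with cluster selection probability
proportional to size (PPS).

Because design performance can only be judged against known population
values, `svysim` takes the simulation route: build a fully known synthetic
finite population, draw thousands of samples under each design, estimate a
continuous mean and a dichotomized proportion from every sample with proper
design weights, and compare designs by root mean squared error (RMSE) against
the census truth.

## The population model

The population is hierarchical: strata $h = 1,\dots,H$ (prefecture-scale,
default $H = 10$) contain clusters $i$, clusters contain households $j$,
households contain individuals $k$. Sizes are drawn as

* clusters per stratum $N_h \sim$ discrete uniform on $\{4000,\dots,40000\}$
  (the range of census enumeration-area counts per prefecture), or anchored
  to an explicit list;
* households per cluster $N_{hi} \sim N(50, 1)$, rounded to the nearest
  integer and floored at 1 — consistent with enumeration areas of about 50
  households;
* members per household $N_{hij} \sim$ discrete uniform on $\{1,\dots,6\}$.

The continuous outcome $X$ (modelled on systolic blood pressure in mmHg)
follows a four-level Gaussian hierarchy:

$$
X_{hijk} \sim N(\mu_{hij}, \sigma_{hij}^2), \qquad
\mu_{hij} \sim N(\mu_{hi}, \sigma_{hi}^2), \qquad
\mu_{hi} \sim N(\mu_h, \sigma_h^2), \qquad
\mu_h \sim N(130, 2.5^2),
$$

with scale parameters drawn once per unit from Gaussian hyperpriors
$\sigma_h \sim N(5, 0.1^2)$, $\sigma_{hi} \sim N(7, 0.2^2)$,
$\sigma_{hij} \sim N(10, 0.2^2)$. By the law of total variance the marginal
variance of $X$ is approximately $2.5^2 + 5^2 + 7^2 + 10^2 = 180.25$, i.e.
SD $\approx 13.4$. A binary indicator marks $X \ge 140$ (the conventional
hypertension threshold); its marginal prevalence is about 22%.

In **anchored mode** (`reference_config()`), the per-stratum cluster counts
and stratum means $\mu_h$ are fixed to the reference layout in
`reference_strata()` instead of being redrawn. Anchoring is what makes
replicated-design comparisons reproducible at the benchmark scale: the
stratum share of households — and therefore every design weight — is pinned
down, while household counts, household sizes and individual outcomes remain
random. Anchored totals (about 9.79M households, 34.3M individuals) therefore
vary slightly from run to run.

### Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| `cluster_count_range` | clusters | 4000–40000 | prefecture-scale frame sizes |
| `households_per_cluster` | households | mean 50, SD 1 | enumeration-area size |
| `members_range` | persons | 1–6 | household size support |
| `mu_h_prior` | mmHg | mean 130, SD 2.5 | between-stratum location spread |
| `sigma_h_prior` | mmHg | mean 5, SD 0.1 | between-cluster spread |
| `sigma_hi_prior` | mmHg | mean 7, SD 0.2 | between-household spread |
| `sigma_hij_prior` | mmHg | mean 10, SD 0.2 | within-household spread |
| `threshold` | mmHg | 140 | dichotomization cutoff |

The variance budget matters more than any single value: the between-cluster
component ($\sigma_h^2 \approx 25$) is what cluster sampling cannot average
away within a stratum, so it drives the RMSE differences between designs.

## The two designs

**Method 1 (conventional).** Within each stratum, `clusters_per_stratum`
(default 100) clusters are drawn by systematic random sampling without
replacement from the cluster list, and *all* households of selected clusters
are enumerated. The individual weight is constant within stratum: stratum
population individuals divided by realized sampled individuals. By
construction the weights sum exactly to the stratum population — an identity
the tests assert on every draw.

**Method 2 (two-stage PPS).** The cluster frame is sorted by (stratum,
cluster) and `n_clusters` clusters are selected across all strata jointly by
fixed-take systematic PPS with the household count as the size measure;
sorting provides implicit stratification, so each stratum receives its
proportional share of clusters to within one cluster on every draw. Within
each selected cluster, $m = \lceil f N_{hi} \rceil$ households are drawn by
simple random sampling without replacement. The household weight is
$1 / (\pi_i \cdot m / N_{hi})$ with $\pi_i = n\,N_{hi} / \sum N_{hi}$; all
members of a sampled household are interviewed and inherit its weight.

The benchmark grid pairs the cluster count with a compensating household
fraction — (1000, 1), (2000, 1/2), (3000, 1/3), (4000, 1/4), (5000, 1/5) —
so the expected household sample size stays near 50,000 across scenarios
while the first-stage sample spreads over more clusters.

## Estimation and the accuracy metric

Means and proportions are estimated in the Hájek (weighted-ratio) form
$\sum w_i x_i / \sum w_i$, matching what survey software computes for complex
designs. Stratum results under Method 2 are *domain* estimates — strata are
not sampling strata of that design — and a stratum missed entirely by a draw
yields `NA`, which the simulation layer counts (this cannot happen at
benchmark scale, where the smallest stratum's expected allocation exceeds 20
clusters).

Accuracy over $R$ replicates is summarized as
$\mathrm{RMSE} = \sqrt{\tfrac1R \sum_r (\hat\theta_r - \theta)^2}$, the root
of variance plus squared bias (population-style divisor $R$, so the
decomposition $\mathrm{RMSE}^2 = \mathrm{SD}^2 (R-1)/R + \mathrm{bias}^2$
holds exactly; the tests assert it cell by cell). Both designs are
design-unbiased for both estimands, so the RMSE is essentially the sampling
SD — a property the suite checks with a $4\,\mathrm{SE}$ Monte Carlo gate on
every total-population cell. The Monte Carlo coefficient of variation of an
RMSE estimate is about $1/\sqrt{2R}$: roughly 4% at $R = 300$ and 2% at
$R = 1000$.

## Numerical and design choices

* **Systematic interval rule.** The default fractional-interval rule (real
  interval $k = N/n$, start uniform on $(0, k]$, positions
  $\lceil u + jk \rceil$) always returns exactly $n$ clusters and gives every
  cluster inclusion probability $n/N$. Integer-interval variants (`"ceil"`,
  `"floor"`) are provided because some production systems use them; their
  realized sample size deviates from the target (e.g. a 4161-cluster stratum
  sampled with interval 42 averages 99.07 clusters), which is visible in
  average-sample-size tables.
* **Second-stage rounding.** The household take is $\lceil f N_{hi} \rceil$
  computed in exact integer arithmetic (never floating point, so a third of
  51 is exactly 17). The ceiling was chosen over nearest-rounding because it
  keeps expected household sample sizes slightly above the nominal fraction,
  consistent with fixed-take field practice; nearest-rounding is available.
* **Weights use the realized fraction** $m/N_{hi}$, not the nominal $f$, so
  the weighted household total is exactly design-unbiased under the rounding
  rule — verified by a Horvitz–Thompson unbiasedness test.
* **Certainty clusters** ($\pi_i \ge 1$, impossible under the benchmark grid
  where $\max \pi \approx 5000 \times 55 / 9.8\mathrm{M} \ll 1$) are rejected
  with an instructive error rather than silently taken with probability one;
  take-all handling is out of scope.
* **Scale-parameter draws**: strictly negative $\sigma$ draws (probability
  $< 10^{-100}$ under the default hyperpriors, but reachable under user
  configurations) are clamped to $10^{-6}$; exact zeros are preserved so
  zero-variance configurations generate exactly constant outcomes.
* **Seed discipline.** All randomness flows through named L'Ecuyer-CMRG
  streams derived from a root seed: one stream for the population, one per
  (design, replicate). Replicates are therefore independent, reproducible,
  and invariant to execution order; reruns are byte-identical.
* **Storage.** The population is stored as cluster- and household-level
  aggregates (counts, sums of $X$, $X^2$ and the indicator), so a replicate
  touches only the aggregates of its selected units; individual records are
  optional and only needed for truth spot-checks. This is what makes 1000
  replicates over a 34M-person population take minutes rather than hours.

## What the generator emulates — and what it does not

The generator reproduces the structural features that drive design
performance: realistic stratum-size imbalance, ~50-household clusters,
within-cluster homogeneity ($\sigma_h$ between clusters vs
$\sigma_{hi}, \sigma_{hij}$ within), and a skewless continuous outcome with a
meaningful tail indicator. It deliberately omits nonresponse and noncoverage,
measurement error, spatial correlation between neighbouring clusters,
realistic household-size demography, and non-Gaussian or categorical
outcomes. Passing benchmarks therefore demonstrate correct *design-based*
behaviour of the samplers, weights and estimators under a known truth — not
that either design is optimal for any particular real survey variable.

## Problem sizes used by the tests

Unit and property tests run on miniature populations (`make_fixture()`:
3–38 clusters) where every estimate can be verified by brute force, plus
moderate random populations (a few hundred clusters) for expectation checks.
The benchmark tests generate the full anchored population once and use
$R = 400$ replicates per design — enough to pin RMSE to a few percent (CV
$\approx 1/\sqrt{800} \approx 3.5\%$) while keeping the whole suite inside a
few minutes. The analysis scripts default to $R = 1000$. The closed-form
variance oracle uses a 401-cluster equal-size fixture, where the
one-stage cluster-sampling variance $(1 - n/N)\,S_b^2/n$ applies and the
fractional systematic interval makes essentially every start distinct, so the
systematic design's variance is close to the formula (the fixture is frozen;
the simulated-to-analytic ratio is about 0.93 and the test allows 10%).

## Known limitations

* Stratum-level results under Method 2 in very small strata rest on few
  clusters (about 21 for the smallest benchmark stratum at $n = 1000$), so
  their RMSE estimates carry larger Monte Carlo error than the totals.
* Per-sample variance estimation (linearization or replication weights) is
  out of scope: the simulation measures accuracy against the known truth, so
  it needs no estimated standard errors.
* Ratio estimation with auxiliary variables, post-stratification and
  nonresponse weighting are not modelled; they belong to follow-up work on
  survey redesign rather than to this design comparison.
* The anchored totals are themselves realizations: cluster counts and
  stratum means are fixed, but household and individual totals vary by
  roughly $\pm 0.05\%$ across seeds, and all benchmark tolerances account
  for that.
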