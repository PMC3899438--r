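# svysim — design-based simulation of household-survey cluster sampling

`svysim` is for survey statisticians and epidemiologists who need to compare
sample designs for national household health surveys *before* fielding them.
Japan's large household interview surveys have traditionally allocated a
constant number of census enumeration areas (clusters of ~50 households) to
every prefecture and enumerated all households in the selected clusters.
Equal allocation equalizes precision across prefectures, but the national
sample no longer mirrors the population distribution. The probabilistic
alternative is two-stage cluster sampling: select clusters with probability
proportional to their household counts (PPS), then subsample households.

Since real population parameters are unknown, the package takes the
simulation route: it builds a fully specified synthetic finite population,
draws replicated samples under both designs, computes design-weighted
estimates, and measures accuracy against the census truth.

## The model and the designs

The population is a four-level hierarchy — strata *h* ⊃ clusters *i* ⊃
households *j* ⊃ individuals *k* — with a Gaussian outcome *X* (modelled on
systolic blood pressure, mmHg):

    X_hijk ~ N(mu_hij, sigma_hij^2)     sigma_hij ~ N(10, 0.2^2)
    mu_hij ~ N(mu_hi, sigma_hi^2)       sigma_hi  ~ N(7, 0.2^2)
    mu_hi  ~ N(mu_h, sigma_h^2)         sigma_h   ~ N(5, 0.1^2)
    mu_h   ~ N(130, 2.5^2)

with N_h clusters per stratum (uniform on 4000–40000, or anchored),
N_hi ~ N(50, 1) households per cluster (rounded, floored at 1), and 1–6
members per household. A binary indicator flags X ≥ 140. By the law of total
variance, SD(X) ≈ √(2.5² + 5² + 7² + 10²) ≈ 13.4 and P(X ≥ 140) ≈ 22%.

Two designs are compared by the root mean squared error of the estimated
mean of X and proportion X ≥ 140, per stratum and in total, over replicated
draws (`RMSE = sqrt(variance + bias²)`):

* **M1 (conventional):** systematic sampling of a constant number of
  clusters (default 100) within each stratum; all households included;
  stratum-constant weights `N_h individuals / sampled individuals`.
* **M2 (two-stage PPS):** fixed-take systematic PPS over the cluster frame
  sorted by (stratum, cluster) with household counts as size measure, then
  SRSWOR of a fraction *f* of households per selected cluster; household
  weights `1 / (pi_cluster × m/N_hi)`. The study grid pairs n = 1000…5000
  clusters with f = 1, 1/2, 1/3, 1/4, 1/5.

Estimates use the Hájek (weighted-ratio) form, as survey software does.

## Worked example

```r
library(svysim)

cfg <- population_config(n_strata = 2, cluster_count_range = c(200, 400),
                         households_per_cluster = c(20, 1), seed = 42)
pop <- generate_population(cfg)
summarize_population(pop)
#>   stratum n_clusters n_households n_individuals mean_x  sd_x prop_ge_threshold
#> 1       1        329         6558         22710  130.2 13.11            0.2283
#> 2       2        203         4097         14065  132.0 13.26            0.2732
#> 3   total       532        10655         36775  130.9 13.19            0.2455

cmp <- compare_designs(pop, list(design_m1(25), design_m2(50, "1/2")),
                       R = 500, seed = 7)
cmp
#> Design comparison: 2 scenarios, R = 500
#> Total-population RMSE, mean of X:
#>     M1  M2-50
#> 0.6854 0.5598
```

The truth table is the census benchmark: this two-stratum toy population has
36,775 individuals with mean X 130.9 and 24.6% at or above 140. Over 500
replicated draws, sampling 50 clusters PPS with half the households (M2)
estimates the national mean with RMSE 0.56 mmHg versus 0.69 for the
conventional 25-clusters-per-stratum design (M1) — an 18% reduction at a
comparable household sample size (`cmp$pct_change_total` holds the exact
percentages).

## The benchmark analysis

The full study lives in `analysis/` as numbered drivers over the package:

1. `analysis/01_generate_population.R` — generates the anchored benchmark
   population (10 strata, ~196K clusters, ~9.79M households, ~34.3M
   individuals; cluster counts and stratum means fixed to
   `reference_strata()`) and writes `results/table1_population.csv`.
2. `analysis/02_run_simulations.R` — runs all six designs × 1000 replicates
   (`--replicates` to override) and writes `results/table2_sample_sizes.csv`,
   `results/table3_rmse.csv`, `results/run_summary.json`.
3. `analysis/03_report.R` — writes `results/headline_comparison.csv` with
   percent RMSE changes of each PPS scenario relative to the conventional
   design.

At seed 1 and R = 1000 the total-population RMSEs of the estimated mean are
0.183 (M1) and 0.165, 0.113, 0.105, 0.089, 0.077 for M2 with 1000–5000
clusters: the PPS design improves national accuracy immediately and keeps
improving as clusters increase and the household fraction falls, stabilizing
near two-fifths of the conventional design's error.

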