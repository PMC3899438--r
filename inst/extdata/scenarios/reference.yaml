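# Benchmark scenario: anchored 10-stratum population (~34M individuals) and
# the six designs under study. Stratum cluster counts and stratum means of X
# are fixed to the reference layout; everything else is drawn from the stated
# hyperpriors. Individual records and household latents are not retained at
# this scale (estimation uses cluster/household aggregates).
population:
  anchored: true
  keep_individuals: false
  keep_latent: false
designs:
  - {name: M1,      method: M1, clusters_per_stratum: 100}
  - {name: M2-1000, method: M2, n_clusters: 1000, household_fraction: "1/1"}
  - {name: M2-2000, method: M2, n_clusters: 2000, household_fraction: "1/2"}
  - {name: M2-3000, method: M2, n_clusters: 3000, household_fraction: "1/3"}
  - {name: M2-4000, method: M2, n_clusters: 4000, household_fraction: "1/4"}
  - {name: M2-5000, method: M2, n_clusters: 5000, household_fraction: "1/5"}
replications: 1000
seed: 1
output_dir: results
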