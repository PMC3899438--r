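# Miniature smoke-test scenario: 2 strata of 8-12 small clusters; completes
# in well under a second. Useful for exercising the pipeline end to end.
population:
  n_strata: 2
  cluster_count_range: [8, 12]
  households_per_cluster: {mean: 5, sd: 1}
  members_range: [1, 4]
designs:
  - {name: M1,   method: M1, clusters_per_stratum: 3}
  - {name: M2-6, method: M2, n_clusters: 6, household_fraction: "1/2"}
replications: 25
seed: 7
output_dir: results/tiny
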