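# Example pipeline configuration for the packaged North Yellow Sea summaries.
# `samples` should point to a per-individual sample table; generate one with
# nys_synthetic_individuals() and write_samples(), or supply survey data.
samples: samples.csv
consumer_group: Sea Anemones
source_groups:
  - Small-Sized Fishes
  - Shrimps
  - Zooplankton
  - POM
  - SOM
baseline:
  base1: Zooplankton
  base2: Gastropods and Bivalves
  baseline_TL: 2
  delta15N_per_level: 3.4
tef:
  mean_d13C: 1.0
  sd_d13C: 0.2
  mean_d15N: 3.4
  sd_d15N: 0.2
stages: [tp, niche, mixspace, mix]
settings:
  niche:
    alpha: 0.95
    draws: 1000
    n_mc: 10000
  mixspace:
    iters: 1500
    grid: 300
    window: 100
  mix:
    chains: 4
    iters: 10000
    burn: 1000
seed: 1
out_dir: results
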