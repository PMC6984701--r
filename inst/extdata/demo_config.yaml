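# Demo run: desk-scale BC2F6 introgression study.
seed: 20
out_dir: intrograph_demo
genome:
  scale_factor: 0.003
  sites_per_chromosome: 120
founders:
  recurrent: Haruyokoi
  donor_ab: Ldn
  donor_d: AT47
plan:
  n_backcrosses: 2
  n_selfings: 5
  population_size: 10
  n_selected: 2
heading:
  baseline_days: 195
  noise_sd: 1
  qtl:
    - chrom: 5D
      pos_frac: 0.5
      effect_days: -1.75
observation:
  mean_depth: 20
  error_rate: 0.005
rule:
  min_depth: 10
  min_fraction: 0.8
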