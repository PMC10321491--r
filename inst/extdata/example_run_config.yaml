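# Example run configuration for the wormbench drivers.
# Load with read_run_config(); unspecified fields keep package defaults.
seed: 1
outdir: results
rates:                     # virtual-bench action success rates
  pick_up_success: 0.90
  put_down_success: 0.90
  post_pick_survival: 0.97
  escape_prob: 0.01
  phenotype_error: 0.0
  contamination_prob_per_plate: 0.0    # 0.034 reproduces a manual bench
control:                   # transmission-engine options
  spontaneous_male_rate: 0.002
  emit_unbalanced: false
  recombination: 0         # breakthrough recombination per meiosis
  brood_size: 100
params:
  protocol: map
  n_scored: 200
registry:                  # optional extensions of the default registry
  loci:
    - id: exampleIs
      chromosome: II
  alleles:
    - symbol: exampleIs1
      locus: exampleIs
      dominance: dominant
      tags: [Red]
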