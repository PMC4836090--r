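# Example configuration for the pathgwas command-line wrapper:
#   pathgwas pipeline --config example_study.yaml --out out/ --seed 7
n_subjects_discovery: 109
n_subjects_replication: 1677
n_snps: 2000
n_chromosomes: 5
ld_block_size: 10
ld_rho: 0.85
missing_rate: 0.01
n_genes: 100
dropout_rate: 0.1
spike:
  enabled: true
  n_causal_per_gene: 5
  or_response: 2.0
phenotypes: [response]
thresholds: [0.05, 0.01]
n_perm: 10000
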