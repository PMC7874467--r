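# Demo configuration for the end-to-end pipeline (see ?simConfig for keys).
seed: 1
n_l1_loci: 12
l1_length: 3600
divergence_rate: 0.02
class_proportions:
  FULLY_INTACT: 0.4
  ORF1_INTACT_ORF2_TRUNC: 0.3
  ORF1_TRUNC: 0.3
host_categories:
  mRNA: 40
  histone: 8
  MT: 4
  rRNA: 2
  lncRNA: 10
  circRNA_host: 4
read_length: 100
fragment_mean: 250
fragment_sd: 40
n_reads_input: 50000
n_reads_ip: 50000
error_rate: 0.002
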