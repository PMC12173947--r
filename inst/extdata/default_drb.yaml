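# Default DRB/TT-seq time-course simulation: undamaged kinetics with a
# true elongation rate of 2 kb/min, release time points 5-40 min, and a
# cohort of 55 genes longer than 60 kb (lengths 85-118 kb so the 40-min
# wave front at 80 kb stays inside every gene body).
drb:
  times: [5, 10, 20, 30, 40]
  rate: 2
  plateau_amp: 2
  crest_amp: 4
  crest_sigma: 1500
  bin_size: 100
  upstream: 2000
  downstream: 120000
  n_genes: 55
  gene_length: [85000, 118000]
  background: 0.1
noise:
  enabled: true
  depth: 10
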