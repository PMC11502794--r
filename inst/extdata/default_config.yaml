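# Default analysis configuration: desk-scale synthetic study of two
# hES-NSC-derived lines (glial, neural) x three conditions (undiff, DM,
# Mac-CM) x two replicates. Thresholds follow the study's significance
# rules: padj < 0.05 with >= 10% methylation change (DML) or >= 2-fold
# change (DHML / DEG).
alpha: 0.05
min_delta: 0.10
lfc_threshold: 1
min_coverage: 5
flank: 2000
sim:
  n_genes: 300
  tf_fraction: 0.3
  chrom_lengths:
    chr1: 4000000
    chr2: 3000000
  gene_length: 5000
  cpgs_per_gene: 10
  ccgg_per_gene: 5
  mean_coverage: 30
  nb_dispersion: 0.1
  bb_dispersion: 0.005
  baseline_mu: 0.35
  planted_delta: 0.30
  planted_lfc: 2
  frac_true: 0.1
  frac_switch: 0.05
  rna_mean: 100
  rna_meanlog_sd: 1
  tag_meanlog_sd: 0.5
  seed: 1
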