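#!/usr/bin/env Rscript
# Step 1 — simulate the synthetic multi-omic study.
#
# Generates the full study emulated throughout this project: RRBS CpG
# methylation counts, RRHP strand-specific CCGG tag counts and RNA-seq gene
# counts for 2 cell lines x 3 conditions x 2 replicates, with planted
# differential effects (including reciprocal 5mC/5hmC switch genes) and a
# machine-readable truth record. All downstream steps read the plain-text
# tables written here.

library(epipattern)

cfg_path <- system.file("extdata", "default_config.yaml",
                        package = "epipattern")
cfg <- pipeline_config_from_yaml(cfg_path)
out <- file.path("results", "data")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

study <- simulate_study(cfg$sim)

write_design(study$design, file.path(out, "design.tsv"))
write_meth_table(study$rrbs, file.path(out, "rrbs_counts.tsv"))
write_count_table(study$rrhp, file.path(out, "rrhp_counts.tsv"))
write_count_table(study$rnaseq, file.path(out, "rna_counts.tsv"))
write_annotation_bed(study$annotation, file.path(out, "annotation.bed"))
write_truth_json(study$truth, file.path(out, "truth.json"),
                 size_factors = study$rna_size_factors)

n_sw <- length(unique(study$truth$gene_id[study$truth$switch_class != "none"]))
message(sprintf(
  "Simulated %d genes (%d TFs) on %d chromosomes: %d CpGs, %d CCGG strand tags, %d samples.",
  nrow(study$annotation), sum(study$annotation$is_tf),
  length(cfg$sim$chrom_lengths), nrow(study$rrbs), nrow(study$rrhp),
  nrow(study$design)))
message(sprintf(
  "Planted truth: %d 5mC, %d 5hmC and %d RNA effects; %d reciprocal-switch genes.",
  sum(study$truth$modality == "5mC"), sum(study$truth$modality == "5hmC"),
  sum(study$truth$modality == "RNA"), n_sw))
message("Tables written under ", out)
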