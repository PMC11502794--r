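#!/usr/bin/env Rscript
# Step 3 — annotate significant loci to genes and restrict to TFs.
#
# Each significant DML/DHML is extended by +/- 2 kb, overlapping extensions
# are merged, and merged regions are assigned to every gene body they
# overlap (0-based half-open coordinates throughout). Per gene the
# direction (gain/loss) is the majority sign of the contributing locus
# effects; DEGs are gene-level already and bypass extension.

library(epipattern)

cfg <- pipeline_config_from_yaml(
  system.file("extdata", "default_config.yaml", package = "epipattern"))
dat <- file.path("results", "data")
dif <- file.path("results", "differential")
out <- file.path("results", "annotation")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

annotation <- read_annotation_bed(file.path(dat, "annotation.bed"))

all_hits <- list()
for (cond in c("undiff", "DM", "MacCM")) {
  dml <- utils::read.delim(file.path(dif, paste0("dml_", cond, ".tsv")))
  dhml <- utils::read.delim(file.path(dif, paste0("dhml_", cond, ".tsv")))
  deg <- utils::read.delim(file.path(dif, paste0("deg_", cond, ".tsv")))
  sig_dml <- dml[dml$significant, ]; sig_dml$effect <- sig_dml$delta
  sig_dhml <- dhml[dhml$significant, ]; sig_dhml$effect <- sig_dhml$log2fc
  hits <- rbind(
    gene_hits_from_loci(sig_dml, annotation, "5mC", cond,
                        flank = cfg$flank,
                        chrom_lengths = cfg$sim$chrom_lengths),
    gene_hits_from_loci(sig_dhml, annotation, "5hmC", cond,
                        flank = cfg$flank,
                        chrom_lengths = cfg$sim$chrom_lengths),
    gene_hits_from_deg(deg, cond)
  )
  all_hits[[cond]] <- hits
  tf <- filter_tfs(hits, annotation)
  utils::write.table(hits, file.path(out, paste0("gene_hits_", cond, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(tf, file.path(out, paste0("tf_hits_", cond, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  # merged DML regions as BED for genome-browser inspection
  if (nrow(sig_dml) > 0) {
    reg <- extend_and_merge(sig_dml, flank = cfg$flank,
                            chrom_lengths = cfg$sim$chrom_lengths)
    utils::write.table(reg[, c("chrom", "start", "end", "region_id")],
                       file.path(out, paste0("dml_regions_", cond, ".bed")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  message(sprintf(
    "%-7s: %d genes hit (%d TFs) — 5mC %d, 5hmC %d, RNA %d",
    cond, length(unique(hits$gene_id)), length(unique(tf$gene_id)),
    length(unique(hits$gene_id[hits$modality == "5mC"])),
    length(unique(hits$gene_id[hits$modality == "5hmC"])),
    length(unique(hits$gene_id[hits$modality == "RNA"]))))
}
message("Gene and TF hit tables written under ", out)
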