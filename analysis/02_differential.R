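#!/usr/bin/env Rscript
# Step 2 — differential calling, glial vs neural within each condition.
#
# DML: beta-binomial dispersion-shrinkage Wald test on RRBS counts
#   (significant when padj < 0.05 and |delta methylation| >= 0.10).
# DHML: NB Wald test on RRHP tag counts, each CCGG strand its own feature
#   (padj < 0.05 and >= 2-fold).
# DEG: the same NB machinery on RNA gene counts (padj < 0.05 and >= 2-fold).

library(epipattern)

cfg <- pipeline_config_from_yaml(
  system.file("extdata", "default_config.yaml", package = "epipattern"))
dat <- file.path("results", "data")
out <- file.path("results", "differential")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

design <- read_design(file.path(dat, "design.tsv"))
rrbs <- read_meth_table(file.path(dat, "rrbs_counts.tsv"))
rrhp <- read_count_table(file.path(dat, "rrhp_counts.tsv"))
rna <- read_count_table(file.path(dat, "rna_counts.tsv"))
rna_counts <- as.matrix(rna[, design$sample_id])
rownames(rna_counts) <- rna$gene_id

labels_for <- function(cond) {
  sel <- design$condition == cond
  setNames(factor(design$line[sel], levels = c("glial", "neural")),
           design$sample_id[sel])
}

for (cond in c("undiff", "DM", "MacCM")) {
  gl <- labels_for(cond)
  dml <- dml_test(rrbs, gl, alpha = cfg$alpha, min_delta = cfg$min_delta,
                  min_coverage = cfg$min_coverage)
  dhml <- call_dhml(rrhp, gl, alpha = cfg$alpha,
                    lfc_threshold = cfg$lfc_threshold)
  deg <- nb_wald_test(rna_counts, gl, alpha = cfg$alpha,
                      lfc_threshold = cfg$lfc_threshold)
  utils::write.table(dml, file.path(out, paste0("dml_", cond, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dhml, file.path(out, paste0("dhml_", cond, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(deg, file.path(out, paste0("deg_", cond, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sig <- deg[deg$significant, ]
  message(sprintf(
    "%-7s: %d DMLs of %d CpGs | %d DHMLs of %d tags | %d DEGs of %d genes (%d up, %d down in neural)",
    cond, sum(dml$significant), nrow(dml), sum(dhml$significant),
    nrow(dhml), nrow(sig), nrow(deg),
    sum(sig$log2fc > 0), sum(sig$log2fc < 0)))
}
message("Differential tables written under ", out)
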