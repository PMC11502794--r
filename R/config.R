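#' Simulation configuration
#'
#' Parameters of the synthetic multi-omic generator. Defaults describe the
#' desk-scale study emulated throughout this package: two hES-NSC-like cell
#' lines (glial, neural) profiled by RRBS (per-CpG methylated/total read
#' counts), RRHP (strand-specific CCGG tag counts) and RNA-seq (gene counts)
#' under three conditions (undifferentiated, normal differentiation medium DM,
#' macrophage-conditioned medium Mac-CM), two biological replicates each.
#'
#' @param n_genes number of genes placed on the synthetic genome.
#' @param tf_fraction fraction of genes flagged as transcription factors,
#'   in (0,1). `round(tf_fraction * n_genes)` genes are flagged.
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param gene_length length of each gene interval (bp).
#' @param cpgs_per_gene CpG loci generated per gene.
#' @param ccgg_per_gene CCGG (MspI) sites generated per gene; each site is
#'   profiled on both strands, as in RRHP.
#' @param mean_coverage expected RRBS total reads per CpG per sample; also the
#'   median scale of RRHP tag counts.
#' @param nb_dispersion negative-binomial dispersion of all count draws
#'   (variance mu + dispersion * mu^2).
#' @param bb_dispersion beta-binomial dispersion phi in (0,1) of methylated
#'   read counts given totals.
#' @param baseline_mu baseline methylation proportion of null CpGs.
#' @param planted_delta methylation shift (proportion) planted at true DMLs.
#' @param planted_lfc log2 fold change planted at true DHMLs and DEGs.
#' @param frac_true fraction of features per modality planted differential.
#' @param frac_switch fraction of genes planted as reciprocal 5mC/5hmC
#'   switch genes (opposite-direction effects under DM vs Mac-CM).
#' @param rna_mean median expected RNA count per gene per sample.
#' @param rna_meanlog_sd sd (log scale) of per-gene RNA baseline means.
#' @param tag_meanlog_sd sd (log scale) of per-site RRHP baseline means.
#' @param seed integer seed; all generator randomness derives from it.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 300,
                       tf_fraction = 0.3,
                       chrom_lengths = c(chr1 = 4e6, chr2 = 3e6),
                       gene_length = 5000,
                       cpgs_per_gene = 10,
                       ccgg_per_gene = 5,
                       mean_coverage = 30,
                       nb_dispersion = 0.1,
                       bb_dispersion = 0.005,
                       baseline_mu = 0.35,
                       planted_delta = 0.30,
                       planted_lfc = 2,
                       frac_true = 0.1,
                       frac_switch = 0.05,
                       rna_mean = 100,
                       rna_meanlog_sd = 1,
                       tag_meanlog_sd = 0.5,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), tf_fraction = tf_fraction,
    chrom_lengths = chrom_lengths, gene_length = as.integer(gene_length),
    cpgs_per_gene = as.integer(cpgs_per_gene),
    ccgg_per_gene = as.integer(ccgg_per_gene),
    mean_coverage = mean_coverage, nb_dispersion = nb_dispersion,
    bb_dispersion = bb_dispersion, baseline_mu = baseline_mu,
    planted_delta = planted_delta, planted_lfc = planted_lfc,
    frac_true = frac_true, frac_switch = frac_switch,
    rna_mean = rna_mean, rna_meanlog_sd = rna_meanlog_sd,
    tag_meanlog_sd = tag_meanlog_sd, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  counts <- c(cfg$n_genes, cfg$gene_length, cfg$cpgs_per_gene,
              cfg$ccgg_per_gene)
  if (any(counts <= 0)) stop("all counts in sim_config must be > 0")
  if (cfg$tf_fraction <= 0 || cfg$tf_fraction >= 1)
    stop("tf_fraction must be in (0, 1)")
  if (is.null(names(cfg$chrom_lengths)) || any(cfg$chrom_lengths <= 0))
    stop("chrom_lengths must be a named vector of positive lengths")
  if (cfg$mean_coverage <= 0) stop("mean_coverage must be positive")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (cfg$bb_dispersion <= 0 || cfg$bb_dispersion >= 1)
    stop("bb_dispersion must be in (0, 1)")
  if (cfg$frac_true < 0 || cfg$frac_true > 1)
    stop("frac_true must be in [0, 1]")
  if (cfg$frac_switch < 0 || cfg$frac_switch > 1)
    stop("frac_switch must be in [0, 1]")
  lo <- cfg$baseline_mu - abs(cfg$planted_delta)
  hi <- cfg$baseline_mu + abs(cfg$planted_delta)
  if (lo < 0.02 || hi > 0.98)
    stop("baseline_mu +/- planted_delta must stay within [0.02, 0.98]")
  invisible(cfg)
}

#' Study sample design
#'
#' The fixed design emulated by the generator: 2 cell lines x 3 conditions x
#' `n_replicates` biological replicates.
#'
#' @param n_replicates replicates per (line, condition); at least 2.
#' @return data.frame with columns sample_id, line, condition, replicate.
#' @export
sample_design <- function(n_replicates = 2) {
  if (n_replicates < 2) stop("every (line, condition) needs >= 2 replicates")
  grid <- expand.grid(
    replicate = seq_len(n_replicates),
    condition = c("undiff", "DM", "MacCM"),
    line = c("glial", "neural"),
    stringsAsFactors = FALSE
  )
  grid <- grid[, c("line", "condition", "replicate")]
  grid$sample_id <- paste(grid$line, grid$condition, grid$replicate, sep = "_")
  grid[, c("sample_id", "line", "condition", "replicate")]
}

#' Sample ids of one side of a pairwise comparison
#'
#' @param design a sample design data.frame.
#' @param line,condition values to select.
#' @return character vector of sample ids.
#' @export
design_samples <- function(design, line = NULL, condition = NULL) {
  keep <- rep(TRUE, nrow(design))
  if (!is.null(line)) keep <- keep & design$line %in% line
  if (!is.null(condition)) keep <- keep & design$condition %in% condition
  design$sample_id[keep]
}
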