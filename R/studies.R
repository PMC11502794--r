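# Calibration and recovery studies: fixed simulation scenarios exercising
# the differential tests against the generator's planted truth. Shared by
# the test suite and the acceptance script.

study_groups <- function(n_per_group, condition = "undiff") {
  design <- sample_design(n_per_group)
  sel <- design$condition == condition
  list(
    design = design,
    labels = stats::setNames(
      factor(design$line[sel], levels = c("glial", "neural")),
      design$sample_id[sel]
    )
  )
}

#' Null calibration study
#'
#' Simulates a null data set (no planted effects) for one assay and reports
#' the fraction of raw p-values below 0.05: a calibrated test keeps it near
#' the nominal level. Scenarios: RRBS 5000 CpGs at coverage 30 and baseline
#' methylation 0.3; RNA 1000 genes; RRHP 1000 strand-specific tags; all
#' n = 3 per group.
#'
#' @param assay one of "rrbs", "rna", "rrhp".
#' @param seed integer seed.
#' @return list with `frac_p05`, `n_features` and `n_significant`.
#' @export
null_calibration_study <- function(assay = c("rrbs", "rna", "rrhp"),
                                   seed = 1) {
  assay <- match.arg(assay)
  g <- study_groups(3)
  cfg <- switch(assay,
    rrbs = sim_config(n_genes = 500, cpgs_per_gene = 10, baseline_mu = 0.3,
                      planted_delta = 0, frac_true = 0, frac_switch = 0,
                      mean_coverage = 30, seed = seed),
    rna = sim_config(n_genes = 1000, chrom_lengths = c(chr1 = 9e6, chr2 = 9e6),
                     planted_lfc = 0, frac_true = 0, frac_switch = 0,
                     seed = seed),
    rrhp = sim_config(n_genes = 100, ccgg_per_gene = 5, planted_lfc = 0,
                      frac_true = 0, frac_switch = 0, seed = seed)
  )
  loci <- simulate_annotation(cfg)
  truth <- plant_effects(cfg, loci)
  res <- switch(assay,
    rrbs = {
      tab <- simulate_rrbs(cfg, g$design, loci, truth)$table
      dml_test(tab, g$labels)
    },
    rna = {
      tab <- simulate_rnaseq(cfg, g$design, loci, truth)$table
      cm <- as.matrix(tab[, names(g$labels)])
      rownames(cm) <- tab$gene_id
      nb_wald_test(cm, g$labels)
    },
    rrhp = {
      tab <- simulate_rrhp(cfg, g$design, loci, truth)$table
      call_dhml(tab, g$labels)
    }
  )
  list(frac_p05 = mean(res$p < 0.05), n_features = nrow(res),
       n_significant = sum(res$significant))
}

recovery_from_calls <- function(called, truth_ids) {
  tp <- length(intersect(called, truth_ids))
  list(
    sensitivity = if (length(truth_ids)) tp / length(truth_ids) else NA_real_,
    fdr = if (length(called)) (length(called) - tp) / length(called)
          else NA_real_,
    n_true = length(truth_ids), n_called = length(called)
  )
}

#' Planted-effect recovery studies
#'
#' Each study plants differential effects for a single comparison
#' (glial vs neural, undifferentiated; n = 3 per group), runs the matching
#' test and reports sensitivity and empirical FDR against the planted
#' truth. Scenarios: DML — 5000 CpGs, 10 percent shifted by +/-0.30 at
#' coverage 30; DEG — 1000 genes, 10 percent at |log2FC| = 2; DHML — 2000
#' strand-specific tags, 10 percent at |log2FC| = 2.
#'
#' @param seed integer seed.
#' @return list with `sensitivity`, `fdr`, `n_true`, `n_called`.
#' @export
dml_recovery_study <- function(seed = 1) {
  g <- study_groups(3)
  cfg <- sim_config(n_genes = 500, cpgs_per_gene = 10, baseline_mu = 0.35,
                    planted_delta = 0.30, frac_true = 0.1, frac_switch = 0,
                    mean_coverage = 30, seed = seed)
  loci <- simulate_annotation(cfg)
  truth <- plant_effects(cfg, loci, conditions = "undiff")
  tab <- simulate_rrbs(cfg, g$design, loci, truth)$table
  res <- dml_test(tab, g$labels)
  called <- paste0(res$chrom, ":", res$pos)[res$significant]
  recovery_from_calls(called, unique(truth$feature_id[truth$modality == "5mC"]))
}

#' @rdname dml_recovery_study
#' @export
deg_recovery_study <- function(seed = 1) {
  g <- study_groups(3)
  cfg <- sim_config(n_genes = 1000, chrom_lengths = c(chr1 = 9e6, chr2 = 9e6),
                    planted_lfc = 2, frac_true = 0.1, frac_switch = 0,
                    seed = seed)
  loci <- simulate_annotation(cfg)
  truth <- plant_effects(cfg, loci, conditions = "undiff")
  tab <- simulate_rnaseq(cfg, g$design, loci, truth)$table
  cm <- as.matrix(tab[, names(g$labels)])
  rownames(cm) <- tab$gene_id
  res <- nb_wald_test(cm, g$labels)
  recovery_from_calls(res$feature_id[res$significant],
                      unique(truth$feature_id[truth$modality == "RNA"]))
}

#' @rdname dml_recovery_study
#' @export
dhml_recovery_study <- function(seed = 1) {
  g <- study_groups(3)
  cfg <- sim_config(n_genes = 200, ccgg_per_gene = 5, planted_lfc = 2,
                    frac_true = 0.1, frac_switch = 0, seed = seed)
  loci <- simulate_annotation(cfg)
  truth <- plant_effects(cfg, loci, conditions = "undiff")
  tab <- simulate_rrhp(cfg, g$design, loci, truth)$table
  res <- call_dhml(tab, g$labels)
  called <- paste0(res$chrom, ":", res$pos, ":", res$strand)[res$significant]
  recovery_from_calls(called,
                      unique(truth$feature_id[truth$modality == "5hmC"]))
}

#' Reciprocal-switch recovery study
#'
#' Runs the full pipeline on the default synthetic study (which plants
#' reciprocal 5mC/5hmC switch genes with flipped directions between DM and
#' Mac-CM) and reports how many planted switch genes [detect_switch()]
#' recovers with the correct class, and how many non-planted genes receive
#' a (false) switch class.
#'
#' @param seed integer seed.
#' @return list with `sensitivity`, `n_planted`, `n_correct`, `n_false`.
#' @export
switch_recovery_study <- function(seed = 1) {
  res <- run_pipeline(pipeline_config(sim_config(seed = seed)))
  r <- res$summary$switch_recovery
  list(sensitivity = r$sensitivity, n_planted = r$n_planted,
       n_correct = r$n_correct, n_false = r$n_false)
}
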