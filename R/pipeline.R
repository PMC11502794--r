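# End-to-end orchestration: simulate -> differential calls (DML / DHML /
# DEG per condition, glial vs neural) -> gene annotation -> patterns,
# trackability and switch detection -> machine-readable summary.

#' Pipeline configuration
#'
#' @param sim a [sim_config()] object (the synthetic study to analyse).
#' @param alpha adjusted-p-value threshold for all tests.
#' @param min_delta minimum |methylation difference| for DML significance.
#' @param lfc_threshold minimum |log2 fold change| for DHML/DEG significance.
#' @param min_coverage RRBS per-sample coverage floor.
#' @param flank locus extension for gene annotation (bp).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), alpha = 0.05,
                            min_delta = 0.10, lfc_threshold = 1,
                            min_coverage = 5, flank = 2000) {
  stopifnot(alpha > 0, min_delta > 0, lfc_threshold > 0, min_coverage > 0,
            flank >= 0)
  structure(list(sim = sim, alpha = alpha, min_delta = min_delta,
                 lfc_threshold = lfc_threshold, min_coverage = min_coverage,
                 flank = flank),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys override [pipeline_config()] defaults; keys under `sim`
#' override [sim_config()] defaults (`chrom_lengths` as a named map).
#'
#' @param path YAML file.
#' @return a `pipeline_config` object.
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  if (!is.null(sim_args$chrom_lengths))
    sim_args$chrom_lengths <- unlist(sim_args$chrom_lengths)
  top <- y[setdiff(names(y), "sim")]
  do.call(pipeline_config,
          c(list(sim = do.call(sim_config, sim_args)), top))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

comparison_labels <- function(design, condition) {
  sel <- design$condition == condition
  stats::setNames(factor(design$line[sel], levels = c("glial", "neural")),
                  design$sample_id[sel])
}

recovery_metrics <- function(called, truth_ids) {
  n_true <- length(truth_ids)
  n_called <- length(called)
  tp <- length(intersect(called, truth_ids))
  list(
    n_true = n_true, n_called = n_called,
    sensitivity = if (n_true > 0) tp / n_true else NA_real_,
    fdr = if (n_called > 0) (n_called - tp) / n_called else NA_real_
  )
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Simulates the study, calls DMLs (beta-binomial Wald), DHMLs and DEGs
#' (NB Wald) for glial vs neural within each condition, maps significant
#' loci to genes by extension and merging, assigns per-stage modality
#' patterns, classifies trackability per differentiation environment,
#' detects reciprocal 5mC/5hmC switches, and computes recovery metrics
#' against the planted truth. Deterministic given the seed in
#' `config$sim`.
#'
#' @param config a [pipeline_config()] object.
#' @param out_dir optional directory; when given, all stage outputs (TSV /
#'   BED / JSON) and `summary.json` are written there.
#' @return (invisibly) a list with the study, per-condition results
#'   (`dml`, `dhml`, `deg`), `gene_hits`, `tf_hits`, `patterns`,
#'   `track_records`, `switch_calls`, `pattern_summary` and `summary`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  study <- simulate_study(config$sim)
  design <- study$design
  conditions <- c("undiff", "DM", "MacCM")
  stage_of <- c(undiff = "undiff", DM = "diff_DM", MacCM = "diff_MacCM")

  rna_counts <- as.matrix(study$rnaseq[, design$sample_id])
  rownames(rna_counts) <- study$rnaseq$gene_id

  dml <- dhml <- deg <- hits <- list()
  summary_counts <- list()
  for (cond in conditions) {
    gl <- comparison_labels(design, cond)
    dml[[cond]] <- dml_test(study$rrbs, gl, alpha = config$alpha,
                            min_delta = config$min_delta,
                            min_coverage = config$min_coverage)
    dhml[[cond]] <- call_dhml(study$rrhp, gl, alpha = config$alpha,
                              lfc_threshold = config$lfc_threshold)
    deg[[cond]] <- nb_wald_test(rna_counts, gl, alpha = config$alpha,
                                lfc_threshold = config$lfc_threshold)

    sig_dml <- dml[[cond]][dml[[cond]]$significant, , drop = FALSE]
    sig_dml$effect <- sig_dml$delta
    sig_dhml <- dhml[[cond]][dhml[[cond]]$significant, , drop = FALSE]
    sig_dhml$effect <- sig_dhml$log2fc
    hits[[cond]] <- rbind(
      gene_hits_from_loci(sig_dml, study$annotation, "5mC", cond,
                          flank = config$flank,
                          chrom_lengths = config$sim$chrom_lengths),
      gene_hits_from_loci(sig_dhml, study$annotation, "5hmC", cond,
                          flank = config$flank,
                          chrom_lengths = config$sim$chrom_lengths),
      gene_hits_from_deg(deg[[cond]], cond)
    )
    deg_sig <- deg[[cond]][deg[[cond]]$significant, , drop = FALSE]
    summary_counts[[cond]] <- list(
      n_loci_tested = nrow(dml[[cond]]),
      n_dml = nrow(sig_dml),
      n_tags_tested = nrow(dhml[[cond]]),
      n_dhml = nrow(sig_dhml),
      n_genes_tested = nrow(deg[[cond]]),
      n_deg = nrow(deg_sig),
      n_deg_up = sum(deg_sig$log2fc > 0),
      n_deg_down = sum(deg_sig$log2fc < 0),
      n_genes_hit = length(unique(hits[[cond]]$gene_id))
    )
  }

  tf_hits <- lapply(hits, filter_tfs, annotation = study$annotation)
  patterns <- lapply(conditions, function(cond) {
    modality_pattern(hits[[cond]], stage_of[[cond]])
  })
  names(patterns) <- conditions

  track_records <- rbind(
    classify_trackability(patterns$undiff, patterns$DM, "DM"),
    classify_trackability(patterns$undiff, patterns$MacCM, "MacCM")
  )
  switch_calls <- detect_switch(hits$DM, hits$MacCM)
  pattern_summary <- summarize_patterns(track_records, switch_calls)

  truth <- study$truth
  truth_ids <- function(modality, cond)
    unique(truth$feature_id[truth$modality == modality &
                              truth$condition == cond])
  dml_ids <- function(res) paste0(res$chrom, ":", res$pos)
  tag_ids <- function(res) paste0(res$chrom, ":", res$pos, ":", res$strand)
  recovery <- list()
  for (cond in conditions) {
    recovery[[cond]] <- list(
      dml = recovery_metrics(
        dml_ids(dml[[cond]][dml[[cond]]$significant, ]),
        truth_ids("5mC", cond)),
      dhml = recovery_metrics(
        tag_ids(dhml[[cond]][dhml[[cond]]$significant, ]),
        truth_ids("5hmC", cond)),
      deg = recovery_metrics(
        deg[[cond]]$feature_id[deg[[cond]]$significant],
        truth_ids("RNA", cond))
    )
  }
  sw_truth <- unique(truth[truth$switch_class != "none",
                           c("gene_id", "switch_class")])
  sw_called <- switch_calls[switch_calls$class != "none", , drop = FALSE]
  correct <- merge(sw_truth, sw_called, by = "gene_id")
  switch_recovery <- list(
    n_planted = nrow(sw_truth),
    n_called = nrow(sw_called),
    n_correct = sum(correct$switch_class == correct$class),
    n_false = sum(!sw_called$gene_id %in% sw_truth$gene_id),
    sensitivity = if (nrow(sw_truth) > 0)
      sum(correct$switch_class == correct$class) / nrow(sw_truth)
    else NA_real_
  )

  n_patterns_observed <- length(unique(unlist(
    lapply(patterns, function(p) p$pattern_id)
  )))
  summary <- list(
    seed = config$sim$seed,
    thresholds = list(alpha = config$alpha, min_delta = config$min_delta,
                      lfc_threshold = config$lfc_threshold,
                      min_coverage = config$min_coverage,
                      flank = config$flank),
    counts = summary_counts,
    n_pattern_classes_possible = nrow(PATTERN_TABLE),
    n_pattern_classes_observed = n_patterns_observed,
    status_counts = pattern_summary$status_counts,
    switch_counts = pattern_summary$switch_counts,
    recovery = recovery,
    switch_recovery = switch_recovery
  )

  result <- list(study = study, dml = dml, dhml = dhml, deg = deg,
                 gene_hits = hits, tf_hits = tf_hits, patterns = patterns,
                 track_records = track_records, switch_calls = switch_calls,
                 pattern_summary = pattern_summary, summary = summary)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  invisible(result)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  study <- result$study
  write_design(study$design, file.path(out_dir, "design.tsv"))
  write_meth_table(study$rrbs, file.path(out_dir, "rrbs_counts.tsv"))
  write_count_table(study$rrhp, file.path(out_dir, "rrhp_counts.tsv"))
  write_count_table(study$rnaseq, file.path(out_dir, "rna_counts.tsv"))
  write_annotation_bed(study$annotation,
                       file.path(out_dir, "annotation.bed"))
  write_truth_json(study$truth, file.path(out_dir, "truth.json"),
                   size_factors = study$rna_size_factors)
  for (cond in names(result$dml)) {
    write_tsv_plain(result$dml[[cond]],
                    file.path(out_dir, paste0("dml_", cond, ".tsv")))
    write_tsv_plain(result$dhml[[cond]],
                    file.path(out_dir, paste0("dhml_", cond, ".tsv")))
    write_tsv_plain(result$deg[[cond]],
                    file.path(out_dir, paste0("deg_", cond, ".tsv")))
    write_tsv_plain(result$gene_hits[[cond]],
                    file.path(out_dir, paste0("gene_hits_", cond, ".tsv")))
  }
  write_tsv_plain(result$track_records,
                  file.path(out_dir, "track_records.tsv"))
  write_tsv_plain(result$switch_calls,
                  file.path(out_dir, "switch_calls.tsv"))
  jsonlite::write_json(result$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(out_dir)
}
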