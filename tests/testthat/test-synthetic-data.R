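test_that("annotation generator places genes, flags TFs and is deterministic", {
  cfg <- sim_config(n_genes = 10, tf_fraction = 0.5,
                    chrom_lengths = c(chr1 = 2e5), seed = 42)
  loci <- simulate_annotation(cfg)
  ann <- loci$annotation
  expect_equal(nrow(ann), 10)
  expect_equal(sum(ann$is_tf), 5)
  expect_true(all(ann$start < ann$end))
  # non-overlapping within chromosome
  for (ch in unique(ann$chrom)) {
    a <- ann[ann$chrom == ch, ]
    a <- a[order(a$start), ]
    if (nrow(a) > 1) expect_true(all(a$start[-1] >= a$end[-nrow(a)]))
  }
  expect_true(all(ann$end <= cfg$chrom_lengths[ann$chrom]))
  # byte-identical reruns; different seed differs
  loci2 <- simulate_annotation(cfg)
  expect_identical(loci, loci2)
  loci3 <- simulate_annotation(sim_config(n_genes = 10, tf_fraction = 0.5,
                                          chrom_lengths = c(chr1 = 2e5),
                                          seed = 43))
  expect_false(identical(loci$annotation$start, loci3$annotation$start))
})

test_that("annotation generator refuses genomes too small for the gene set", {
  cfg <- sim_config(n_genes = 1000, gene_length = 2000,
                    chrom_lengths = c(chr1 = 1e6))
  expect_error(simulate_annotation(cfg), "too small")
})

test_that("config validation enforces parameter ranges", {
  expect_error(sim_config(tf_fraction = 0), "tf_fraction")
  expect_error(sim_config(baseline_mu = 0.2, planted_delta = 0.3),
               "baseline_mu")
  expect_error(sim_config(bb_dispersion = 1.2), "bb_dispersion")
})

test_that("RRBS counts respect meth <= total and match the null mean", {
  cfg <- sim_config(n_genes = 200, cpgs_per_gene = 10, baseline_mu = 0.3,
                    planted_delta = 0, frac_true = 0, frac_switch = 0,
                    seed = 5)
  des <- sample_design(2)
  loci <- simulate_annotation(cfg)
  truth <- plant_effects(cfg, loci)
  expect_equal(nrow(truth), 0)  # nothing planted
  rrbs <- simulate_rrbs(cfg, des, loci, truth)
  mcols <- paste0("meth_", des$sample_id)
  tcols <- paste0("total_", des$sample_id)
  meth <- as.matrix(rrbs$table[, mcols])
  total <- as.matrix(rrbs$table[, tcols])
  expect_true(all(meth >= 0) && all(total >= 0))
  expect_true(all(meth <= total))
  expect_true(is.integer(meth) && is.integer(total))
  # law of large numbers over 2000 null loci
  ratio <- sum(meth) / sum(total)
  expect_lt(abs(ratio - 0.3), 0.02)
})

test_that("planted truth size follows frac_true and is gene-linked", {
  cfg <- sim_config(n_genes = 100, cpgs_per_gene = 10, frac_true = 0.1,
                    frac_switch = 0, seed = 8)
  loci <- simulate_annotation(cfg)
  truth <- plant_effects(cfg, loci)
  expect_equal(sum(truth$modality == "5mC"), 100)  # 0.1 x 1000 CpGs
  expect_equal(sum(truth$modality == "RNA"), 10)   # 0.1 x 100 genes
  expect_true(all(truth$gene_id %in% loci$annotation$gene_id))
  # every planted feature maps to exactly one gene
  expect_false(any(duplicated(
    truth[, c("feature_id", "modality", "condition")])))
})

test_that("RRHP profiles both strands and reproduces the planted fold", {
  cfg <- sim_config(n_genes = 50, ccgg_per_gene = 5, planted_lfc = 1,
                    frac_true = 1, frac_switch = 0, tag_meanlog_sd = 0,
                    seed = 3)
  des <- sample_design(2)
  loci <- simulate_annotation(cfg)
  # every (chrom, pos) appears once per strand
  keys <- paste0(loci$ccgg_loci$chrom, ":", loci$ccgg_loci$pos)
  expect_true(all(table(keys) == 2))
  expect_setequal(unique(loci$ccgg_loci$strand), c("+", "-"))
  truth <- plant_effects(cfg, loci, conditions = "undiff")
  rrhp <- simulate_rrhp(cfg, des, loci, truth)
  up <- truth$feature_id[truth$modality == "5hmC" & truth$effect > 0]
  idx <- match(up, paste0(rrhp$table$chrom, ":", rrhp$table$pos, ":",
                          rrhp$table$strand))
  glial <- rrhp$table[idx, design_samples(des, "glial", "undiff")]
  neural <- rrhp$table[idx, design_samples(des, "neural", "undiff")]
  ratio <- mean(as.matrix(neural)) / mean(as.matrix(glial))
  expect_lt(abs(ratio - 2), 0.2)  # within 10% of 2^1
})

test_that("zero planted effect sizes yield empty differential truth", {
  cfg <- sim_config(n_genes = 20, planted_delta = 0, planted_lfc = 0,
                    frac_true = 0, frac_switch = 0, seed = 2)
  loci <- simulate_annotation(cfg)
  truth <- plant_effects(cfg, loci)
  expect_equal(nrow(truth), 0)
})

test_that("RNA size factors are recoverable by median-of-ratios", {
  cfg <- sim_config(n_genes = 500, chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
                    frac_true = 0, frac_switch = 0, seed = 9)
  des <- sample_design(2)
  loci <- simulate_annotation(cfg)
  truth <- plant_effects(cfg, loci)
  rna <- simulate_rnaseq(cfg, des, loci, truth)
  est <- size_factors(as.matrix(rna$table[, des$sample_id]))
  true_sf <- rna$size_factors / exp(mean(log(rna$size_factors)))
  expect_true(all(abs(est / true_sf - 1) < 0.05))
})

test_that("planted truth round-trips through JSON losslessly", {
  cfg <- sim_config(n_genes = 30, frac_true = 0.2, seed = 4)
  loci <- simulate_annotation(cfg)
  truth <- plant_effects(cfg, loci)
  path <- withr::local_tempfile(fileext = ".json")
  write_truth_json(truth, path, size_factors = c(a = 0.75, b = 1.5))
  back <- read_truth_json(path)
  expect_equal(back$truth, truth)
  expect_equal(back$size_factors, c(a = 0.75, b = 1.5))
})

test_that("count tables and annotation round-trip through text formats", {
  cfg <- sim_config(n_genes = 10, seed = 6)
  des <- sample_design(2)
  loci <- simulate_annotation(cfg)
  truth <- plant_effects(cfg, loci)
  rrbs <- simulate_rrbs(cfg, des, loci, truth)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  write_meth_table(rrbs$table, p1)
  expect_equal(read_meth_table(p1), rrbs$table)
  p2 <- withr::local_tempfile(fileext = ".bed")
  write_annotation_bed(loci$annotation, p2)
  back <- read_annotation_bed(p2)
  expect_equal(back$gene_id, loci$annotation$gene_id)
  expect_equal(back$is_tf, loci$annotation$is_tf)
  expect_equal(back$start, loci$annotation$start)
})
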