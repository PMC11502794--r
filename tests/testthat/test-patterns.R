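all_modality_subsets <- function() {
  mods <- c("RNA", "5mC", "5hmC")
  subsets <- list()
  for (k in 1:3)
    subsets <- c(subsets, combn(mods, k, simplify = FALSE))
  subsets
}

test_that("the canonical pattern table enumerates exactly 7 classes", {
  ids <- vapply(all_modality_subsets(), pattern_id, integer(1))
  expect_setequal(ids, 1:7)
  expect_equal(length(ids), 7)
  expect_equal(pattern_id("RNA"), 1L)
  expect_equal(pattern_id(c("RNA", "5mC", "5hmC")), 7L)
  expect_equal(pattern_id(c("5mC", "5hmC")), 6L)
  expect_error(pattern_id(character(0)), "non-empty")
  expect_error(pattern_id("ChIP"), "unknown")
})

test_that("modality_pattern collapses hits to one pattern per gene", {
  hits <- data.frame(
    gene_id = c("g1", "g1", "g2", "g3", "g3", "g3"),
    modality = c("RNA", "5mC", "5hmC", "RNA", "5mC", "5hmC"),
    comparison = "undiff", direction = "gain", n_loci = 1L,
    stringsAsFactors = FALSE
  )
  p <- modality_pattern(hits, "undiff")
  expect_equal(p$gene_id, c("g1", "g2", "g3"))
  expect_equal(p$pattern_id, c(4L, 3L, 7L))
  expect_equal(p$modalities, c("RNA+5mC", "5hmC", "RNA+5mC+5hmC"))
  # a stage partitions detected genes: one row per gene
  expect_false(any(duplicated(p$gene_id)))
  expect_equal(nrow(modality_pattern(hits[0, ], "undiff")), 0)
})

test_that("trackability statuses and transition ids match hand labels", {
  undiff <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                       stage = "undiff",
                       modalities = c("RNA", "5mC", "RNA+5mC+5hmC", "5hmC"),
                       pattern_id = c(1L, 2L, 7L, 3L),
                       stringsAsFactors = FALSE)
  diff <- data.frame(gene_id = c("g1", "g3", "g5", "g6"),
                     stage = "diff_DM",
                     modalities = c("5hmC", "RNA", "5mC+5hmC", "RNA"),
                     pattern_id = c(3L, 1L, 6L, 1L),
                     stringsAsFactors = FALSE)
  tr <- classify_trackability(undiff, diff, "DM")
  expect_equal(tr$status[match(c("g1", "g2", "g3", "g4", "g5", "g6"),
                               tr$gene_id)],
               c("trackable", "untrackable_undiff_only", "trackable",
                 "untrackable_undiff_only", "untrackable_diff_only",
                 "untrackable_diff_only"))
  # transition ids: trackable 7 + (u-1)*7 + d; undiff-only u; diff-only 56+d
  expect_equal(tr$transition_id[tr$gene_id == "g1"], 7L + 0L * 7L + 3L)
  expect_equal(tr$transition_id[tr$gene_id == "g3"], 7L + 6L * 7L + 1L)
  expect_equal(tr$transition_id[tr$gene_id == "g2"], 2L)
  expect_equal(tr$transition_id[tr$gene_id == "g5"], 56L + 6L)
  # statuses partition all pattern-bearing genes
  expect_setequal(tr$gene_id, union(undiff$gene_id, diff$gene_id))
  expect_false(any(duplicated(tr$gene_id)))
})

make_hits <- function(gene, m5c = NULL, m5hmc = NULL) {
  rows <- NULL
  if (!is.null(m5c))
    rows <- rbind(rows, data.frame(gene_id = gene, modality = "5mC",
                                   comparison = "x", direction = m5c,
                                   n_loci = 1L, stringsAsFactors = FALSE))
  if (!is.null(m5hmc))
    rows <- rbind(rows, data.frame(gene_id = gene, modality = "5hmC",
                                   comparison = "x", direction = m5hmc,
                                   n_loci = 1L, stringsAsFactors = FALSE))
  rows
}

test_that("switch detection requires the full reciprocal configuration", {
  dm <- make_hits("g1", m5c = "loss", m5hmc = "gain")
  mc <- make_hits("g1", m5c = "gain", m5hmc = "loss")
  expect_equal(detect_switch(dm, mc)$class, "gain5mC_loss5hmC")
  expect_equal(detect_switch(mc, dm)$class, "gain5hmC_loss5mC")
  # identical hits in both environments: no switch
  expect_equal(detect_switch(dm, dm)$class, "none")
  # gene absent from one environment: no record
  expect_equal(nrow(detect_switch(dm, make_hits("g2", m5c = "gain",
                                                m5hmc = "loss"))), 0)
  # missing modality in one environment: none
  dm_partial <- make_hits("g1", m5c = "loss")
  expect_equal(detect_switch(dm_partial, mc)$class, "none")
})

test_that("switch calls equal brute-force truth-table evaluation", {
  set.seed(19)
  dirs <- c("gain", "loss", NA)
  genes <- paste0("g", 1:100)
  draw <- function() dirs[sample.int(3, 100, replace = TRUE)]
  cfgs <- data.frame(gene_id = genes,
                     dm_5mc = draw(), dm_5hmc = draw(),
                     mc_5mc = draw(), mc_5hmc = draw(),
                     stringsAsFactors = FALSE)
  build <- function(col5mc, col5hmc) {
    do.call(rbind, lapply(seq_along(genes), function(i) {
      make_hits(genes[i],
                m5c = if (!is.na(cfgs[[col5mc]][i])) cfgs[[col5mc]][i],
                m5hmc = if (!is.na(cfgs[[col5hmc]][i])) cfgs[[col5hmc]][i])
    }))
  }
  dm <- build("dm_5mc", "dm_5hmc")
  mc <- build("mc_5mc", "mc_5hmc")
  calls <- detect_switch(dm, mc)
  oracle <- with(cfgs, ifelse(
    !is.na(dm_5mc) & !is.na(dm_5hmc) & !is.na(mc_5mc) & !is.na(mc_5hmc) &
      mc_5mc == "gain" & mc_5hmc == "loss" &
      dm_5mc == "loss" & dm_5hmc == "gain", "gain5mC_loss5hmC",
    ifelse(
      !is.na(dm_5mc) & !is.na(dm_5hmc) & !is.na(mc_5mc) & !is.na(mc_5hmc) &
        mc_5mc == "loss" & mc_5hmc == "gain" &
        dm_5mc == "gain" & dm_5hmc == "loss", "gain5hmC_loss5mC", "none")))
  # detect_switch only reports genes with some 5mC/5hmC hit in both envs
  expect_equal(calls$class, oracle[match(calls$gene_id, genes)])
  # mutually exclusive classes: one call per gene
  expect_false(any(duplicated(calls$gene_id)))
})

test_that("pattern summaries tally exactly to their inputs", {
  undiff <- data.frame(gene_id = c("g1", "g2"), stage = "undiff",
                       modalities = c("RNA", "5mC"), pattern_id = c(1L, 2L),
                       stringsAsFactors = FALSE)
  diff_dm <- data.frame(gene_id = c("g1", "g3"), stage = "diff_DM",
                        modalities = c("RNA", "5hmC"), pattern_id = c(1L, 3L),
                        stringsAsFactors = FALSE)
  tr <- classify_trackability(undiff, diff_dm, "DM")
  sw <- data.frame(gene_id = "g1", class = "none", stringsAsFactors = FALSE)
  s <- summarize_patterns(tr, sw)
  expect_equal(sum(s$status_counts$n), nrow(tr))
  expect_equal(sum(s$transition_counts$n), nrow(tr))
  expect_equal(sum(s$switch_counts$n), nrow(sw))
  expect_equal(s$status_counts$n[s$status_counts$status == "trackable"], 1L)

  s0 <- summarize_patterns(tr[0, ], sw[0, ])
  expect_equal(sum(s0$status_counts$n), 0)
  expect_equal(sum(s0$switch_counts$n), 0)
})
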