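# Synthetic multi-omic generator: count-level emulation of an RRBS / RRHP /
# RNA-seq study of two cell lines under three differentiation conditions,
# with machine-readable planted truth. Counts are simulated directly; read
# simulation and alignment are upstream of this package's scope.

#' Simulate a gene annotation and locus catalogue
#'
#' Places `n_genes` non-overlapping gene intervals on the configured
#' chromosomes, flags `round(tf_fraction * n_genes)` of them as transcription
#' factors, and generates per-gene CpG loci and strand-specific CCGG (MspI)
#' sites inside or within 1 kb of each gene body.
#'
#' @param config a [sim_config()] object.
#' @return list with elements `annotation` (gene_id, chrom, start, end,
#'   strand, is_tf; 0-based half-open coordinates), `cpg_loci` (chrom, pos,
#'   strand, gene_id) and `ccgg_loci` (chrom, pos, strand, gene_id; one row
#'   per strand of each CCGG site).
#' @export
simulate_annotation <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed, simulate_annotation_impl(config))
}

simulate_annotation_impl <- function(config) {
  chroms <- names(config$chrom_lengths)
  gene_len <- config$gene_length
  min_gap <- 2500  # keeps neighbouring locus windows apart
  # capacity-proportional allocation of genes to chromosomes
  cap <- floor((config$chrom_lengths + min_gap) / (gene_len + min_gap))
  if (sum(cap) < config$n_genes)
    stop("chrom_lengths too small to place ", config$n_genes,
         " non-overlapping genes of length ", gene_len)
  alloc <- floor(cap * config$n_genes / sum(cap))
  i <- 1
  while (sum(alloc) < config$n_genes) {  # distribute remainder
    k <- ((i - 1) %% length(alloc)) + 1
    if (alloc[k] < cap[k]) alloc[k] <- alloc[k] + 1
    i <- i + 1
  }
  rows <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    n <- alloc[ci]
    if (n == 0) next
    L <- config$chrom_lengths[ci]
    slack <- L - n * gene_len - (n - 1) * min_gap
    # split slack into n+1 gaps via sorted uniform spacings
    cuts <- sort(stats::runif(n, 0, 1))
    gaps <- floor(c(cuts, 1) * slack) - floor(c(0, cuts) * slack)
    starts <- cumsum(gaps[seq_len(n)] + c(0, rep(gene_len + min_gap, n - 1)))
    rows[[ci]] <- data.frame(
      chrom = chroms[ci], start = starts, end = starts + gene_len,
      stringsAsFactors = FALSE
    )
  }
  ann <- do.call(rbind, rows)
  ann$gene_id <- sprintf("gene%04d", seq_len(nrow(ann)))
  ann$strand <- sample(c("+", "-"), nrow(ann), replace = TRUE)
  n_tf <- round(config$tf_fraction * config$n_genes)
  ann$is_tf <- FALSE
  ann$is_tf[sample.int(nrow(ann), n_tf)] <- TRUE
  ann <- ann[, c("gene_id", "chrom", "start", "end", "strand", "is_tf")]
  rownames(ann) <- NULL

  sample_loci <- function(per_gene) {
    pos <- lapply(seq_len(nrow(ann)), function(i) {
      lo <- max(0, ann$start[i] - 1000)
      hi <- min(config$chrom_lengths[[ann$chrom[i]]], ann$end[i] + 1000)
      sort(sample(seq.int(lo, hi - 1), per_gene))
    })
    data.frame(
      chrom = rep(ann$chrom, each = per_gene),
      pos = unlist(pos),
      gene_id = rep(ann$gene_id, each = per_gene),
      stringsAsFactors = FALSE
    )
  }
  cpg <- sample_loci(config$cpgs_per_gene)
  cpg$strand <- "+"
  cpg <- cpg[, c("chrom", "pos", "strand", "gene_id")]
  ccgg1 <- sample_loci(config$ccgg_per_gene)
  # RRHP profiles each MspI site on both strands
  ccgg <- rbind(
    data.frame(ccgg1[, c("chrom", "pos")], strand = "+",
               gene_id = ccgg1$gene_id, stringsAsFactors = FALSE),
    data.frame(ccgg1[, c("chrom", "pos")], strand = "-",
               gene_id = ccgg1$gene_id, stringsAsFactors = FALSE)
  )
  ord <- order(ccgg$chrom, ccgg$pos, ccgg$strand)
  ccgg <- ccgg[ord, ]
  rownames(ccgg) <- NULL
  list(annotation = ann, cpg_loci = cpg, ccgg_loci = ccgg)
}

#' Plant differential effects
#'
#' Builds the ground-truth table of planted effects. A fraction `frac_true`
#' of features per modality receives a condition-specific effect (applied to
#' the neural line in that condition), with random sign. Additionally,
#' `frac_switch` of genes are planted as reciprocal 5mC/5hmC switch genes:
#' all their CpGs and CCGG strands carry opposite-direction 5mC and 5hmC
#' effects under DM, and the reversed pairing under Mac-CM.
#'
#' @param config a [sim_config()] object.
#' @param loci output of [simulate_annotation()].
#' @param conditions conditions among which planted effects are assigned
#'   (uniformly at random). A single condition plants every effect for that
#'   comparison, as in the dedicated recovery studies.
#' @return data.frame with columns feature_id, modality (one of "RNA",
#'   "5mC", "5hmC"), gene_id, condition, effect (delta methylation for 5mC,
#'   log2 fold change otherwise), switch_class ("none",
#'   "gain5mC_loss5hmC" or "gain5hmC_loss5mC").
#' @export
plant_effects <- function(config, loci,
                          conditions = c("undiff", "DM", "MacCM")) {
  stopifnot(all(conditions %in% c("undiff", "DM", "MacCM")))
  validate_sim_config(config)
  withr::with_seed(config$seed + 1L,
                   plant_effects_impl(config, loci, conditions))
}

plant_effects_impl <- function(config, loci, conditions) {
  cpg_id <- feature_id_cpg(loci$cpg_loci)
  ccgg_id <- feature_id_tag(loci$ccgg_loci)

  pick <- function(ids, genes, modality, effect_size) {
    n_true <- round(config$frac_true * length(ids))
    if (n_true == 0) return(NULL)
    idx <- sample.int(length(ids), n_true)
    data.frame(
      feature_id = ids[idx], modality = modality, gene_id = genes[idx],
      condition = conditions[sample.int(length(conditions), n_true,
                                        replace = TRUE)],
      effect = effect_size * sample(c(-1, 1), n_true, replace = TRUE),
      switch_class = "none", stringsAsFactors = FALSE
    )
  }
  truth <- rbind(
    pick(cpg_id, loci$cpg_loci$gene_id, "5mC", config$planted_delta),
    pick(ccgg_id, loci$ccgg_loci$gene_id, "5hmC", config$planted_lfc),
    pick(loci$annotation$gene_id, loci$annotation$gene_id, "RNA",
         config$planted_lfc)
  )

  # reciprocal switch genes: effects in BOTH differentiation environments,
  # flipped between DM and Mac-CM
  n_sw <- round(config$frac_switch * nrow(loci$annotation))
  if (n_sw > 0) {
    planted_genes <- unique(truth$gene_id[truth$modality %in% c("5mC", "5hmC")])
    eligible <- setdiff(loci$annotation$gene_id, planted_genes)
    sw_genes <- eligible[sample.int(length(eligible),
                                    min(n_sw, length(eligible)))]
    classes <- rep(c("gain5mC_loss5hmC", "gain5hmC_loss5mC"),
                   length.out = length(sw_genes))
    sw <- lapply(seq_along(sw_genes), function(i) {
      g <- sw_genes[i]
      # sign of the 5mC effect under Mac-CM; 5hmC is the reciprocal
      s <- if (classes[i] == "gain5mC_loss5hmC") 1 else -1
      ci <- which(loci$cpg_loci$gene_id == g)
      hi <- which(loci$ccgg_loci$gene_id == g)
      rbind(
        data.frame(feature_id = cpg_id[ci], modality = "5mC", gene_id = g,
                   condition = "MacCM", effect = s * config$planted_delta,
                   switch_class = classes[i], stringsAsFactors = FALSE),
        data.frame(feature_id = cpg_id[ci], modality = "5mC", gene_id = g,
                   condition = "DM", effect = -s * config$planted_delta,
                   switch_class = classes[i], stringsAsFactors = FALSE),
        data.frame(feature_id = ccgg_id[hi], modality = "5hmC", gene_id = g,
                   condition = "MacCM", effect = -s * config$planted_lfc,
                   switch_class = classes[i], stringsAsFactors = FALSE),
        data.frame(feature_id = ccgg_id[hi], modality = "5hmC", gene_id = g,
                   condition = "DM", effect = s * config$planted_lfc,
                   switch_class = classes[i], stringsAsFactors = FALSE)
      )
    })
    truth <- rbind(truth, do.call(rbind, sw))
  }
  if (is.null(truth)) {
    truth <- data.frame(feature_id = character(), modality = character(),
                        gene_id = character(), condition = character(),
                        effect = numeric(), switch_class = character(),
                        stringsAsFactors = FALSE)
  }
  rownames(truth) <- NULL
  truth
}

feature_id_cpg <- function(cpg_loci) paste0(cpg_loci$chrom, ":", cpg_loci$pos)

feature_id_tag <- function(ccgg_loci)
  paste0(ccgg_loci$chrom, ":", ccgg_loci$pos, ":", ccgg_loci$strand)

# effect per feature x sample given the planted truth for one modality:
# effects apply to the neural line under the planted condition
effect_matrix <- function(feature_ids, design, truth, modality) {
  eff <- matrix(0, nrow = length(feature_ids), ncol = nrow(design),
                dimnames = list(feature_ids, design$sample_id))
  tr <- truth[truth$modality == modality, , drop = FALSE]
  if (nrow(tr) == 0) return(eff)
  target <- design$line == "neural"
  for (k in seq_len(nrow(tr))) {
    i <- match(tr$feature_id[k], feature_ids)
    if (is.na(i)) next
    cols <- target & design$condition == tr$condition[k]
    eff[i, cols] <- eff[i, cols] + tr$effect[k]
  }
  eff
}

rnbinom_mat <- function(n_feat, n_samp, mu, dispersion, dimnames = NULL) {
  m <- matrix(
    stats::rnbinom(n_feat * n_samp, mu = mu, size = 1 / dispersion),
    nrow = n_feat, ncol = n_samp, dimnames = dimnames
  )
  storage.mode(m) <- "integer"
  m
}

#' Simulate an RRBS methylation count table
#'
#' Total reads per CpG and sample are negative binomial with mean
#' `mean_coverage`; methylated reads given totals are beta-binomial with
#' mean mu and dispersion phi, parameterised as a = mu(1-phi)/phi,
#' b = (1-mu)(1-phi)/phi. Planted 5mC effects shift mu by the signed delta in
#' the neural line under the planted condition.
#'
#' @param config a [sim_config()] object.
#' @param design a [sample_design()] data.frame.
#' @param loci output of [simulate_annotation()].
#' @param truth output of [plant_effects()] (may be an empty table).
#' @return list with `table` (chrom, pos, strand, then meth_<id> and
#'   total_<id> per sample) and `truth` (the 5mC rows of the planted truth).
#' @export
simulate_rrbs <- function(config, design, loci, truth) {
  validate_sim_config(config)
  withr::with_seed(config$seed + 2L, {
    ids <- feature_id_cpg(loci$cpg_loci)
    nf <- length(ids); ns <- nrow(design)
    total <- rnbinom_mat(nf, ns, config$mean_coverage, config$nb_dispersion,
                         list(NULL, design$sample_id))
    mu <- pmin(pmax(config$baseline_mu +
                      effect_matrix(ids, design, truth, "5mC"), 0.02), 0.98)
    phi <- config$bb_dispersion
    p <- matrix(
      stats::rbeta(nf * ns, mu * (1 - phi) / phi, (1 - mu) * (1 - phi) / phi),
      nrow = nf, ncol = ns
    )
    meth <- matrix(stats::rbinom(nf * ns, as.vector(total), as.vector(p)),
                   nrow = nf, ncol = ns,
                   dimnames = list(NULL, design$sample_id))
    storage.mode(meth) <- "integer"
    tab <- loci$cpg_loci[, c("chrom", "pos", "strand")]
    for (s in design$sample_id) {
      tab[[paste0("meth_", s)]] <- meth[, s]
      tab[[paste0("total_", s)]] <- total[, s]
    }
    list(table = tab, truth = truth[truth$modality == "5mC", , drop = FALSE])
  })
}

#' Simulate an RRHP strand-specific tag count table
#'
#' Each strand of each CCGG site is an independent feature with a log-normal
#' baseline mean (median `mean_coverage`); counts are negative binomial.
#' Planted 5hmC effects multiply the mean by 2^effect in the neural line
#' under the planted condition.
#'
#' @inheritParams simulate_rrbs
#' @return list with `table` (chrom, pos, strand, then one count column per
#'   sample) and `truth` (the 5hmC rows of the planted truth).
#' @export
simulate_rrhp <- function(config, design, loci, truth) {
  validate_sim_config(config)
  withr::with_seed(config$seed + 3L, {
    ids <- feature_id_tag(loci$ccgg_loci)
    nf <- length(ids); ns <- nrow(design)
    base <- stats::rlnorm(nf, meanlog = log(config$mean_coverage),
                          sdlog = config$tag_meanlog_sd)
    mu <- base * 2^effect_matrix(ids, design, truth, "5hmC")
    counts <- rnbinom_mat(nf, ns, as.vector(mu), config$nb_dispersion,
                          list(NULL, design$sample_id))
    tab <- cbind(loci$ccgg_loci[, c("chrom", "pos", "strand")],
                 as.data.frame(counts))
    list(table = tab, truth = truth[truth$modality == "5hmC", , drop = FALSE])
  })
}

#' Simulate an RNA-seq gene count table
#'
#' Per-gene baseline means are log-normal (median `rna_mean`); per-sample
#' library-size factors are drawn uniformly from [0.5, 2] and recorded in the
#' returned truth. Planted expression effects multiply the mean by 2^effect
#' in the neural line under the planted condition.
#'
#' @inheritParams simulate_rrbs
#' @return list with `table` (gene_id plus one count column per sample),
#'   `truth` (the RNA rows of the planted truth) and `size_factors` (named
#'   per-sample factors actually used).
#' @export
simulate_rnaseq <- function(config, design, loci, truth) {
  validate_sim_config(config)
  withr::with_seed(config$seed + 4L, {
    ids <- loci$annotation$gene_id
    nf <- length(ids); ns <- nrow(design)
    base <- stats::rlnorm(nf, meanlog = log(config$rna_mean),
                          sdlog = config$rna_meanlog_sd)
    sf <- stats::runif(ns, 0.5, 2)
    names(sf) <- design$sample_id
    mu <- sweep(base * 2^effect_matrix(ids, design, truth, "RNA"), 2, sf, "*")
    counts <- rnbinom_mat(nf, ns, as.vector(mu), config$nb_dispersion,
                          list(NULL, design$sample_id))
    tab <- cbind(data.frame(gene_id = ids, stringsAsFactors = FALSE),
                 as.data.frame(counts))
    list(table = tab, truth = truth[truth$modality == "RNA", , drop = FALSE],
         size_factors = sf)
  })
}

#' Simulate the full synthetic study
#'
#' Convenience wrapper running [simulate_annotation()], [plant_effects()] and
#' the three table generators under one configuration.
#'
#' @param config a [sim_config()] object.
#' @param design a [sample_design()] data.frame (default: the 2x3x2 study).
#' @return list with design, annotation, cpg_loci, ccgg_loci, truth,
#'   rrbs, rrhp, rnaseq (tables), and rna_size_factors.
#' @export
simulate_study <- function(config = sim_config(), design = sample_design()) {
  loci <- simulate_annotation(config)
  truth <- plant_effects(config, loci)
  rrbs <- simulate_rrbs(config, design, loci, truth)
  rrhp <- simulate_rrhp(config, design, loci, truth)
  rna <- simulate_rnaseq(config, design, loci, truth)
  list(design = design, annotation = loci$annotation,
       cpg_loci = loci$cpg_loci, ccgg_loci = loci$ccgg_loci,
       truth = truth, rrbs = rrbs$table, rrhp = rrhp$table,
       rnaseq = rna$table, rna_size_factors = rna$size_factors)
}
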