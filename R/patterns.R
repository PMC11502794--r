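# Combinatorial epigenetic patterns: each gene detected at a stage is
# assigned the subset of assays (RNA, 5mC, 5hmC) with at least one
# significant hit; patterns are tracked from the undifferentiated to the
# differentiated stage per environment, and reciprocal 5mC/5hmC switching
# between environments is called per gene.

# canonical single-stage pattern table (ids 1..7)
PATTERN_TABLE <- data.frame(
  pattern_id = 1:7,
  modalities = c("RNA", "5mC", "5hmC", "RNA+5mC", "RNA+5hmC", "5mC+5hmC",
                 "RNA+5mC+5hmC"),
  stringsAsFactors = FALSE
)

modality_key <- function(has_rna, has_5mc, has_5hmc) {
  paste(c("RNA", "5mC", "5hmC")[c(has_rna, has_5mc, has_5hmc)],
        collapse = "+")
}

#' Canonical pattern id of a modality subset
#'
#' 1 = RNA only, 2 = 5mC only, 3 = 5hmC only, 4 = RNA+5mC, 5 = RNA+5hmC,
#' 6 = 5mC+5hmC, 7 = all three.
#'
#' @param modalities character vector, subset of c("RNA", "5mC", "5hmC").
#' @return integer pattern id in 1..7.
#' @export
pattern_id <- function(modalities) {
  if (length(modalities) == 0) stop("modalities must be non-empty")
  if (!all(modalities %in% c("RNA", "5mC", "5hmC")))
    stop("unknown modality")
  key <- modality_key("RNA" %in% modalities, "5mC" %in% modalities,
                      "5hmC" %in% modalities)
  PATTERN_TABLE$pattern_id[match(key, PATTERN_TABLE$modalities)]
}

#' Per-gene modality patterns at one stage
#'
#' A gene is detected at a stage when it has at least one significant hit in
#' any assay for the stage's comparison; its pattern is the subset of assays
#' that detected it.
#'
#' @param gene_hits GeneHit data.frame (gene_id, modality, comparison,
#'   direction, n_loci) already restricted to one stage.
#' @param stage stage label carried through (e.g. "undiff", "diff_DM").
#' @return data.frame: gene_id, stage, modalities (e.g. "RNA+5mC"),
#'   pattern_id; one row per detected gene.
#' @export
modality_pattern <- function(gene_hits, stage) {
  if (nrow(gene_hits) == 0)
    return(data.frame(gene_id = character(), stage = character(),
                      modalities = character(), pattern_id = integer(),
                      stringsAsFactors = FALSE))
  mods <- split(gene_hits$modality, gene_hits$gene_id)
  keys <- vapply(mods, function(m) {
    modality_key("RNA" %in% m, "5mC" %in% m, "5hmC" %in% m)
  }, character(1))
  out <- data.frame(
    gene_id = names(mods), stage = stage, modalities = unname(keys),
    pattern_id = PATTERN_TABLE$pattern_id[match(keys,
                                                PATTERN_TABLE$modalities)],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(out$gene_id), ]
}

#' Classify pattern trackability across differentiation
#'
#' A gene is trackable in an environment when it carries a pattern both
#' undifferentiated and differentiated; genes detected at only one stage are
#' untrackable. Transition ids are a deterministic enumeration:
#' undiff-only genes keep their single-stage id (1..7), trackable genes get
#' 7 + (undiff_id - 1) * 7 + diff_id (8..56), and diff-only genes get
#' 56 + diff_id (57..63).
#'
#' @param undiff_patterns [modality_pattern()] result for the
#'   undifferentiated stage.
#' @param diff_patterns [modality_pattern()] result for the differentiated
#'   stage of this environment.
#' @param environment "DM" or "MacCM".
#' @return data.frame: gene_id, environment, undiff_pattern_id,
#'   diff_pattern_id (NA when absent), status, transition_id.
#' @export
classify_trackability <- function(undiff_patterns, diff_patterns,
                                  environment) {
  genes <- sort(union(undiff_patterns$gene_id, diff_patterns$gene_id))
  u <- undiff_patterns$pattern_id[match(genes, undiff_patterns$gene_id)]
  d <- diff_patterns$pattern_id[match(genes, diff_patterns$gene_id)]
  status <- ifelse(!is.na(u) & !is.na(d), "trackable",
                   ifelse(!is.na(u), "untrackable_undiff_only",
                          "untrackable_diff_only"))
  transition_id <- ifelse(
    status == "trackable", 7L + (u - 1L) * 7L + d,
    ifelse(status == "untrackable_undiff_only", u, 56L + d)
  )
  data.frame(
    gene_id = genes, environment = environment,
    undiff_pattern_id = u, diff_pattern_id = d,
    status = status, transition_id = as.integer(transition_id),
    stringsAsFactors = FALSE
  )
}

# per-gene direction of one modality in one environment's hits:
# "gain"/"loss", "ambiguous" when both recorded, NA when absent
gene_direction <- function(gene_hits, gene, modality) {
  dirs <- unique(gene_hits$direction[gene_hits$gene_id == gene &
                                       gene_hits$modality == modality])
  if (length(dirs) == 0) return(NA_character_)
  if (length(dirs) > 1) return("ambiguous")
  dirs
}

#' Detect reciprocal 5mC/5hmC switching between environments
#'
#' A gene switches when its 5mC and 5hmC changes point in opposite
#' directions under Mac-CM and in the reversed pairing under DM:
#' gain5mC_loss5hmC means (5mC gain, 5hmC loss) under Mac-CM with
#' (5mC loss, 5hmC gain) under DM; gain5hmC_loss5mC is the mirror. All
#' other configurations (including genes absent from either environment or
#' ambiguous directions) are "none".
#'
#' @param hits_dm,hits_maccm GeneHit data.frames for the differentiated
#'   stage under DM and Mac-CM.
#' @return data.frame: gene_id, class ("gain5mC_loss5hmC",
#'   "gain5hmC_loss5mC" or "none"); one row per gene with any 5mC/5hmC hit
#'   in both environments.
#' @export
detect_switch <- function(hits_dm, hits_maccm) {
  epi <- function(h) h[h$modality %in% c("5mC", "5hmC"), , drop = FALSE]
  hits_dm <- epi(hits_dm); hits_maccm <- epi(hits_maccm)
  genes <- sort(intersect(hits_dm$gene_id, hits_maccm$gene_id))
  if (length(genes) == 0)
    return(data.frame(gene_id = character(), class = character(),
                      stringsAsFactors = FALSE))
  cls <- vapply(genes, function(g) {
    dm_5mc <- gene_direction(hits_dm, g, "5mC")
    dm_5hmc <- gene_direction(hits_dm, g, "5hmC")
    mc_5mc <- gene_direction(hits_maccm, g, "5mC")
    mc_5hmc <- gene_direction(hits_maccm, g, "5hmC")
    if (anyNA(c(dm_5mc, dm_5hmc, mc_5mc, mc_5hmc))) return("none")
    if (identical(mc_5mc, "gain") && identical(mc_5hmc, "loss") &&
        identical(dm_5mc, "loss") && identical(dm_5hmc, "gain"))
      return("gain5mC_loss5hmC")
    if (identical(mc_5mc, "loss") && identical(mc_5hmc, "gain") &&
        identical(dm_5mc, "gain") && identical(dm_5hmc, "loss"))
      return("gain5hmC_loss5mC")
    "none"
  }, character(1))
  data.frame(gene_id = genes, class = unname(cls), stringsAsFactors = FALSE)
}

#' Summarize pattern tracking and switching
#'
#' @param track_records rbind of [classify_trackability()] results.
#' @param switch_calls rbind of [detect_switch()] results (may be empty).
#' @return list of count tables: `status_counts` (environment, status, n),
#'   `transition_counts` (environment, transition_id, n) and
#'   `switch_counts` (class, n). Totals equal the input record counts.
#' @export
summarize_patterns <- function(track_records, switch_calls = NULL) {
  if (is.null(track_records) || nrow(track_records) == 0) {
    status_counts <- data.frame(environment = character(),
                                status = character(), n = integer())
    transition_counts <- data.frame(environment = character(),
                                    transition_id = integer(), n = integer())
  } else {
    status_counts <- as.data.frame(
      table(environment = track_records$environment,
            status = track_records$status),
      responseName = "n", stringsAsFactors = FALSE
    )
    transition_counts <- as.data.frame(
      table(environment = track_records$environment,
            transition_id = track_records$transition_id),
      responseName = "n", stringsAsFactors = FALSE
    )
    transition_counts$transition_id <-
      as.integer(transition_counts$transition_id)
  }
  if (is.null(switch_calls) || nrow(switch_calls) == 0) {
    switch_counts <- data.frame(class = character(), n = integer(),
                                stringsAsFactors = FALSE)
  } else {
    switch_counts <- as.data.frame(table(class = switch_calls$class),
                                   responseName = "n",
                                   stringsAsFactors = FALSE)
  }
  rownames(status_counts) <- rownames(transition_counts) <- NULL
  list(status_counts = status_counts, transition_counts = transition_counts,
       switch_counts = switch_counts)
}
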