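# Locus-to-gene annotation: significant loci are extended by +/- 2 kb,
# overlapping extensions merged, and merged regions assigned to every gene
# body they overlap. All coordinates 0-based half-open (BED convention);
# GenomicRanges does the interval arithmetic.

loci_to_granges <- function(chrom, start0, end0) {
  # 0-based half-open [start0, end0) -> 1-based closed IRanges
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1, end = end0)
  )
}

#' Extend point loci and merge overlapping extensions
#'
#' Each locus at `pos` becomes the interval
#' [max(0, pos - flank), pos + flank + 1); overlapping or book-ended
#' intervals are merged. Source locus indices are preserved per merged
#' region.
#'
#' @param loci data.frame with columns chrom and pos (0-based bp).
#' @param flank extension in bp on each side (default 2000).
#' @param chrom_lengths optional named vector; loci extending past a
#'   chromosome end are clipped with a warning.
#' @return data.frame with chrom, start, end (0-based half-open), region_id,
#'   and a list-column `source_loci` of input row indices; disjoint and
#'   sorted within each chromosome.
#' @export
extend_and_merge <- function(loci, flank = 2000, chrom_lengths = NULL) {
  if (flank < 0) stop("flank must be >= 0")
  if (nrow(loci) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), region_id = integer()))
  start0 <- pmax(0, loci$pos - flank)
  end0 <- loci$pos + flank + 1
  if (!is.null(chrom_lengths)) {
    lim <- chrom_lengths[loci$chrom]
    over <- !is.na(lim) & (end0 > lim | loci$pos >= lim)
    if (any(over)) {
      warning(sum(over), " locus extension(s) clipped at chromosome end")
      end0 <- pmin(end0, ifelse(is.na(lim), end0, lim))
      start0 <- pmin(start0, end0 - 1)
    }
  }
  gr <- loci_to_granges(loci$chrom, start0, end0)
  merged <- GenomicRanges::reduce(gr)  # merges overlapping and book-ended
  hits <- GenomicRanges::findOverlaps(gr, merged)
  src <- split(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits))
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged) - 1,
    end = GenomicRanges::end(merged),
    region_id = seq_along(merged),
    stringsAsFactors = FALSE
  )
  out$source_loci <- unname(src[as.character(out$region_id)])
  out
}

#' Assign merged regions to overlapping genes
#'
#' A gene receives an assignment iff any merged region overlaps its
#' [start, end) body by at least 1 bp (half-open on both sides).
#'
#' @param regions output of [extend_and_merge()].
#' @param annotation gene annotation data.frame (gene_id, chrom, start, end,
#'   strand, is_tf).
#' @return data.frame with gene_id and region_id, one row per overlapping
#'   (gene, region) pair.
#' @export
assign_regions_to_genes <- function(regions, annotation) {
  if (nrow(regions) == 0)
    return(data.frame(gene_id = character(), region_id = integer()))
  unknown <- setdiff(unique(regions$chrom), unique(annotation$chrom))
  if (length(unknown) > 0)
    stop("regions on chromosome(s) absent from the annotation: ",
         paste(unknown, collapse = ", "))
  rgr <- loci_to_granges(regions$chrom, regions$start, regions$end)
  ggr <- loci_to_granges(annotation$chrom, annotation$start, annotation$end)
  hits <- GenomicRanges::findOverlaps(rgr, ggr)
  data.frame(
    gene_id = annotation$gene_id[S4Vectors::subjectHits(hits)],
    region_id = regions$region_id[S4Vectors::queryHits(hits)],
    stringsAsFactors = FALSE
  )
}

#' Gene hits from significant loci of one modality and comparison
#'
#' Extends significant loci, merges, assigns regions to genes and derives
#' per-gene direction from the signs of the contributing locus effects:
#' majority sign wins; an exact tie records both a gain and a loss hit.
#' `n_loci` counts the contributing loci of the recorded direction.
#'
#' @param sig_loci data.frame of significant loci with chrom, pos and an
#'   `effect` column (signed delta or log2fc).
#' @param annotation gene annotation data.frame.
#' @param modality one of "5mC", "5hmC" (extension applies) — RNA hits are
#'   built by [gene_hits_from_deg()] instead.
#' @param comparison comparison label carried through.
#' @param flank extension in bp.
#' @param chrom_lengths optional, passed to [extend_and_merge()].
#' @return GeneHit data.frame: gene_id, modality, comparison, direction
#'   ("gain"/"loss"), n_loci.
#' @export
gene_hits_from_loci <- function(sig_loci, annotation, modality, comparison,
                                flank = 2000, chrom_lengths = NULL) {
  empty <- data.frame(gene_id = character(), modality = character(),
                      comparison = character(), direction = character(),
                      n_loci = integer(), stringsAsFactors = FALSE)
  if (nrow(sig_loci) == 0) return(empty)
  regions <- extend_and_merge(sig_loci, flank = flank,
                              chrom_lengths = chrom_lengths)
  pairs <- assign_regions_to_genes(regions, annotation)
  if (nrow(pairs) == 0) return(empty)
  rows <- lapply(split(pairs$region_id, pairs$gene_id), function(rids) {
    idx <- unique(unlist(regions$source_loci[match(rids, regions$region_id)]))
    signs <- sign(sig_loci$effect[idx])
    n_gain <- sum(signs > 0); n_loss <- sum(signs < 0)
    if (n_gain > n_loss) {
      data.frame(direction = "gain", n_loci = n_gain)
    } else if (n_loss > n_gain) {
      data.frame(direction = "loss", n_loci = n_loss)
    } else {
      data.frame(direction = c("gain", "loss"), n_loci = c(n_gain, n_loss))
    }
  })
  out <- do.call(rbind, rows)
  out$gene_id <- rep(names(rows), vapply(rows, nrow, integer(1)))
  out$modality <- modality
  out$comparison <- comparison
  out <- out[out$n_loci >= 1,
             c("gene_id", "modality", "comparison", "direction", "n_loci")]
  rownames(out) <- NULL
  out
}

#' Gene hits from significant DEGs
#'
#' RNA results are gene-level already and bypass extension; direction is
#' the sign of the log2 fold change.
#'
#' @param deg_result [nb_wald_test()] result whose feature_id is a gene_id.
#' @param comparison comparison label carried through.
#' @return GeneHit data.frame as in [gene_hits_from_loci()].
#' @export
gene_hits_from_deg <- function(deg_result, comparison) {
  sig <- deg_result[deg_result$significant & deg_result$log2fc != 0, ,
                    drop = FALSE]
  data.frame(
    gene_id = sig$feature_id, modality = "RNA", comparison = comparison,
    direction = ifelse(sig$log2fc > 0, "gain", "loss"),
    n_loci = 1L, stringsAsFactors = FALSE
  )
}

#' Restrict gene hits to transcription factors
#'
#' @param hits GeneHit data.frame.
#' @param annotation gene annotation with an is_tf column.
#' @return the subset of `hits` whose gene is flagged TF, counts preserved.
#' @export
filter_tfs <- function(hits, annotation) {
  tf_genes <- annotation$gene_id[annotation$is_tf]
  out <- hits[hits$gene_id %in% tf_genes, , drop = FALSE]
  rownames(out) <- NULL
  out
}
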