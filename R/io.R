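# Plain-text interchange: TSV count tables, BED6+1 annotation, JSON truth.
# Coordinates are 0-based half-open everywhere (BED convention).

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_plain <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write / read a methylation count table
#'
#' TSV with columns chrom, pos (0-based), strand, then per-sample
#' `meth_<id>` and `total_<id>`.
#'
#' @param table,path table and file path.
#' @return the path (write) or the table (read).
#' @export
write_meth_table <- function(table, path) write_tsv_plain(table, path)

#' @rdname write_meth_table
#' @export
read_meth_table <- function(path) {
  tab <- read_tsv_plain(path)
  stopifnot(all(c("chrom", "pos", "strand") %in% names(tab)))
  tab
}

#' Write / read a feature-by-sample count matrix table
#'
#' RRHP tables carry chrom, pos, strand key columns; RNA tables carry
#' gene_id. Remaining columns are per-sample counts.
#'
#' @param table,path table and file path.
#' @return the path (write) or the table (read).
#' @export
write_count_table <- function(table, path) write_tsv_plain(table, path)

#' @rdname write_count_table
#' @export
read_count_table <- function(path) read_tsv_plain(path)

#' Write / read a gene annotation as BED6+1
#'
#' Columns: chrom, start, end, name (gene_id), score (0), strand, is_tf
#' (0/1). No header, per BED convention.
#'
#' @param annotation,path annotation data.frame and file path.
#' @return the path (write) or the annotation data.frame (read).
#' @export
write_annotation_bed <- function(annotation, path) {
  bed <- data.frame(
    chrom = annotation$chrom, start = annotation$start, end = annotation$end,
    name = annotation$gene_id, score = 0L, strand = annotation$strand,
    is_tf = as.integer(annotation$is_tf)
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation_bed
#' @export
read_annotation_bed <- function(path) {
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  stopifnot(ncol(bed) >= 7)
  data.frame(
    gene_id = bed[[4]], chrom = bed[[1]], start = bed[[2]], end = bed[[3]],
    strand = bed[[6]], is_tf = as.logical(bed[[7]]), stringsAsFactors = FALSE
  )
}

#' Write / read planted truth as JSON
#'
#' @param truth planted-truth data.frame (see [plant_effects()]).
#' @param size_factors optional named per-sample library-size factors.
#' @param path file path.
#' @return the path (write) or a list with `truth` and `size_factors` (read).
#' @export
write_truth_json <- function(truth, path, size_factors = NULL) {
  obj <- list(truth = truth)
  if (!is.null(size_factors))
    obj$size_factors <- as.list(size_factors)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  truth <- as.data.frame(obj$truth, stringsAsFactors = FALSE)
  sf <- if (!is.null(obj$size_factors)) unlist(obj$size_factors) else NULL
  list(truth = truth, size_factors = sf)
}

#' Write / read a sample design table
#'
#' @param design,path design data.frame and file path.
#' @return the path (write) or the design (read).
#' @export
write_design <- function(design, path) write_tsv_plain(design, path)

#' @rdname write_design
#' @export
read_design <- function(path) read_tsv_plain(path)
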