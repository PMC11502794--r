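# Exploratory summaries: PCA on feature-centered log2 counts, average-
# linkage hierarchical clustering of samples, and the delta-delta-Ct qPCR
# fold-change utility.

#' Principal-component embedding of samples
#'
#' Feature-centered singular-value decomposition (via [stats::prcomp()]) of
#' a features-by-samples matrix; count matrices should be log2(x + 1)
#' transformed upstream (see [normalized_log2()]). Coordinates are
#' reproducible up to a sign flip per component.
#'
#' @param mat numeric matrix, features x samples.
#' @param n_components number of components to keep.
#' @return list with `coordinates` (samples x components) and
#'   `explained_variance` (fraction per component, non-increasing).
#' @export
pca_embed <- function(mat, n_components = 2) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("need >= 2 samples")
  if (n_components > min(dim(mat)))
    stop("n_components exceeds matrix rank bound")
  pc <- stats::prcomp(t(mat), center = TRUE, scale. = FALSE)
  k <- seq_len(n_components)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(coordinates = pc$x[, k, drop = FALSE],
       explained_variance = ev[k])
}

#' Average-linkage hierarchical clustering of samples
#'
#' Euclidean distances between columns, agglomerated with average linkage
#' (UPGMA). Ties break deterministically by index order (as in
#' [stats::hclust()]).
#'
#' @param mat numeric matrix, features x samples (columns are clustered).
#' @return the [stats::hclust()] object (merge, height, order, labels).
#' @export
hierarchical_cluster <- function(mat) {
  mat <- as.matrix(mat)
  if (!is.numeric(mat)) stop("matrix must be numeric")
  if (ncol(mat) < 2) stop("need >= 2 columns")
  stats::hclust(stats::dist(t(mat), method = "euclidean"),
                method = "average")
}

#' Delta-delta-Ct relative quantification
#'
#' Fold change of a target gene in a sample relative to a calibrator, each
#' normalized to a reference gene:
#' 2^-((Ct_target_sample - Ct_ref_sample) -
#'     (Ct_target_calibrator - Ct_ref_calibrator)).
#'
#' @param ct_target_sample,ct_ref_sample Ct of target and reference gene in
#'   the sample of interest.
#' @param ct_target_calibrator,ct_ref_calibrator Ct of target and reference
#'   gene in the calibrator sample.
#' @return the fold change (vectorized).
#' @export
ddct_fold_change <- function(ct_target_sample, ct_ref_sample,
                             ct_target_calibrator, ct_ref_calibrator) {
  cts <- cbind(ct_target_sample, ct_ref_sample, ct_target_calibrator,
               ct_ref_calibrator)
  if (any(!is.finite(cts))) stop("Ct values must be finite")
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_calibrator - ct_ref_calibrator)
  2^(-ddct)
}
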