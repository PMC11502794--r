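# Differential methylation (DML) calling from per-CpG methylated/total read
# counts: beta-binomial model with empirical-Bayes dispersion shrinkage and
# a Wald test on the group methylation difference.

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' returned in the input order. Shared by the methylation and count-based
#' tests.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same length and order as `p`.
#' @export
benjamini_hochberg <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# split a methylation table into meth/total matrices for given samples
meth_matrices <- function(table, samples) {
  mcols <- paste0("meth_", samples)
  tcols <- paste0("total_", samples)
  missing <- c(mcols, tcols)[!c(mcols, tcols) %in% names(table)]
  if (length(missing) > 0)
    stop("methylation table lacks columns: ", paste(missing, collapse = ", "))
  meth <- as.matrix(table[, mcols, drop = FALSE])
  total <- as.matrix(table[, tcols, drop = FALSE])
  colnames(meth) <- colnames(total) <- samples
  if (any(meth > total)) stop("methylated counts exceed totals")
  list(meth = meth, total = total)
}

#' Per-locus beta-binomial dispersion with shrinkage
#'
#' Method-of-moments per-locus dispersion (floored at 1e-4), shrunk toward
#' the 10 percent trimmed mean across loci with weight n_l / (n_l + k),
#' where n_l is the number of samples passing the coverage floor at the
#' locus and k = 4. Estimates are capped at 0.5.
#'
#' @param meth,total integer matrices (loci x samples) of methylated and
#'   total read counts, identical dimensions.
#' @param group_labels factor/character vector over columns with two levels.
#' @param min_coverage samples with total below this do not contribute.
#' @return list with `phi` (shrunk per-locus dispersion), `phi_raw`
#'   (method-of-moments estimates) and `phi_prior` (trimmed mean).
#' @export
estimate_locus_dispersion <- function(meth, total, group_labels,
                                      min_coverage = 5) {
  group_labels <- as.factor(group_labels)
  if (nlevels(group_labels) != 2) stop("exactly two groups required")
  if (any(table(group_labels) < 2)) stop("each group needs >= 2 samples")
  nl <- nrow(meth)
  phi_raw <- rep(1e-4, nl)
  n_pass <- integer(nl)
  for (i in seq_len(nl)) {
    use <- total[i, ] >= min_coverage
    n_pass[i] <- sum(use)
    num <- 0; den_df <- 0
    bin_part <- numeric(0); scale_part <- numeric(0)
    for (g in levels(group_labels)) {
      sel <- use & group_labels == g
      if (sum(sel) < 2) next
      c_s <- total[i, sel]
      p_s <- meth[i, sel] / c_s
      pbar <- sum(meth[i, sel]) / sum(c_s)
      num <- num + sum((p_s - pbar)^2)
      den_df <- den_df + (sum(sel) - 1)
      bin_part <- c(bin_part, pbar * (1 - pbar) / c_s)
      scale_part <- c(scale_part, pbar * (1 - pbar) * (c_s - 1) / c_s)
    }
    if (den_df == 0 || mean(scale_part) <= 0) next
    v <- num / den_df
    phi_raw[i] <- (v - mean(bin_part)) / mean(scale_part)
  }
  phi_raw <- pmin(pmax(phi_raw, 1e-4), 0.5)
  phi_prior <- mean(phi_raw, trim = 0.1)
  w <- n_pass / (n_pass + 4)
  phi <- pmin(pmax(w * phi_raw + (1 - w) * phi_prior, 1e-4), 0.5)
  list(phi = phi, phi_raw = phi_raw, phi_prior = phi_prior)
}

#' Differential methylation test (DML calling)
#'
#' For each locus covered by at least `min_coverage` reads in every sample
#' of the comparison, estimates per-group methylation as the
#' coverage-weighted proportion, computes a Wald statistic on the group
#' difference with beta-binomial variance
#' mu(1-mu)(1 + (c-1) phi) summed over samples by the delta method, adjusts
#' two-sided normal p-values by Benjamini-Hochberg, and flags loci
#' significant when padj < alpha and |delta| >= min_delta (the
#' at-least-10-percent-change rule by default).
#'
#' @param table methylation count table (chrom, pos, strand, meth_*/total_*).
#' @param group_labels named vector mapping sample ids to two group levels;
#'   names select the samples entering the comparison. The first level (by
#'   factor order) is group A; delta = mu_B - mu_A.
#' @param alpha adjusted-p-value threshold.
#' @param min_delta minimum absolute methylation difference.
#' @param min_coverage required total reads per sample at a locus.
#' @return data.frame: chrom, pos, strand, mu_A, mu_B, delta, se, wald_z,
#'   p, padj, significant.
#' @export
dml_test <- function(table, group_labels, alpha = 0.05, min_delta = 0.10,
                     min_coverage = 5) {
  samples <- names(group_labels)
  if (is.null(samples)) stop("group_labels must be named by sample id")
  grp <- as.factor(unname(group_labels))
  if (nlevels(grp) != 2) stop("exactly two groups required")
  if (any(tabulate(grp) < 2)) stop("each group needs >= 2 samples")
  mm <- meth_matrices(table, samples)
  keep <- rowSums(mm$total >= min_coverage) == length(samples)
  if (!any(keep)) stop("no locus passes the coverage floor in every sample")
  meth <- mm$meth[keep, , drop = FALSE]
  total <- mm$total[keep, , drop = FALSE]
  disp <- estimate_locus_dispersion(meth, total, grp,
                                    min_coverage = min_coverage)
  a_sel <- grp == levels(grp)[1]
  b_sel <- grp == levels(grp)[2]

  group_stats <- function(sel) {
    msum <- rowSums(meth[, sel, drop = FALSE])
    tsum <- rowSums(total[, sel, drop = FALSE])
    mu <- msum / tsum
    # variance evaluated at a continuity-stabilised mean so degenerate
    # all-0/all-1 groups keep a positive standard error
    mu_v <- (msum + 0.5) / (tsum + 1)
    vnum <- rowSums(total[, sel, drop = FALSE] *
                      (1 + (total[, sel, drop = FALSE] - 1) * disp$phi))
    list(mu = mu, var = mu_v * (1 - mu_v) * vnum / tsum^2)
  }
  A <- group_stats(a_sel)
  B <- group_stats(b_sel)
  delta <- B$mu - A$mu
  se <- sqrt(A$var + B$var)
  z <- ifelse(delta == 0, 0, delta / se)
  p <- 2 * stats::pnorm(-abs(z))
  padj <- benjamini_hochberg(p)
  out <- data.frame(
    chrom = table$chrom[keep], pos = table$pos[keep],
    strand = table$strand[keep],
    mu_A = A$mu, mu_B = B$mu, delta = delta, se = se, wald_z = z,
    p = p, padj = padj,
    significant = padj < alpha & abs(delta) >= min_delta,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
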