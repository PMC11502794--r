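# Negative-binomial differential testing for count features: RRHP
# strand-specific CCGG tag counts (DHML) and RNA gene counts (DEG).
# Median-of-ratios normalization, moment dispersion estimates shrunk toward
# a fitted mean-dispersion trend, Wald test, BH adjustment, and the
# padj < 0.05 / at-least-2-fold significance rule.

#' Median-of-ratios size factors
#'
#' Per sample, the median over all-positive features of count divided by the
#' feature's geometric mean across samples; factors are rescaled to
#' geometric mean 1. If no feature is positive in every sample, total-count
#' ratios are used instead.
#'
#' @param counts integer matrix, features x samples.
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(colSums(counts) == 0))
    stop("cannot normalize: a sample has all-zero counts")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (any(pos)) {
    lc <- log(counts[pos, , drop = FALSE])
    logratio <- lc - rowMeans(lc)
    sf <- exp(apply(logratio, 2, stats::median))
  } else {
    sf <- colSums(counts)
  }
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- colnames(counts)
  sf
}

#' Per-feature NB dispersion with trend shrinkage
#'
#' Method-of-moments dispersion on normalized counts (floored at 1e-8),
#' shrunk toward a fitted mean-dispersion trend d(mu) = a/mu + b (least
#' squares on the log scale) with weight w = nu / (nu + 4), nu = n - 2 the
#' residual degrees of freedom of the raw estimate. Because the log-scale
#' fit targets the (skew-biased) typical raw estimate, the fitted trend is
#' moment-matched to the mean of the raw estimates before shrinkage; the
#' rescaling factor is 1 when the raw estimates are noiseless. With fewer
#' than 10 usable features the trend falls back to the global mean
#' dispersion, with a warning.
#'
#' @param counts integer matrix, features x samples.
#' @param sf per-sample size factors (see [size_factors()]).
#' @param group_labels two-level factor/character over columns.
#' @return list with `dispersion` (shrunk), `raw`, and `trend` (fitted
#'   trend value per feature).
#' @export
nb_dispersion <- function(counts, sf, group_labels) {
  counts <- as.matrix(counts)
  group_labels <- as.factor(group_labels)
  if (nlevels(group_labels) != 2) stop("exactly two groups required")
  if (any(tabulate(group_labels) < 2)) stop("each group needs >= 2 samples")
  y <- sweep(counts, 2, sf, "/")
  n <- ncol(y)
  m <- rowMeans(y)
  # pooled within-group variance
  num <- 0; df <- 0
  for (g in levels(group_labels)) {
    sel <- group_labels == g
    yg <- y[, sel, drop = FALSE]
    num <- num + rowSums((yg - rowMeans(yg))^2)
    df <- df + (sum(sel) - 1)
  }
  v <- num / df
  raw <- ifelse(m > 0, (v - m * mean(1 / sf)) / m^2, 1e-8)
  raw <- pmax(raw, 1e-8)

  usable <- m > 0 & raw > 1e-8
  if (sum(usable) < 10) {
    warning("fewer than 10 usable features; trend falls back to the ",
            "global mean dispersion")
    trend_fun <- function(mu) rep(mean(raw), length(mu))
  } else {
    mu_u <- m[usable]; d_u <- raw[usable]
    obj <- function(par) {
      a <- exp(par[1]); b <- exp(par[2])
      sum((log(d_u) - log(a / mu_u + b))^2)
    }
    init <- c(log(max(stats::median(d_u * mu_u), 1e-6)),
              log(max(stats::median(d_u), 1e-6)))
    fit <- stats::optim(init, obj, method = "Nelder-Mead")
    a_hat <- exp(fit$par[1]); b_hat <- exp(fit$par[2])
    raw_fit <- function(mu) ifelse(mu > 0, a_hat / mu + b_hat, b_hat)
    # moment-match the log-fitted trend to the mean raw estimate
    corr <- mean(d_u) / mean(raw_fit(mu_u))
    trend_fun <- function(mu) corr * raw_fit(mu)
  }
  trend <- trend_fun(m)
  nu <- max(n - 2, 1)
  w <- nu / (nu + 4)
  disp <- pmax(w * raw + (1 - w) * trend, 1e-8)
  list(dispersion = disp, raw = raw, trend = trend, df = nu, weight = w)
}

#' Negative-binomial Wald test
#'
#' Features with zero counts in every sample are excluded. Group means are
#' taken on normalized counts; the reported log2 fold change (group B over
#' group A) adds a 0.5 pseudo-count to each group mean. The Wald statistic
#' compares log group means with a delta-method standard error from the NB
#' variance mu + d mu^2; two-sided normal p-values are BH-adjusted and a
#' feature is significant when padj < alpha and |log2fc| >= lfc_threshold
#' (the at-least-2-fold rule by default).
#'
#' @param counts integer matrix, features x samples (rownames = feature ids).
#' @param group_labels named vector mapping sample ids (columns of `counts`)
#'   to two group levels; first level is group A.
#' @param alpha adjusted-p-value threshold.
#' @param lfc_threshold minimum |log2 fold change|.
#' @return data.frame: feature_id, base_mean, log2fc, se, wald_z, p, padj,
#'   significant.
#' @export
nb_wald_test <- function(counts, group_labels, alpha = 0.05,
                         lfc_threshold = 1) {
  samples <- names(group_labels)
  if (is.null(samples)) stop("group_labels must be named by sample id")
  counts <- as.matrix(counts)[, samples, drop = FALSE]
  grp <- as.factor(unname(group_labels))
  if (nlevels(grp) != 2) stop("exactly two groups required")
  if (any(tabulate(grp) < 2)) stop("each group needs >= 2 samples")
  ids <- rownames(counts)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(counts)))
  keep <- rowSums(counts) > 0
  if (!any(keep)) stop("no feature with nonzero counts")
  counts <- counts[keep, , drop = FALSE]
  ids <- ids[keep]

  sf <- size_factors(counts)
  nd <- nb_dispersion(counts, sf, grp)
  # plug-in precision correction: the shrunk dispersion enters the Wald
  # variance as an estimate with effective df nu / w^2 (Jensen)
  nu_eff <- nd$df / nd$weight^2
  disp <- nd$dispersion * if (nu_eff > 2) nu_eff / (nu_eff - 2) else 1
  y <- sweep(counts, 2, sf, "/")
  a_sel <- grp == levels(grp)[1]
  b_sel <- grp == levels(grp)[2]

  group_stats <- function(sel) {
    n_g <- sum(sel)
    m <- rowMeans(y[, sel, drop = FALSE])
    # zero group means are floored for the test statistic only
    m_t <- pmax(m, 0.5 / n_g)
    v <- (m_t * sum(1 / sf[sel]) + disp * m_t^2 * n_g) / n_g^2
    list(m = m, m_t = m_t, var = v)
  }
  A <- group_stats(a_sel)
  B <- group_stats(b_sel)
  log2fc <- log2((B$m + 0.5) / (A$m + 0.5))
  se_ln <- sqrt(A$var / A$m_t^2 + B$var / B$m_t^2)
  z <- (log(B$m_t) - log(A$m_t)) / se_ln
  p <- 2 * stats::pnorm(-abs(z))
  padj <- benjamini_hochberg(p)
  out <- data.frame(
    feature_id = ids,
    base_mean = rowMeans(y),
    log2fc = log2fc,
    se = se_ln / log(2),
    wald_z = z,
    p = p, padj = padj,
    significant = padj < alpha & abs(log2fc) >= lfc_threshold,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' DHML calling on strand-specific RRHP tag counts
#'
#' Runs the NB Wald machinery with features keyed by (chrom, pos, strand);
#' the two strands of a CCGG site are always tested separately.
#'
#' @param tag_table data.frame with chrom, pos, strand and per-sample counts.
#' @inheritParams nb_wald_test
#' @return [nb_wald_test()] result with chrom, pos, strand columns restored.
#' @export
call_dhml <- function(tag_table, group_labels, alpha = 0.05,
                      lfc_threshold = 1) {
  key <- paste0(tag_table$chrom, ":", tag_table$pos, ":", tag_table$strand)
  if (anyDuplicated(key)) stop("duplicate (chrom, pos, strand) loci")
  samples <- names(group_labels)
  counts <- as.matrix(tag_table[, samples, drop = FALSE])
  rownames(counts) <- key
  res <- nb_wald_test(counts, group_labels, alpha = alpha,
                      lfc_threshold = lfc_threshold)
  idx <- match(res$feature_id, key)
  cbind(
    data.frame(chrom = tag_table$chrom[idx], pos = tag_table$pos[idx],
               strand = tag_table$strand[idx], stringsAsFactors = FALSE),
    res
  )
}

#' Normalized log2 count matrix
#'
#' log2(x + 1) on size-factor-normalized counts; the transform used upstream
#' of PCA and hierarchical clustering.
#'
#' @param counts integer matrix, features x samples.
#' @param sf optional size factors; computed by [size_factors()] if missing.
#' @return numeric matrix of the same dimensions.
#' @export
normalized_log2 <- function(counts, sf = NULL) {
  counts <- as.matrix(counts)
  if (is.null(sf)) sf <- size_factors(counts)
  log2(sweep(counts, 2, sf, "/") + 1)
}
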