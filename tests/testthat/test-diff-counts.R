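test_that("size factors match hand-computed medians of ratios", {
  m <- matrix(c(10, 20, 30, 40), 4, 2, dimnames = list(NULL, c("s1", "s2")))
  m[, 2] <- m[, 1]
  expect_equal(unname(size_factors(m)), c(1, 1))

  a <- c(5, 10, 20, 40)
  m2 <- cbind(s1 = a, s2 = 2 * a)
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)))

  # order-free: permuting feature rows changes nothing
  set.seed(2)
  m3 <- matrix(rpois(40, 20) + 1, 10, 4)
  expect_equal(size_factors(m3), size_factors(m3[sample(10), ]))

  expect_error(size_factors(cbind(a = c(0, 0), b = c(1, 2))), "all-zero")
})

test_that("NB dispersion shrinkage: fixed point, Poisson floor, recovery", {
  # identical features: the shrunk value equals the common raw estimate
  row <- c(5, 30, 10, 6, 28, 12)
  m <- matrix(rep(row, each = 50), 50, 6)
  grp <- factor(rep(c("A", "B"), each = 3))
  nd <- nb_dispersion(m, rep(1, 6), grp)
  expect_equal(length(unique(round(nd$raw, 12))), 1)
  expect_equal(nd$dispersion, nd$raw, tolerance = 1e-3)

  # Poisson counts: dispersions collapse toward the floor
  set.seed(14)
  mp <- matrix(rpois(500 * 8, 50), 500, 8)
  ndp <- suppressWarnings(
    nb_dispersion(mp, rep(1, 8), factor(rep(c("A", "B"), each = 4)))
  )
  expect_lt(mean(ndp$dispersion), 0.02)

  # planted dispersion 0.1, 500 features, n = 4 per group
  set.seed(15)
  mu <- rlnorm(500, log(100), 1)
  mk <- matrix(rnbinom(500 * 8, mu = rep(mu, 8), size = 10), 500, 8)
  ndk <- nb_dispersion(mk, rep(1, 8), factor(rep(c("A", "B"), each = 4)))
  expect_gt(mean(ndk$dispersion), 0.05)
  expect_lt(mean(ndk$dispersion), 0.2)
})

test_that("nb_wald_test enforces both significance thresholds", {
  set.seed(4)
  counts <- matrix(rpois(60 * 6, 40), 60, 6,
                   dimnames = list(NULL, names(two_group_labels(3))))
  gl <- two_group_labels(3)
  # equal groups: tiny fold changes, nothing significant
  res <- nb_wald_test(counts, gl)
  expect_false(any(res$significant))

  # a strong but sub-2-fold effect: padj can be small, never significant
  counts2 <- counts
  counts2[1:10, 4:6] <- matrix(rpois(30, 40 * 1.45), 10, 3)
  big <- rbind(counts2, matrix(rep(c(20000L, 28000L), each = 30 * 3),
                               30, 6))  # 1.4-fold at huge counts
  colnames(big) <- names(gl)
  res2 <- nb_wald_test(big, gl)
  sub2 <- res2$padj < 0.05 & abs(res2$log2fc) < 1
  expect_false(any(res2$significant[sub2]))
  expect_true(all(res2$significant == (res2$padj < 0.05 &
                                         abs(res2$log2fc) >= 1)))
})

test_that("all-zero features are dropped and results are order-invariant", {
  set.seed(5)
  counts <- matrix(rpois(50 * 4, 30), 50, 4,
                   dimnames = list(paste0("f", 1:50),
                                   names(two_group_labels())))
  counts[7, ] <- 0L
  gl <- two_group_labels()
  res <- nb_wald_test(counts, gl)
  expect_false("f7" %in% res$feature_id)
  expect_equal(nrow(res), 49)

  perm <- sample(50)
  res_p <- nb_wald_test(counts[perm, ], gl)
  res_p <- res_p[match(res$feature_id, res_p$feature_id), ]
  rownames(res_p) <- NULL
  expect_equal(res, res_p)
})

test_that("log2 fold changes are invariant to per-sample rescaling", {
  set.seed(6)
  counts <- matrix(rnbinom(200 * 6, mu = 50, size = 10), 200, 6,
                   dimnames = list(NULL, names(two_group_labels(3))))
  gl <- two_group_labels(3)
  res <- nb_wald_test(counts, gl)
  # per-sample scaling with geometric mean 1 (the component median-of-ratios
  # normalization can identify)
  cs <- c(0.5, 1, 2, 0.8, 1.25, 1)
  cs <- cs / exp(mean(log(cs)))
  scaled <- sweep(counts, 2, cs, "*")
  res_s <- nb_wald_test(scaled, gl)
  expect_equal(res_s$log2fc, res$log2fc, tolerance = 1e-9)
})

test_that("DHML calling keeps strands separate and symmetric", {
  set.seed(8)
  ns <- names(two_group_labels(3))
  tab <- data.frame(chrom = "chr1", pos = rep(seq(1000, 20000, 1000), 2),
                    strand = rep(c("+", "-"), each = 20),
                    stringsAsFactors = FALSE)
  counts <- matrix(rnbinom(40 * 6, mu = 30, size = 10), 40, 6,
                   dimnames = list(NULL, ns))
  # plant a strong effect on the + strand of pos 1000 only
  counts[1, 4:6] <- counts[1, 4:6] * 8L
  tab <- cbind(tab, as.data.frame(counts))
  gl <- two_group_labels(3)
  res <- call_dhml(tab, gl)
  sig <- res[res$significant, ]
  expect_true(all(sig$strand == "+" | sig$pos != 1000))
  expect_equal(sum(sig$pos == 1000 & sig$strand == "+"), 1)
  expect_equal(sum(sig$pos == 1000 & sig$strand == "-"), 0)

  # swapping strand labels swaps them in the output, nothing else
  tab2 <- tab
  tab2$strand <- ifelse(tab$strand == "+", "-", "+")
  res2 <- call_dhml(tab2, gl)
  expect_equal(res2$log2fc, res$log2fc)
  expect_equal(res2$strand, ifelse(res$strand == "+", "-", "+"))

  dup <- rbind(tab, tab[1, ])
  expect_error(call_dhml(dup, gl), "duplicate")
})

test_that("NB test agrees with DESeq2 on a shared data set", {
  skip_if_not_installed("DESeq2")
  set.seed(9)
  n <- 3
  ns <- names(two_group_labels(n))
  mu <- rlnorm(200, log(80), 1)
  counts <- matrix(rnbinom(200 * 2 * n, mu = rep(mu, 2 * n), size = 10),
                   200, 2 * n, dimnames = list(paste0("g", 1:200), ns))
  idx <- 1:30
  counts[idx, (n + 1):(2 * n)] <-
    matrix(rnbinom(30 * n, mu = rep(mu[idx] * 4, n), size = 10), 30, n)
  gl <- two_group_labels(n)
  res <- nb_wald_test(counts, gl)

  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      countData = counts,
      colData = data.frame(group = unname(gl)),
      design = ~group
    )
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    dres <- DESeq2::results(dds, contrast = c("group", "B", "A"))
  })
  shared <- intersect(res$feature_id, rownames(dres))
  ours <- res$p[match(shared, res$feature_id)]
  theirs <- dres$pvalue[match(shared, rownames(dres))]
  ok <- is.finite(ours) & is.finite(theirs)
  expect_gte(cor(ours[ok], theirs[ok], method = "spearman"), 0.9)
  # fold-change direction agrees for clear calls
  clear <- ok & dres$padj[match(shared, rownames(dres))] < 0.01
  expect_true(all(sign(res$log2fc[match(shared, res$feature_id)][clear]) ==
                    sign(dres$log2FoldChange[match(shared,
                                                   rownames(dres))][clear])))
})
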