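# Independent brute-force oracles used to check the package's operations.
# These deliberately use naive algorithms, not the implementation under test.

# step-up BH by direct definition: padj_i = min over k with p_(k) >= p_(i)
# of m * p_(k) / k, capped at 1
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  padj <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(ord == i)
    cand <- vapply(rank_i:m, function(k) m * p[ord[k]] / k, numeric(1))
    padj[i] <- min(1, min(cand))
  }
  padj
}

# quadratic union of half-open intervals [s, e): returns merged set sorted
interval_union_bruteforce <- function(start, end) {
  n <- length(start)
  merged <- cbind(start, end)
  repeat {
    again <- FALSE
    i <- 1
    while (i <= nrow(merged)) {
      j <- i + 1
      while (j <= nrow(merged)) {
        # overlap or book-ended
        if (merged[i, 1] <= merged[j, 2] && merged[j, 1] <= merged[i, 2]) {
          merged[i, ] <- c(min(merged[i, 1], merged[j, 1]),
                           max(merged[i, 2], merged[j, 2]))
          merged <- merged[-j, , drop = FALSE]
          again <- TRUE
        } else j <- j + 1
      }
      i <- i + 1
    }
    if (!again) break
  }
  merged[order(merged[, 1]), , drop = FALSE]
}

# all-pairs overlap of half-open intervals
overlap_bruteforce <- function(r_start, r_end, g_start, g_end) {
  hits <- NULL
  for (i in seq_along(r_start)) {
    for (j in seq_along(g_start)) {
      if (r_start[i] < g_end[j] && g_start[j] < r_end[i])
        hits <- rbind(hits, c(i, j))
    }
  }
  hits
}

# exhaustive average-linkage (UPGMA) agglomeration on a distance matrix;
# returns successive merge heights and the partition sizes at each step
agglom_bruteforce <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# small deterministic methylation table fixture
toy_meth_table <- function(meth, total, chrom = "chr1") {
  samples <- colnames(meth)
  tab <- data.frame(chrom = chrom, pos = seq_len(nrow(meth)) * 100,
                    strand = "+", stringsAsFactors = FALSE)
  for (s in samples) {
    tab[[paste0("meth_", s)]] <- meth[, s]
    tab[[paste0("total_", s)]] <- total[, s]
  }
  tab
}

two_group_labels <- function(n_per_group = 2, prefix = c("a", "b")) {
  ids <- c(paste0(prefix[1], seq_len(n_per_group)),
           paste0(prefix[2], seq_len(n_per_group)))
  stats::setNames(factor(rep(c("A", "B"), each = n_per_group)), ids)
}
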