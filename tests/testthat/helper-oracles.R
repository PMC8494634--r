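# Independent oracles used to cross-check package implementations.  These
# deliberately use brute force / enumeration and share no code with R/.

# Quadratic brute-force version of the iterative overlap merge: scan the
# ranked list, keep a peak iff it overlaps no previously kept peak.
brute_merge_oracle <- function(peaks) {
  df <- as.data.frame(peaks)
  df <- df[order(-df$spm, df$chrom, df$start), , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(df))) {
    ok <- TRUE
    for (j in kept) {
      if (df$chrom[i] == df$chrom[j] &&
          df$start[i] < df$end[j] && df$start[j] < df$end[i]) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  out <- df[kept, , drop = FALSE]
  out[order(out$chrom, out$start), c("chrom", "start", "end")]
}

# Full-arrangement enumeration of the Mann-Whitney U null for sizes n1, n2:
# probability of each achievable U over all choose(n1+n2, n1) rank splits.
enum_u_null <- function(n1, n2) {
  combos <- utils::combn(n1 + n2, n1)
  u <- colSums(combos) - n1 * (n1 + 1) / 2
  tabulate(u + 1, nbins = n1 * n2 + 1) / ncol(combos)
}

enum_u_pvalue <- function(u, n1, n2, alternative = "two_sided") {
  pu <- enum_u_null(n1, n2)
  p_le <- sum(pu[seq_len(u + 1)])
  p_ge <- sum(pu[(u + 1):length(pu)])
  switch(alternative,
         two_sided = min(1, 2 * min(p_le, p_ge)),
         greater = p_ge,
         less = p_le)
}

# random fixed-width peak set (possibly with engineered A-B-C chains)
random_peaks <- function(n, width = 501L, chrom = c("chr1", "chr2"),
                         span = 2e5, chains = 0L) {
  ch <- sample(chrom, n, replace = TRUE)
  start <- sample.int(span, n, replace = TRUE)
  df <- data.frame(chrom = ch, start = start, end = start + width,
                   score = runif(n, 1, 50), spm = NA_real_,
                   cluster = "c1", stringsAsFactors = FALSE)
  if (chains > 0L) {
    gap <- floor(width * 0.8)
    anchors <- sample.int(span, chains)
    chain_df <- do.call(rbind, lapply(anchors, function(a) {
      s <- a + c(0L, gap, 2L * gap)
      data.frame(chrom = sample(chrom, 1), start = s, end = s + width,
                 score = runif(3, 1, 50), spm = NA_real_, cluster = "c1",
                 stringsAsFactors = FALSE)
    }))
    df <- rbind(df, chain_df)
  }
  df$spm <- df$score * 1e6 / sum(df$score)
  class(df) <- c("peak_set", "data.frame")
  df$ccre_id <- sprintf("p%04d", seq_len(nrow(df)))
  df
}

# tiny deterministic expression object: k clusters of identical cells with
# disjoint marker blocks (noiseless; every statistic is exact)
noiseless_expression <- function(n_clusters = 6, cells_per_cluster = 20,
                                 genes_per_cluster = 5, n_species = 2) {
  n_genes <- n_clusters * genes_per_cluster + 10
  counts <- matrix(0L, n_clusters * cells_per_cluster, n_genes)
  oc <- rep(seq_len(n_clusters), each = cells_per_cluster)
  for (k in seq_len(n_clusters)) {
    cols <- (k - 1) * genes_per_cluster + seq_len(genes_per_cluster)
    # distinct marker magnitudes keep all between-cluster distances unique,
    # so tree topology is not decided by floating-point tie-breaking
    counts[oc == k, cols] <- 30L + 15L * k
  }
  counts[, n_genes - 9:0] <- 5L   # shared background genes
  sp <- rep(rep(sprintf("sp%d", seq_len(n_species)),
                length.out = cells_per_cluster), n_clusters)
  cell_expression(counts, sp, paste0(sp, "_d1"), "classA",
                  sprintf("oc%02d", oc), sprintf("g%03d", seq_len(n_genes)))
}
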