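# Cross-species quantitative comparisons per consensus cluster: profile
# correlation, pseudobulk differential expression, and the conserved vs
# species-enriched marker partition.

#' Spearman correlation between cluster profiles of two species
#'
#' Profiles are cluster x gene matrices of per-cluster median log2(CPM + 1);
#' gene columns are aligned by name (one-to-one orthologues should share
#' names or be renamed upstream).
#'
#' @param profiles_a,profiles_b cluster x gene matrices with dimnames.
#' @param cluster_pairs two-column data frame / matrix of (cluster in a,
#'   cluster in b); default pairs clusters with identical names.
#' @return data frame (cluster_a, cluster_b, rho, n_genes).
#' @export
profile_spearman <- function(profiles_a, profiles_b, cluster_pairs = NULL) {
  profiles_a <- as.matrix(profiles_a)
  profiles_b <- as.matrix(profiles_b)
  shared <- intersect(colnames(profiles_a), colnames(profiles_b))
  if (length(shared) < 3)
    stop_bad("profiles_b", "fewer than 3 shared genes")
  if (is.null(cluster_pairs)) {
    cl <- intersect(rownames(profiles_a), rownames(profiles_b))
    cluster_pairs <- cbind(cl, cl)
  }
  cluster_pairs <- as.matrix(cluster_pairs)
  rho <- vapply(seq_len(nrow(cluster_pairs)), function(i) {
    a <- profiles_a[cluster_pairs[i, 1], shared]
    b <- profiles_b[cluster_pairs[i, 2], shared]
    cor(a, b, method = "spearman")
  }, numeric(1))
  data.frame(cluster_a = cluster_pairs[, 1], cluster_b = cluster_pairs[, 2],
             rho = rho, n_genes = length(shared), stringsAsFactors = FALSE)
}

#' Sum counts into pseudobulk samples
#'
#' Counts are summed per (species, donor, cluster) sample; samples with
#' fewer than `min_cells` cells are flagged (not dropped).
#'
#' @param expr a [cell_expression()].
#' @param cluster_labels per-cell cluster labels (e.g. consensus clusters).
#' @param min_cells flag threshold (default 10).
#' @return an object of class `pseudobulk` with `counts` (sample x gene) and
#'   `samples` metadata.
#' @export
make_pseudobulk <- function(expr, cluster_labels, min_cells = 10) {
  stopifnot(inherits(expr, "cell_expression"))
  cluster_labels <- as.character(cluster_labels)
  if (length(cluster_labels) != nrow(expr$counts))
    stop_bad("cluster_labels", "must have one label per cell")
  key <- interaction(expr$meta$species, expr$meta$donor, cluster_labels,
                     sep = "\r", drop = TRUE)
  counts <- rowsum(as.matrix(expr$counts), key)
  parts <- do.call(rbind, strsplit(rownames(counts), "\r", fixed = TRUE))
  n_cells <- as.vector(table(key))
  samples <- data.frame(sample = sprintf("pb%03d", seq_len(nrow(counts))),
                        species = parts[, 1], donor = parts[, 2],
                        cluster = parts[, 3], n_cells = n_cells,
                        flagged = n_cells < min_cells,
                        stringsAsFactors = FALSE)
  rownames(counts) <- samples$sample
  structure(list(counts = counts, samples = samples), class = "pseudobulk")
}

# DESeq2-style median-of-ratios size factors, with library-size fallback
# when no gene is expressed in every sample.
size_factors <- function(counts) {
  log_geo <- colMeans(log(counts + 0L), na.rm = FALSE)  # -Inf where any zero
  use <- is.finite(log_geo)
  if (sum(use) >= 10) {
    sf <- apply(counts[, use, drop = FALSE], 1, function(r)
      exp(median(log(r) - log_geo[use])))
  } else {
    ls <- rowSums(counts)
    sf <- ls / exp(mean(log(ls)))
  }
  sf
}

# Vectorized IRLS for a per-gene NB log-link model with a two-level species
# indicator and log size-factor offset, at fixed per-gene dispersion alpha
# (variance = mu + alpha * mu^2).  Returns coefficient, SE and Wald stats.
nb_wald_fit <- function(y, x, sf, alpha, n_iter = 25) {
  # y: samples x genes; x: 0/1 indicator; sf: size factors
  off <- log(sf)
  n <- length(x)
  m0 <- colSums(y[x == 0, , drop = FALSE]) / sum(sf[x == 0])
  m1 <- colSums(y[x == 1, , drop = FALSE]) / sum(sf[x == 1])
  b0 <- log(pmax(m0, 1e-8))
  b1 <- log(pmax(m1, 1e-8)) - b0
  se1 <- rep(NA_real_, length(b0))
  for (it in seq_len(n_iter)) {
    eta <- outer(off, b0, "+") + outer(x, b1)       # samples x genes
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + rep(alpha, each = n) * mu)
    z <- eta - off + (y - mu) / mu
    sw <- colSums(w); swx <- colSums(w * x)
    swz <- colSums(w * z); swxz <- colSums(w * x * z)
    det <- sw * swx - swx^2                          # swxx == swx for 0/1 x
    det[det < 1e-12] <- 1e-12
    b0_new <- (swx * swz - swx * swxz) / det
    b1_new <- (sw * swxz - swx * swz) / det
    delta <- max(abs(b0_new - b0), abs(b1_new - b1))
    b0 <- b0_new; b1 <- b1_new
    if (delta < 1e-8) break
  }
  eta <- outer(off, b0, "+") + outer(x, b1)
  eta <- pmin(pmax(eta, -30), 30)
  mu <- exp(eta)
  w <- mu / (1 + rep(alpha, each = n) * mu)
  sw <- colSums(w); swx <- colSums(w * x)
  det <- sw * swx - swx^2
  det[det < 1e-12] <- 1e-12
  se1 <- sqrt(sw / det)
  list(beta = b1, se = se1, wald = b1 / se1)
}

#' Pseudobulk differential expression between a species pair
#'
#' Per-gene negative-binomial model with species as the only covariate and a
#' log size-factor offset.  Dispersion is a pooled method-of-moments
#' estimate across both species' donor replicates; no shrinkage is applied.
#' The Wald statistic is coefficient / SE; its two-sided p-value uses a t
#' reference with residual degrees of freedom (the normal reference is
#' anti-conservative at typical donor counts).
#' Benjamini-Hochberg adjustment is applied across all tested genes (genes
#' with zero counts in every sample are dropped from the family).
#'
#' @param pb a [make_pseudobulk()] result.
#' @param cluster cluster id to test.
#' @param species_pair character vector `c(A, B)`; log2 fold change is A
#'   over B.
#' @param alpha adjusted-p cutoff for the `passes` flag (default 0.05).
#' @param lfc_threshold |log2FC| cutoff for `passes` (default 2, i.e.
#'   fold change > 4).
#' @return a `de_result` data frame with per-gene `log2_fold_change`,
#'   `wald_stat`, `p_value`, `adjusted_p`, `passes`; counts of passing genes
#'   per direction as attributes.
#' @export
pairwise_de <- function(pb, cluster, species_pair, alpha = 0.05,
                        lfc_threshold = 2) {
  stopifnot(inherits(pb, "pseudobulk"))
  if (length(species_pair) != 2)
    stop_bad("species_pair", "must name exactly two species")
  sel <- pb$samples$cluster == cluster & pb$samples$species %in% species_pair
  if (!any(sel)) stop_bad("cluster", "no samples for this cluster/species pair")
  y <- pb$counts[sel, , drop = FALSE]
  sp <- pb$samples$species[sel]
  n_rep <- table(factor(sp, levels = species_pair))
  if (any(n_rep < 2))
    stop_bad("species_pair", sprintf(
      "species %s has %d replicate(s); >= 2 donors per species required for a dispersion estimate",
      names(n_rep)[which(n_rep < 2)[1]], min(n_rep)))

  tested <- colSums(y) > 0
  y_t <- y[, tested, drop = FALSE]
  sf <- size_factors(y)
  x <- as.numeric(sp == species_pair[1])

  # pooled method-of-moments dispersion on normalized counts.  Var(y/sf)
  # within a group is mu/mean(1/sf) corrected: mu * E(1/sf) + alpha * mu^2.
  k <- sweep(y_t, 1, sf, "/")
  alpha_hat <- rep(0, ncol(y_t))
  num <- 0; den <- 0
  v_sum <- rep(0, ncol(y_t)); shot <- rep(0, ncol(y_t)); msq <- rep(0, ncol(y_t))
  wt <- 0
  for (g in c(0, 1)) {
    rows <- x == g
    m_g <- colMeans(k[rows, , drop = FALSE])
    v_g <- apply(k[rows, , drop = FALSE], 2, var)
    w_g <- sum(rows) - 1
    v_sum <- v_sum + w_g * v_g
    shot <- shot + w_g * m_g * mean(1 / sf[rows])
    msq <- msq + w_g * m_g^2
    wt <- wt + w_g
  }
  alpha_hat <- (v_sum - shot) / pmax(msq, 1e-12)
  alpha_hat <- pmin(pmax(alpha_hat, 1e-8), 10)

  fit <- nb_wald_fit(y_t, x, sf, alpha_hat)
  lfc <- fit$beta / log(2)
  # small-sample Wald reference: t with residual df rather than normal,
  # which is badly anti-conservative at typical donor counts
  df_resid <- max(nrow(y_t) - 2L, 1L)
  p <- 2 * stats::pt(-abs(fit$wald), df = df_resid)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  padj <- bh_adjust(p)
  res <- data.frame(gene_id = colnames(pb$counts), tested = tested,
                    log2_fold_change = NA_real_, wald_stat = NA_real_,
                    p_value = NA_real_, adjusted_p = NA_real_,
                    passes = FALSE, stringsAsFactors = FALSE)
  res$log2_fold_change[tested] <- lfc
  res$wald_stat[tested] <- fit$wald
  res$p_value[tested] <- p
  res$adjusted_p[tested] <- padj
  res$passes[tested] <- padj < alpha & abs(lfc) > lfc_threshold
  attr(res, "n_up") <- sum(res$passes & res$log2_fold_change > 0, na.rm = TRUE)
  attr(res, "n_down") <- sum(res$passes & res$log2_fold_change < 0, na.rm = TRUE)
  attr(res, "species_pair") <- species_pair
  class(res) <- c("de_result", "data.frame")
  res
}

#' Partition per-species marker sets into conserved and enriched groups
#'
#' Genes present in every species' set are conserved; genes in exactly one
#' set are species-enriched; genes in an intermediate subset of species are
#' reported under that subset (for two present species, the pairwise-shared
#' set).  The resulting groups are disjoint and cover the union.
#'
#' @param per_species_marker_sets named list mapping species -> character
#'   vector of genes.
#' @return an object of class `marker_partition` with `conserved`,
#'   `species_enriched` (named list) and `shared` (named by species subset).
#' @export
partition_markers <- function(per_species_marker_sets) {
  sets <- lapply(per_species_marker_sets, unique)
  if (length(sets) < 2) stop_bad("per_species_marker_sets", "need >= 2 species")
  all_genes <- unique(unlist(sets))
  species <- names(sets)
  membership <- vapply(sets, function(s) all_genes %in% s,
                       logical(length(all_genes)))
  if (length(all_genes) == 1) membership <- matrix(membership, nrow = 1)
  n_in <- rowSums(membership)
  conserved <- all_genes[n_in == length(sets)]
  enriched <- lapply(seq_along(sets), function(i)
    all_genes[membership[, i] & n_in == 1])
  names(enriched) <- species
  mid <- which(n_in > 1 & n_in < length(sets))
  shared <- list()
  if (length(mid)) {
    keys <- vapply(mid, function(r)
      paste(species[membership[r, ]], collapse = "&"), character(1))
    shared <- split(all_genes[mid], keys)
  }
  structure(list(conserved = conserved, species_enriched = enriched,
                 shared = shared),
            class = "marker_partition")
}
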