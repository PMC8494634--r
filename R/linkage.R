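# Enhancer-gene linking: empirical normal-fit FDR null for any score
# (co-accessibility or PCC), proximal/distal classification, 1-Mb-window
# candidate pairs, accessibility-expression correlation, shuffled background,
# and link selection.

#' Genome annotation container
#'
#' @param genes data frame with `gene_id` (unique), `chrom`, `tss` (bp,
#'   0-based), `strand` (`+`/`-`).
#' @param chrom_sizes named vector of chromosome lengths.
#' @return an object of class `genome_annotation`.
#' @export
genome_annotation <- function(genes, chrom_sizes) {
  need <- c("gene_id", "chrom", "tss", "strand")
  if (!all(need %in% names(genes)))
    stop_bad("genes", paste("must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(genes$gene_id)) stop_bad("genes", "gene_id must be unique")
  if (is.null(names(chrom_sizes)))
    stop_bad("chrom_sizes", "must be a named vector")
  bad <- genes$tss < 0 | genes$tss >= chrom_sizes[genes$chrom]
  if (anyNA(bad) || any(bad))
    stop_bad("genes", "tss outside chromosome bounds (or unknown chromosome)")
  structure(list(genes = genes, chrom_sizes = chrom_sizes),
            class = "genome_annotation")
}

#' Fit an empirical normal null and derive an FDR score threshold
#'
#' A normal distribution is fitted to shuffled-background scores by maximum
#' likelihood.  For each candidate threshold t on the observed score grid the
#' expected number of false positives is `(1 - Phi((t - mu)/sigma)) * N`
#' where N is the size of the observed family; the threshold is the smallest
#' observed t whose ratio of expected false positives to observed passes is
#' <= `fdr`.
#'
#' @param background_scores numeric vector (>= 30 values, nonzero variance).
#' @param observed_scores the score family the threshold will be applied to;
#'   defaults to the background itself.
#' @param fdr target false-discovery rate, in (0, 1] (default 0.01).
#' @return an object of class `null_model` with `mu`, `sigma`, `background`,
#'   `score_threshold` (may be `Inf` when no threshold attains the FDR) and
#'   `fdr`.
#' @export
fit_null_threshold <- function(background_scores, observed_scores = background_scores,
                               fdr = 0.01) {
  background_scores <- background_scores[is.finite(background_scores)]
  observed_scores <- observed_scores[is.finite(observed_scores)]
  if (length(background_scores) < 30)
    stop_bad("background_scores", "need >= 30 background scores")
  check_scalar_number(fdr, "fdr", lower = 0, upper = 1, strict_lower = TRUE)
  mu <- mean(background_scores)
  sigma <- sqrt(mean((background_scores - mu)^2))   # ML estimate
  if (sigma <= 0)
    stop_bad("background_scores", "degenerate background (zero variance)")
  grid <- sort(unique(observed_scores))
  n_obs <- length(observed_scores)
  # observed count >= t for each grid point (grid is sorted ascending)
  ge_count <- n_obs - findInterval(grid, sort(observed_scores), left.open = TRUE)
  exp_fp <- (1 - pnorm(grid, mu, sigma)) * n_obs
  ok <- exp_fp / ge_count <= fdr
  threshold <- if (any(ok)) grid[which(ok)[1]] else Inf
  structure(list(mu = mu, sigma = sigma, background = background_scores,
                 score_threshold = threshold, fdr = fdr),
            class = "null_model")
}

#' @export
print.null_model <- function(x, ...) {
  cat(sprintf("<null_model> N(%.4f, %.4f); threshold %.4f at FDR %g\n",
              x$mu, x$sigma, x$score_threshold, x$fdr))
  invisible(x)
}

peak_centers <- function(peaks) as.integer(floor((peaks$start + peaks$end) / 2))

#' Classify peaks as proximal or distal to transcription start sites
#'
#' A peak is proximal when its centre lies within `proximal_window` bp of the
#' nearest TSS; everything else (including peaks on gene-free chromosomes)
#' is distal.
#'
#' @param peaks a `peak_set`.
#' @param annotation a [genome_annotation()].
#' @param proximal_window bp window around the TSS (default 1000).
#' @return character vector (`"proximal"`/`"distal"`) aligned with `peaks`.
#' @export
classify_proximity <- function(peaks, annotation, proximal_window = 1000) {
  stopifnot(inherits(annotation, "genome_annotation"))
  if (nrow(annotation$genes) == 0) stop_bad("annotation", "empty annotation")
  centers <- peak_centers(peaks)
  out <- rep("distal", nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    tss <- sort(annotation$genes$tss[annotation$genes$chrom == ch])
    if (!length(tss)) next
    idx <- which(peaks$chrom == ch)
    pos <- centers[idx]
    j <- findInterval(pos, tss)
    d_lo <- ifelse(j >= 1, pos - tss[pmax(j, 1)], Inf)
    d_hi <- ifelse(j < length(tss), tss[pmin(j + 1, length(tss))] - pos, Inf)
    nearest <- pmin(abs(d_lo), abs(d_hi))
    out[idx][nearest <= proximal_window] <- "proximal"
  }
  out
}

#' Enumerate cCRE-gene candidate pairs within a window centred on the TSS
#'
#' All same-chromosome pairs with |centre - TSS| <= `window / 2` (a 1-Mb
#' window centred on the TSS at the default).  The signed distance is
#' `centre - tss`, negated for minus-strand genes, so positive distances are
#' downstream of the gene.
#'
#' @param peaks a `peak_set` with `ccre_id`.
#' @param annotation a [genome_annotation()].
#' @param window full window width in bp (default 1e6).
#' @return data frame (ccre_id, gene_id, distance_bp).
#' @export
candidate_pairs <- function(peaks, annotation, window = 1e6) {
  stopifnot(inherits(annotation, "genome_annotation"))
  half <- window / 2
  centers <- peak_centers(peaks)
  out <- list()
  for (ch in unique(peaks$chrom)) {
    g <- annotation$genes[annotation$genes$chrom == ch, , drop = FALSE]
    if (!nrow(g)) next
    p_idx <- which(peaks$chrom == ch)
    ord <- order(centers[p_idx])
    p_idx <- p_idx[ord]
    pos <- centers[p_idx]
    for (i in seq_len(nrow(g))) {
      lo <- findInterval(g$tss[i] - half, pos) + 1L
      hi <- findInterval(g$tss[i] + half, pos)
      if (hi < lo) next
      sel <- p_idx[lo:hi]
      d <- centers[sel] - g$tss[i]
      if (g$strand[i] == "-") d <- -d
      out[[length(out) + 1L]] <- data.frame(
        ccre_id = peaks$ccre_id[sel], gene_id = g$gene_id[i],
        distance_bp = d, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(ccre_id = character(0), gene_id = character(0),
                      distance_bp = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# row-wise Pearson correlation between paired rows of two matrices
paired_pcc <- function(a, b) {
  az <- a - rowMeans(a)
  bz <- b - rowMeans(b)
  sa <- sqrt(rowSums(az^2))
  sb <- sqrt(rowSums(bz^2))
  pcc <- rowSums(az * bz) / (sa * sb)
  pcc[sa == 0 | sb == 0] <- NA_real_
  pcc
}

#' Correlate accessibility and expression across clusters for candidate pairs
#'
#' Pearson correlation across the shared cluster axis for every pair.
#' Accessibility rows are cCRE profiles (typically log2 CPM), expression rows
#' are gene profiles (typically log2 TPM).  Zero-variance profiles yield
#' `NA`; such pairs are excluded from the threshold family downstream.
#'
#' @param pairs data frame from [candidate_pairs()].
#' @param accessibility cCRE x cluster matrix with rownames = cCRE ids.
#' @param expression gene x cluster matrix with rownames = gene ids.
#' @return `pairs` with a `pcc` column appended.
#' @export
correlate_pairs <- function(pairs, accessibility, expression) {
  shared <- intersect(colnames(accessibility), colnames(expression))
  if (length(shared) < 3) stop_bad("accessibility", "need >= 3 shared clusters")
  a <- accessibility[pairs$ccre_id, shared, drop = FALSE]
  b <- expression[pairs$gene_id, shared, drop = FALSE]
  pairs$pcc <- paired_pcc(as.matrix(a), as.matrix(b))
  pairs
}

#' Shuffled background correlations for the empirical null
#'
#' Background pairs are formed from cCREs and genes on *different*
#' chromosomes, and each pair's cluster labels are independently permuted
#' before the correlation is computed, destroying any residual structure.
#'
#' @param peaks a `peak_set` (provides cCRE chromosomes).
#' @param annotation a [genome_annotation()].
#' @param accessibility,expression matrices as in [correlate_pairs()].
#' @param n_background number of background pairs (> 0).
#' @param seed integer seed.
#' @return numeric vector of background correlations.
#' @export
shuffled_background <- function(peaks, annotation, accessibility, expression,
                                n_background, seed = 1L) {
  check_scalar_number(n_background, "n_background", lower = 1, integer = TRUE)
  check_scalar_number(seed, "seed", integer = TRUE)
  if (length(unique(annotation$genes$chrom)) < 2 ||
      length(unique(peaks$chrom)) < 2)
    stop_bad("annotation", "need >= 2 chromosomes for cross-chromosome background")
  withr::local_seed(seed)
  shared <- intersect(colnames(accessibility), colnames(expression))
  m <- length(shared)
  acc <- as.matrix(accessibility[, shared, drop = FALSE])
  ex <- as.matrix(expression[, shared, drop = FALSE])
  gene_chrom <- setNames(annotation$genes$chrom, annotation$genes$gene_id)
  ccre_chrom <- setNames(peaks$chrom, peaks$ccre_id)
  cc <- sample(peaks$ccre_id, n_background, replace = TRUE)
  gg <- character(n_background)
  for (i in seq_len(n_background)) {
    cand <- annotation$genes$gene_id[annotation$genes$chrom != ccre_chrom[cc[i]]]
    gg[i] <- cand[sample.int(length(cand), 1)]
  }
  perm <- vapply(seq_len(n_background), function(i) sample.int(m), integer(m))
  a <- t(vapply(seq_len(n_background),
                function(i) acc[cc[i], perm[, i]], numeric(m)))
  b <- ex[gg, , drop = FALSE]
  paired_pcc(a, b)
}

#' Select significant positively correlated cCRE-gene links
#'
#' A pair passes when its correlation is at or above the null-model threshold
#' and (with `positive_only`, the default) strictly positive.  Pairs with
#' undefined correlation never pass.
#'
#' @param pairs data frame with `pcc` (from [correlate_pairs()]); a
#'   `proximity` column, when present, is carried through.
#' @param null a [fit_null_threshold()] result on the same score scale.
#' @param positive_only require pcc > 0 (default TRUE).
#' @return a `link_table` data frame (ccre_id, gene_id, distance_bp, pcc,
#'   passes, proximity).
#' @export
select_links <- function(pairs, null, positive_only = TRUE) {
  stopifnot(inherits(null, "null_model"))
  passes <- !is.na(pairs$pcc) & pairs$pcc >= null$score_threshold
  if (positive_only) passes <- passes & pairs$pcc > 0
  pairs$passes <- passes
  if (!"proximity" %in% names(pairs)) pairs$proximity <- NA_character_
  class(pairs) <- c("link_table", "data.frame")
  attr(pairs, "score_threshold") <- null$score_threshold
  pairs
}
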