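# Statistics connecting molecular types to projections and regulators:
# exact Mann-Whitney rank tests, Benjamini-Hochberg correction,
# retrograde-tracing enrichment ratios, projection-fraction tables, and
# subclass-selective transcription-factor selection.

# Exact null distribution of the Mann-Whitney U statistic for sample sizes
# n1, n2 without ties, via a subset-sum dynamic program over the rank sum:
# counts[j, s] = number of ways to choose j of the ranks 1..(n1+n2) summing
# to s.  Returns the probability vector over U = 0..n1*n2.
u_null_distribution <- function(n1, n2) {
  n <- n1 + n2
  smax <- sum((n - n1 + 1):n)
  counts <- matrix(0, n1 + 1, smax + 1)   # [j+1, s+1]
  counts[1, 1] <- 1
  for (i in seq_len(n)) {
    jmax <- min(i, n1)
    for (j in jmax:1) {
      s_idx <- (i + 1):(smax + 1)
      counts[j + 1, s_idx] <- counts[j + 1, s_idx] + counts[j, s_idx - i]
    }
  }
  w <- counts[n1 + 1, ]                   # rank-sum counts, sum = 0..smax
  smin <- n1 * (n1 + 1) / 2
  u_counts <- w[(smin + 1):(smax + 1)]    # U = ranksum - n1(n1+1)/2
  u_counts / sum(u_counts)
}

#' Exact (or tie-corrected approximate) Mann-Whitney rank-sum test
#'
#' The statistic reported is the Mann-Whitney U of the first sample
#' (`U = ranksum(x) - n1(n1+1)/2`).  When `n1 + n2 <= 30` and there are no
#' ties the p-value is exact, from the full null distribution of U computed
#' by a counting recurrence; otherwise a normal approximation with tie
#' correction and 0.5 continuity correction is used.  The two-sided p-value
#' is twice the smaller tail probability, capped at 1.
#'
#' @param x_values,y_values nonempty numeric samples.
#' @param alternative `"two_sided"` (default), `"greater"` (x tends larger)
#'   or `"less"`.
#' @param exact_limit largest `n1 + n2` for which the exact null is used
#'   (default 30).
#' @return an object of class `rank_test_result` with `u`, `n1`, `n2`,
#'   `p_value`, `method` and `alternative`.
#' @export
exact_wilcoxon <- function(x_values, y_values,
                           alternative = c("two_sided", "greater", "less"),
                           exact_limit = 30) {
  alternative <- match.arg(alternative)
  if (!length(x_values) || !length(y_values))
    stop_bad("x_values", "both samples must be nonempty")
  n1 <- length(x_values); n2 <- length(y_values)
  r <- rank(c(x_values, y_values))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x_values, y_values)) > 0
  wilcoxon_u_pvalue(u, n1, n2, alternative, ties = ties,
                    tie_table = if (ties) table(r) else NULL,
                    exact_limit = exact_limit)
}

#' P-value for a Mann-Whitney U statistic given sample sizes
#'
#' Useful when only the printed (W, n1, n2) triple of a published test is
#' available.
#'
#' @param u Mann-Whitney U of the first sample, in `[0, n1 * n2]`.
#' @param n1,n2 sample sizes.
#' @param alternative as in [exact_wilcoxon()].
#' @param ties whether ties were present (forces the normal approximation).
#' @param tie_table optional `table()` of midranks for the tie correction.
#' @param exact_limit as in [exact_wilcoxon()].
#' @return a `rank_test_result`.
#' @export
wilcoxon_u_pvalue <- function(u, n1, n2,
                              alternative = c("two_sided", "greater", "less"),
                              ties = FALSE, tie_table = NULL,
                              exact_limit = 30) {
  alternative <- match.arg(alternative)
  check_scalar_number(u, "u", lower = 0, upper = n1 * n2)
  if (!ties && n1 + n2 <= exact_limit && u == round(u)) {
    pu <- u_null_distribution(n1, n2)
    p_le <- sum(pu[seq_len(u + 1)])
    p_ge <- sum(pu[(u + 1):length(pu)])
    method <- "exact"
  } else {
    m <- n1 * n2 / 2
    n <- n1 + n2
    tie_term <- if (!is.null(tie_table))
      sum(tie_table^3 - tie_table) / (n * (n - 1)) else 0
    sigma <- sqrt(n1 * n2 / 12 * (n + 1 - tie_term))
    p_le <- pnorm(u + 0.5, m, sigma)
    p_ge <- 1 - pnorm(u - 0.5, m, sigma)
    method <- "normal_approx"
  }
  p <- switch(alternative,
              two_sided = min(1, 2 * min(p_le, p_ge)),
              greater = p_ge,
              less = p_le)
  structure(list(u = u, n1 = n1, n2 = n2, p_value = p, method = method,
                 alternative = alternative),
            class = "rank_test_result")
}

#' @export
print.rank_test_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n1 = %d, n2 = %d), p = %.4g [%s, %s]\n",
              x$u, x$n1, x$n2, x$p_value, x$method, x$alternative))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: with p-values sorted ascending,
#' `adjusted_(i) = min over j >= i of p_(j) * m / j`, capped at 1, returned
#' in the input order.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop_bad("p_values", "all p-values must lie in (0, 1]")
  m <- length(p_values)
  o <- order(p_values)
  adj_sorted <- rev(cummin(rev(p_values[o] * m / seq_len(m))))
  out <- numeric(m)
  out[o] <- pmin(adj_sorted, 1)
  out
}

#' Projection enrichment ratios from retrograde-tracing counts
#'
#' Per sorting run, `r_p = on_target / off_target`; the unbiased baseline
#' ratio is `r_u = on_baseline / off_baseline`; the per-run fold enrichment
#' is `r_p / r_u` and the reported fold is the arithmetic mean across runs
#' (runs with zero off-target cells are excluded and logged).
#'
#' @param counts a `projection_counts` data frame (run, on_target,
#'   off_target); baselines are taken from its attributes unless given.
#' @param baseline_on,baseline_off unbiased baseline counts (> 0).
#' @return list with `r_u`, per-run table (`r_p`, `fold`), `mean_fold` and
#'   `n_runs_used`.
#' @export
projection_enrichment <- function(counts,
                                  baseline_on = attr(counts, "baseline_on"),
                                  baseline_off = attr(counts, "baseline_off")) {
  if (is.null(baseline_on) || is.null(baseline_off))
    stop_bad("baseline_on", "baseline counts required")
  check_scalar_number(baseline_on, "baseline_on", lower = 0, strict_lower = TRUE)
  check_scalar_number(baseline_off, "baseline_off", lower = 0, strict_lower = TRUE)
  if (any(counts$on_target < 0) || any(counts$off_target < 0))
    stop_bad("counts", "counts must be nonnegative")
  r_u <- baseline_on / baseline_off
  usable <- counts$off_target > 0
  if (any(!usable))
    message(sprintf("%d run(s) with zero off-target cells excluded", sum(!usable)))
  r_p <- counts$on_target[usable] / counts$off_target[usable]
  fold <- r_p / r_u
  list(r_u = r_u,
       runs = data.frame(run = counts$run[usable], r_p = r_p, fold = fold),
       mean_fold = mean(fold), n_runs_used = sum(usable))
}

#' Projection-fraction dot-plot table
#'
#' Restricted to single-projecting cells; returns per-cluster fractions over
#' targets (rows sum to 1) and per-target fractions over clusters (columns
#' of the second view sum to 1).
#'
#' @param cells data frame with `cluster`, `projection_target`,
#'   `n_targets_labelled`.
#' @return list with `by_cluster` and `by_target` fraction matrices and the
#'   underlying count matrix.
#' @export
projection_fraction_table <- function(cells) {
  need <- c("cluster", "projection_target", "n_targets_labelled")
  if (!all(need %in% names(cells)))
    stop_bad("cells", paste("must have columns", paste(need, collapse = ", ")))
  single <- cells[cells$n_targets_labelled == 1, , drop = FALSE]
  omitted <- setdiff(unique(cells$cluster), unique(single$cluster))
  if (length(omitted))
    message(sprintf("%d cluster(s) without single-projecting cells omitted",
                    length(omitted)))
  tab <- table(single$cluster, single$projection_target)
  counts <- unclass(as.matrix(tab))
  by_cluster <- counts / rowSums(counts)
  by_target <- sweep(counts, 2, colSums(counts), "/")
  list(counts = counts, by_cluster = by_cluster, by_target = by_target)
}

#' Select subclass-selective transcription factors
#'
#' For each TF and subclass: a one-tailed (greater) rank test of the TF's
#' expression in the subclass versus all other cells, BH-corrected across
#' TFs within the subclass, plus a fold-change requirement on linear-scale
#' (CPM) group means.  A TF is selected when it passes both the expression
#' criteria and the supplied motif-enrichment criteria in at least one
#' common subclass (set `same_subclass = FALSE` for the looser rule where
#' each criterion may hold in a different subclass).
#'
#' @param expr a [cell_expression()] restricted to TF genes, or a
#'   cells-by-TF matrix of raw counts.
#' @param subclass_labels per-cell subclass labels.
#' @param motif_table data frame with `tf`, `subclass`, `adjusted_p`,
#'   `odds_ratio` from an external motif-enrichment run.
#' @param alpha expression adjusted-p cutoff (default 0.05).
#' @param fold_threshold expression fold-change cutoff (default 2).
#' @param motif_alpha motif adjusted-p cutoff (default 1e-3).
#' @param motif_or motif odds-ratio cutoff (default 1.3).
#' @param same_subclass require both criteria in the same subclass (default).
#' @return a `tf_selection` data frame with per-(tf, subclass) test results
#'   and a per-TF `selected` flag.
#' @export
select_tfs <- function(expr, subclass_labels, motif_table, alpha = 0.05,
                       fold_threshold = 2, motif_alpha = 1e-3,
                       motif_or = 1.3, same_subclass = TRUE) {
  counts <- if (inherits(expr, "cell_expression")) expr$counts else as.matrix(expr)
  subclass_labels <- as.character(subclass_labels)
  if (length(subclass_labels) != nrow(counts))
    stop_bad("subclass_labels", "must have one label per cell")
  need <- c("tf", "subclass", "adjusted_p", "odds_ratio")
  if (!all(need %in% names(motif_table)))
    stop_bad("motif_table", paste("must have columns", paste(need, collapse = ", ")))
  cpm <- sweep(as.matrix(counts), 1, pmax(rowSums(counts), 1), "/") * 1e6
  tfs <- colnames(counts)
  missing_tf <- setdiff(tfs, motif_table$tf)
  if (length(missing_tf))
    message(sprintf("%d TF(s) absent from motif_table; motif_pass = FALSE",
                    length(missing_tf)))
  rows <- list()
  for (sc in sort(unique(subclass_labels))) {
    in_sc <- subclass_labels == sc
    pv <- vapply(tfs, function(tf)
      exact_wilcoxon(cpm[in_sc, tf], cpm[!in_sc, tf],
                     alternative = "greater")$p_value, numeric(1))
    padj <- bh_adjust(pmax(pv, .Machine$double.xmin))
    fold <- (colMeans(cpm[in_sc, , drop = FALSE]) + 1e-9) /
      (colMeans(cpm[!in_sc, , drop = FALSE]) + 1e-9)
    mt <- motif_table[motif_table$subclass == sc, , drop = FALSE]
    motif_pass <- vapply(tfs, function(tf) {
      row <- mt[mt$tf == tf, , drop = FALSE]
      nrow(row) > 0 && row$adjusted_p[1] < motif_alpha && row$odds_ratio[1] > motif_or
    }, logical(1))
    rows[[sc]] <- data.frame(
      tf = tfs, subclass = sc, p_value = pv, adjusted_p = padj,
      fold_change = fold,
      expression_pass = padj < alpha & fold > fold_threshold,
      motif_pass = motif_pass, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  sel_by_tf <- if (same_subclass) {
    tapply(res$expression_pass & res$motif_pass, res$tf, any)
  } else {
    tapply(res$expression_pass, res$tf, any) & tapply(res$motif_pass, res$tf, any)
  }
  res$selected <- as.vector(sel_by_tf[res$tf])
  class(res) <- c("tf_selection", "data.frame")
  res
}
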