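# Internal helpers shared across modules.

# Fail with a message naming the offending argument.
stop_bad <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_scalar_number <- function(x, field, lower = -Inf, upper = Inf,
                                integer = FALSE, strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_bad(field, "must be a single finite number")
  if (integer && x != round(x))
    stop_bad(field, "must be an integer")
  if (strict_lower) {
    if (x <= lower) stop_bad(field, sprintf("must be > %s", lower))
  } else if (x < lower) {
    stop_bad(field, sprintf("must be >= %s", lower))
  }
  if (x > upper) stop_bad(field, sprintf("must be <= %s", upper))
  invisible(x)
}

#' Log2 counts-per-million normalization
#'
#' CPM is computed per cell (row) as `count * 1e6 / total`, then transformed
#' as `log2(CPM + 1)`.  Cells with zero total counts map to all-zero rows.
#'
#' @param counts cells-by-genes matrix of nonnegative counts (dense or
#'   `Matrix` sparse).
#' @return dense matrix of the same dimensions.
#' @export
log2_cpm <- function(counts) {
  counts <- as.matrix(counts)
  tot <- rowSums(counts)
  tot[tot == 0] <- 1
  log2(counts / tot * 1e6 + 1)
}

#' Adjusted Rand index between two labelings
#'
#' Measures agreement of two partitions of the same items, corrected for
#' chance; 1 for identical partitions, ~0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return a single number in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop_bad("b", "labelings must cover the same items")
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(0)
  (sum_ij - expected) / (max_idx - expected)
}

# Shannon entropy of a count vector normalized to [0, 1] by log(n_categories).
# Returns 0 when only one category exists in the universe.
normalized_entropy <- function(counts, n_categories = length(counts)) {
  if (n_categories <= 1L) return(0)
  p <- counts / sum(counts)
  p <- p[p > 0]
  h <- -sum(p * log(p))
  h / log(n_categories)
}
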