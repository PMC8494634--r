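# Nonnegative matrix factorization of the cCRE-by-cluster accessibility
# matrix into cis-regulatory modules, with Hoyer-sparseness-based rank
# selection and module-cluster / module-element association.

#' Hoyer sparseness of a nonnegative vector
#'
#' `(sqrt(n) - sum(x) / sqrt(sum(x^2))) / (sqrt(n) - 1)`: 0 for a constant
#' positive vector, 1 for a one-hot vector.
#'
#' @param x nonnegative numeric vector of length >= 2, not all zero.
#' @return a number in \[0, 1\].
#' @export
sparseness <- function(x) {
  if (length(x) < 2) stop_bad("x", "need length >= 2")
  if (any(x < 0)) stop_bad("x", "must be nonnegative")
  l2 <- sqrt(sum(x^2))
  if (l2 == 0) stop_bad("x", "zero vector has undefined sparseness")
  n <- length(x)
  (sqrt(n) - sum(x) / l2) / (sqrt(n) - 1)
}

# mean Hoyer sparseness over the rows of H (module usage across clusters)
h_sparseness <- function(H) mean(apply(H, 1, sparseness))

nmf_single_run <- function(V, rank, max_iter, tol, seed) {
  withr::local_seed(seed)
  n <- nrow(V); m <- ncol(V)
  scale0 <- sqrt(mean(V) / rank)
  W <- matrix(runif(n * rank), n, rank) * scale0
  H <- matrix(runif(rank * m), rank, m) * scale0
  eps <- 1e-10
  obj <- numeric(0)
  err_prev <- Inf
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, V)) / (crossprod(W) %*% H + eps)
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
    err <- sum((V - W %*% H)^2)
    obj <- c(obj, err)
    if (is.finite(err_prev) && (err_prev - err) <= tol * max(err_prev, eps)) break
    err_prev <- err
  }
  list(W = W, H = H, error = obj[length(obj)], objective = obj)
}

#' NMF decomposition of a nonnegative matrix into regulatory modules
#'
#' Multiplicative-update NMF minimizing the squared Frobenius error
#' `||V - WH||^2` with `n_runs` random nonnegative initializations (run r is
#' seeded `seed + r - 1`); the run with the lowest final error is retained.
#' The per-run Hoyer sparseness of H (mean over module rows) is recorded for
#' rank selection.
#'
#' @param V nonnegative cCRE x cluster matrix (N rows elements, M columns
#'   clusters).
#' @param rank number of modules R, `1 <= R <= min(N, M)`.
#' @param n_runs random restarts (default 100).
#' @param max_iter maximum multiplicative updates per run (default 500).
#' @param tol relative objective-improvement stopping tolerance (default 1e-6).
#' @param seed integer seed.
#' @return an object of class `module_decomposition` with `W`, `H`, `rank`,
#'   best-run `objective` trace, `run_errors`, and `run_sparseness`.
#' @export
nmf_decompose <- function(V, rank, n_runs = 100, max_iter = 500, tol = 1e-6,
                          seed = 1L) {
  V <- as.matrix(V)
  if (any(V < 0)) stop_bad("V", "must be entrywise nonnegative")
  check_scalar_number(rank, "rank", lower = 1, upper = min(dim(V)),
                      integer = TRUE)
  check_scalar_number(n_runs, "n_runs", lower = 1, integer = TRUE)
  best <- NULL
  run_errors <- numeric(n_runs)
  run_sparseness <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    fit <- nmf_single_run(V, rank, max_iter, tol, seed + r - 1L)
    run_errors[r] <- fit$error
    run_sparseness[r] <- if (ncol(fit$H) >= 2) h_sparseness(fit$H) else NA_real_
    if (is.null(best) || fit$error < best$error) best <- fit
  }
  structure(list(V = V, W = best$W, H = best$H, rank = rank,
                 objective = best$objective, error = best$error,
                 run_errors = run_errors, run_sparseness = run_sparseness,
                 seed = seed),
            class = "module_decomposition")
}

#' @export
print.module_decomposition <- function(x, ...) {
  cat(sprintf("<module_decomposition> %d elements x %d clusters, rank %d, error %.4g\n",
              nrow(x$W), ncol(x$H), x$rank, x$error))
  invisible(x)
}

#' Select the NMF rank by median sparseness with an error guard
#'
#' For each rank in the grid, `n_runs` seeded NMF runs are performed; the
#' median Hoyer sparseness of H and the median reconstruction error are
#' recorded.  A rank is eligible when moving to the next larger rank in the
#' grid improves the median error by less than `error_gain` (relative), i.e.
#' additional modules no longer buy reconstruction quality; the largest rank
#' is always eligible.  Among eligible ranks the one with maximal median
#' sparseness is chosen (ties: smallest rank).  The full per-rank curve is
#' returned so the rule can be overridden by inspection.
#'
#' @param V nonnegative matrix as in [nmf_decompose()].
#' @param rank_grid integer vector of candidate ranks.
#' @param n_runs NMF restarts per rank (default 100).
#' @param max_iter,tol passed to [nmf_decompose()].
#' @param error_gain relative improvement threshold (default 0.05).
#' @param seed integer seed.
#' @return list with `rank` (the selection) and `curve` (per-rank medians).
#' @export
select_rank <- function(V, rank_grid, n_runs = 100, max_iter = 300,
                        tol = 1e-6, error_gain = 0.05, seed = 1L) {
  if (!length(rank_grid)) stop_bad("rank_grid", "must be nonempty")
  rank_grid <- sort(unique(as.integer(rank_grid)))
  med_sp <- numeric(length(rank_grid))
  med_err <- numeric(length(rank_grid))
  for (i in seq_along(rank_grid)) {
    fit <- nmf_decompose(V, rank_grid[i], n_runs = n_runs,
                         max_iter = max_iter, tol = tol,
                         seed = seed + 1000L * i)
    med_sp[i] <- median(fit$run_sparseness, na.rm = TRUE)
    med_err[i] <- median(fit$run_errors)
  }
  k <- length(rank_grid)
  eligible <- logical(k)
  eligible[k] <- TRUE
  if (k > 1) {
    gain <- (med_err[-k] - med_err[-1]) / pmax(med_err[-k], 1e-12)
    eligible[-k] <- gain < error_gain
  }
  cand <- which(eligible)
  pick <- cand[which.max(med_sp[cand])]
  list(rank = rank_grid[pick],
       curve = data.frame(rank = rank_grid, median_sparseness = med_sp,
                          median_error = med_err, eligible = eligible))
}

#' Associate modules with clusters and elements
#'
#' The coefficient matrix H is min-max scaled per column (cluster) to
#' \[0, 1\]; a cluster is associated with a module when its scaled
#' coefficient exceeds `coef_threshold` (0.1, roughly the 95th percentile of
#' a typical scaled matrix).  Module elements are ranked by their basis
#' coefficient in W.
#'
#' @param decomp a [nmf_decompose()] result.
#' @param coef_threshold scaled-coefficient threshold (default 0.1).
#' @return list with `scaled_H`, `module_clusters` (list of cluster ids per
#'   module), `module_elements` (per module, elements ordered by decreasing
#'   basis coefficient, with scores), `element_module` (argmax module per
#'   element) and the observed 95th percentile of scaled H.
#' @export
associate_modules <- function(decomp, coef_threshold = 0.1) {
  stopifnot(inherits(decomp, "module_decomposition"))
  H <- decomp$H
  W <- decomp$W
  rng <- apply(H, 2, function(col) {
    span <- max(col) - min(col)
    if (span == 0) {
      rep(0, length(col))   # constant column scales to 0 by convention
    } else (col - min(col)) / span
  })
  scaled_H <- matrix(rng, nrow(H), ncol(H))
  dimnames(scaled_H) <- dimnames(H)
  if (any(apply(H, 2, function(c) max(c) == min(c))))
    message("constant H column(s) scaled to 0")
  cl_names <- colnames(H)
  if (is.null(cl_names)) cl_names <- sprintf("cl%02d", seq_len(ncol(H)))
  el_names <- rownames(W)
  if (is.null(el_names)) el_names <- sprintf("el%04d", seq_len(nrow(W)))
  module_clusters <- lapply(seq_len(nrow(H)), function(m)
    cl_names[scaled_H[m, ] > coef_threshold])
  module_elements <- lapply(seq_len(ncol(W)), function(m) {
    ord <- order(-W[, m])
    setNames(W[ord, m], el_names[ord])
  })
  element_module <- max.col(W, ties.method = "first")
  list(scaled_H = scaled_H, module_clusters = module_clusters,
       module_elements = module_elements,
       element_module = setNames(element_module, el_names),
       q95 = quantile(scaled_H, 0.95))
}
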