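# Union cCRE construction: summit extension to fixed width, score-per-million
# normalization, iterative overlap merging without daisy-chaining, SPM filter.
# Intervals are 0-based half-open throughout; [a,b) and [c,d) overlap iff
# a < d and c < b, so book-ended intervals do not overlap.

new_peak_set <- function(df) {
  need <- c("chrom", "start", "end", "score", "spm", "cluster")
  stopifnot(all(need %in% names(df)))
  if (!"ccre_id" %in% names(df))
    df$ccre_id <- sprintf("%s:%d-%d", df$chrom, df$start, df$end)
  rownames(df) <- NULL
  class(df) <- c("peak_set", "data.frame")
  df
}

#' Extend peak summits to fixed-width intervals
#'
#' Each summit becomes the interval `[summit - flank, summit + flank + 1)`
#' of width `2 * flank + 1` (501 bp at the default).  Intervals running past
#' a chromosome end are shifted inward so the fixed width is preserved
#' (fixed width is what makes the ranked merge well behaved).
#'
#' @param summits data frame with `chrom`, `summit_pos` (0-based), `score`,
#'   `cluster` (a `summit_set`).
#' @param flank half-width in bp (default 250).
#' @param chrom_sizes named vector of chromosome lengths covering every
#'   summit chromosome.
#' @return a `peak_set` data frame (chrom, start, end, score, spm, cluster).
#' @export
extend_summits <- function(summits, flank = 250L, chrom_sizes) {
  check_scalar_number(flank, "flank", lower = 0, integer = TRUE)
  need <- c("chrom", "summit_pos", "score", "cluster")
  if (!all(need %in% names(summits)))
    stop_bad("summits", paste("must have columns", paste(need, collapse = ", ")))
  unknown <- setdiff(unique(summits$chrom), names(chrom_sizes))
  if (length(unknown))
    stop_bad("chrom_sizes", paste("unknown chromosome:", unknown[1]))
  width <- 2L * flank + 1L
  len <- chrom_sizes[summits$chrom]
  if (any(len < width))
    stop_bad("chrom_sizes", "chromosome shorter than the peak width")
  start <- summits$summit_pos - flank
  end <- summits$summit_pos + flank + 1L
  shift_right <- pmax(0L, -start)
  start <- start + shift_right; end <- end + shift_right
  shift_left <- pmax(0L, end - len)
  start <- start - shift_left; end <- end - shift_left
  new_peak_set(data.frame(chrom = summits$chrom, start = as.integer(start),
                          end = as.integer(end), score = summits$score,
                          spm = NA_real_, cluster = summits$cluster,
                          stringsAsFactors = FALSE))
}

#' Score-per-million normalization
#'
#' Within each source cluster, `spm = score * 1e6 / sum(score)`, so the
#' per-cluster SPM total is 1e6 and scores become comparable across clusters
#' of different sequencing depth.
#'
#' @param peaks a `peak_set` with raw scores.
#' @return the `peak_set` with `spm` filled in.
#' @export
score_per_million <- function(peaks) {
  tot <- tapply(peaks$score, peaks$cluster, sum)
  if (any(tot <= 0))
    stop_bad("peaks", sprintf("cluster %s has nonpositive total score",
                              names(tot)[which(tot <= 0)[1]]))
  peaks$spm <- as.numeric(peaks$score * 1e6 / tot[peaks$cluster])
  new_peak_set(as.data.frame(peaks))
}

#' Iterative overlap merge of fixed-width peaks
#'
#' Pools all input peaks, ranks them by SPM (descending; ties broken by
#' chromosome then start, deterministically), then repeatedly keeps the
#' top-ranked remaining peak and discards every remaining peak overlapping
#' it by >= 1 bp.  The kept set is pairwise non-overlapping and fixed-width.
#' Unlike a coordinate-span merge, non-overlapping peaks can never be fused
#' through a chain of pairwise overlaps (no daisy-chaining).
#'
#' @param peaksets a `peak_set` or list of `peak_set`s with `spm` computed.
#' @return the merged `peak_set`, sorted by chromosome and start.
#' @export
iterative_overlap_merge <- function(peaksets) {
  if (inherits(peaksets, "peak_set")) peaksets <- list(peaksets)
  pool <- do.call(rbind, lapply(peaksets, as.data.frame))
  if (anyNA(pool$spm)) stop_bad("peaksets", "spm missing; run score_per_million()")
  widths <- unique(pool$end - pool$start)
  if (length(widths) != 1)
    stop_bad("peaksets", "mixed peak widths")
  w <- widths
  ord <- order(-pool$spm, pool$chrom, pool$start)
  pool <- pool[ord, , drop = FALSE]
  keep <- logical(nrow(pool))
  kept_starts <- split(numeric(0), character(0))  # per-chrom starts kept so far
  for (i in seq_len(nrow(pool))) {
    ch <- pool$chrom[i]
    ks <- kept_starts[[ch]]
    if (is.null(ks) || !any(abs(ks - pool$start[i]) < w)) {
      keep[i] <- TRUE
      kept_starts[[ch]] <- c(ks, pool$start[i])
    }
  }
  out <- pool[keep, , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  new_peak_set(out)
}

#' Filter peaks by score-per-million cutoff
#'
#' @param peaks a `peak_set` with `spm`.
#' @param cutoff SPM cutoff (default 5).
#' @param strict use `>` instead of the default `>=` at the boundary.
#' @return the filtered `peak_set`.
#' @export
filter_spm <- function(peaks, cutoff = 5, strict = FALSE) {
  if (anyNA(peaks$spm)) stop_bad("peaks", "spm missing; run score_per_million()")
  keep <- if (strict) peaks$spm > cutoff else peaks$spm >= cutoff
  new_peak_set(as.data.frame(peaks)[keep, , drop = FALSE])
}
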