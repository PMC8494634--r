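# Readers and writers for the plain-text formats the pipeline consumes and
# produces: matrix-market counts with sidecar name files, TSV metadata,
# narrowPeak summits, BED, Newick trees with confidence labels, JSON truth.

#' Write a cell-expression object as matrix-market plus TSV metadata
#'
#' Produces `counts.mtx`, `genes.txt`, `cells.txt` and `metadata.tsv` in
#' `dir`.
#'
#' @param expr a [cell_expression()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cell_expression <- function(expr, dir) {
  stopifnot(inherits(expr, "cell_expression"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(expr$counts, sparse = TRUE),
                  file.path(dir, "counts.mtx"))
  writeLines(expr$gene_ids, file.path(dir, "genes.txt"))
  writeLines(expr$meta$cell_id, file.path(dir, "cells.txt"))
  write.table(expr$meta, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a cell-expression object written by [write_cell_expression()]
#'
#' @param dir directory holding `counts.mtx`, `genes.txt`, `cells.txt`,
#'   `metadata.tsv`.
#' @return a [cell_expression()].
#' @export
read_cell_expression <- function(dir) {
  counts <- as.matrix(Matrix::readMM(file.path(dir, "counts.mtx")))
  genes <- readLines(file.path(dir, "genes.txt"))
  meta <- read.table(file.path(dir, "metadata.tsv"), sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
  cell_expression(counts, meta$species, meta$donor, meta$class_label,
                  meta$over_cluster, genes)
}

#' Write summits as narrowPeak
#'
#' Standard 6+4 narrowPeak: the summit offset relative to `start` goes in
#' column 10 and the score (-log10 q) in column 7 (`signalValue`).  Peaks are
#' written as 1-bp intervals at the summit when no extension is available.
#'
#' @param summits a `summit_set` data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(summits, path) {
  df <- data.frame(chrom = summits$chrom,
                   start = summits$summit_pos,
                   end = summits$summit_pos + 1L,
                   name = sprintf("peak%05d", seq_len(nrow(summits))),
                   score = 0L, strand = ".",
                   signalValue = summits$score,
                   pValue = -1, qValue = summits$score,
                   peak = 0L)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a narrowPeak file into a summit set
#'
#' The summit position is `start + column 10`; the score is taken from
#' `qValue` (column 9) when nonnegative, else `signalValue` (column 7).
#'
#' @param path narrowPeak file.
#' @param cluster cluster label to attach (default the file name).
#' @return a `summit_set` data frame.
#' @export
read_narrowpeak <- function(path, cluster = basename(path)) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 10) stop_bad("path", "narrowPeak needs 10 columns")
  score <- ifelse(df[[9]] >= 0, df[[9]], df[[7]])
  out <- data.frame(chrom = df[[1]], summit_pos = df[[2]] + df[[10]],
                    score = score, cluster = cluster,
                    stringsAsFactors = FALSE)
  class(out) <- c("summit_set", "data.frame")
  out
}

#' Write a peak set as BED6 (SPM in the score column) plus a full TSV
#'
#' @param peaks a `peak_set`.
#' @param path BED output path; a `.tsv` twin with all columns is written
#'   alongside.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  bed <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$ccre_id,
                    peaks$spm, ".")
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  write.table(as.data.frame(peaks), paste0(path, ".tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a taxonomy tree as Newick with node statistics sidecar
#'
#' Bootstrap confidence (when present) is written as internal node labels;
#' all node statistics go to a JSON sidecar `<path>.json`.
#'
#' @param tree a `taxonomy_tree`.
#' @param path Newick output path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  phy <- ape::as.phylo(tree$hc)
  conf <- tree$nodes$confidence
  if (!all(is.na(conf))) {
    # ape internal nodes follow the hclust merge order via as.phylo
    phy$node.label <- format(round(conf, 3))
  }
  ape::write.tree(phy, file = path)
  jsonlite::write_json(tree$nodes, paste0(path, ".json"), digits = NA)
  invisible(path)
}

#' Write a link table as TSV
#' @param links a `link_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_link_table <- function(links, path) {
  write.table(as.data.frame(links), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
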