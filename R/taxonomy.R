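# Consensus taxonomy construction: metacells, Ward tree, subsample-based
# node assessment, recursive pruning, dendrogram bootstrap confidence, ROC
# marker selection and taxonomy-to-taxonomy matching.

#' Aggregate cells into metacells (per over-cluster mean profiles)
#'
#' Each over-cluster's profile is the per-gene mean of log2(CPM + 1) over its
#' cells.  Cluster sizes and per-species cell counts are recorded; they feed
#' node statistics during tree assessment.
#'
#' @param expr a [cell_expression()].
#' @return an object of class `metacell_matrix` with `profiles`
#'   (over-cluster x gene), `sizes`, and `species_composition`
#'   (over-cluster x species counts).
#' @export
aggregate_metacells <- function(expr) {
  stopifnot(inherits(expr, "cell_expression"))
  oc <- expr$meta$over_cluster
  if (any(!nzchar(oc)))
    stop_bad("over_cluster", "empty over-cluster label")
  lc <- log2_cpm(expr$counts)
  f <- factor(oc)
  n_per <- as.vector(table(f))
  if (any(n_per == 0))
    stop_bad("over_cluster", sprintf("empty cluster: %s",
                                     levels(f)[which(n_per == 0)[1]]))
  profiles <- rowsum(lc, f) / n_per
  comp <- as.matrix(table(f, expr$meta$species))
  structure(list(profiles = profiles,
                 sizes = setNames(n_per, levels(f)),
                 species_composition = comp,
                 n_species = length(unique(expr$meta$species))),
            class = "metacell_matrix")
}

# internal: leaf sets for every internal node of an hclust object
hclust_node_leaves <- function(hc) {
  n <- nrow(hc$merge) + 1L
  leaves <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    kids <- hc$merge[i, ]
    lv <- integer(0)
    for (k in kids)
      lv <- c(lv, if (k < 0) -k else leaves[[k]])
    leaves[[i]] <- sort(lv)
  }
  leaves
}

node_key <- function(labels) paste(sort(labels), collapse = "\r")

#' Build a Ward merge tree over metacell profiles
#'
#' Agglomerative clustering with Ward's minimum-variance criterion on
#' Euclidean distances between profiles (`hclust` method `ward.D2`, whose
#' heights are the Ward merge costs).
#'
#' @param metacells a `metacell_matrix` (or a plain numeric matrix of
#'   profiles with row names).
#' @return an object of class `taxonomy_tree`.
#' @export
build_tree <- function(metacells) {
  profiles <- if (inherits(metacells, "metacell_matrix"))
    metacells$profiles else as.matrix(metacells)
  if (nrow(profiles) < 2) stop_bad("metacells", "need >= 2 metacells")
  if (anyNA(profiles) || any(!is.finite(profiles)))
    stop_bad("metacells", "profiles contain NaN or infinite values")
  hc <- hclust(dist(profiles), method = "ward.D2")
  new_taxonomy_tree(hc, metacells)
}

new_taxonomy_tree <- function(hc, metacells = NULL) {
  leaves_idx <- hclust_node_leaves(hc)
  labels <- hc$labels
  node_leaves <- lapply(leaves_idx, function(i) labels[i])
  nodes <- data.frame(node = seq_along(node_leaves),
                      height = hc$height,
                      n_leaves = lengths(node_leaves),
                      stability = NA_real_, size = NA_real_,
                      mixing = NA_real_, confidence = NA_real_)
  structure(list(hc = hc, labels = labels, nodes = nodes,
                 node_leaves = node_leaves,
                 leaf_stats = NULL, metacells = metacells),
            class = "taxonomy_tree")
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat(sprintf("<taxonomy_tree> %d leaves, %d internal nodes\n",
              length(x$labels), nrow(x$nodes)))
  if (!all(is.na(x$nodes$stability)))
    cat(sprintf("  stability assessed (median %.2f)\n",
                median(x$nodes$stability, na.rm = TRUE)))
  if (!all(is.na(x$nodes$confidence)))
    cat(sprintf("  bootstrap confidence (median %.2f)\n",
                median(x$nodes$confidence, na.rm = TRUE)))
  invisible(x)
}

#' Assess tree nodes by repeated subsampling
#'
#' For each replicate, cells are subsampled without replacement, metacells
#' and the Ward tree rebuilt, and each original internal node scored present
#' when some rebuilt node has the identical leaf set (or Jaccard >=
#' `jaccard` when a relaxed match is requested).  Stability is the presence
#' fraction; size is the number of cells under the node; species mixing is
#' the Shannon entropy of the species proportions under the node, normalized
#' by log(number of species) so it is 0 for one species and 1 when uniform.
#'
#' @param expr the [cell_expression()] the tree was built from.
#' @param tree a `taxonomy_tree` whose leaves are `expr`'s over-clusters.
#' @param n_subsamples number of replicates (default 100).
#' @param subsample_fraction fraction of cells kept per replicate, in (0, 1].
#' @param seed integer seed.
#' @param jaccard `NULL` for strict leaf-set equality (default), or a value
#'   in (0, 1\] for relaxed Jaccard matching of node identity.
#' @return the tree with `nodes$stability`, `nodes$size`, `nodes$mixing` and
#'   per-leaf statistics filled in.
#' @export
assess_tree <- function(expr, tree, n_subsamples = 100, subsample_fraction = 0.95,
                        seed = 1L, jaccard = NULL) {
  stopifnot(inherits(expr, "cell_expression"), inherits(tree, "taxonomy_tree"))
  check_scalar_number(n_subsamples, "n_subsamples", lower = 1, integer = TRUE)
  check_scalar_number(subsample_fraction, "subsample_fraction",
                      lower = 0, upper = 1, strict_lower = TRUE)
  if (!setequal(tree$labels, unique(expr$meta$over_cluster)))
    stop_bad("tree", "tree leaves do not match expr over-clusters")
  withr::local_seed(seed)

  lc <- log2_cpm(expr$counts)
  oc <- factor(expr$meta$over_cluster)
  n_cells <- nrow(lc)
  k <- max(2L, round(subsample_fraction * n_cells))

  keys <- vapply(tree$node_leaves, node_key, character(1))
  present <- numeric(length(keys))
  for (b in seq_len(n_subsamples)) {
    idx <- sample.int(n_cells, k)
    fb <- droplevels(oc[idx])
    if (nlevels(fb) < 2) next
    prof <- rowsum(lc[idx, , drop = FALSE], fb) / as.vector(table(fb))
    hcb <- hclust(dist(prof), method = "ward.D2")
    lv <- hclust_node_leaves(hcb)
    labs <- hcb$labels
    if (is.null(jaccard)) {
      kb <- vapply(lv, function(i) node_key(labs[i]), character(1))
      present <- present + (keys %in% kb)
    } else {
      sets_b <- lapply(lv, function(i) labs[i])
      for (j in seq_along(keys)) {
        a <- tree$node_leaves[[j]]
        jac <- vapply(sets_b, function(s)
          length(intersect(a, s)) / length(union(a, s)), numeric(1))
        if (any(jac >= jaccard)) present[j] <- present[j] + 1
      }
    }
  }
  mc <- if (!is.null(tree$metacells)) tree$metacells else aggregate_metacells(expr)
  comp <- mc$species_composition
  n_sp <- ncol(comp)
  node_comp <- t(vapply(tree$node_leaves, function(lvs)
    colSums(comp[lvs, , drop = FALSE]), numeric(n_sp)))
  tree$nodes$stability <- present / n_subsamples
  tree$nodes$size <- rowSums(node_comp)
  tree$nodes$mixing <- apply(node_comp, 1, normalized_entropy,
                             n_categories = n_sp)
  tree$leaf_stats <- data.frame(
    label = rownames(comp),
    size = rowSums(comp),
    mixing = apply(comp, 1, normalized_entropy, n_categories = n_sp),
    stringsAsFactors = FALSE)
  tree$metacells <- mc
  tree
}

#' Prune an assessed tree to consensus clusters
#'
#' Depth-first from the root: a split is retained only when both children
#' satisfy all criteria (size, species mixing, stability); otherwise the
#' subtree below the current node is collapsed into a single consensus
#' cluster.  Leaves count as satisfying stability (a leaf is trivially
#' preserved in every replicate).  Every retained split therefore satisfies
#' the criteria on both children, and re-pruning the result is a no-op.
#'
#' @param tree an assessed `taxonomy_tree` (see [assess_tree()]).
#' @param criteria list with `min_size`, `min_mixing`, `min_stability`
#'   (all >= 0).
#' @return an object of class `consensus_clusters` with `assignment`
#'   (over-cluster -> consensus id), `composition` (per-cluster species
#'   counts and cell totals) and the criteria used.
#' @export
prune_to_consensus <- function(tree,
                               criteria = list(min_size = 20, min_mixing = 0.1,
                                               min_stability = 0.6)) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  for (nm in c("min_size", "min_mixing", "min_stability")) {
    if (is.null(criteria[[nm]])) stop_bad("criteria", paste("missing", nm))
    check_scalar_number(criteria[[nm]], nm, lower = 0)
  }
  if (anyNA(tree$nodes$stability) || is.null(tree$leaf_stats))
    stop_bad("tree", "nodes lack statistics; run assess_tree() first")

  merge <- tree$hc$merge
  n_node <- nrow(merge)
  leaf_ok <- function(i) {
    st <- tree$leaf_stats[match(tree$labels[i], tree$leaf_stats$label), ]
    st$size >= criteria$min_size && st$mixing >= criteria$min_mixing
  }
  node_ok <- function(j) {
    nd <- tree$nodes[j, ]
    nd$size >= criteria$min_size && nd$mixing >= criteria$min_mixing &&
      nd$stability >= criteria$min_stability
  }
  child_ok <- function(k) if (k < 0) leaf_ok(-k) else node_ok(k)

  groups <- list()
  walk <- function(k) {
    if (k < 0) {
      groups[[length(groups) + 1L]] <<- tree$labels[-k]
      return(invisible())
    }
    kids <- merge[k, ]
    if (all(vapply(kids, child_ok, logical(1)))) {
      walk(kids[1]); walk(kids[2])
    } else {
      groups[[length(groups) + 1L]] <<- tree$node_leaves[[k]]
    }
  }
  walk(n_node)   # root is the last merge

  # stable ordering: by first leaf in the tree's leaf order
  ord <- order(vapply(groups, function(g) min(match(g, tree$labels[tree$hc$order])),
                      numeric(1)))
  groups <- groups[ord]
  ids <- sprintf("cc%02d", seq_along(groups))
  assignment <- setNames(rep(ids, lengths(groups)), unlist(groups))
  comp <- tree$metacells$species_composition
  composition <- t(vapply(groups, function(g)
    colSums(comp[g, , drop = FALSE]), numeric(ncol(comp))))
  rownames(composition) <- ids
  structure(list(assignment = assignment,
                 composition = composition,
                 n_cells = rowSums(composition),
                 criteria = criteria),
            class = "consensus_clusters")
}

#' @export
print.consensus_clusters <- function(x, ...) {
  cat(sprintf("<consensus_clusters> %d clusters over %d over-clusters\n",
              nrow(x$composition), length(x$assignment)))
  invisible(x)
}

#' Bootstrap branch confidence for a cluster dendrogram
#'
#' The reference dendrogram is built on all genes with average linkage on
#' 1 - Pearson correlation between cluster profiles (typically median
#' log2 CPM over marker genes).  Each iteration rebuilds the dendrogram on a
#' uniform random subset of `gene_fraction` of the genes; a node's confidence
#' is the fraction of iterations in which its exact leaf set reappears as a
#' clade.
#'
#' @param profiles cluster x gene numeric matrix with row names.
#' @param n_iter number of bootstrap iterations (default 10000).
#' @param gene_fraction fraction of genes drawn per iteration, in (0, 1].
#' @param seed integer seed.
#' @return a `taxonomy_tree` with `nodes$confidence` filled in.
#' @export
bootstrap_dendrogram <- function(profiles, n_iter = 10000, gene_fraction = 0.8,
                                 seed = 1L) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2) stop_bad("profiles", "need >= 2 clusters")
  if (ncol(profiles) < 5) stop_bad("profiles", "need >= 5 genes")
  check_scalar_number(n_iter, "n_iter", lower = 1, integer = TRUE)
  check_scalar_number(gene_fraction, "gene_fraction", lower = 0, upper = 1,
                      strict_lower = TRUE)
  withr::local_seed(seed)
  if (is.null(rownames(profiles)))
    rownames(profiles) <- sprintf("cl%02d", seq_len(nrow(profiles)))

  cor_tree <- function(m) {
    d <- as.dist(1 - cor(t(m)))
    hclust(d, method = "average")
  }
  ref <- cor_tree(profiles)
  tree <- new_taxonomy_tree(ref)
  keys <- vapply(tree$node_leaves, node_key, character(1))
  hits <- numeric(length(keys))
  n_genes <- ncol(profiles)
  k <- max(2L, round(gene_fraction * n_genes))
  for (b in seq_len(n_iter)) {
    gs <- sample.int(n_genes, k)
    hcb <- cor_tree(profiles[, gs, drop = FALSE])
    lv <- hclust_node_leaves(hcb)
    kb <- vapply(lv, function(i) node_key(hcb$labels[i]), character(1))
    hits <- hits + (keys %in% kb)
  }
  tree$nodes$confidence <- hits / n_iter
  tree
}

#' ROC-based marker selection
#'
#' For each cluster and gene, the AUC of expression for cluster-versus-rest
#' is computed from midranks (equivalent to the Mann-Whitney statistic);
#' classification power is `2 * |AUC - 0.5|`.  Genes with power above the
#' threshold are kept, at most `max_markers` per cluster, ranked by power.
#'
#' @param expr a [cell_expression()] (log2 CPM is computed internally) or a
#'   cells-by-genes numeric matrix of expression values.
#' @param labels per-cell cluster labels.
#' @param power_threshold minimum classification power (default 0.7).
#' @param max_markers maximum markers kept per cluster (default 50).
#' @param direction `"up"` (default) keeps only genes enriched in the
#'   cluster (AUC > 0.5); `"both"` also admits strongly depleted genes,
#'   which are equally discriminative but are not markers in the usual
#'   sense and can crowd out enriched ones under the `max_markers` cap.
#' @return a `marker_table` data frame (gene_id, cluster, auc, power, rank).
#' @export
select_markers_roc <- function(expr, labels, power_threshold = 0.7,
                               max_markers = 50,
                               direction = c("up", "both")) {
  direction <- match.arg(direction)
  x <- if (inherits(expr, "cell_expression")) log2_cpm(expr$counts)
       else as.matrix(expr)
  labels <- as.character(labels)
  if (length(labels) != nrow(x))
    stop_bad("labels", "must have one label per cell")
  if (length(unique(labels)) < 2) stop_bad("labels", "need >= 2 clusters")
  check_scalar_number(power_threshold, "power_threshold", lower = 0, upper = 1)
  check_scalar_number(max_markers, "max_markers", lower = 1, integer = TRUE)

  ranks <- apply(x, 2, rank)       # midranks handle ties
  n <- nrow(x)
  out <- list()
  for (cl in sort(unique(labels))) {
    in_cl <- labels == cl
    n1 <- sum(in_cl)
    if (n1 < 2) {
      warning(sprintf("cluster %s has < 2 cells; skipped", cl))
      next
    }
    n2 <- n - n1
    u <- colSums(ranks[in_cl, , drop = FALSE]) - n1 * (n1 + 1) / 2
    auc <- u / (n1 * n2)
    power <- 2 * abs(auc - 0.5)
    keep <- which(power > power_threshold &
                    (direction == "both" | auc > 0.5))
    if (!length(keep)) next
    keep <- keep[order(-power[keep])]
    keep <- head(keep, max_markers)
    out[[cl]] <- data.frame(gene_id = colnames(x)[keep], cluster = cl,
                            auc = auc[keep], power = power[keep],
                            rank = seq_along(keep), stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(gene_id = character(0), cluster = character(0),
               auc = numeric(0), power = numeric(0), rank = integer(0))
  rownames(res) <- NULL
  class(res) <- c("marker_table", "data.frame")
  res
}

#' Match two cluster labelings of the same cells
#'
#' Builds the confusion matrix of co-labelled cell counts; each query cluster
#' is matched to the reference cluster holding the maximum of its row
#' (ties: lowest reference index, logged).  The exact match fraction is the
#' fraction of cells whose reference label equals the best match of their
#' query label; with `subclass_of` supplied, the subclass match fraction
#' requires agreement only at the subclass level.
#'
#' @param query_labels,reference_labels label vectors over the same cells
#'   (aligned positionally; names, when present on both, are used to align).
#' @param subclass_of optional named vector mapping reference cluster ->
#'   subclass.
#' @return an object of class `confusion_summary`.
#' @export
match_taxonomies <- function(query_labels, reference_labels, subclass_of = NULL) {
  if (!is.null(names(query_labels)) && !is.null(names(reference_labels))) {
    common <- intersect(names(query_labels), names(reference_labels))
    if (!length(common)) stop_bad("query_labels", "disjoint cell id sets")
    query_labels <- query_labels[common]
    reference_labels <- reference_labels[common]
  }
  if (length(query_labels) != length(reference_labels))
    stop_bad("reference_labels", "labelings must cover the same cells")
  q <- as.character(query_labels)
  r <- as.character(reference_labels)
  tab <- table(q, r)
  ref_names <- colnames(tab)
  best_idx <- apply(tab, 1, which.max)   # which.max takes the first maximum
  ties <- apply(tab, 1, function(row) sum(row == max(row)) > 1)
  if (any(ties))
    message(sprintf("best_match ties in %d query cluster(s); lowest reference index used",
                    sum(ties)))
  best_match <- setNames(ref_names[best_idx], rownames(tab))
  exact <- mean(r == best_match[q])
  subclass_frac <- NA_real_
  if (!is.null(subclass_of)) {
    if (!all(ref_names %in% names(subclass_of)))
      stop_bad("subclass_of", "must cover every reference cluster")
    subclass_frac <- mean(subclass_of[r] == subclass_of[best_match[q]])
  }
  structure(list(matrix = unclass(tab), best_match = best_match,
                 exact_match_fraction = exact,
                 subclass_match_fraction = subclass_frac),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("<confusion_summary> exact match %.3f", x$exact_match_fraction))
  if (!is.na(x$subclass_match_fraction))
    cat(sprintf(", subclass match %.3f", x$subclass_match_fraction))
  cat("\n")
  invisible(x)
}

#' Fallback k-means over-clustering
#'
#' Provided for self-contained runs when no upstream over-clustering is
#' available; k defaults to 10 times the expected number of types.
#'
#' @param expr a [cell_expression()].
#' @param k number of over-clusters.
#' @param seed integer seed.
#' @return the expression object with `over_cluster` replaced by k-means
#'   labels computed on log2 CPM.
#' @export
overcluster_kmeans <- function(expr, k, seed = 1L) {
  stopifnot(inherits(expr, "cell_expression"))
  check_scalar_number(k, "k", lower = 2, integer = TRUE)
  withr::local_seed(seed)
  km <- kmeans(log2_cpm(expr$counts), centers = k, nstart = 5, iter.max = 50)
  expr$meta$over_cluster <- sprintf("km%03d", km$cluster)
  expr
}
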