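# Synthetic-data generators with planted ground truth.  Every downstream
# module can be exercised offline against these; the planted structures
# (taxonomy, modules, links, enrichment factor) are returned alongside the
# data so recovery can be scored.

#' Simulation settings for a planted cross-species taxonomy
#'
#' Describes a two-level cell-type hierarchy (types nested in subclasses)
#' shared across species, with species-specific marker divergence and donor
#' structure.  Counts are negative binomial with variance
#' `mu + mu^2 / nb_dispersion`.
#'
#' @param n_species number of species (>= 1).
#' @param n_subclasses number of subclasses.
#' @param types_per_subclass types nested within each subclass.
#' @param cells_per_type_per_species cells per (type, species).
#' @param donors_per_species donors per species; cells are spread evenly.
#' @param n_genes total genes.
#' @param marker_genes_per_type markers planted per type (and per subclass).
#' @param species_divergence fraction of each type's markers re-drawn per
#'   species, in \[0, 1\]; the re-drawn genes become species-enriched markers.
#' @param nb_mean baseline negative-binomial mean per gene.
#' @param nb_dispersion negative-binomial size parameter theta (> 0).
#' @param marker_fold fold elevation of marker genes over baseline (> 1,
#'   except `marker_fold = 1` which plants no structure at all).
#' @param donor_sd standard deviation (log scale) of the log-normal
#'   donor-by-gene multiplicative effect.
#' @param overclusters_per_type fine clusters each (type, species) group of
#'   cells is split into, emulating over-clustering.
#' @param seed integer seed; all randomness in the generator flows from it.
#' @return an object of class `taxonomy_sim_spec`.
#' @export
taxonomy_sim_spec <- function(n_species = 2L, n_subclasses = 5L,
                              types_per_subclass = 3L,
                              cells_per_type_per_species = 60L,
                              donors_per_species = 4L, n_genes = 1000L,
                              marker_genes_per_type = 10L,
                              species_divergence = 0.2, nb_mean = 1,
                              nb_dispersion = 10, marker_fold = 8,
                              donor_sd = 0.15, overclusters_per_type = 2L,
                              seed = 1L) {
  check_scalar_number(n_species, "n_species", lower = 1, integer = TRUE)
  check_scalar_number(n_subclasses, "n_subclasses", lower = 1, integer = TRUE)
  check_scalar_number(types_per_subclass, "types_per_subclass", lower = 1, integer = TRUE)
  check_scalar_number(cells_per_type_per_species, "cells_per_type_per_species",
                      lower = 1, integer = TRUE)
  check_scalar_number(donors_per_species, "donors_per_species", lower = 1, integer = TRUE)
  check_scalar_number(n_genes, "n_genes", lower = 1, integer = TRUE)
  check_scalar_number(marker_genes_per_type, "marker_genes_per_type",
                      lower = 0, integer = TRUE)
  check_scalar_number(species_divergence, "species_divergence", lower = 0, upper = 1)
  check_scalar_number(nb_mean, "nb_mean", lower = 0, strict_lower = TRUE)
  check_scalar_number(nb_dispersion, "nb_dispersion", lower = 0, strict_lower = TRUE)
  check_scalar_number(marker_fold, "marker_fold", lower = 1)
  check_scalar_number(donor_sd, "donor_sd", lower = 0)
  check_scalar_number(overclusters_per_type, "overclusters_per_type",
                      lower = 1, integer = TRUE)
  check_scalar_number(seed, "seed", integer = TRUE)
  n_types <- n_subclasses * types_per_subclass
  need <- n_types * marker_genes_per_type * (2 + n_species) +
    4 * n_subclasses * marker_genes_per_type
  if (n_genes < need)
    stop_bad("n_genes", sprintf(
      "too few genes to host markers: need >= %d", need))
  structure(as.list(environment())[c(
    "n_species", "n_subclasses", "types_per_subclass",
    "cells_per_type_per_species", "donors_per_species", "n_genes",
    "marker_genes_per_type", "species_divergence", "nb_mean",
    "nb_dispersion", "marker_fold", "donor_sd", "overclusters_per_type",
    "seed")], class = "taxonomy_sim_spec")
}

#' Cell-by-gene expression container
#'
#' Bundles a nonnegative integer count matrix with the four per-cell labels
#' every taxonomy operation requires (species, donor, class, over-cluster)
#' plus unique gene identifiers.
#'
#' @param counts cells-by-genes matrix of nonnegative integers.
#' @param species,donor,class_label,over_cluster per-cell label vectors.
#' @param gene_ids unique per-gene identifiers.
#' @param ortho_group optional per-gene orthologue-group identifiers.
#' @param truth optional list of planted ground-truth labels.
#' @return an object of class `cell_expression`.
#' @export
cell_expression <- function(counts, species, donor, class_label, over_cluster,
                            gene_ids, ortho_group = NULL, truth = NULL) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  for (nm in c("species", "donor", "class_label", "over_cluster")) {
    v <- get(nm)
    if (length(v) == 1L) assign(nm, rep(v, n))   # scalar labels recycle
    else if (length(v) != n || anyNA(v))
      stop_bad(nm, "must be a complete per-cell label vector")
  }
  if (length(gene_ids) != ncol(counts) || anyDuplicated(gene_ids))
    stop_bad("gene_ids", "must be unique and match the gene dimension")
  if (any(counts < 0) || any(counts != round(counts)))
    stop_bad("counts", "must be nonnegative integers")
  rownames(counts) <- sprintf("cell%05d", seq_len(n))
  colnames(counts) <- gene_ids
  structure(list(
    counts = counts,
    meta = data.frame(cell_id = rownames(counts),
                      species = as.character(species),
                      donor = as.character(donor),
                      class_label = as.character(class_label),
                      over_cluster = as.character(over_cluster),
                      stringsAsFactors = FALSE),
    gene_ids = as.character(gene_ids),
    ortho_group = ortho_group,
    truth = truth
  ), class = "cell_expression")
}

#' @export
print.cell_expression <- function(x, ...) {
  cat(sprintf("<cell_expression> %d cells x %d genes; %d species, %d over-clusters\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$meta$species)),
              length(unique(x$meta$over_cluster))))
  invisible(x)
}

#' Simulate counts with a planted two-level cross-species taxonomy
#'
#' Each type gets `marker_genes_per_type` marker genes at
#' `marker_fold` times the baseline mean; each subclass additionally gets
#' shared subclass markers so the planted hierarchy is clean at both levels.
#' Per species, a `species_divergence` fraction of each type's markers is
#' replaced by species-specific alternatives.  A log-normal donor-by-gene
#' factor gives pseudobulk replicates genuine between-donor variance.
#'
#' @param spec a [taxonomy_sim_spec()].
#' @return a [cell_expression()] whose `truth` holds planted `type`,
#'   `subclass` and marker assignments.
#' @export
simulate_taxonomy_counts <- function(spec) {
  if (!inherits(spec, "taxonomy_sim_spec"))
    stop_bad("spec", "must be a taxonomy_sim_spec")
  withr::local_seed(spec$seed)
  n_types <- spec$n_subclasses * spec$types_per_subclass
  genes <- sprintf("g%04d", seq_len(spec$n_genes))
  mk <- spec$marker_genes_per_type

  # reserve gene blocks: subclass markers, shared type markers, then a pool
  # of species-specific replacement markers
  idx <- 1L
  take <- function(k) {
    out <- seq.int(idx, length.out = k)
    idx <<- idx + k
    out
  }
  # subclass-level (and higher) signatures are broader than type-level ones
  # in real data; planting them at twice the type-marker count keeps
  # within-subclass types more similar to each other than to outsiders
  subclass_markers <- lapply(seq_len(spec$n_subclasses), function(s) take(2L * mk))
  # real taxonomies are hierarchical above the subclass level too; plant
  # markers for each internal grouping of a balanced binary tree over
  # subclasses so the upper tree structure is well determined
  subclass_groups <- balanced_groups(seq_len(spec$n_subclasses))
  group_markers <- lapply(subclass_groups, function(g) take(2L * mk))
  type_groups <- list()   # groups of types within each subclass
  for (sc in seq_len(spec$n_subclasses)) {
    base <- (sc - 1L) * spec$types_per_subclass
    type_groups <- c(type_groups,
                     balanced_groups(base + seq_len(spec$types_per_subclass)))
  }
  type_group_markers <- lapply(type_groups, function(g) take(mk))
  type_markers <- lapply(seq_len(n_types), function(t) take(mk))
  n_div <- round(spec$species_divergence * mk)
  species_markers <- lapply(seq_len(n_types), function(t)
    lapply(seq_len(spec$n_species), function(s)
      if (n_div > 0) take(n_div) else integer(0)))

  type_of <- rep(seq_len(n_types), each = spec$cells_per_type_per_species)
  subclass_of_type <- rep(seq_len(spec$n_subclasses), each = spec$types_per_subclass)

  blocks <- list()
  meta <- list()
  for (s in seq_len(spec$n_species)) {
    # per-species mean matrix at the type level
    mu_type <- matrix(spec$nb_mean, n_types, spec$n_genes)
    for (t in seq_len(n_types)) {
      sc_t <- subclass_of_type[t]
      for (gi in seq_along(subclass_groups))
        if (sc_t %in% subclass_groups[[gi]])
          mu_type[t, group_markers[[gi]]] <- spec$nb_mean * spec$marker_fold
      for (gi in seq_along(type_groups))
        if (t %in% type_groups[[gi]])
          mu_type[t, type_group_markers[[gi]]] <- spec$nb_mean * spec$marker_fold
      mu_type[t, subclass_markers[[sc_t]]] <- spec$nb_mean * spec$marker_fold
      shared <- type_markers[[t]]
      if (n_div > 0) {
        drop_idx <- seq_len(n_div)           # first n_div shared markers diverge
        shared <- shared[-drop_idx]
        mu_type[t, species_markers[[t]][[s]]] <- spec$nb_mean * spec$marker_fold
      }
      mu_type[t, shared] <- spec$nb_mean * spec$marker_fold
    }
    n_cells_s <- n_types * spec$cells_per_type_per_species
    donor_of <- rep_len(seq_len(spec$donors_per_species), n_cells_s)
    donor_fx <- matrix(rlnorm(spec$donors_per_species * spec$n_genes,
                              meanlog = -spec$donor_sd^2 / 2,
                              sdlog = spec$donor_sd),
                       spec$donors_per_species, spec$n_genes)
    mu_cell <- mu_type[type_of, , drop = FALSE] * donor_fx[donor_of, , drop = FALSE]
    cnt <- matrix(rnbinom(length(mu_cell), mu = mu_cell, size = spec$nb_dispersion),
                  nrow = n_cells_s)
    blocks[[s]] <- cnt
    oc_split <- unlist(lapply(seq_len(n_types), function(t)
      sample(rep_len(seq_len(spec$overclusters_per_type),
                     spec$cells_per_type_per_species))))
    meta[[s]] <- data.frame(
      species = sprintf("sp%d", s),
      donor = sprintf("sp%d_d%d", s, donor_of),
      type = sprintf("t%02d", type_of),
      subclass = sprintf("sc%02d", subclass_of_type[type_of]),
      over_cluster = sprintf("sp%d_t%02d_oc%d", s, type_of, oc_split),
      stringsAsFactors = FALSE)
  }
  counts <- do.call(rbind, blocks)
  meta <- do.call(rbind, meta)
  class_of_subclass <- rep_len(c("classA", "classB", "classC"),
                               spec$n_subclasses)
  class_label <- class_of_subclass[as.integer(sub("sc", "", meta$subclass))]
  truth <- list(
    type = meta$type, subclass = meta$subclass,
    subclass_of_type = setNames(sprintf("sc%02d", subclass_of_type),
                                sprintf("t%02d", seq_len(n_types))),
    # conserved type markers only: the first n_div of each block are the
    # ones replaced per species and are not elevated in any species
    type_markers = setNames(lapply(type_markers, function(i)
      genes[if (n_div > 0) i[-seq_len(n_div)] else i]),
      sprintf("t%02d", seq_len(n_types))),
    subclass_markers = setNames(lapply(subclass_markers, function(i) genes[i]),
                                sprintf("sc%02d", seq_len(spec$n_subclasses))),
    subclass_groups = lapply(subclass_groups,
                             function(g) sprintf("sc%02d", g)),
    species_markers = species_markers,
    spec = spec)
  cell_expression(counts, meta$species, meta$donor, class_label,
                  meta$over_cluster, genes, truth = truth)
}

#' Simulation settings for a planted regulatory landscape
#'
#' @param n_clusters number of cell clusters (shared axis of accessibility
#'   and expression).
#' @param n_ccres number of candidate cis-regulatory elements.
#' @param n_genes number of genes.
#' @param n_modules number of planted cis-regulatory modules; module
#'   membership partitions the cCREs.
#' @param n_true_links number of planted cCRE-to-gene links (same chromosome,
#'   > 1 kb and <= 500 kb from the TSS).
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param link_effect scaling of a linked gene's expression profile relative
#'   to its cCRE's accessibility profile, in (0, 1\].
#' @param noise_sd additive Gaussian noise on both matrices.
#' @param seed integer seed.
#' @return an object of class `reg_sim_spec`.
#' @export
reg_sim_spec <- function(n_clusters = 20L, n_ccres = 300L, n_genes = 100L,
                         n_modules = 5L, n_true_links = 50L,
                         chrom_lengths = c(chr1 = 1e7, chr2 = 1e7),
                         link_effect = 0.9, noise_sd = 0.1, seed = 1L) {
  check_scalar_number(n_clusters, "n_clusters", lower = 2, integer = TRUE)
  check_scalar_number(n_ccres, "n_ccres", lower = 1, integer = TRUE)
  check_scalar_number(n_genes, "n_genes", lower = 1, integer = TRUE)
  check_scalar_number(n_modules, "n_modules", lower = 1,
                      upper = min(n_ccres, n_clusters), integer = TRUE)
  check_scalar_number(n_true_links, "n_true_links", lower = 0, integer = TRUE)
  if (is.null(names(chrom_lengths)) || any(chrom_lengths <= 0))
    stop_bad("chrom_lengths", "must be a named vector of positive lengths")
  check_scalar_number(link_effect, "link_effect", lower = 0, upper = 1,
                      strict_lower = TRUE)
  check_scalar_number(noise_sd, "noise_sd", lower = 0)
  check_scalar_number(seed, "seed", integer = TRUE)
  if (n_true_links > min(n_ccres, n_genes))
    stop_bad("n_true_links", "cannot exceed min(n_ccres, n_genes)")
  # feasibility: each element occupies ~1 kb and links need 1 Mb of room
  if (sum(chrom_lengths) < 1000 * (n_ccres + n_genes) ||
      min(chrom_lengths) < 1.2e6)
    stop_bad("chrom_lengths", "chromosomes too short for requested elements")
  structure(list(n_clusters = n_clusters, n_ccres = n_ccres,
                 n_genes = n_genes, n_modules = n_modules,
                 n_true_links = n_true_links, chrom_lengths = chrom_lengths,
                 link_effect = link_effect, noise_sd = noise_sd, seed = seed),
            class = "reg_sim_spec")
}

#' Simulate a regulatory landscape with planted modules and links
#'
#' Accessibility is built as a nonnegative module-basis x cluster-coefficient
#' product plus noise.  For each planted link the gene's cluster expression
#' profile equals the cCRE's accessibility profile scaled by `link_effect`
#' plus noise; unlinked genes get independent profiles.
#'
#' @param spec a [reg_sim_spec()].
#' @return list with `accessibility` (cCRE x cluster), `expression`
#'   (gene x cluster), `annotation` (a [genome_annotation()]), `ccres`
#'   (a `peak_set` of element positions) and `truth` (planted pairs, module
#'   assignments and module-cluster activity).
#' @export
simulate_regulatory_landscape <- function(spec) {
  if (!inherits(spec, "reg_sim_spec"))
    stop_bad("spec", "must be a reg_sim_spec")
  withr::local_seed(spec$seed)
  chroms <- names(spec$chrom_lengths)

  module_of <- sort(rep_len(seq_len(spec$n_modules), spec$n_ccres))
  W <- matrix(0, spec$n_ccres, spec$n_modules)
  W[cbind(seq_len(spec$n_ccres), module_of)] <- runif(spec$n_ccres, 0.5, 1.5)
  H <- matrix(0, spec$n_modules, spec$n_clusters)
  # each module is active in its own disjoint slice of clusters (plus, when
  # clusters remain, a few extra random ones) so modules are identifiable
  slice <- split(seq_len(spec$n_clusters),
                 sort(rep_len(seq_len(spec$n_modules), spec$n_clusters)))
  cluster_activity <- list()
  for (m in seq_len(spec$n_modules)) {
    act <- slice[[m]]
    H[m, act] <- runif(length(act), 1, 2)
    cluster_activity[[m]] <- act
  }
  acc <- W %*% H
  if (spec$noise_sd > 0)
    acc <- pmax(acc + matrix(rnorm(length(acc), sd = spec$noise_sd),
                             nrow(acc)), 0)
  ccre_ids <- sprintf("ccre%04d", seq_len(spec$n_ccres))
  gene_ids <- sprintf("gene%04d", seq_len(spec$n_genes))
  dimnames(acc) <- list(ccre_ids, sprintf("cl%02d", seq_len(spec$n_clusters)))

  # place cCREs on a grid (>= 1 kb spacing keeps them non-overlapping)
  ccre_chrom <- sample(chroms, spec$n_ccres, replace = TRUE)
  ccre_center <- integer(spec$n_ccres)
  for (ch in chroms) {
    on_ch <- which(ccre_chrom == ch)
    slots <- seq(6e5, spec$chrom_lengths[[ch]] - 6e5, by = 1000)
    ccre_center[on_ch] <- sort(sample(slots, length(on_ch)))
  }
  ccres <- data.frame(chrom = ccre_chrom,
                      start = ccre_center - 250L,
                      end = ccre_center + 251L,
                      score = 10, spm = NA_real_, cluster = "union",
                      ccre_id = ccre_ids, stringsAsFactors = FALSE)
  class(ccres) <- c("peak_set", "data.frame")

  # planted links: gene TSS placed 1 kb - 500 kb from its cCRE
  linked_ccre <- sample(spec$n_ccres, spec$n_true_links)
  linked_gene <- sample(spec$n_genes, spec$n_true_links)
  gene_chrom <- sample(chroms, spec$n_genes, replace = TRUE)
  gene_tss <- integer(spec$n_genes)
  for (ch in chroms) {
    on_ch <- which(gene_chrom == ch)
    slots <- seq(5e5, spec$chrom_lengths[[ch]] - 5e5, by = 1500) + 750
    gene_tss[on_ch] <- sort(sample(slots, length(on_ch)))
  }
  if (spec$n_true_links > 0) {
    offs <- sample(c(-1, 1), spec$n_true_links, replace = TRUE) *
      round(runif(spec$n_true_links, 1500, 4.99e5))
    gene_chrom[linked_gene] <- ccre_chrom[linked_ccre]
    gene_tss[linked_gene] <- pmin(
      pmax(ccre_center[linked_ccre] + offs, 1001),
      spec$chrom_lengths[gene_chrom[linked_gene]] - 1001)
  }
  annotation <- genome_annotation(
    data.frame(gene_id = gene_ids, chrom = gene_chrom, tss = gene_tss,
               strand = sample(c("+", "-"), spec$n_genes, replace = TRUE),
               stringsAsFactors = FALSE),
    spec$chrom_lengths)

  expr <- matrix(0, spec$n_genes, spec$n_clusters,
                 dimnames = list(gene_ids, colnames(acc)))
  base_m <- mean(acc)
  base_s <- sd(acc)
  for (g in seq_len(spec$n_genes)) {
    li <- match(g, linked_gene)
    if (!is.na(li)) {
      expr[g, ] <- spec$link_effect * acc[linked_ccre[li], ]
    } else {
      expr[g, ] <- pmax(rnorm(spec$n_clusters, mean = base_m, sd = base_s), 0)
    }
  }
  if (spec$noise_sd > 0)
    expr <- pmax(expr + matrix(rnorm(length(expr), sd = spec$noise_sd),
                               nrow(expr)), 0)
  truth <- list(
    pairs = data.frame(ccre_id = ccre_ids[linked_ccre],
                       gene_id = gene_ids[linked_gene],
                       stringsAsFactors = FALSE),
    module_assignments = setNames(module_of, ccre_ids),
    cluster_activity = lapply(cluster_activity,
                              function(i) colnames(acc)[i]))
  list(accessibility = acc, expression = expr, annotation = annotation,
       ccres = ccres, truth = truth)
}

#' Simulate per-cluster peak summit sets with engineered overlap chains
#'
#' Most summits are isolated (their 501-bp extensions are pairwise disjoint);
#' a stated fraction is laid out as A-B-C chains in which A overlaps B and B
#' overlaps C but A does not overlap C after extension - the stress case for
#' daisy-chain-free merging.
#'
#' @param n_per_cluster summits per cluster.
#' @param n_clusters number of clusters.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param overlap_chain_fraction fraction of summits placed in chains, \[0, 1\].
#' @param seed integer seed.
#' @param flank half-width used to reason about extension overlap (default 250).
#' @return a `summit_set` data frame (chrom, summit_pos, score, cluster) with
#'   a `chains` attribute listing planted chain member indices.
#' @export
simulate_summits <- function(n_per_cluster, n_clusters, chrom_lengths,
                             overlap_chain_fraction = 0.2, seed = 1L,
                             flank = 250L) {
  check_scalar_number(n_per_cluster, "n_per_cluster", lower = 1, integer = TRUE)
  check_scalar_number(n_clusters, "n_clusters", lower = 1, integer = TRUE)
  check_scalar_number(overlap_chain_fraction, "overlap_chain_fraction",
                      lower = 0, upper = 1)
  check_scalar_number(seed, "seed", integer = TRUE)
  if (is.null(names(chrom_lengths)) || any(chrom_lengths <= 0))
    stop_bad("chrom_lengths", "must be a named vector of positive lengths")
  width <- 2L * flank + 1L
  if (min(chrom_lengths) < 10 * width)
    stop_bad("chrom_lengths", "chromosome too short for extended peaks")
  withr::local_seed(seed)
  total <- n_per_cluster * n_clusters
  n_chains <- floor(overlap_chain_fraction * total / 3)
  n_iso <- total - 3L * n_chains
  chroms <- names(chrom_lengths)

  # anchor slots spaced >= 3 widths apart guarantee no accidental overlap
  pos <- character(0)
  anchor_chrom <- character(0)
  anchor_pos <- integer(0)
  need <- n_chains + n_iso
  per_chrom <- table(sample(chroms, need, replace = TRUE))
  for (ch in names(per_chrom)) {
    k <- per_chrom[[ch]]
    slots <- seq(flank + 1, chrom_lengths[[ch]] - 4L * width, by = 3L * width)
    if (length(slots) < k)
      stop_bad("chrom_lengths", sprintf("chromosome %s too short for %d summits", ch, k))
    p <- sort(sample(slots, k))
    anchor_chrom <- c(anchor_chrom, rep(ch, k))
    anchor_pos <- c(anchor_pos, p)
  }
  ord <- sample(need)
  anchor_chrom <- anchor_chrom[ord]
  anchor_pos <- anchor_pos[ord]

  gap <- as.integer(floor(width * 0.8))  # < width: adjacent members overlap;
  stopifnot(2L * gap >= width)           # 2*gap >= width: outer members do not
  chrom <- c(anchor_chrom[seq_len(n_iso)],
             rep(anchor_chrom[n_iso + seq_len(n_chains)], each = 3L))
  summit <- c(anchor_pos[seq_len(n_iso)],
              as.vector(vapply(anchor_pos[n_iso + seq_len(n_chains)],
                               function(p) p + c(0, gap, 2 * gap),
                               numeric(3))))
  score <- round(rgamma_scores(length(summit)), 3)
  cluster <- sprintf("cl%02d", sample(rep_len(seq_len(n_clusters), length(summit))))
  out <- data.frame(chrom = chrom, summit_pos = as.integer(summit),
                    score = score, cluster = cluster, stringsAsFactors = FALSE)
  class(out) <- c("summit_set", "data.frame")
  attr(out, "chains") <- if (n_chains > 0)
    lapply(seq_len(n_chains), function(i) n_iso + 3L * (i - 1L) + 1:3)
  else list()
  out
}

# internal groupings (size >= 2, excluding the root set) of a balanced
# binary tree over the given items
balanced_groups <- function(items) {
  out <- list()
  recurse <- function(v, is_root) {
    if (length(v) < 2) return(invisible())
    if (!is_root) out[[length(out) + 1L]] <<- v
    h <- ceiling(length(v) / 2)
    recurse(v[seq_len(h)], FALSE)
    recurse(v[-seq_len(h)], FALSE)
  }
  recurse(items, TRUE)
  out
}

# -log10(q)-style scores: gamma-distributed, bounded away from zero
rgamma_scores <- function(n) stats::rgamma(n, shape = 2, scale = 5) + 0.5

#' Simulate pseudobulk counts for two species with optional planted shifts
#'
#' Draws donor-replicate negative-binomial counts at the pseudobulk level
#' for a single cluster and two species, with log-normal gene baselines and
#' per-sample depth (size) factors.  `fold_genes` are elevated `fold`-times
#' in the first species.  Used to calibrate and validate [pairwise_de()].
#'
#' @param n_genes number of genes.
#' @param donors_per_species replicates per species.
#' @param dispersion NB dispersion alpha (variance = mu + alpha mu^2).
#' @param base_log_mean,base_log_sd log-normal parameters of gene baselines.
#' @param size_factor_sd log-sd of per-sample depth factors.
#' @param fold_genes indices of genes shifted in species A.
#' @param fold fold change applied to `fold_genes`.
#' @param cluster cluster label for the samples.
#' @param seed integer seed.
#' @return a `pseudobulk` object (see [make_pseudobulk()]).
#' @export
simulate_pseudobulk_counts <- function(n_genes = 2000, donors_per_species = 4,
                                       dispersion = 0.1, base_log_mean = log(20),
                                       base_log_sd = 1, size_factor_sd = 0.2,
                                       fold_genes = integer(0), fold = 1,
                                       cluster = "cc01", seed = 1L) {
  check_scalar_number(n_genes, "n_genes", lower = 1, integer = TRUE)
  check_scalar_number(donors_per_species, "donors_per_species", lower = 1,
                      integer = TRUE)
  check_scalar_number(dispersion, "dispersion", lower = 0, strict_lower = TRUE)
  check_scalar_number(seed, "seed", integer = TRUE)
  withr::local_seed(seed)
  n_samp <- 2L * donors_per_species
  base <- exp(rnorm(n_genes, base_log_mean, base_log_sd))
  mu <- matrix(rep(base, each = n_samp), n_samp, n_genes)
  sp <- rep(c("spA", "spB"), each = donors_per_species)
  if (length(fold_genes))
    mu[sp == "spA", fold_genes] <- mu[sp == "spA", fold_genes] * fold
  depth <- exp(rnorm(n_samp, 0, size_factor_sd))
  mu <- mu * depth
  y <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion), n_samp)
  colnames(y) <- sprintf("g%04d", seq_len(n_genes))
  samples <- data.frame(sample = sprintf("pb%03d", seq_len(n_samp)),
                        species = sp,
                        donor = sprintf("%s_d%d", sp,
                                        rep(seq_len(donors_per_species), 2)),
                        cluster = cluster, n_cells = NA_integer_,
                        flagged = FALSE, stringsAsFactors = FALSE)
  rownames(y) <- samples$sample
  structure(list(counts = y, samples = samples), class = "pseudobulk")
}

#' Simulate a projection-labelling (retrograde tracing) experiment
#'
#' Each FANS-style run sorts `cells_per_run` cells into on-target and
#' off-target subclasses.  The on-target odds are `true_fold` times the
#' unbiased baseline odds `baseline_on / baseline_off`, so the expected
#' enrichment ratio r_p equals `true_fold * r_u`.
#'
#' @param n_runs number of independent runs.
#' @param baseline_on,baseline_off on/off-target cell counts in unbiased data.
#' @param true_fold planted fold enrichment (> 0).
#' @param cells_per_run cells sorted per run (> 0).
#' @param seed integer seed.
#' @return a `projection_counts` data frame (run, on_target, off_target) with
#'   baseline counts stored as attributes.
#' @export
simulate_projection_experiment <- function(n_runs, baseline_on, baseline_off,
                                           true_fold, cells_per_run,
                                           seed = 1L) {
  check_scalar_number(n_runs, "n_runs", lower = 1, integer = TRUE)
  check_scalar_number(baseline_on, "baseline_on", lower = 0, strict_lower = TRUE)
  check_scalar_number(baseline_off, "baseline_off", lower = 0, strict_lower = TRUE)
  check_scalar_number(true_fold, "true_fold", lower = 0, strict_lower = TRUE)
  check_scalar_number(cells_per_run, "cells_per_run", lower = 1, integer = TRUE)
  check_scalar_number(seed, "seed", integer = TRUE)
  withr::local_seed(seed)
  odds <- true_fold * baseline_on / baseline_off
  p_on <- odds / (1 + odds)
  on <- rbinom(n_runs, cells_per_run, p_on)
  out <- data.frame(run = seq_len(n_runs), on_target = on,
                    off_target = cells_per_run - on)
  attr(out, "baseline_on") <- baseline_on
  attr(out, "baseline_off") <- baseline_off
  attr(out, "true_fold") <- true_fold
  class(out) <- c("projection_counts", "data.frame")
  out
}
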