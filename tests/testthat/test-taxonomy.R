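test_that("aggregate_metacells reproduces single-cell profiles exactly", {
  ex <- noiseless_expression(n_clusters = 3, cells_per_cluster = 1)
  mc <- aggregate_metacells(ex)
  expect_equal(unname(mc$profiles), unname(log2_cpm(ex$counts)))

  ex2 <- noiseless_expression(n_clusters = 3, cells_per_cluster = 15)
  mc2 <- aggregate_metacells(ex2)
  # identical cells within a cluster: profile equals any one cell's vector
  lc <- log2_cpm(ex2$counts)
  expect_equal(unname(mc2$profiles["oc01", ]), unname(lc[1, ]))
  expect_identical(sum(mc2$sizes), nrow(ex2$counts))
})

test_that("build_tree implements Ward merges (4-point oracle) and validity", {
  # two well-separated pairs: first merges must join the pairs
  prof <- rbind(a1 = c(0, 0.1), a2 = c(0.1, 0), b1 = c(10, 10.1),
                b2 = c(10.1, 10))
  tree <- build_tree(prof)
  first_two <- lapply(1:2, function(i) sort(tree$node_leaves[[i]]))
  expect_setequal(lapply(first_two, paste, collapse = "+"),
                  list("a1+a2", "b1+b2"))
  expect_error(build_tree(rbind(c(1, NaN), c(0, 1))), "NaN")
  expect_error(build_tree(prof[1, , drop = FALSE]), ">= 2")

  # property: leaf-set partition and height monotonicity on random profiles
  for (s in 1:5) {
    p <- withr::with_seed(s, matrix(rnorm(80), 8,
                                    dimnames = list(letters[1:8], NULL)))
    tr <- build_tree(p)
    expect_true(all(diff(tr$nodes$height) >= -1e-9))
    root <- tr$node_leaves[[length(tr$node_leaves)]]
    expect_setequal(root, letters[1:8])
    for (i in seq_len(nrow(tr$hc$merge))) {
      kids <- tr$hc$merge[i, ]
      sets <- lapply(kids, function(k)
        if (k < 0) tr$labels[-k] else tr$node_leaves[[k]])
      expect_length(intersect(sets[[1]], sets[[2]]), 0)
      expect_setequal(c(sets[[1]], sets[[2]]), tr$node_leaves[[i]])
    }
  }
})

test_that("assess_tree scores noiseless data fully stable and mixing correctly", {
  ex <- noiseless_expression(n_clusters = 6, cells_per_cluster = 20,
                             n_species = 2)
  tree <- build_tree(aggregate_metacells(ex))
  tree <- assess_tree(ex, tree, n_subsamples = 25, seed = 5)
  expect_true(all(tree$nodes$stability == 1))
  expect_true(all(tree$nodes$mixing >= 0 & tree$nodes$mixing <= 1))

  # single species: entropy-based mixing is identically zero
  ex1 <- noiseless_expression(n_clusters = 4, n_species = 1)
  tr1 <- assess_tree(ex1, build_tree(aggregate_metacells(ex1)),
                     n_subsamples = 5, seed = 1)
  expect_true(all(tr1$nodes$mixing == 0))

  expect_error(assess_tree(ex, tree, n_subsamples = 0), "n_subsamples")
  expect_error(assess_tree(ex, tree, subsample_fraction = 1.2),
               "subsample_fraction")
})

test_that("prune_to_consensus honours degenerate criteria and is stable", {
  ex <- noiseless_expression(n_clusters = 6, cells_per_cluster = 20)
  tree <- assess_tree(ex, build_tree(aggregate_metacells(ex)),
                      n_subsamples = 20, seed = 2)
  all_zero <- list(min_size = 0, min_mixing = 0, min_stability = 0)
  cc0 <- prune_to_consensus(tree, all_zero)
  expect_identical(length(unique(cc0$assignment)), length(tree$labels))

  cc_big <- prune_to_consensus(tree, list(min_size = 1e9, min_mixing = 0,
                                          min_stability = 0))
  expect_identical(length(unique(cc_big$assignment)), 1L)

  expect_error(prune_to_consensus(tree, list(min_size = -1, min_mixing = 0,
                                             min_stability = 0)), "min_size")

  # determinism / idempotence: identical inputs give identical partitions,
  # and every retained split satisfies the criteria on both children
  crit <- list(min_size = 10, min_mixing = 0, min_stability = 0.5)
  cc_a <- prune_to_consensus(tree, crit)
  cc_b <- prune_to_consensus(tree, crit)
  expect_identical(cc_a$assignment, cc_b$assignment)
  keys <- vapply(tree$node_leaves, function(l) paste(sort(l), collapse = "|"),
                 character(1))
  for (id in unique(cc_a$assignment)) {
    members <- sort(names(cc_a$assignment)[cc_a$assignment == id])
    expect_true(length(members) == 1 ||
                  paste(members, collapse = "|") %in% keys)
  }
})

test_that("bootstrap_dendrogram confidence behaves at its edges", {
  prof2 <- rbind(a = c(1, 2, 3, 4, 5, 1), b = c(5, 4, 3, 2, 1, 2))
  bt2 <- bootstrap_dendrogram(prof2, n_iter = 20, seed = 1)
  expect_equal(bt2$nodes$confidence, 1)   # two leaves: only one topology

  prof <- withr::with_seed(2, matrix(rnorm(60), 6) + 10 * tcrossprod(
    rep(1:3, each = 2), rep(1, 10)))
  rownames(prof) <- paste0("c", 1:6)
  bt <- bootstrap_dendrogram(prof, n_iter = 50, gene_fraction = 1, seed = 3)
  expect_true(all(bt$nodes$confidence == 1))  # no resampling variation

  expect_error(bootstrap_dendrogram(prof, gene_fraction = 0), "gene_fraction")
  expect_error(bootstrap_dendrogram(prof[, 1:3], n_iter = 5), "genes")
})

test_that("select_markers_roc finds exclusive genes and skips flat ones", {
  ex <- noiseless_expression(n_clusters = 3, cells_per_cluster = 10,
                             genes_per_cluster = 4)
  mk <- select_markers_roc(ex, ex$meta$over_cluster)
  m1 <- mk[mk$cluster == "oc01", ]
  expect_true(all(c("g001", "g002", "g003", "g004") %in% m1$gene_id))
  expect_true(all(m1$power[m1$gene_id %in% sprintf("g%03d", 1:4)] == 1))
  expect_true(all(mk$power >= 0 & mk$power <= 1))
  expect_true(all(abs(mk$power - 2 * abs(mk$auc - 0.5)) < 1e-12))

  # planted markers recovered on the NB simulation
  spec <- taxonomy_sim_spec(n_subclasses = 2, types_per_subclass = 2,
                            cells_per_type_per_species = 40, n_genes = 300,
                            seed = 7)
  sim <- simulate_taxonomy_counts(spec)
  mk2 <- select_markers_roc(sim, sim$truth$type)
  recall <- mean(vapply(names(sim$truth$type_markers), function(t)
    mean(sim$truth$type_markers[[t]] %in% mk2$gene_id[mk2$cluster == t]),
    numeric(1)))
  expect_gte(recall, 0.9)
})

test_that("match_taxonomies is exact for relabelings and ~chance for noise", {
  lab <- sprintf("c%d", rep(1:5, each = 20))
  m <- match_taxonomies(lab, lab)
  expect_equal(m$exact_match_fraction, 1)
  ren <- setNames(sprintf("r%d", 5:1), sprintf("c%d", 1:5))
  expect_equal(match_taxonomies(lab, ren[lab])$exact_match_fraction, 1)
  expect_equal(match_taxonomies(ren[lab], lab)$exact_match_fraction, 1)

  q <- withr::with_seed(1, sample(sprintf("q%02d", 1:10), 10000, TRUE))
  r <- withr::with_seed(2, sample(sprintf("r%02d", 1:10), 10000, TRUE))
  frac <- match_taxonomies(q, r)$exact_match_fraction
  expect_lt(abs(frac - 0.1), 0.02)

  expect_error(match_taxonomies(setNames(lab, paste0("x", seq_along(lab))),
                                setNames(lab, paste0("y", seq_along(lab)))),
               "disjoint")

  # subclass-level match through a coarser mapping
  sub_of <- setNames(c("s1", "s1", "s2", "s2", "s2"), sprintf("c%d", 1:5))
  swap <- setNames(c("c2", "c1", "c3", "c4", "c5"), sprintf("c%d", 1:5))
  ms <- match_taxonomies(swap[lab], lab, subclass_of = sub_of)
  expect_equal(ms$subclass_match_fraction, 1)
})
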