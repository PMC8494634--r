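test_that("taxonomy generator is deterministic and keeps its invariants", {
  spec <- taxonomy_sim_spec(n_subclasses = 2, types_per_subclass = 2,
                            cells_per_type_per_species = 10, n_genes = 300,
                            seed = 1)
  a <- simulate_taxonomy_counts(spec)
  b <- simulate_taxonomy_counts(spec)
  expect_identical(a$counts, b$counts)
  expect_identical(a$meta, b$meta)

  expect_true(all(a$counts >= 0))
  expect_true(all(a$counts == round(a$counts)))
  expect_false(anyNA(a$meta))
  # 2-level hierarchy: each type maps to exactly one subclass
  expect_true(all(tapply(a$truth$subclass, a$truth$type,
                         function(x) length(unique(x))) == 1))
  # over-clusters nest within (species, type)
  key <- paste(a$meta$species, a$truth$type)
  expect_true(all(tapply(key, a$meta$over_cluster,
                         function(x) length(unique(x))) == 1))
})

test_that("taxonomy generator rejects invalid specs naming the field", {
  expect_error(taxonomy_sim_spec(species_divergence = 1.5), "species_divergence")
  expect_error(taxonomy_sim_spec(nb_mean = 0), "nb_mean")
  expect_error(taxonomy_sim_spec(n_genes = 10), "n_genes")
  expect_error(taxonomy_sim_spec(cells_per_type_per_species = -1),
               "cells_per_type_per_species")
})

test_that("single species with zero divergence plants only conserved markers", {
  spec <- taxonomy_sim_spec(n_species = 1, species_divergence = 0,
                            n_subclasses = 2, types_per_subclass = 2,
                            cells_per_type_per_species = 10, n_genes = 300,
                            seed = 3)
  ex <- simulate_taxonomy_counts(spec)
  expect_true(all(lengths(lapply(ex$truth$species_markers, unlist)) == 0))
  expect_identical(unique(ex$meta$species), "sp1")
})

test_that("marker_fold = 1 plants no recoverable structure", {
  spec <- taxonomy_sim_spec(n_subclasses = 2, types_per_subclass = 2,
                            cells_per_type_per_species = 30, n_genes = 300,
                            marker_fold = 1, seed = 5)
  ex <- simulate_taxonomy_counts(spec)
  tree <- assess_tree(ex, build_tree(aggregate_metacells(ex)),
                      n_subsamples = 30, seed = 6)
  cc <- prune_to_consensus(tree)
  cell_cc <- cc$assignment[ex$meta$over_cluster]
  expect_lt(adjusted_rand_index(cell_cc, ex$truth$type), 0.2)
})

test_that("regulatory generator honours the noiseless limit and edge cases", {
  spec0 <- reg_sim_spec(n_true_links = 10, link_effect = 1, noise_sd = 0,
                        seed = 2)
  sim <- simulate_regulatory_landscape(spec0)
  for (i in seq_len(nrow(sim$truth$pairs))) {
    r <- cor(sim$accessibility[sim$truth$pairs$ccre_id[i], ],
             sim$expression[sim$truth$pairs$gene_id[i], ])
    expect_equal(r, 1, tolerance = 1e-12)
  }
  # planted links obey the distance rules
  centers <- with(as.data.frame(sim$ccres), floor((start + end) / 2))
  names(centers) <- sim$ccres$ccre_id
  tss <- setNames(sim$annotation$genes$tss, sim$annotation$genes$gene_id)
  gchr <- setNames(sim$annotation$genes$chrom, sim$annotation$genes$gene_id)
  cchr <- setNames(sim$ccres$chrom, sim$ccres$ccre_id)
  d <- abs(centers[sim$truth$pairs$ccre_id] - tss[sim$truth$pairs$gene_id])
  expect_true(all(cchr[sim$truth$pairs$ccre_id] == gchr[sim$truth$pairs$gene_id]))
  expect_true(all(d > 1000 & d <= 5e5))

  # rank-1 structure when a single module is planted without noise
  sim1 <- simulate_regulatory_landscape(
    reg_sim_spec(n_modules = 1, n_true_links = 0, noise_sd = 0, seed = 3))
  sv <- svd(sim1$accessibility)$d
  expect_lt(sv[2] / sv[1], 1e-10)
  expect_identical(nrow(sim1$truth$pairs), 0L)

  expect_error(reg_sim_spec(chrom_lengths = c(chr1 = 1e5, chr2 = 1e5)),
               "chrom_lengths")
  spec <- reg_sim_spec(seed = 4)
  expect_identical(simulate_regulatory_landscape(spec)$accessibility,
                   simulate_regulatory_landscape(spec)$accessibility)
})

test_that("summit generator controls chains, disjointness and determinism", {
  cl <- c(chr1 = 1e7, chr2 = 5e6)
  s0 <- simulate_summits(40, 3, cl, overlap_chain_fraction = 0, seed = 4)
  p0 <- extend_summits(s0, chrom_sizes = cl)
  # all extended peaks pairwise disjoint
  for (ch in unique(p0$chrom)) {
    st <- sort(p0$start[p0$chrom == ch])
    if (length(st) > 1) expect_true(all(diff(st) >= 501))
  }
  s1 <- simulate_summits(40, 3, cl, overlap_chain_fraction = 0.3, seed = 4)
  chains <- attr(s1, "chains")
  expect_gt(length(chains), 0)
  for (idx in chains) {
    pos <- s1$summit_pos[idx]
    expect_true(all(diff(pos) < 501))     # adjacent members overlap
    expect_gte(pos[3] - pos[1], 501)      # outer members do not
  }
  expect_identical(simulate_summits(10, 2, cl, seed = 9),
                   simulate_summits(10, 2, cl, seed = 9))
  expect_error(simulate_summits(10, 2, c(chr1 = 100), seed = 1), "chrom_lengths")
})

test_that("projection generator matches its planted enrichment", {
  pc <- simulate_projection_experiment(200, 202, 3434, true_fold = 30,
                                       cells_per_run = 500, seed = 2)
  pe <- projection_enrichment(pc)
  expect_lt(abs(pe$mean_fold - 30) / 30, 0.1)

  pc1 <- simulate_projection_experiment(400, 100, 100, true_fold = 1,
                                        cells_per_run = 400, seed = 3)
  pe1 <- projection_enrichment(pc1)
  expect_lt(abs(pe1$mean_fold - 1), 0.05)

  expect_error(simulate_projection_experiment(10, 0, 10, 2, 100), "baseline_on")
  expect_error(simulate_projection_experiment(10, 10, 10, 2, 0), "cells_per_run")
})

test_that("pseudobulk generator is deterministic with valid structure", {
  pb <- simulate_pseudobulk_counts(n_genes = 50, seed = 11)
  expect_identical(pb$counts, simulate_pseudobulk_counts(n_genes = 50, seed = 11)$counts)
  expect_identical(dim(pb$counts), c(8L, 50L))
  expect_setequal(unique(pb$samples$species), c("spA", "spB"))
})
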