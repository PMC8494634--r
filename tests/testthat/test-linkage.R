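toy_annotation <- function() {
  genome_annotation(
    data.frame(gene_id = c("gA", "gB", "gC"),
               chrom = c("chr1", "chr1", "chr2"),
               tss = c(100000, 900000, 500000),
               strand = c("+", "-", "+")),
    c(chr1 = 2e6, chr2 = 2e6))
}

toy_peaks <- function(centers, chrom = "chr1") {
  df <- data.frame(chrom = chrom, start = centers - 250L, end = centers + 251L,
                   score = 1, spm = 10, cluster = "c1",
                   ccre_id = sprintf("p%02d", seq_along(centers)))
  class(df) <- c("peak_set", "data.frame")
  df
}

test_that("fit_null_threshold honours its FDR definition", {
  bg <- withr::with_seed(1, rnorm(5000))
  # vacuous control: fdr = 1 puts the threshold at the minimum observed score
  nm1 <- fit_null_threshold(bg, fdr = 1)
  expect_equal(nm1$score_threshold, min(bg))

  # observed = background: essentially nothing passes at fdr 0.01
  nm <- fit_null_threshold(bg, fdr = 0.01)
  expect_lte(mean(bg >= nm$score_threshold), 0.005)

  # half the observations shifted far above the null: the shifted half passes
  obs <- c(bg[1:1000], bg[1:1000] + 5)
  nm2 <- fit_null_threshold(bg, observed_scores = obs, fdr = 0.01)
  expect_gte(mean(obs >= nm2$score_threshold), 0.45)
  expect_lte(mean(obs[1:1000] >= nm2$score_threshold), 0.02)

  expect_error(fit_null_threshold(rep(1, 100)), "zero variance")
  expect_error(fit_null_threshold(rnorm(10)), "30")
})

test_that("classify_proximity applies the +/- 1 kb rule", {
  ann <- toy_annotation()
  pk <- toy_peaks(c(100500, 101500, 98500))
  expect_identical(classify_proximity(pk, ann),
                   c("proximal", "distal", "distal"))
  # gene-free chromosome is distal
  pk2 <- toy_peaks(5000, chrom = "chr3")
  ann2 <- genome_annotation(ann$genes, c(chr1 = 2e6, chr2 = 2e6, chr3 = 1e5))
  expect_identical(classify_proximity(pk2, ann2), "distal")
  empty_ann <- ann; empty_ann$genes <- ann$genes[0, ]
  expect_error(classify_proximity(pk, empty_ann), "empty")
})

test_that("candidate_pairs equals a brute-force window scan", {
  ann <- toy_annotation()
  pk <- toy_peaks(c(100000, 500000, 610000, 1e6 + 5e5))
  got <- candidate_pairs(pk, ann)
  centers <- floor((pk$start + pk$end) / 2)
  want <- expand.grid(i = seq_len(nrow(pk)), j = seq_len(nrow(ann$genes)))
  want$ok <- pk$chrom[want$i] == ann$genes$chrom[want$j] &
    abs(centers[want$i] - ann$genes$tss[want$j]) <= 5e5
  expect_identical(nrow(got), sum(want$ok))
  # 400 kb in, 600 kb out, cross-chromosome out
  expect_true(any(got$ccre_id == "p02" & got$gene_id == "gA"))   # 400 kb
  expect_false(any(got$ccre_id == "p03" & got$gene_id == "gA"))  # 510 kb
  expect_false(any(got$gene_id == "gC"))
  # minus-strand genes flip the distance sign: p02 centre is 400 kb
  # upstream of gB's TSS, but gB is on the minus strand
  d <- got$distance_bp[got$ccre_id == "p02" & got$gene_id == "gB"]
  expect_equal(d, 4e5)
})

test_that("correlate_pairs yields exact correlations and flags degeneracy", {
  acc <- rbind(p1 = c(1, 2, 3, 4), p2 = c(1, 1, 1, 1))
  colnames(acc) <- paste0("cl", 1:4)
  ex <- rbind(gA = c(1, 2, 3, 4), gB = c(4, 3, 2, 1))
  colnames(ex) <- paste0("cl", 1:4)
  pairs <- data.frame(ccre_id = c("p1", "p1", "p2"),
                      gene_id = c("gA", "gB", "gA"))
  out <- correlate_pairs(pairs, acc, ex)
  expect_equal(out$pcc[1:2], c(1, -1))
  expect_true(is.na(out$pcc[3]))
  expect_error(correlate_pairs(pairs, acc[, 1:2], ex[, 1:2]), "clusters")
})

test_that("shuffled_background is centred, seeded, and needs 2 chromosomes", {
  sim <- simulate_regulatory_landscape(reg_sim_spec(n_true_links = 0, seed = 3))
  acc <- log2(sim$accessibility + 1)
  ex <- log2(sim$expression + 1)
  bg1 <- shuffled_background(sim$ccres, sim$annotation, acc, ex, 500, seed = 5)
  bg2 <- shuffled_background(sim$ccres, sim$annotation, acc, ex, 500, seed = 5)
  expect_identical(bg1, bg2)
  expect_lt(abs(mean(bg1, na.rm = TRUE)), 0.05)
  expect_error(shuffled_background(sim$ccres, sim$annotation, acc, ex, 0),
               "n_background")
  ann1 <- genome_annotation(transform(sim$annotation$genes, chrom = "chr1"),
                            sim$annotation$chrom_sizes)
  pk1 <- sim$ccres; pk1$chrom <- "chr1"
  expect_error(shuffled_background(pk1, ann1, acc, ex, 10), "chromosomes")
})

test_that("select_links applies threshold and positivity", {
  nm <- structure(list(mu = 0, sigma = 1, score_threshold = 0.5, fdr = 0.01),
                  class = "null_model")
  pairs <- data.frame(ccre_id = "p", gene_id = "g",
                      pcc = c(0.9, 0.4, -0.95, NA))
  links <- select_links(pairs, nm)
  expect_identical(links$passes, c(TRUE, FALSE, FALSE, FALSE))
  nm_neg <- structure(list(mu = 0, sigma = 1, score_threshold = -2, fdr = 0.5),
                      class = "null_model")
  links2 <- select_links(pairs, nm_neg)
  expect_false(links2$passes[3])   # hugely negative pcc can never pass
  links3 <- select_links(pairs, nm_neg, positive_only = FALSE)
  expect_true(links3$passes[3])
})

test_that("planted links are recovered with high correlation", {
  sim <- simulate_regulatory_landscape(reg_sim_spec(seed = 8))
  acc <- log2(sim$accessibility * 100 + 1)
  ex <- log2(sim$expression * 100 + 1)
  pairs <- correlate_pairs(candidate_pairs(sim$ccres, sim$annotation), acc, ex)
  key <- paste(pairs$ccre_id, pairs$gene_id)
  tkey <- paste(sim$truth$pairs$ccre_id, sim$truth$pairs$gene_id)
  planted_pcc <- pairs$pcc[key %in% tkey]
  expect_gt(mean(planted_pcc, na.rm = TRUE), 0.8)
})
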