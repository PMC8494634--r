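test_that("exact_wilcoxon reproduces hand-derived exact p-values", {
  # all x below all y with n1 = 4, n2 = 22: one extreme arrangement each tail
  r <- wilcoxon_u_pvalue(0, 4, 22)
  expect_equal(r$p_value, 2 / choose(26, 4))
  expect_identical(r$method, "exact")

  # n1 = n2 = 4, U = 5: 34 of the 70 arrangements are as or more extreme
  expect_equal(wilcoxon_u_pvalue(5, 4, 4)$p_value, 34 / 70)

  # U at the null centre: two-sided p capped at 1
  expect_equal(wilcoxon_u_pvalue(8, 4, 4)$p_value, 1)

  # value-interface agrees with the triple interface
  x <- c(1, 2, 3, 4); y <- 5:26
  rx <- exact_wilcoxon(x, y)
  expect_equal(rx$u, 0)
  expect_equal(rx$p_value, 2 / choose(26, 4))
  expect_error(exact_wilcoxon(numeric(0), y), "nonempty")
})

test_that("exact_wilcoxon agrees with enumeration and stats::wilcox.test", {
  cases <- list(c(3, 5), c(4, 4), c(2, 7), c(5, 6))
  for (cs in cases) {
    n1 <- cs[1]; n2 <- cs[2]
    for (u in 0:(n1 * n2)) {
      for (alt in c("two_sided", "greater", "less")) {
        expect_equal(wilcoxon_u_pvalue(u, n1, n2, alternative = alt)$p_value,
                     enum_u_pvalue(u, n1, n2, alt), tolerance = 1e-12)
      }
    }
  }
  for (s in 1:10) {
    xy <- withr::with_seed(s, list(x = rnorm(sample(2:10, 1)),
                                   y = rnorm(sample(2:10, 1))))
    expect_equal(exact_wilcoxon(xy$x, xy$y)$p_value,
                 wilcox.test(xy$x, xy$y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # ties or large samples fall back to the tie-corrected approximation
  big <- exact_wilcoxon(rnorm(20), rnorm(20))
  expect_identical(big$method, "normal_approx")
  tied <- exact_wilcoxon(c(1, 2, 2), c(2, 3, 4))
  expect_identical(tied$method, "normal_approx")
})

test_that("bh_adjust matches the step-up definition and oracle", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  for (s in 1:10) {
    p <- withr::with_seed(s, runif(sample(1:50, 1)))
    adj <- bh_adjust(p)
    expect_equal(adj, p.adjust(p, "BH"))
    expect_true(all(adj >= p - 1e-15))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-15))
  }
  expect_error(bh_adjust(c(0.5, 0)), "p_values")
  expect_error(bh_adjust(c(0.5, 1.2)), "p_values")
})

test_that("projection_enrichment computes r_u, folds and exclusions", {
  # the unbiased intratelencephalic baseline ratio
  expect_equal(projection_enrichment(
    data.frame(run = 1, on_target = 2652, off_target = 1775),
    baseline_on = 2652, baseline_off = 1775)$r_u, 2652 / 1775)
  expect_equal(2652 / 1775, 1.4941, tolerance = 1e-4)

  # run counts at baseline proportions give fold exactly 1
  pe <- projection_enrichment(
    data.frame(run = 1:2, on_target = c(2652, 5304), off_target = c(1775, 3550)),
    baseline_on = 2652, baseline_off = 1775)
  expect_equal(pe$runs$fold, c(1, 1))

  # scale invariance per run
  cnt <- data.frame(run = 1:3, on_target = c(10, 20, 30),
                    off_target = c(5, 8, 2))
  f1 <- projection_enrichment(cnt, 10, 20)$runs$fold
  f2 <- projection_enrichment(transform(cnt, on_target = on_target * 7,
                                        off_target = off_target * 7),
                              10, 20)$runs$fold
  expect_equal(f1, f2)

  # zero off-target runs excluded with a message
  cnt0 <- data.frame(run = 1:2, on_target = c(5, 5), off_target = c(0, 5))
  expect_message(pe0 <- projection_enrichment(cnt0, 1, 1), "excluded")
  expect_identical(pe0$n_runs_used, 1L)
})

test_that("projection_fraction_table fractions behave", {
  cells <- data.frame(
    cluster = c(rep("k1", 10), rep("k2", 4)),
    projection_target = c(rep("A", 6), rep("B", 4), rep("A", 4)),
    n_targets_labelled = 1)
  tabs <- projection_fraction_table(cells)
  expect_equal(unname(tabs$by_cluster["k1", ]), c(0.6, 0.4))
  expect_equal(unname(rowSums(tabs$by_cluster)), c(1, 1))
  expect_equal(unname(colSums(tabs$by_target)), c(1, 1))

  # double-projecting cells are excluded from both denominators
  cells2 <- rbind(cells, data.frame(cluster = "k1", projection_target = "B",
                                    n_targets_labelled = 2))
  expect_equal(projection_fraction_table(cells2)$by_cluster["k1", "B"], 0.4)

  # single cluster and target: both views are exactly 1
  one <- data.frame(cluster = "k", projection_target = "A",
                    n_targets_labelled = 1)
  t1 <- projection_fraction_table(one)
  expect_equal(unname(t1$by_cluster[1, 1]), 1)
  expect_equal(unname(t1$by_target[1, 1]), 1)
})

test_that("select_tfs requires both criteria in a common subclass", {
  set.seed(3)
  n_per <- 30
  subclass <- rep(c("S1", "S2", "S3"), each = n_per)
  # "other" stands in for the rest of the library so CPM normalization is
  # not dominated by the few TF columns themselves
  base <- matrix(rpois(3 * n_per * 4, 5), ncol = 4,
                 dimnames = list(NULL, c("tf1", "tf2", "tf3", "other")))
  base[, "other"] <- rpois(3 * n_per, 2000)
  base[subclass == "S1", "tf1"] <- rpois(n_per, 60)
  base[subclass == "S1", "tf2"] <- rpois(n_per, 60)
  motif <- data.frame(tf = c("tf1", "tf2", "tf3"),
                      subclass = c("S1", "S2", "S1"),
                      adjusted_p = c(1e-5, 1e-5, 1e-5),
                      odds_ratio = c(2, 2, 2))
  suppressMessages(sel <- select_tfs(base, subclass, motif))
  by_tf <- tapply(sel$selected, sel$tf, unique)
  expect_true(by_tf[["tf1"]])    # expression and motif both in S1
  expect_false(by_tf[["tf2"]])   # expression in S1, motif only in S2
  expect_false(by_tf[["tf3"]])   # uniform expression: fold change ~1

  suppressMessages(
    sel_loose <- select_tfs(base, subclass, motif, same_subclass = FALSE))
  expect_true(unique(sel_loose$selected[sel_loose$tf == "tf2"]))

  # TF absent from the motif table is logged and never motif-passes
  expect_message(
    sel2 <- select_tfs(base, subclass, motif[motif$tf != "tf1", ]),
    "absent")
  expect_false(any(sel2$motif_pass[sel2$tf == "tf1"]))
})
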