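test_that("wilcoxon_test handles canonical small-sample cases", {
  res <- wilcoxon_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 0.1)       # 2 / choose(6, 3)
  same <- wilcoxon_test(c(1, 5, 9, 12), c(1, 5, 9, 12))
  expect_equal(same$statistic, 8)      # |a||b| / 2
  expect_gte(same$p.value, 0.99)
  expect_equal(wilcoxon_test(rep(2, 30), rep(2, 40))$p.value, 1)
  expect_error(wilcoxon_test(numeric(), 1:3), "nonempty")
})

test_that("exact p-values equal complete enumeration for all sizes up to 10", {
  set.seed(31)
  for (n1 in 1:5) for (n2 in n1:(10 - n1)) {
    vals <- sample(seq_len(50), n1 + n2)   # tie-free
    a <- vals[seq_len(n1)]; b <- vals[-seq_len(n1)]
    got <- wilcoxon_test(a, b)
    want <- enum_wilcox(a, b)
    expect_equal(got$statistic, want$statistic)
    expect_equal(got$p.value, want$p.value, tolerance = 1e-12,
                 info = sprintf("n1=%d n2=%d", n1, n2))
  }
})

test_that("log2 fold change is the de-logged group-mean contrast", {
  vals <- rbind(g1 = log1p(c(4, 4, 1, 1)), g2 = log1p(c(2, 2, 2, 2)))
  colnames(vals) <- paste0("c", 1:4)
  norm <- make_norm(vals)
  cmp <- comparison("x", c("c1", "c2"), c("c3", "c4"))
  expect_equal(log2_fold_change(norm, cmp, "g1", pseudocount = 0), 2)
  expect_equal(log2_fold_change(norm, cmp, "g2", pseudocount = 0), 0)
  rev_cmp <- comparison("y", c("c3", "c4"), c("c1", "c2"))
  expect_equal(log2_fold_change(norm, rev_cmp, "g1", pseudocount = 0), -2)
  expect_error(log2_fold_change(norm, cmp, "nope"), "unknown gene")
})

test_that("bh_fdr matches the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.04, 0.03, 0.02)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(32)
  for (i in 1:1000) {
    p <- stats::runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), stepup_bh(p), tolerance = 1e-12)
  }
})

test_that("run_de flags programmed markers, spares nulls, and is antisymmetric", {
  cfg <- two_pop_marker_config(n_cells = 200, n_genes = 120, mult = 8, seed = 33)
  coh <- generate_cohort(cfg)
  norm <- nonde_normalize(coh$counts$counts, "MarkerA")
  a <- coh$truth$barcode[coh$truth$population == "A"]
  b <- coh$truth$barcode[coh$truth$population == "B"]
  de_ab <- run_de(norm, comparison("AvB", a, b))
  expect_true(de_ab$significant[de_ab$gene == "MarkerA"])
  expect_gt(de_ab$l2fc[de_ab$gene == "MarkerA"], 0.2)
  expect_lte(sum(de_ab$significant[de_ab$gene != "MarkerA"]), 2)
  de_ba <- run_de(norm, comparison("BvA", b, a))
  expect_equal(de_ba$l2fc, -de_ab$l2fc)
  expect_equal(de_ba$pct_a, de_ab$pct_b)
  # q >= p wherever tested
  expect_true(all(de_ab$q >= de_ab$p - 1e-12, na.rm = TRUE))
})

test_that("disabling the filters tests every gene", {
  cfg <- two_pop_marker_config(n_cells = 60, n_genes = 40, seed = 34)
  coh <- generate_cohort(cfg)
  norm <- lognormalize(coh$counts$counts)
  a <- coh$truth$barcode[coh$truth$population == "A"]
  b <- coh$truth$barcode[coh$truth$population == "B"]
  de <- run_de(norm, comparison("AvB", a, b), l2fc_min = 0, min_pct = 0)
  expect_false(anyNA(de$p))
  expect_false(anyNA(de$q))
  # the pre-test screen, when enabled, restricts the BH universe
  de_pre <- run_de(norm, comparison("AvB", a, b), min_pct = 0,
                   l2fc_prefilter = TRUE)
  expect_true(anyNA(de_pre$p))
})

test_that("comparisons validate their group structure", {
  expect_error(comparison("x", character(), "c1"), "nonempty")
  expect_error(comparison("x", c("c1", "c2"), c("c2", "c3")), "disjoint")
  labels <- structure(tibble::tibble(barcode = paste0("c", 1:6),
                                     cluster = c(0L, 0L, 1L, 1L, 2L, 2L)),
                      K = 3L, class = c("eec_clusters", "tbl_df", "tbl", "data.frame"))
  comps <- one_vs_rest_comparisons(labels)
  expect_length(comps, 3)
  expect_identical(comps[[1]]$group_a, c("c1", "c2"))
  expect_length(comps[[1]]$group_b, 4)
})

test_that("tidy and glance summarize DE tables", {
  cfg <- two_pop_marker_config(n_cells = 60, n_genes = 30, seed = 35)
  coh <- generate_cohort(cfg)
  norm <- lognormalize(coh$counts$counts)
  a <- coh$truth$barcode[coh$truth$population == "A"]
  b <- coh$truth$barcode[coh$truth$population == "B"]
  de <- run_de(norm, comparison("AvB", a, b))
  td <- generics::tidy(de)
  expect_s3_class(td, "tbl_df")
  gl <- generics::glance(de)
  expect_identical(names(gl), c("comparison", "n_genes", "n_tested", "n_significant"))
  expect_equal(gl$n_genes, 30)
})
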