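de_table <- function(id, genes, l2fc, sig) {
  structure(tibble::tibble(comparison = id, gene = genes, l2fc = l2fc,
                           p = ifelse(sig, 1e-5, 0.5),
                           q = ifelse(sig, 1e-4, 0.8),
                           pct_a = 0.5, pct_b = 0.5, significant = sig),
            class = c("eec_de", "tbl_df", "tbl", "data.frame"))
}

test_that("axis correlation degenerates correctly for self and reversed input", {
  genes <- paste0("g", 1:20)
  set.seed(41)
  l2fc <- stats::runif(20, -2, 2)
  sig <- abs(l2fc) > 0.5
  de_x <- de_table("x", genes, l2fc, sig)
  ax_self <- axis_correlation(de_x, de_x)
  expect_equal(ax_self$pearson_r, 1)
  de_rev <- de_table("xr", genes, -l2fc, sig)
  expect_equal(axis_correlation(de_x, de_rev)$pearson_r, -1)
  # symmetry: swapping tables transposes the gene table, r unchanged
  de_y <- de_table("y", genes, l2fc + stats::rnorm(20, 0, 0.3), sig)
  ab <- axis_correlation(de_x, de_y)
  ba <- axis_correlation(de_y, de_x)
  expect_equal(ab$pearson_r, ba$pearson_r)
  expect_equal(ab$genes$l2fc_x, ba$genes$l2fc_y)
})

test_that("the selection rule is exactly enforced", {
  genes <- c("sig_both_big", "sig_one_small_y", "nosig_big", "sig_neg_big",
             "sig_boundary")
  de_x <- de_table("x", genes, c(1.0, 1.0, 1.5, -1.2, 0.2),
                   c(TRUE, TRUE, FALSE, TRUE, TRUE))
  de_y <- de_table("y", genes, c(0.8, 0.1, 1.4, -0.9, 0.2),
                   c(FALSE, FALSE, FALSE, TRUE, FALSE))
  ax <- axis_correlation(de_x, de_y, l2fc_min = 0.2)
  # selected: significant in >= 1 table AND |l2fc| strictly > 0.2 in both
  expect_setequal(ax$genes$gene, c("sig_both_big", "sig_neg_big"))
  expect_true(ax$undefined)        # fewer than 3 genes
  expect_true(is.na(ax$pearson_r))
})

test_that("glance/tidy/autoplot expose the axis-correlation result", {
  genes <- paste0("g", 1:10)
  de_x <- de_table("x", genes, seq(-2, 2, length.out = 10), rep(TRUE, 10))
  de_y <- de_table("y", genes, seq(-2, 2, length.out = 10) + 0.1, rep(TRUE, 10))
  ax <- axis_correlation(de_x, de_y)
  gl <- generics::glance(ax)
  expect_equal(gl$n_genes, nrow(generics::tidy(ax)))
  expect_gt(gl$pearson_r, 0.99)
  expect_s3_class(ggplot2::autoplot(ax), "ggplot")
})

test_that("annotation assigns major types from programmed markers", {
  genes <- c("Tph1", "Gcg", "Sst", "Piezo2", "Sct", "Tac1", "Nts", "Insl5")
  mk <- function(tph, gcg, sst) log1p(c(tph, gcg, sst, 1, 1, 1, 1, 1))
  vals <- cbind(mk(50, 1, 1), mk(50, 1, 1),   # cluster 0: Ecm
                mk(1, 40, 1), mk(1, 40, 1),   # cluster 1: L
                mk(1, 1, 30), mk(1, 1, 30))   # cluster 2: D
  dimnames(vals) <- list(genes, paste0("c", 1:6))
  labels <- tibble::tibble(barcode = paste0("c", 1:6),
                           cluster = c(0L, 0L, 1L, 1L, 2L, 2L))
  ann <- annotate_clusters(make_norm(vals), labels)
  expect_identical(ann$major_type, c("Ecm", "L", "D"))
  expect_error(annotate_clusters(make_norm(vals[1:3, , drop = FALSE]), labels),
               "missing from matrix")
})

test_that("tied major markers fall back to priority order with a warning", {
  genes <- c("Tph1", "Gcg", "Sst", "Piezo2", "Sct", "Tac1", "Nts", "Insl5")
  vals <- matrix(log1p(2), nrow = 8, ncol = 4,
                 dimnames = list(genes, paste0("c", 1:4)))
  labels <- tibble::tibble(barcode = paste0("c", 1:4),
                           cluster = c(0L, 0L, 1L, 1L))
  expect_warning(ann <- annotate_clusters(make_norm(vals), labels), "tied")
  expect_identical(unique(ann$major_type), "Ecm")
})

test_that("grouped comparisons pool annotated clusters and validate rules", {
  labels <- tibble::tibble(barcode = paste0("c", 1:70),
                           cluster = rep(c(0L, 1L), c(30, 40)))
  ann <- tibble::tibble(cluster = c(0L, 1L), major_type = c("L", "L"),
                        Sct_pos = c(TRUE, FALSE))
  cmp <- grouped_comparison(labels, ann, list(Sct_pos = TRUE),
                            list(Sct_pos = FALSE), id = "sct")
  expect_length(cmp$group_a, 30)
  expect_length(cmp$group_b, 40)
  expect_error(grouped_comparison(labels, ann, list(Nope = TRUE),
                                  list(Sct_pos = FALSE)), "unknown annotation")
  expect_error(grouped_comparison(labels, ann, list(major_type = "L"),
                                  list(Sct_pos = FALSE)), "overlapping")
})

test_that("re-clustering a homogeneous subset keeps its mechanical contract", {
  # modularity clustering partitions even pure noise, and testing clusters
  # found on the same data yields spuriously significant markers (the
  # uncorrected post-selection inference inherent to this design), so the
  # null case asserts the stage's contract: a complete, deterministic,
  # contiguously labeled partition of the subset
  cfg <- two_pop_marker_config(n_cells = 150, n_genes = 200, mult = 1, seed = 44)
  m <- generate_cohort(cfg)$counts$counts
  labels <- structure(tibble::tibble(barcode = colnames(m),
                                     cluster = 0L),
                      K = 1L, class = c("eec_clusters", "tbl_df", "tbl",
                                        "data.frame"))
  sub <- subset_and_recluster(m, labels, 0,
                              eec_pipeline_params(n_hvg = 150))
  expect_setequal(sub$barcode, colnames(m))
  expect_identical(sort(unique(sub$cluster)),
                   seq_len(attr(sub, "K")) - 1L)
  sub2 <- subset_and_recluster(m, labels, 0,
                               eec_pipeline_params(n_hvg = 150))
  expect_identical(sub$cluster, sub2$cluster)
  expect_error(subset_and_recluster(m, labels[1:10, ], 0,
                                    eec_pipeline_params()), "at least 20")
})

test_that("shared-axis correlation is positive and grows with effect size", {
  r_at <- function(strength) {
    cfg <- eec_atlas_config(n_cells = 800, seed = 45,
                            maturation_strength = strength)
    coh <- generate_cohort(cfg)
    tr <- coh$truth
    norm <- nonde_normalize(coh$counts$counts,
                            unlist(lapply(cfg$populations, function(p) names(p$markers))))
    pair <- function(id, pa, pb)
      run_de(norm, comparison(id, tr$barcode[tr$program == pa],
                              tr$barcode[tr$program == pb]),
             min_pct = 0.05)
    ax <- axis_correlation(
      pair("insl5", "L-Insl5/Sct", "L-Insl5/Gcg"),
      pair("nts", "L-Nts/Sct", "L-Nts/Gcg"))
    ax$pearson_r
  }
  rs <- vapply(c(0.25, 0.6, 1), r_at, numeric(1))
  expect_gt(rs[1], 0)
  expect_true(all(diff(rs) > 0))
  expect_gt(rs[3], 0.5)
})
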