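#' Define a two-group comparison
#'
#' @param id Short identifier, e.g. `"cluster3_vs_rest"`.
#' @param group_a,group_b Disjoint, nonempty barcode vectors.
#' @param description Free-text description.
#' @return An `eec_comparison` list.
#' @export
comparison <- function(id, group_a, group_b, description = id) {
  if (!length(group_a) || !length(group_b))
    abort(paste0("comparison `", id, "`: both groups must be nonempty"))
  if (length(intersect(group_a, group_b)))
    abort(paste0("comparison `", id, "`: groups must be disjoint"))
  structure(list(id = id, group_a = unique(group_a), group_b = unique(group_b),
                 description = description), class = "eec_comparison")
}

#' One-vs-rest comparisons for every cluster
#'
#' @param labels An `eec_clusters` tibble (`barcode`, `cluster`).
#' @return List of [comparison()] objects, one per cluster.
#' @export
one_vs_rest_comparisons <- function(labels) {
  ks <- sort(unique(labels$cluster))
  lapply(ks, function(k) {
    comparison(sprintf("cluster%d_vs_rest", k),
               labels$barcode[labels$cluster == k],
               labels$barcode[labels$cluster != k],
               sprintf("cluster %d vs all other cells", k))
  })
}

#' Wilcoxon rank-sum test
#'
#' Two-sided Mann-Whitney U test.  Exact enumeration is used when the
#' combined sample size is at most 20 and there are no ties; otherwise the
#' normal approximation with midrank tie correction and continuity
#' correction.
#'
#' @param a,b Numeric vectors (each nonempty).
#' @return List with `statistic` (U for `a` vs `b`) and `p.value`.
#' @export
wilcoxon_test <- function(a, b) {
  if (!length(a) || !length(b)) abort("both groups must be nonempty")
  ties <- anyDuplicated(c(a, b)) > 0
  if (length(a) + length(b) <= 20 && !ties) {
    ht <- suppressWarnings(wilcox.test(a, b, exact = TRUE, correct = FALSE))
  } else {
    ht <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
  }
  p <- ht$p.value
  if (is.nan(p)) p <- 1   # zero-variance (all values tied) degenerate case
  list(statistic = unname(ht$statistic), p.value = min(p, 1))
}

#' Log2 fold change between group means of de-logged expression
#'
#' `log2(mean_a + pc) - log2(mean_b + pc)` where each mean is taken over
#' `expm1(normalized value)` within the group.
#'
#' @param norm An `eec_norm`.
#' @param comp An [comparison()] object.
#' @param gene Gene name.
#' @param pseudocount Stabilizing pseudocount added to each mean (default
#'   0.01).
#' @return Numeric log2 fold change (A vs B).
#' @export
log2_fold_change <- function(norm, comp, gene, pseudocount = 0.01) {
  if (!gene %in% rownames(norm$values)) abort(paste0("unknown gene: ", gene))
  va <- expm1(as.numeric(norm$values[gene, comp$group_a]))
  vb <- expm1(as.numeric(norm$values[gene, comp$group_b]))
  log2(mean(va) + pseudocount) - log2(mean(vb) + pseudocount)
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p Raw p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Wilcoxon differential expression for a set of comparisons
#'
#' For each comparison, genes expressed in at least `min_pct` of cells in
#' one group are tested with [wilcoxon_test()] on normalized values, and
#' q-values are computed by Benjamini-Hochberg within the comparison over
#' tested genes.  The fold-change threshold is applied *after* testing, as
#' part of the significance flag (`significant` is `q <= fdr & |l2fc| >=
#' l2fc_min`, both inclusive), so that the BH universe is not selected on
#' observed fold changes and the false discovery rate stays controlled.
#' `l2fc_prefilter = TRUE` restores the faster screen-before-test behaviour
#' of common toolchains (at the cost of FDR control against ground truth).
#' All genes appear in the output (with `NA` p/q when not tested) so fold
#' changes are available comparison-wide.
#'
#' @param norm An `eec_norm`.
#' @param comps A list of [comparison()] objects (or a single one).
#' @param l2fc_min Absolute log2-fold-change threshold (default 0.2).
#' @param fdr FDR threshold (default 0.05).
#' @param min_pct Minimum expressing fraction in at least one group
#'   (default 0.1).
#' @param pseudocount Passed to the fold-change estimator.
#' @param l2fc_prefilter Apply the fold-change threshold before testing
#'   (default `FALSE`; see details).
#' @return An `eec_de` tibble: `comparison`, `gene`, `l2fc`, `p`, `q`,
#'   `pct_a`, `pct_b`, `significant`.
#' @export
run_de <- function(norm, comps, l2fc_min = 0.2, fdr = 0.05, min_pct = 0.1,
                   pseudocount = 0.01, l2fc_prefilter = FALSE) {
  stopifnot(inherits(norm, "eec_norm"))
  if (inherits(comps, "eec_comparison")) comps <- list(comps)
  v <- norm$values
  e <- v; e@x <- expm1(e@x)
  out <- purrr::map(comps, function(cmp) {
    ia <- match(cmp$group_a, colnames(v))
    ib <- match(cmp$group_b, colnames(v))
    if (anyNA(ia) || anyNA(ib))
      abort(paste0("comparison `", cmp$id, "`: barcodes missing from the matrix"))
    mean_a <- Matrix::rowMeans(e[, ia, drop = FALSE])
    mean_b <- Matrix::rowMeans(e[, ib, drop = FALSE])
    pct_a <- Matrix::rowMeans(v[, ia, drop = FALSE] > 0)
    pct_b <- Matrix::rowMeans(v[, ib, drop = FALSE] > 0)
    l2fc <- log2(mean_a + pseudocount) - log2(mean_b + pseudocount)
    tested <- pmax(pct_a, pct_b) >= min_pct
    if (l2fc_prefilter) tested <- tested & abs(l2fc) >= l2fc_min
    p <- rep(NA_real_, nrow(v))
    if (any(tested)) {
      sub <- as.matrix(v[tested, c(ia, ib), drop = FALSE])
      na <- length(ia)
      p[tested] <- vapply(seq_len(nrow(sub)), function(r) {
        wilcoxon_test(sub[r, seq_len(na)], sub[r, -seq_len(na)])$p.value
      }, numeric(1))
    }
    q <- rep(NA_real_, nrow(v))
    q[tested] <- bh_fdr(p[tested])
    tibble(comparison = cmp$id, gene = rownames(v),
           l2fc = unname(l2fc), p = p, q = q,
           pct_a = unname(pct_a), pct_b = unname(pct_b),
           significant = !is.na(q) & q <= fdr & abs(l2fc) >= l2fc_min)
  })
  out <- bind_rows(out)
  structure(out, fdr = fdr, l2fc_min = l2fc_min,
            class = c("eec_de", class(out)))
}

#' @exportS3Method generics::tidy
tidy.eec_de <- function(x, ...) {
  as_tibble(x)
}

#' @exportS3Method generics::glance
glance.eec_de <- function(x, ...) {
  as_tibble(x) |>
    group_by(.data$comparison) |>
    summarise(n_genes = n(), n_tested = sum(!is.na(.data$p)),
              n_significant = sum(.data$significant), .groups = "drop")
}
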