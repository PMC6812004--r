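#' Log-normalize UMI counts against a basis gene set
#'
#' Each cell's size factor is its UMI total over the basis genes; values are
#' `log1p(count / size_factor * scale)` (natural log).  With
#' `basis_genes = NULL` (all genes) this is the community-standard
#' total-count log-normalization; with the complement of a
#' differentially-expressed gene set it is the DE-aware normalization used
#' in the second pass (see [nonde_normalize()]).
#'
#' @param x Counts (`eec_counts` or genes-by-cells matrix).
#' @param scale Size-factor target (default 10,000).
#' @param basis_genes Character vector of gene names defining size factors,
#'   or `NULL` for all genes.
#' @return An `eec_norm` list: `values` (sparse log-normalized matrix),
#'   `size_factors` (named), `basis` (`"total"` or `"nonDE"`), `de_genes`,
#'   `scale`.
#' @export
lognormalize <- function(x, scale = 1e4, basis_genes = NULL) {
  m <- as_count_matrix(x)
  assert_positive_scalar(scale, "scale")
  if (is.null(basis_genes)) {
    sf <- Matrix::colSums(m)
    basis <- "total"
  } else {
    keep <- rownames(m) %in% basis_genes
    if (!any(keep)) abort("no basis genes present in the matrix")
    sf <- Matrix::colSums(m[keep, , drop = FALSE])
    basis <- "basis"
  }
  zero <- sf <= 0
  if (any(zero))
    abort(paste0("cells with zero basis-gene UMIs: ",
                 paste(head(colnames(m)[zero], 5), collapse = ", "),
                 if (sum(zero) > 5) sprintf(" (+%d more)", sum(zero) - 5)))
  values <- m
  values@x <- log1p(m@x / rep.int(sf, diff(m@p)) * scale)
  structure(list(values = values,
                 size_factors = setNames(as.numeric(sf), colnames(m)),
                 basis = basis, de_genes = character(), scale = scale),
            class = "eec_norm")
}

#' @export
print.eec_norm <- function(x, ...) {
  cat(sprintf("eec_norm: %d genes x %d cells, basis = %s, scale = %g\n",
              nrow(x$values), ncol(x$values), x$basis, x$scale))
  invisible(x)
}

#' Normalize on non-differentially-expressed genes
#'
#' Size factors are computed from the UMIs of genes *not* in the supplied DE
#' set, so strongly regulated hormone genes (which dominate enteroendocrine
#' libraries) no longer distort per-cell scaling; all genes are still
#' transformed and kept as features.  With an empty DE set this reduces
#' exactly to [lognormalize()] over all genes.
#'
#' @param x Counts.
#' @param de_genes Character vector of DE gene names (may be an
#'   `eec_de_gene_set`).
#' @param scale Size-factor target.
#' @return An `eec_norm` with `basis = "nonDE"` and the DE set recorded.
#' @export
nonde_normalize <- function(x, de_genes, scale = 1e4) {
  if (inherits(de_genes, "eec_de_gene_set")) de_genes <- de_genes$genes
  m <- as_count_matrix(x)
  non_de <- setdiff(rownames(m), de_genes)
  if (!length(non_de)) abort("complement of the DE gene set is empty")
  out <- lognormalize(m, scale = scale,
                      basis_genes = if (length(de_genes)) non_de else NULL)
  out$basis <- if (length(de_genes)) "nonDE" else "total"
  out$de_genes <- intersect(de_genes, rownames(m))
  out
}

#' Second-pass cell filter on DE-gene UMIs
#'
#' Retains cells whose UMI count over the first-pass differentially
#' expressed genes is at least `min_de_umi` (inclusive).
#'
#' @param x Counts.
#' @param de_genes DE gene names (or `eec_de_gene_set`).
#' @param min_de_umi Minimum DE-gene UMI count (default 800).
#' @return Character vector of retained barcodes.
#' @export
refilter_on_de_umis <- function(x, de_genes, min_de_umi = 800) {
  if (inherits(de_genes, "eec_de_gene_set")) de_genes <- de_genes$genes
  if (!length(de_genes)) abort("DE gene set is empty")
  m <- as_count_matrix(x)
  keep <- rownames(m) %in% de_genes
  de_umi <- Matrix::colSums(m[keep, , drop = FALSE])
  retained <- colnames(m)[de_umi >= min_de_umi]
  if (!length(retained))
    abort("no cells have enough DE-gene UMIs; review min_de_umi")
  retained
}

#' First-pass screen for genes differentially expressed in any population
#'
#' Runs the standard (total-count) normalization, highly-variable-gene
#' selection, PCA, shared-nearest-neighbor Louvain clustering and
#' one-vs-rest Wilcoxon differential expression, and returns the union of
#' genes significant (BH-FDR and fold-change thresholds) in at least one
#' cluster.  This set defines both the second-pass cell filter
#' ([refilter_on_de_umis()]) and the non-DE normalization basis
#' ([nonde_normalize()]).
#'
#' @param x QC-filtered counts.
#' @param params Pipeline parameters, see [eec_pipeline_params()].
#' @return An `eec_de_gene_set`: `genes`, `provenance` (per-comparison
#'   significant-gene counts), `params`.
#' @export
first_pass_de_genes <- function(x, params = eec_pipeline_params()) {
  m <- as_count_matrix(x)
  norm <- lognormalize(m, scale = params$scale)
  hvg <- select_hvgs(norm, n_hvg = params$n_hvg, n_bins = params$hvg_bins)
  emb <- run_pca(norm, hvg, n_dims = params$n_dims)
  graph <- build_snn(emb, k = params$snn_k, prune = params$snn_prune)
  labels <- cluster_graph(graph, resolution = params$resolution,
                          seed = params$seed)
  if (attr(labels, "K") < 2)
    abort("first-pass clustering found < 2 clusters; DE screen undefined")
  comps <- one_vs_rest_comparisons(labels)
  de <- run_de(norm, comps, l2fc_min = params$l2fc_min, fdr = params$fdr,
               min_pct = params$min_pct)
  sig <- de |> dplyr::filter(.data$significant)
  structure(list(
    genes = sort(unique(sig$gene)),
    provenance = sig |> dplyr::count(.data$comparison, name = "n_significant"),
    params = params[c("fdr", "l2fc_min", "min_pct")]),
    class = "eec_de_gene_set")
}

#' @export
print.eec_de_gene_set <- function(x, ...) {
  cat(sprintf("eec_de_gene_set: %d genes from %d comparisons (FDR %.2g, |L2FC| >= %.2g)\n",
              length(x$genes), nrow(x$provenance), x$params$fdr, x$params$l2fc_min))
  invisible(x)
}
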