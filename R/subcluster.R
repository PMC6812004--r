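#' Subset selected clusters and re-run the clustering stage
#'
#' Mirrors the global analysis on the subset only: the normalization basis
#' is unchanged, highly variable genes and PCA are recomputed on the subset,
#' the dimensionality is chosen by the elbow rule (unless overridden), and
#' a fresh SNN graph is clustered by Louvain.
#'
#' @param x Counts (full cohort).
#' @param labels Global `eec_clusters`.
#' @param targets Cluster ids to subset.
#' @param params Pipeline parameters ([eec_pipeline_params()]); set
#'   `params$sub_dims` to an integer to override the elbow rule.
#' @param de_genes DE gene set defining the normalization basis (empty for
#'   standard normalization).
#' @return An `eec_clusters` tibble over the subset barcodes.
#' @export
subset_and_recluster <- function(x, labels, targets,
                                 params = eec_pipeline_params(),
                                 de_genes = character()) {
  if (!length(targets)) abort("`targets` must name at least one cluster")
  cells <- labels$barcode[labels$cluster %in% targets]
  if (length(cells) < 20)
    abort(sprintf("only %d cells selected; need at least 20", length(cells)))
  m <- as_count_matrix(x)[, cells, drop = FALSE]
  norm <- nonde_normalize(m, de_genes, scale = params$scale)
  hvg <- select_hvgs(norm, n_hvg = min(params$n_hvg, nrow(m)),
                     n_bins = params$hvg_bins)
  probe <- run_pca(norm, hvg,
                   n_dims = min(20L, length(hvg), length(cells) - 1L))
  dims <- if (is.numeric(params$sub_dims)) as.integer(params$sub_dims)
          else choose_dims_elbow(probe$explained_variance)
  emb <- probe
  emb$scores <- probe$scores[, seq_len(dims), drop = FALSE]
  graph <- build_snn(emb, k = min(params$snn_k, length(cells) - 1L),
                     prune = params$snn_prune)
  cluster_graph(graph, resolution = params$resolution, seed = params$seed)
}

#' Annotate clusters by hormone marker dominance
#'
#' Major type is the argmax, over the major-marker map (default Tph1 ->
#' enterochromaffin, Gcg -> L, Sst -> D), of the cluster mean of de-logged
#' expression standardized across clusters.  Subtype tags record the sign of
#' the standardized cluster mean for each tag gene (default Piezo2, Sct,
#' Tac1, Nts, Insl5): positive means the cluster is enriched for that gene
#' relative to the other clusters.  Ties on the major markers are broken by
#' map order (with a warning).
#'
#' @param norm An `eec_norm`.
#' @param labels An `eec_clusters`.
#' @param major_markers Named character vector: marker gene -> type label.
#' @param tag_genes Genes to tag by enrichment sign.
#' @return An `eec_annotation` tibble: `cluster`, `major_type`, `tags`
#'   (comma-joined `Gene+` tags) plus one logical column per tag gene.
#' @export
annotate_clusters <- function(norm, labels,
                              major_markers = c(Tph1 = "Ecm", Gcg = "L", Sst = "D"),
                              tag_genes = c("Piezo2", "Sct", "Tac1", "Nts", "Insl5")) {
  genes <- c(names(major_markers), tag_genes)
  missing <- setdiff(genes, rownames(norm$values))
  if (length(missing))
    abort(paste0("marker gene(s) missing from matrix: ",
                 paste(missing, collapse = ", ")))
  ks <- sort(unique(labels$cluster))
  e <- norm$values[genes, labels$barcode, drop = FALSE]
  e@x <- expm1(e@x)
  cm <- vapply(ks, function(k) {
    Matrix::rowMeans(e[, labels$cluster == k, drop = FALSE])
  }, numeric(length(genes)))
  cm <- matrix(cm, nrow = length(genes),
               dimnames = list(genes, paste0("c", ks)))
  zs <- t(apply(cm, 1, function(x) {
    s <- sd(x)
    if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }))
  mm <- zs[names(major_markers), , drop = FALSE]
  tied <- vapply(seq_along(ks), function(j) {
    col <- mm[, j]
    max(col) - min(col) < 1e-12 || sum(col == max(col)) > 1
  }, logical(1))
  if (any(tied))
    warn(sprintf("cluster(s) %s: tied major markers; using priority order %s",
                 paste(ks[tied], collapse = ", "),
                 paste(unname(major_markers), collapse = " > ")))
  major <- vapply(seq_along(ks), function(j) {
    unname(major_markers[which.max(mm[, j])])
  }, character(1))
  out <- tibble(cluster = ks, major_type = major)
  for (g in tag_genes) out[[paste0(g, "_pos")]] <- zs[g, ] > 0
  out$tags <- vapply(seq_along(ks), function(j) {
    paste0(tag_genes[zs[tag_genes, j] > 0], "+", collapse = ",")
  }, character(1))
  structure(out, standardized_means = zs,
            class = c("eec_annotation", class(out)))
}

#' Pooled comparison from annotated cluster groups
#'
#' Builds a two-group [comparison()] by pooling the cells of clusters
#' selected on annotation columns, e.g. Sct-positive vs Sct-negative L
#' cells.
#'
#' @param labels An `eec_clusters`.
#' @param annotation An `eec_annotation`.
#' @param rule_a,rule_b Named lists of requirements on annotation columns,
#'   e.g. `list(major_type = "L", Sct_pos = TRUE)`.
#' @param id Comparison id.
#' @return An [comparison()].
#' @export
grouped_comparison <- function(labels, annotation, rule_a, rule_b,
                               id = "grouped") {
  match_rule <- function(rule) {
    unknown <- setdiff(names(rule), names(annotation))
    if (length(unknown))
      abort(paste0("unknown annotation field(s): ", paste(unknown, collapse = ", ")))
    sel <- rep(TRUE, nrow(annotation))
    for (f in names(rule)) sel <- sel & annotation[[f]] %in% rule[[f]]
    annotation$cluster[sel]
  }
  ka <- match_rule(rule_a); kb <- match_rule(rule_b)
  if (length(intersect(ka, kb)))
    abort("grouping rules select overlapping clusters")
  comparison(id,
             labels$barcode[labels$cluster %in% ka],
             labels$barcode[labels$cluster %in% kb],
             sprintf("clusters {%s} vs {%s}", paste(ka, collapse = ","),
                     paste(kb, collapse = ",")))
}

#' Correlate fold changes across two comparisons
#'
#' Reproduces the paired-comparison correlation analysis: genes are selected
#' iff they are significant (FDR-controlled flag) in at least one of the two
#' differential-expression tables and have `|l2fc| > l2fc_min` in both;
#' the Pearson correlation of their fold-change pairs measures whether the
#' two comparisons share a transcriptional program (e.g. the crypt-surface
#' maturation axis shared by the Sct/Gcg splits of both L-cell types).
#'
#' @param de_x,de_y `eec_de` tables, each for a single comparison.
#' @param l2fc_min Strict absolute fold-change threshold required in both
#'   tables (default 0.2).
#' @return An `eec_axis_cor`: `genes` tibble (`gene`, `l2fc_x`, `l2fc_y`),
#'   `pearson_r` (NA, flagged `undefined`, when fewer than 3 genes pass),
#'   `n_genes`, comparison ids, and the selection rule.
#' @export
axis_correlation <- function(de_x, de_y, l2fc_min = 0.2) {
  one <- function(d, suffix) {
    d <- as_tibble(d)
    if (length(unique(d$comparison)) != 1)
      abort("each DE table must contain exactly one comparison")
    d |> select("gene", "l2fc", "significant") |>
      rlang::set_names(c("gene", paste0("l2fc_", suffix),
                         paste0("sig_", suffix)))
  }
  tab <- dplyr::inner_join(one(de_x, "x"), one(de_y, "y"), by = "gene")
  if (!nrow(tab)) abort("the two DE tables share no genes")
  sel <- (tab$sig_x | tab$sig_y) &
    abs(tab$l2fc_x) > l2fc_min & abs(tab$l2fc_y) > l2fc_min
  genes <- tab[sel, c("gene", "l2fc_x", "l2fc_y")]
  n <- nrow(genes)
  r <- if (n >= 3) cor(genes$l2fc_x, genes$l2fc_y, method = "pearson") else NA_real_
  structure(list(
    genes = genes, pearson_r = r, n_genes = n, undefined = n < 3,
    comparison_x = unique(as_tibble(de_x)$comparison),
    comparison_y = unique(as_tibble(de_y)$comparison),
    selection = sprintf("significant in >=1 comparison & |l2fc| > %g in both",
                        l2fc_min)),
    class = "eec_axis_cor")
}

#' @export
print.eec_axis_cor <- function(x, ...) {
  cat(sprintf("eec_axis_cor: %s vs %s, %d genes, Pearson r = %s\n",
              x$comparison_x, x$comparison_y, x$n_genes,
              if (x$undefined) "undefined (< 3 genes)" else sprintf("%.3f", x$pearson_r)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.eec_axis_cor <- function(x, ...) x$genes

#' @exportS3Method generics::glance
glance.eec_axis_cor <- function(x, ...) {
  tibble(comparison_x = x$comparison_x, comparison_y = x$comparison_y,
         pearson_r = x$pearson_r, n_genes = x$n_genes,
         undefined = x$undefined)
}
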