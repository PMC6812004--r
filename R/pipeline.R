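#' Pipeline tuning parameters
#'
#' One object holding every tunable of the two-pass workflow.  Defaults are
#' the toolchain-generation defaults referenced by the study: size-factor
#' target 10,000 with natural-log transform; top 1000 variable genes from 20
#' dispersion bins; 7 principal components for global clustering; SNN with
#' k = 20 neighbors pruned at Jaccard 1/15; Louvain resolution 0.8; Wilcoxon
#' DE at 5% FDR with |log2 fold change| >= 0.2 and a 10% minimum expressing
#' fraction; second-pass cell filter at 800 DE-gene UMIs; 7 dimensions for
#' subcluster re-analyses.
#'
#' @param scale,n_hvg,hvg_bins,n_dims,snn_k,snn_prune,resolution Numeric
#'   stage parameters (see description).
#' @param fdr,l2fc_min,min_pct Differential-expression thresholds.
#' @param min_de_umi Second-pass DE-UMI cell filter.
#' @param sub_dims Integer dimensionality for subcluster analyses (default
#'   7, the dimensionality the study used when re-clustering L cells), or
#'   `"elbow"` for the data-driven rule in [choose_dims_elbow()].
#' @param seed Integer seed used by graph clustering and t-SNE.
#' @return An `eec_pipeline_params` list.
#' @export
eec_pipeline_params <- function(scale = 1e4, n_hvg = 1000, hvg_bins = 20,
                                n_dims = 7, snn_k = 20, snn_prune = 1/15,
                                resolution = 0.8, fdr = 0.05, l2fc_min = 0.2,
                                min_pct = 0.1, min_de_umi = 800,
                                sub_dims = 7, seed = 0) {
  structure(list(scale = scale, n_hvg = n_hvg, hvg_bins = hvg_bins,
                 n_dims = n_dims, snn_k = snn_k, snn_prune = snn_prune,
                 resolution = resolution, fdr = fdr, l2fc_min = l2fc_min,
                 min_pct = min_pct, min_de_umi = min_de_umi,
                 sub_dims = sub_dims, seed = as.integer(seed)),
            class = "eec_pipeline_params")
}

#' Full pipeline configuration
#'
#' Drives [run_pipeline()] from a single object: either a generator
#' configuration (synthetic cohort) or an input directory with a count
#' triple, plus QC thresholds and stage parameters.  A seed is mandatory.
#'
#' @param generator An [eec_generator_config()], or `NULL` when reading from
#'   disk.
#' @param input_dir Directory with `matrix.mtx`/`barcodes.tsv`/
#'   `features.tsv`, or `NULL` when simulating.
#' @param thresholds [qc_thresholds()].
#' @param params [eec_pipeline_params()].
#' @param seed Integer seed (mandatory); overrides `params$seed`.
#' @return An `eec_pipeline_config` list.
#' @export
eec_pipeline_config <- function(generator = NULL, input_dir = NULL,
                                thresholds = qc_thresholds(),
                                params = eec_pipeline_params(), seed) {
  if (missing(seed) || is.null(seed))
    abort("`seed` is mandatory in a pipeline configuration")
  if (is.null(generator) && is.null(input_dir))
    abort("provide either a generator config or an input directory")
  params$seed <- as.integer(seed)
  structure(list(generator = generator, input_dir = input_dir,
                 thresholds = thresholds, params = params,
                 seed = as.integer(seed)),
            class = "eec_pipeline_config")
}

#' Run the two-pass clustering and axis-correlation pipeline
#'
#' Executes, in order: cohort input (read or simulate + debris spike),
#' cell-level QC, first-pass standard normalization with clustering and
#' one-vs-rest differential expression to collect the DE gene set, the
#' second-pass cell filter on DE-gene UMIs, non-DE normalization,
#' clustering, differential expression and hormone-based annotation, L-cell
#' subset re-clustering with subcluster annotation, and the paired
#' fold-change correlation analyses (Sct/Gcg split within each L type, and
#' pooled L vs enterochromaffin maturation splits).  Deterministic given the
#' configuration and seed.
#'
#' @param config An [eec_pipeline_config()].
#' @param out_dir Optional directory; when given, all tables plus a run
#'   manifest are written as TSV.
#' @param verbose Log stage progress to stderr.
#' @return An `eec_pipeline_result` list (see elements in the examples of
#'   the package vignette).
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "eec_pipeline_config"))
  par <- config$params
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()

  if (!is.null(config$input_dir)) {
    say("reading counts from %s", config$input_dir)
    counts <- read_counts(config$input_dir)
    truth <- NULL
  } else {
    say("simulating cohort (seed %d)", config$generator$seed)
    cohort <- generate_cohort(config$generator)
    cohort <- spike_debris(cohort)
    counts <- cohort$counts
    truth <- cohort$truth
  }
  m <- as_count_matrix(counts)

  say("QC on %d cells", ncol(m))
  qc <- compute_qc(m)
  filt <- filter_cells(qc, config$thresholds)
  m1 <- m[, filt$retained, drop = FALSE]

  say("pass 1: standard normalization + DE screen (%d cells)", ncol(m1))
  de_set <- first_pass_de_genes(m1, par)
  say("pass 1 found %d DE genes", length(de_set$genes))

  retained2 <- refilter_on_de_umis(m1, de_set, min_de_umi = par$min_de_umi)
  m2 <- m1[, retained2, drop = FALSE]
  say("pass 2: %d cells after DE-UMI filter", ncol(m2))

  norm <- nonde_normalize(m2, de_set, scale = par$scale)
  hvg <- select_hvgs(norm, n_hvg = par$n_hvg, n_bins = par$hvg_bins)
  emb <- run_pca(norm, hvg, n_dims = par$n_dims)
  graph <- build_snn(emb, k = par$snn_k, prune = par$snn_prune)
  labels <- cluster_graph(graph, resolution = par$resolution, seed = par$seed)
  say("pass 2: %d clusters", attr(labels, "K"))

  de <- run_de(norm, one_vs_rest_comparisons(labels),
               l2fc_min = par$l2fc_min, fdr = par$fdr, min_pct = par$min_pct)
  ann <- annotate_clusters(norm, labels)

  l_clusters <- ann$cluster[ann$major_type == "L"]
  sub <- NULL; sub_ann <- NULL; axes <- list(); sub_norm <- NULL
  if (length(l_clusters) && sum(labels$cluster %in% l_clusters) >= 20) {
    say("subclustering %d L clusters", length(l_clusters))
    sub <- subset_and_recluster(m2, labels, l_clusters, par,
                                de_genes = de_set$genes)
    sub_norm <- nonde_normalize(m2[, sub$barcode, drop = FALSE],
                                de_set$genes, scale = par$scale)
    sub_ann <- tryCatch(
      annotate_clusters(sub_norm, sub,
                        major_markers = c(Nts = "L-Nts", Insl5 = "L-Insl5"),
                        tag_genes = c("Sct", "Gcg", "Pyy")),
      error = function(e) NULL)
    if (!is.null(sub_ann)) {
      pair_axis <- function(type, id_prefix) {
        cmp <- grouped_comparison(
          sub, sub_ann,
          rule_a = list(major_type = type, Sct_pos = TRUE),
          rule_b = list(major_type = type, Sct_pos = FALSE),
          id = paste0(id_prefix, "_Sct_vs_Gcg"))
        run_de(sub_norm, cmp, l2fc_min = 0, fdr = par$fdr, min_pct = par$min_pct)
      }
      de_insl5 <- tryCatch(pair_axis("L-Insl5", "LInsl5"), error = function(e) NULL)
      de_nts <- tryCatch(pair_axis("L-Nts", "LNts"), error = function(e) NULL)
      if (!is.null(de_insl5) && !is.null(de_nts))
        axes$l_maturation <- axis_correlation(de_insl5, de_nts,
                                              l2fc_min = par$l2fc_min)
    }
    # pooled Sct+ vs Sct- L cells against the Ecm Sct vs Tac1 split,
    # both taken from the global clustering
    ecm <- ann$cluster[ann$major_type == "Ecm"]
    if (!is.null(sub_ann) && length(ecm) >= 2) {
      cmp_l <- tryCatch(grouped_comparison(
        sub, sub_ann, rule_a = list(Sct_pos = TRUE),
        rule_b = list(Sct_pos = FALSE), id = "L_Sct_vs_Gcg_pooled"),
        error = function(e) NULL)
      cmp_ecm <- tryCatch(grouped_comparison(
        labels, ann, rule_a = list(major_type = "Ecm", Sct_pos = TRUE),
        rule_b = list(major_type = "Ecm", Tac1_pos = TRUE),
        id = "Ecm_Sct_vs_Tac_pooled"), error = function(e) NULL)
      if (!is.null(cmp_l) && !is.null(cmp_ecm)) {
        de_l <- run_de(sub_norm, cmp_l, l2fc_min = 0, fdr = par$fdr,
                       min_pct = par$min_pct)
        de_e <- run_de(norm, cmp_ecm, l2fc_min = 0, fdr = par$fdr,
                       min_pct = par$min_pct)
        axes$l_vs_ecm_maturation <-
          axis_correlation(de_l, de_e, l2fc_min = par$l2fc_min)
      }
    }
  }

  hormones <- intersect(c("Tph1", "Gcg", "Pyy", "Sst", "Sct", "Tac1", "Nts",
                          "Insl5", "Cck", "Piezo2"), rownames(norm$values))
  heat <- heatmap_table(norm, labels, hormones)
  hoxb <- intersect(c("Hoxb6", "Hoxb7", "Hoxb8", "Hoxb13"), rownames(norm$values))
  violin <- if (length(hoxb)) violin_table(norm, labels, hoxb) else NULL
  tsne <- tsne_embed(emb, perplexity = min(30, floor((ncol(m2) - 2) / 3)),
                     seed = par$seed)

  result <- structure(list(
    config = config, qc = filt, de_gene_set = de_set,
    retained_pass1 = filt$retained, retained_pass2 = retained2,
    norm = norm, embedding = emb, labels = labels, de = de,
    annotation = ann, subclusters = sub, sub_annotation = sub_ann,
    axes = axes, heatmap = heat, violin = violin, tsne = tsne,
    truth = truth,
    elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "eec_pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' @export
print.eec_pipeline_result <- function(x, ...) {
  cat(sprintf(paste0(
    "eec_pipeline_result: %d cells retained (of %d), %d clusters",
    "%s, %d first-pass DE genes [%.1f s]\n"),
    length(x$retained_pass2), nrow(x$qc$metrics), attr(x$labels, "K"),
    if (!is.null(x$subclusters))
      sprintf(", %d L subclusters", attr(x$subclusters, "K")) else "",
    length(x$de_gene_set$genes), x$elapsed))
  if (length(x$axes)) for (a in x$axes) print(a)
  invisible(x)
}

#' Cluster-by-gene table of expression relative to average
#'
#' For each gene: the per-cluster mean of de-logged normalized expression,
#' centered by the mean of the cluster means, so each gene's values sum to
#' zero across clusters.
#'
#' @param norm An `eec_norm`.
#' @param labels An `eec_clusters`.
#' @param genes Genes to include.
#' @return Tibble `(gene, cluster, relative_expression)` in long format.
#' @export
heatmap_table <- function(norm, labels, genes) {
  missing <- setdiff(genes, rownames(norm$values))
  if (length(missing))
    abort(paste0("unknown gene(s): ", paste(missing, collapse = ", ")))
  ks <- sort(unique(labels$cluster))
  e <- norm$values[genes, labels$barcode, drop = FALSE]
  e@x <- expm1(e@x)
  cm <- vapply(ks, function(k)
    Matrix::rowMeans(e[, labels$cluster == k, drop = FALSE]),
    numeric(length(genes)))
  cm <- matrix(cm, nrow = length(genes), dimnames = list(genes, ks))
  centered <- cm - rowMeans(cm)
  as_tibble(as.table(centered), .name_repair = "minimal") |>
    rlang::set_names(c("gene", "cluster", "relative_expression")) |>
    mutate(cluster = as.integer(as.character(.data$cluster)))
}

#' Long table of per-cell log2 normalized expression by cluster
#'
#' One row per cell and gene with `log2(normalized count + 1)`, the
#' quantity shown in violin plots of normalized UMIs.
#'
#' @param norm An `eec_norm`.
#' @param labels An `eec_clusters`.
#' @param genes Genes to include.
#' @return Tibble `(barcode, cluster, gene, log2_numi)`.
#' @export
violin_table <- function(norm, labels, genes) {
  missing <- setdiff(genes, rownames(norm$values))
  if (length(missing))
    abort(paste0("unknown gene(s): ", paste(missing, collapse = ", ")))
  e <- expm1(as.matrix(norm$values[genes, labels$barcode, drop = FALSE]))
  as_tibble(as.table(e), .name_repair = "minimal") |>
    rlang::set_names(c("gene", "barcode", "value")) |>
    mutate(log2_numi = log2(.data$value + 1)) |>
    left_join(as_tibble(labels), by = "barcode") |>
    select("barcode", "cluster", "gene", "log2_numi")
}

write_tsv_plain <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write all pipeline tables and a run manifest
#'
#' @param result An `eec_pipeline_result`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_tsv_plain(result$qc$report, p("qc_report.tsv"))
  writeLines(result$retained_pass2, p("retained_barcodes.tsv"))
  write_tsv_plain(tibble(gene = result$de_gene_set$genes), p("de_gene_set.tsv"))
  write_tsv_plain(result$labels, p("cluster_labels.tsv"))
  write_tsv_plain(as_tibble(result$de), p("de_tables.tsv"))
  write_tsv_plain(select(result$annotation, -dplyr::any_of("tags")) |>
                    mutate(tags = result$annotation$tags),
                  p("cluster_annotation.tsv"))
  if (!is.null(result$subclusters))
    write_tsv_plain(result$subclusters, p("subcluster_labels.tsv"))
  if (length(result$axes)) {
    summaries <- purrr::map(result$axes, glance) |> bind_rows()
    write_tsv_plain(summaries, p("axis_summary.tsv"))
    for (nm in names(result$axes))
      write_tsv_plain(result$axes[[nm]]$genes, p(sprintf("axis_%s.tsv", nm)))
  }
  write_tsv_plain(result$heatmap, p("heatmap_hormones.tsv"))
  if (!is.null(result$violin)) write_tsv_plain(result$violin, p("violin_hoxb.tsv"))
  write_tsv_plain(result$tsne, p("tsne.tsv"))
  manifest <- c(
    sprintf("package_version\t%s", as.character(utils::packageVersion("eecaxes"))),
    sprintf("r_version\t%s", R.version.string),
    sprintf("seed\t%d", result$config$seed),
    sprintf("config_hash\t%s", rlang::hash(result$config)),
    sprintf("n_cells_input\t%d", nrow(result$qc$metrics)),
    sprintf("n_cells_retained\t%d", length(result$retained_pass2)),
    sprintf("n_clusters\t%d", attr(result$labels, "K")))
  writeLines(manifest, p("manifest.tsv"))
  invisible(out_dir)
}
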