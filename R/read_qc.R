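#' Read a CellRanger-style count triple
#'
#' Expects `matrix.mtx`, `barcodes.tsv` and `features.tsv` (or `genes.tsv`)
#' in `dir`, each optionally gzipped.  The matrix must be genes-by-cells,
#' integer and non-negative; gene and cell order are preserved from the
#' files.
#'
#' @param dir Directory containing the triple.
#' @return An `eec_counts` object.
#' @export
read_counts <- function(dir) {
  find1 <- function(stems) {
    for (s in stems) for (ext in c("", ".gz")) {
      p <- file.path(dir, paste0(s, ext))
      if (file.exists(p)) return(p)
    }
    abort(paste0("missing input file in ", dir, ": expected one of ",
                 paste(stems, collapse = " / "), " (optionally .gz)"))
  }
  mtx_path <- find1("matrix.mtx")
  bc_path <- find1("barcodes.tsv")
  ft_path <- find1(c("features.tsv", "genes.tsv"))

  open_maybe_gz <- function(p) if (endsWith(p, ".gz")) gzfile(p, "r") else file(p, "r")
  con <- open_maybe_gz(mtx_path)
  m <- tryCatch(Matrix::readMM(con),
                error = function(e) abort(paste0("malformed Matrix Market file ",
                                                 mtx_path, ": ", conditionMessage(e))))
  close(con)
  barcodes <- readLines(open_gz <- open_maybe_gz(bc_path)); close(open_gz)
  ft_raw <- readLines(open_gz <- open_maybe_gz(ft_path)); close(open_gz)
  ft <- strsplit(ft_raw, "\t", fixed = TRUE)
  genes <- tibble(gene_id = vapply(ft, `[[`, character(1), 1),
                  gene_name = vapply(ft, function(x) x[[min(2, length(x))]],
                                     character(1)))
  if (nrow(genes) != nrow(m))
    abort(sprintf("dimension mismatch: %s declares %d genes but %s has %d lines",
                  basename(mtx_path), nrow(m), basename(ft_path), nrow(genes)))
  if (length(barcodes) != ncol(m))
    abort(sprintf("dimension mismatch: %s declares %d cells but %s has %d lines",
                  basename(mtx_path), ncol(m), basename(bc_path), length(barcodes)))
  if (anyDuplicated(barcodes)) abort(paste0("duplicate barcodes in ", bc_path))
  if (anyDuplicated(genes$gene_id)) abort(paste0("duplicate gene ids in ", ft_path))
  vals <- methods::as(m, "TsparseMatrix")@x
  if (length(vals) && (any(vals < 0) || any(vals != round(vals))))
    abort(paste0("non-integer or negative values in ", mtx_path))
  genes$row_name <- make.unique(genes$gene_name)
  m <- methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
  dimnames(m) <- list(genes$row_name, barcodes)
  new_eec_counts(m, genes[, c("gene_id", "gene_name")])
}

#' Per-cell quality-control metrics
#'
#' Computes, for every barcode, the number of expressed genes (count > 0),
#' the total UMI count, the percentage of UMIs in mitochondrial genes
#' (0-100), and optionally the UMI count restricted to a supplied gene set
#' (used by the second-pass filter on differentially expressed genes).
#'
#' @param x Counts (`eec_counts` or genes-by-cells matrix).
#' @param mito_pattern Regular expression on gene names identifying
#'   mitochondrial genes; the default is the mouse `mt-` prefix,
#'   case-insensitive.
#' @param de_genes Optional character vector of gene names; adds an
#'   `n_umi_de` column with per-cell UMIs in that set.
#' @return Tibble with one row per cell: `barcode`, `n_genes`, `n_umi`,
#'   `pct_mito` (and `n_umi_de` if requested).
#' @export
compute_qc <- function(x, mito_pattern = "^mt-", de_genes = NULL) {
  m <- as_count_matrix(x)
  is_mito <- grepl(mito_pattern, rownames(m), ignore.case = TRUE)
  if (!any(is_mito))
    warn(paste0("no gene names match mito pattern '", mito_pattern,
                "'; pct_mito will be 0 for all cells"))
  n_umi <- Matrix::colSums(m)
  n_genes <- Matrix::colSums(m > 0)
  mito_umi <- if (any(is_mito)) Matrix::colSums(m[is_mito, , drop = FALSE]) else 0
  out <- tibble(barcode = colnames(m),
                n_genes = as.integer(n_genes),
                n_umi = as.numeric(n_umi),
                pct_mito = ifelse(n_umi > 0, 100 * mito_umi / n_umi, 0))
  if (!is.null(de_genes)) {
    keep <- rownames(m) %in% de_genes
    out$n_umi_de <- as.numeric(Matrix::colSums(m[keep, , drop = FALSE]))
  }
  out
}

#' Quality-control thresholds
#'
#' Defaults follow the published filters: at least 800 expressed genes, at
#' least 1250 UMIs, at most the third quartile plus one interquartile range
#' of UMIs (computed among cells passing the other rules, unless a fixed
#' `max_umi` is supplied), and a mitochondrial percentage between 1 and 7.5
#' (both bounds inclusive).
#'
#' @param min_genes,min_umi Lower bounds (inclusive).
#' @param max_umi Fixed upper UMI bound; `NULL` (default) computes
#'   `Q3 + IQR` at filter time.
#' @param mito_range Length-2 inclusive percentage bounds.
#' @param min_de_umi Minimum UMIs in the differentially-expressed gene set
#'   (second pass only).
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_genes = 800, min_umi = 1250, max_umi = NULL,
                          mito_range = c(1, 7.5), min_de_umi = 800) {
  stopifnot(min_genes > 0, min_umi > 0, mito_range[1] < mito_range[2])
  structure(list(min_genes = min_genes, min_umi = min_umi, max_umi = max_umi,
                 mito_range = mito_range, min_de_umi = min_de_umi),
            class = "qc_thresholds")
}

#' Filter cells on quality-control metrics
#'
#' A cell is retained iff `n_genes >= min_genes`, `n_umi >= min_umi`,
#' `n_umi <= max_umi` and `mito_range[1] <= pct_mito <= mito_range[2]`.
#' When `max_umi` is not fixed in `thresholds` it is computed once as
#' `Q3 + IQR` (linear-interpolation quartiles) of `n_umi` among the cells
#' that already pass the three other rules, then applied in the same single
#' pass; the computed cutoff is stored in the result so that re-filtering
#' with it is a fixed point.
#'
#' @param metrics Tibble from [compute_qc()].
#' @param thresholds A [qc_thresholds()] object.
#' @return An `eec_qc_filter` list: `retained` (barcodes), `umi_upper` (the
#'   cutoff applied), `report` (tibble of per-rule removal counts; a cell
#'   failing several rules is counted under each), and `metrics` with a
#'   `retained` column added.
#' @export
filter_cells <- function(metrics, thresholds = qc_thresholds()) {
  stopifnot(is.data.frame(metrics), nrow(metrics) > 0)
  th <- thresholds
  pass_genes <- metrics$n_genes >= th$min_genes
  pass_low_umi <- metrics$n_umi >= th$min_umi
  pass_mito <- metrics$pct_mito >= th$mito_range[1] &
    metrics$pct_mito <= th$mito_range[2]
  if (is.null(th$max_umi)) {
    candidates <- metrics$n_umi[pass_genes & pass_low_umi & pass_mito]
    if (!length(candidates))
      abort("no cells pass the lower QC bounds; review thresholds")
    q <- quantile(candidates, c(0.25, 0.75), type = 7, names = FALSE)
    umi_upper <- q[2] + (q[2] - q[1])
  } else {
    umi_upper <- th$max_umi
  }
  pass_high_umi <- metrics$n_umi <= umi_upper
  retained <- pass_genes & pass_low_umi & pass_mito & pass_high_umi
  if (!any(retained))
    abort("all cells removed by QC; review thresholds")
  report <- tibble(
    rule = c("min_genes", "min_umi", "max_umi", "mito_range", "total_removed"),
    threshold = c(th$min_genes, th$min_umi, umi_upper,
                  paste(th$mito_range, collapse = "-"), NA) |> as.character(),
    removed = c(sum(!pass_genes), sum(!pass_low_umi), sum(!pass_high_umi),
                sum(!pass_mito), sum(!retained)))
  metrics$retained <- retained
  structure(list(retained = metrics$barcode[retained],
                 umi_upper = umi_upper, report = report, metrics = metrics),
            class = "eec_qc_filter")
}

#' @export
print.eec_qc_filter <- function(x, ...) {
  cat(sprintf("eec_qc_filter: %d of %d cells retained (nUMI upper bound %.1f)\n",
              length(x$retained), nrow(x$metrics), x$umi_upper))
  print(x$report)
  invisible(x)
}
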