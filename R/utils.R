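#' @importFrom rlang abort warn inform %||% .data
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows n across all_of desc pull rename row_number
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats prcomp quantile rnbinom rpois rlnorm rbeta runif setNames
#'   p.adjust wilcox.test var sd cor median
#' @importFrom utils head modifyList
#' @importFrom Matrix colSums rowSums rowMeans t readMM sparseMatrix
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

# Accept either an eec_counts container or a bare dgCMatrix (genes x cells,
# dimnames set) wherever a count matrix is expected.
as_count_matrix <- function(x) {
  if (inherits(x, "eec_counts")) x <- x$counts
  if (!methods::is(x, "sparseMatrix")) {
    if (is.matrix(x)) {
      x <- methods::as(methods::as(Matrix::Matrix(x, sparse = TRUE),
                                   "CsparseMatrix"), "generalMatrix")
    } else {
      abort("counts must be an eec_counts object or a (sparse) matrix")
    }
  }
  if (is.null(colnames(x)) && ncol(x) == 0) x@Dimnames[[2]] <- character(0)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    abort("count matrix must carry gene rownames and barcode colnames")
  x
}

assert_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    abort(paste0("`", name, "` must be a single positive number"))
  invisible(x)
}

# largest-remainder apportionment of n among proportions (exact quota)
quota_sizes <- function(proportions, n) {
  raw <- proportions * n
  sizes <- floor(raw)
  short <- n - sum(sizes)
  if (short > 0) {
    extra <- order(raw - sizes, decreasing = TRUE)[seq_len(short)]
    sizes[extra] <- sizes[extra] + 1L
  }
  as.integer(sizes)
}
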