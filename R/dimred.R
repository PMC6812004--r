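#' Select highly variable genes by binned standardized dispersion
#'
#' Genes are scored on de-logged normalized expression: dispersion =
#' log(variance/mean), standardized (z-scored) within equal-width bins of
#' log mean expression so that highly expressed genes do not dominate, then
#' ranked.  Zero-variance genes are never selected.
#'
#' @param norm An `eec_norm` from [lognormalize()].
#' @param n_hvg Number of genes to return (clamped, with a warning, to the
#'   number of genes with positive variance).
#' @param n_bins Number of mean bins (default 20).
#' @return Character vector of gene names, ranked most variable first.
#' @export
select_hvgs <- function(norm, n_hvg = 1000, n_bins = 20) {
  stopifnot(inherits(norm, "eec_norm"))
  v <- norm$values
  if (ncol(v) < 2) abort("need at least 2 cells to select variable genes")
  e <- v; e@x <- expm1(e@x)
  n <- ncol(e)
  mu <- Matrix::rowMeans(e)
  e2 <- e; e2@x <- e2@x^2
  vv <- (Matrix::rowMeans(e2) - mu^2) * n / (n - 1)
  vv <- pmax(vv, 0)
  ok <- vv > 0 & mu > 0
  if (!any(ok)) abort("all genes have zero variance")
  disp <- log(vv[ok] / mu[ok])
  bins <- cut(log1p(mu[ok]), breaks = min(n_bins, sum(ok)), labels = FALSE,
              include.lowest = TRUE)
  z <- stats::ave(disp, bins, FUN = function(x) {
    s <- sd(x)
    if (!is.finite(s) || s == 0) return(rep(0, length(x)))
    (x - mean(x)) / s
  })
  genes <- rownames(v)[ok]
  ranked <- genes[order(-z, genes)]
  if (n_hvg > length(ranked)) {
    warn(sprintf("n_hvg = %d exceeds the %d genes with positive variance; returning all",
                 n_hvg, length(ranked)))
    n_hvg <- length(ranked)
  }
  ranked[seq_len(n_hvg)]
}

#' Principal component analysis on highly variable genes
#'
#' Genes are centered and (by default) unit-scaled across cells, scaled
#' values are clipped at `clip` standard deviations, and cells are projected
#' onto the top right-singular directions.  The sign of each component is
#' fixed so its largest-magnitude gene loading is positive, making scores
#' reproducible across platforms.
#'
#' @param norm An `eec_norm`.
#' @param hvg Genes to use (default: [select_hvgs()] with its defaults).
#' @param n_dims Number of components to retain.
#' @param scale. Unit-scale genes before PCA (default `TRUE`).
#' @param clip Clip scaled values at +/- this many SDs (default 10; `Inf`
#'   disables).
#' @return An `eec_embedding`: `scores` (cells x dims), `explained_variance`
#'   (all available components, non-increasing), `rotation`, `hvg`.
#' @export
run_pca <- function(norm, hvg = NULL, n_dims = 7, scale. = TRUE, clip = 10) {
  stopifnot(inherits(norm, "eec_norm"), n_dims >= 1)
  if (is.null(hvg)) hvg <- select_hvgs(norm)
  missing <- setdiff(hvg, rownames(norm$values))
  if (length(missing))
    abort(paste0("HVGs not in matrix: ", paste(head(missing, 5), collapse = ", ")))
  X <- as.matrix(Matrix::t(norm$values[hvg, , drop = FALSE]))
  X <- scale(X, center = TRUE, scale = scale.)
  X[is.na(X)] <- 0
  if (is.finite(clip)) X[X > clip] <- clip; X[X < -clip] <- -clip
  max_rank <- min(ncol(X), nrow(X) - 1L)
  if (n_dims > max_rank)
    abort(sprintf("n_dims = %d exceeds the maximum rank %d", n_dims, max_rank))
  fit <- prcomp(X, center = FALSE, scale. = FALSE)
  ev <- fit$sdev^2
  keep <- seq_len(min(length(ev), max_rank))
  rot <- fit$rotation[, seq_len(n_dims), drop = FALSE]
  scores <- fit$x[, seq_len(n_dims), drop = FALSE]
  for (k in seq_len(n_dims)) {
    j <- which.max(abs(rot[, k]))
    if (rot[j, k] < 0) {
      rot[, k] <- -rot[, k]
      scores[, k] <- -scores[, k]
    }
  }
  rownames(scores) <- colnames(norm$values)
  structure(list(scores = scores, explained_variance = ev[keep],
                 rotation = rot, hvg = hvg),
            class = "eec_embedding")
}

#' @export
print.eec_embedding <- function(x, ...) {
  cat(sprintf("eec_embedding: %d cells x %d dims (top EV %.3g)\n",
              nrow(x$scores), ncol(x$scores), x$explained_variance[1]))
  invisible(x)
}

#' Elbow rule for the number of informative components
#'
#' Counts the components whose variance exceeds a noise floor estimated as
#' `floor_mult` times the median of the leading (up to 30) component
#' variances (the bulk of uninformative components concentrates around that
#' median); an alternative to a fixed dimensionality for subcluster
#' analyses.
#'
#' @param explained_variance Non-increasing variances from [run_pca()].
#' @param floor_mult Multiple of the median variance separating signal from
#'   the noise bulk (default 1.3).
#' @param min_dims,max_dims Clamp of the result.
#' @return Integer number of dimensions.
#' @export
choose_dims_elbow <- function(explained_variance, floor_mult = 1.3,
                              min_dims = 2, max_dims = 20) {
  ev <- explained_variance
  bulk <- median(ev[seq_len(min(30L, length(ev)))])
  d <- sum(ev > floor_mult * bulk)
  as.integer(min(max(d, min_dims), max_dims, length(ev)))
}

#' Shared-nearest-neighbor graph
#'
#' Finds each cell's `k` nearest neighbors by Euclidean distance in the
#' embedding (distance ties broken by ascending cell index), forms neighbor
#' sets that include the cell itself, and connects cells `i`, `j` with
#' weight `|N(i) \eqn{\cap}{ } N(j)| / |N(i) \eqn{\cup}{ } N(j)|` (Jaccard);
#' edges below `prune` are dropped.
#'
#' @param embedding An `eec_embedding` (or a numeric cells x dims matrix
#'   with rownames).
#' @param k Number of neighbors (must be < number of cells).
#' @param prune Minimum Jaccard weight kept (default 1/15).
#' @return An `eec_snn`: sparse symmetric `adjacency` plus parameters.
#' @export
build_snn <- function(embedding, k = 20, prune = 1/15) {
  scores <- if (inherits(embedding, "eec_embedding")) embedding$scores else embedding
  n <- nrow(scores)
  if (k >= n) abort(sprintf("k = %d must be smaller than the number of cells (%d)", k, n))
  d <- as.matrix(stats::dist(scores))
  idx <- matrix(0L, n, k + 1L)
  for (i in seq_len(n)) {
    ord <- order(d[i, ], method = "radix")     # stable: ties by cell index
    ord <- ord[ord != i]
    idx[i, ] <- c(i, ord[seq_len(k)])
  }
  A <- sparseMatrix(i = rep(seq_len(n), each = k + 1L), j = as.vector(t(idx)),
                    x = 1, dims = c(n, n))
  S <- methods::as(methods::as(Matrix::tcrossprod(A), "generalMatrix"),
                   "TsparseMatrix")
  w <- S@x / (2 * (k + 1) - S@x)
  keep <- S@i != S@j & w >= prune
  adj <- sparseMatrix(i = S@i[keep] + 1L, j = S@j[keep] + 1L, x = w[keep],
                      dims = c(n, n), dimnames = list(rownames(scores),
                                                      rownames(scores)))
  structure(list(adjacency = adj, k = k, prune = prune), class = "eec_snn")
}

#' Louvain community detection on the SNN graph
#'
#' Modularity-based Louvain clustering at the given resolution.  Labels are
#' integers `0..K-1`, renumbered by decreasing cluster size for stability;
#' the result is deterministic given the seed.
#'
#' @param graph An `eec_snn` from [build_snn()].
#' @param resolution Modularity resolution (default 0.8).
#' @param seed Integer seed.
#' @return An `eec_clusters` tibble `(barcode, cluster)` with attributes
#'   `K` and `params`.
#' @export
cluster_graph <- function(graph, resolution = 0.8, seed = 0) {
  stopifnot(inherits(graph, "eec_snn"))
  adj <- graph$adjacency
  if (nrow(adj) == 0) abort("empty graph")
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  mem <- igraph::membership(comm)
  sizes <- table(mem)
  new_id <- rank(-as.numeric(sizes), ties.method = "first") - 1L
  cluster <- as.integer(new_id[match(as.character(mem), names(sizes))])
  out <- tibble(barcode = rownames(adj), cluster = cluster)
  structure(out, K = length(sizes),
            params = list(k = graph$k, prune = graph$prune,
                          resolution = resolution, seed = seed),
            class = c("eec_clusters", class(out)))
}

#' Two-dimensional t-SNE layout for visualization
#'
#' Seed-deterministic t-SNE of the PCA scores.  The layout is for plotting
#' only; no downstream computation depends on it.
#'
#' @param embedding An `eec_embedding`.
#' @param perplexity t-SNE perplexity; must be below `(n_cells - 1) / 3`.
#' @param seed Integer seed.
#' @return Tibble `(barcode, tsne1, tsne2)`.
#' @export
tsne_embed <- function(embedding, perplexity = 30, seed = 0) {
  scores <- embedding$scores
  n <- nrow(scores)
  if (perplexity >= (n - 1) / 3)
    abort(sprintf("perplexity = %g too large for %d cells (must be < %g)",
                  perplexity, n, (n - 1) / 3))
  set.seed(seed)
  fit <- Rtsne::Rtsne(scores, dims = 2, perplexity = perplexity, pca = FALSE,
                      check_duplicates = FALSE, verbose = FALSE)
  tibble(barcode = rownames(scores),
         tsne1 = fit$Y[, 1], tsne2 = fit$Y[, 2])
}
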