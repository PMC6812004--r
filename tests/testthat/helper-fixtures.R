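# Shared fixtures and independent oracles.  Everything here is built in
# code at test time; no binary data.

sparse_counts <- function(mat, genes = NULL, cells = NULL) {
  if (is.null(rownames(mat)) && nrow(mat) > 0)
    rownames(mat) <- genes %||% paste0("g", seq_len(nrow(mat)))
  if (is.null(colnames(mat)) && ncol(mat) > 0)
    cells <- cells %||% paste0("c", seq_len(ncol(mat)))
  if (!is.null(cells) && ncol(mat) > 0) colnames(mat) <- cells
  methods::as(methods::as(Matrix::Matrix(mat, sparse = TRUE), "CsparseMatrix"),
              "generalMatrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hand-built eec_norm from a dense matrix of already-normalized log values
make_norm <- function(values, size_factors = rep(1, ncol(values)),
                      basis = "total", de_genes = character(), scale = 1e4) {
  v <- sparse_counts(values)
  structure(list(values = v,
                 size_factors = stats::setNames(size_factors, colnames(v)),
                 basis = basis, de_genes = de_genes, scale = scale),
            class = "eec_norm")
}

# two-population toy generator config: one strong marker in pop A
two_pop_marker_config <- function(n_cells = 200, n_genes = 60, mult = 8,
                                  seed = 5, dispersion = 0.3,
                                  marker = "MarkerA", program_genes = 0) {
  stopifnot(n_genes > program_genes + 1)
  prog <- if (program_genes > 0) sprintf("progA%02d", seq_len(program_genes))
  genes <- tibble::tibble(
    gene_id = sprintf("G%03d", seq_len(n_genes)),
    gene_name = c(marker, prog,
                  sprintf("bg%03d", seq_len(n_genes - 1 - program_genes))),
    base_weight = c(0.2, rep(0.5, program_genes),
                    rep(1, n_genes - 1 - program_genes)),
    is_mito = FALSE)
  markers_a <- c(stats::setNames(mult, marker),
                 stats::setNames(rep(4, program_genes), prog))
  eec_generator_config(
    n_cells = n_cells, genes = genes,
    populations = list(
      population_spec("A", 0.5, markers_a),
      population_spec("B", 0.5)),
    library_size = c(meanlog = log(3000), sdlog = 0.1),
    nb_dispersion = dispersion, debris_fraction = 0, seed = seed)
}

# Exact two-sided Mann-Whitney p-value by complete enumeration of group
# assignments (tie-free data); independent of stats::wilcox.test.
enum_wilcox <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * n2 / 2
  if (u_obs > mu) {
    p <- 2 * mean(u_all >= u_obs)
  } else if (u_obs < mu) {
    p <- 2 * mean(u_all <= u_obs)
  } else p <- 1
  list(statistic = u_obs, p.value = min(p, 1))
}

# Benjamini-Hochberg step-up from its defining formula, restored to the
# input order; independent of stats::p.adjust.
stepup_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  pmin(q_sorted, 1)[order(o)]
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
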