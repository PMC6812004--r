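test_that("constant genes are never selected and markers outrank background", {
  cfg <- two_pop_marker_config(n_cells = 150, n_genes = 100, mult = 10, seed = 11)
  norm <- lognormalize(generate_cohort(cfg)$counts$counts)
  # append an exactly constant gene
  const <- make_norm(matrix(1, 1, ncol(norm$values),
                            dimnames = list("flat", colnames(norm$values))))
  norm$values <- rbind(norm$values, const$values)
  hvg <- select_hvgs(norm, n_hvg = 50)
  expect_false("flat" %in% hvg)
  expect_lte(match("MarkerA", hvg), 5)
  expect_warning(all_g <- select_hvgs(norm, n_hvg = 1e5), "exceeds")
  expect_false("flat" %in% all_g)
})

test_that("PCA handles rank-1 data and matches an eigendecomposition oracle", {
  set.seed(21)
  # rank-1: cells on a single line in gene space
  t_coord <- seq(-2, 2, length.out = 15)
  profile <- stats::rnorm(6)
  vals <- outer(profile, t_coord)
  dimnames(vals) <- list(paste0("g", 1:6), paste0("c", 1:15))
  norm1 <- make_norm(vals)
  emb1 <- run_pca(norm1, rownames(vals), n_dims = 2, scale. = FALSE)
  expect_gt(emb1$explained_variance[1] / sum(emb1$explained_variance), 0.999)

  # oracle on a 20 x 10 fixture: full eigendecomposition of the covariance
  X <- matrix(stats::rnorm(200), nrow = 10, ncol = 20,
              dimnames = list(paste0("g", 1:10), paste0("c", 1:20)))
  norm <- make_norm(X)
  emb <- run_pca(norm, rownames(X), n_dims = 5, scale. = FALSE, clip = Inf)
  Xc <- scale(t(X), center = TRUE, scale = FALSE)
  eig <- eigen(stats::cov(Xc), symmetric = TRUE)
  expect_equal(emb$explained_variance[1:5], eig$values[1:5], tolerance = 1e-8)
  oracle_scores <- Xc %*% eig$vectors[, 1:5]
  for (k in 1:5) {
    j <- which.max(abs(eig$vectors[, k]))
    if (eig$vectors[j, k] < 0) oracle_scores[, k] <- -oracle_scores[, k]
  }
  expect_equal(unname(emb$scores), unname(oracle_scores), tolerance = 1e-8)
})

test_that("explained variances are rotation invariant and rank errors are caught", {
  set.seed(22)
  X <- matrix(stats::rnorm(30 * 8), nrow = 8,
              dimnames = list(paste0("g", 1:8), paste0("c", 1:30)))
  R <- qr.Q(qr(matrix(stats::rnorm(64), 8)))
  XR <- t(R) %*% X
  dimnames(XR) <- dimnames(X)
  ev1 <- run_pca(make_norm(X), rownames(X), n_dims = 3, scale. = FALSE,
                 clip = Inf)$explained_variance
  ev2 <- run_pca(make_norm(XR), rownames(X), n_dims = 3, scale. = FALSE,
                 clip = Inf)$explained_variance
  expect_equal(ev1, ev2, tolerance = 1e-8)
  expect_error(run_pca(make_norm(X), rownames(X), n_dims = 9), "rank")
})

test_that("elbow rule counts components above the noise floor", {
  expect_equal(choose_dims_elbow(c(20, 7, rep(1, 28))), 2L)
  expect_equal(choose_dims_elbow(c(20, rep(5, 29)), min_dims = 2), 2L)
  expect_equal(choose_dims_elbow(rep(1, 30), min_dims = 3), 3L)
})

test_that("SNN weights follow the Jaccard definition on constructed geometry", {
  # identical coordinates share full neighbor sets: weight 1
  pts <- rbind(matrix(0, 2, 2), matrix(10, 3, 2), matrix(c(20, 20, 21, 21), 2))
  rownames(pts) <- paste0("c", 1:7)
  g <- build_snn(pts, k = 2, prune = 0.01)
  expect_equal(g$adjacency["c1", "c2"], 1)
  # two tight, distant groups with k below group size: no cross edges
  set.seed(23)
  blob1 <- matrix(stats::rnorm(40, 0, 0.1), 20)
  blob2 <- matrix(stats::rnorm(40, 50, 0.1), 20)
  pts2 <- rbind(blob1, blob2)
  rownames(pts2) <- paste0("c", 1:40)
  g2 <- build_snn(pts2, k = 5, prune = 1/15)
  expect_equal(sum(g2$adjacency[1:20, 21:40]), 0)
  # deterministic: same input, same graph
  g3 <- build_snn(pts2, k = 5, prune = 1/15)
  expect_identical(as.matrix(g2$adjacency), as.matrix(g3$adjacency))
  expect_error(build_snn(pts, k = 10), "smaller")
})

test_that("Louvain separates disconnected cliques and is seed-deterministic", {
  block <- function(n) matrix(1, n, n) - diag(n)
  adj <- Matrix::bdiag(block(10), block(8))
  dimnames(adj) <- list(paste0("c", 1:18), paste0("c", 1:18))
  graph <- structure(list(adjacency = methods::as(adj, "CsparseMatrix"),
                          k = 5, prune = 0), class = "eec_snn")
  lab <- cluster_graph(graph, seed = 1)
  expect_equal(attr(lab, "K"), 2)
  expect_equal(unname(table(lab$cluster)[["0"]]), 10)  # labels ordered by size
  expect_length(unique(lab$cluster[1:10]), 1)
  lab2 <- cluster_graph(graph, seed = 1)
  expect_identical(lab$cluster, lab2$cluster)
})

test_that("t-SNE validates perplexity, is deterministic, and separates blobs", {
  set.seed(24)
  scores <- rbind(matrix(stats::rnorm(60, 0, 0.3), 30),
                  matrix(stats::rnorm(60, 8, 0.3), 30))
  rownames(scores) <- paste0("c", 1:60)
  emb <- structure(list(scores = scores), class = "eec_embedding")
  expect_error(tsne_embed(structure(list(scores = scores[1:10, ]),
                                    class = "eec_embedding"), perplexity = 5),
               "perplexity")
  y1 <- tsne_embed(emb, perplexity = 8, seed = 3)
  y2 <- tsne_embed(emb, perplexity = 8, seed = 3)
  expect_identical(y1, y2)
  co <- as.matrix(y1[, c("tsne1", "tsne2")])
  d <- as.matrix(dist(co))
  intra <- mean(d[1:30, 1:30])
  inter <- mean(d[1:30, 31:60])
  expect_gt(inter, intra)
})

test_that("cluster labels are invariant to gene and cell permutations", {
  cfg <- two_pop_marker_config(n_cells = 120, n_genes = 150, mult = 10, seed = 25)
  m <- generate_cohort(cfg)$counts$counts
  run <- function(mm) {
    norm <- lognormalize(mm)
    emb <- run_pca(norm, select_hvgs(norm, n_hvg = 100), n_dims = 3)
    cluster_graph(build_snn(emb, k = 10), seed = 0)
  }
  lab1 <- run(m)
  mp <- m[sample(nrow(m)), ]
  lab2 <- run(mp)
  j <- match(lab1$barcode, lab2$barcode)
  expect_equal(ari(lab1$cluster, lab2$cluster[j]), 1)
})
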