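make_scaled <- function(n = 40, g = 15, seed = 2) {
  set.seed(seed)
  v <- matrix(rnorm(n * g), n, g)
  structure(list(values = v, genes = sprintf("G%02d", seq_len(g)),
                 barcodes = sprintf("c%02d", seq_len(n)), clip_max = 10),
            class = "ScaledMatrix")
}

test_that("PCA matches the dense eigendecomposition oracle up to sign", {
  sm <- make_scaled(50, 20)
  pca <- run_pca(sm, n_pcs = 5)
  X <- sweep(sm$values, 2, colMeans(sm$values))
  eo <- eigen(cov(X), symmetric = TRUE)
  emb_o <- X %*% eo$vectors[, 1:5]
  for (j in 1:5) {
    agree <- max(abs(pca$embeddings[, j] - emb_o[, j]))
    flipped <- max(abs(pca$embeddings[, j] + emb_o[, j]))
    expect_lt(min(agree, flipped), 1e-8)
  }
  expect_equal(pca$explained,
               pmax(eo$values, 0) / sum(pmax(eo$values, 0)))
  # deterministic, including the sign convention
  expect_identical(pca$embeddings, run_pca(sm, n_pcs = 5)$embeddings)
  expect_true(all(diff(pca$explained) < 1e-12))
})

test_that("PCA reports exact rank for low-rank data and checks n_pcs", {
  set.seed(3)
  base <- matrix(rnorm(40 * 2), 40, 2) %*% matrix(rnorm(2 * 12), 2, 12)
  sm <- make_scaled(40, 12)
  sm$values <- base
  pca <- run_pca(sm, n_pcs = 5)
  expect_lt(sum(pca$explained[-(1:2)]), 1e-10)
  expect_error(run_pca(sm, n_pcs = 12), "n_pcs")
})

test_that("elbow choice maximizes chord distance, brute-force checked", {
  # for this scree the chord-distance maximum falls on the third point
  # (the last of the steep segment), as direct enumeration shows
  scree <- c(.5, .3, .05, .05, .05, .05)
  expect_equal(choose_elbow(scree), 3L)
  # brute-force perpendicular distance over random screes
  set.seed(9)
  for (i in 1:20) {
    f <- sort(runif(8), decreasing = TRUE)
    n <- length(f)
    a <- c(1, f[1]); b <- c(n, f[n])
    d <- sapply(seq_len(n), function(j) {
      v <- c(j, f[j]) - a; w <- b - a
      abs(w[1] * v[2] - w[2] * v[1]) / sqrt(sum(w^2))
    })
    expect_equal(choose_elbow(f), which.max(d))
  }
  # linear scree: all distances zero, smallest index wins with a warning
  expect_warning(el <- choose_elbow(seq(0.5, 0.1, length.out = 5)),
                 "flat")
  expect_equal(el, 1L)
  expect_error(choose_elbow(c(.6, .4)), "at least 3")
})

test_that("SNN weights equal the brute-force Jaccard oracle", {
  set.seed(5)
  emb <- matrix(rnorm(40 * 3), 40, 3)
  k <- 6
  snn <- build_snn(emb, k = k, prune = 0)
  d <- as.matrix(dist(emb))
  sets <- lapply(1:40, function(i) c(i, order(d[i, -i] + 0)[0])) # placeholder
  sets <- lapply(1:40, function(i) {
    nb <- setdiff(order(d[i, ]), i)[1:k]
    c(i, nb)
  })
  A <- igraph::as_adjacency_matrix(snn$graph, attr = "weight",
                                   sparse = FALSE)
  for (i in 1:39) for (j in (i + 1):40) {
    inter <- length(intersect(sets[[i]], sets[[j]]))
    expect_equal(A[i, j], inter / (2 * (k + 1) - inter))
  }
})

test_that("SNN separates blobs and saturates on duplicated points", {
  set.seed(6)
  blob1 <- matrix(rnorm(30, 0, .2), 15, 2)
  blob2 <- matrix(rnorm(30, 8, .2), 15, 2)
  snn <- build_snn(rbind(blob1, blob2), k = 10, prune = 1 / 15)
  A <- igraph::as_adjacency_matrix(snn$graph, sparse = FALSE,
                                   attr = "weight")
  expect_equal(sum(A[1:15, 16:30]), 0)
  # identical points share identical neighbor sets -> weight 1
  pts <- rbind(matrix(0, 5, 2), matrix(rnorm(40, 4, 1), 20, 2))
  snn2 <- build_snn(pts, k = 4, prune = 0)
  A2 <- igraph::as_adjacency_matrix(snn2$graph, sparse = FALSE,
                                    attr = "weight")
  expect_true(all(A2[1:5, 1:5][upper.tri(diag(5))] == 1))
  expect_error(build_snn(pts, k = 30), "smaller")
})

test_that("modularity clustering resolves components and the resolution limit", {
  # two disconnected cliques
  emb <- rbind(matrix(rnorm(20, 0, .1), 10, 2),
               matrix(rnorm(20, 9, .1), 10, 2))
  snn <- build_snn(emb, k = 5, prune = 0)
  lab <- cluster_modularity(snn, resolution = 1, seed = 1)
  expect_equal(lab$k, 2L)
  expect_equal(length(unique(lab$labels[1:10])), 1L)
  # gamma -> 0 merges everything that is connected
  set.seed(2)
  emb2 <- matrix(rnorm(60 * 2), 60, 2)
  snn2 <- build_snn(emb2, k = 20, prune = 0)
  lab0 <- cluster_modularity(snn2, resolution = 1e-4, seed = 1)
  expect_equal(lab0$k, 1L)
  # seed-deterministic
  expect_identical(cluster_modularity(snn2, 1, seed = 7)$labels,
                   cluster_modularity(snn2, 1, seed = 7)$labels)
})

test_that("resolution sweep yields a normalized cluster tree", {
  sim <- cached_sim("clean6_small", function()
    simulate_atlas(simulation_design(
      n_genes = 600, n_cells = 600, types = discrete_types(4),
      doublet_rate = 0, cycling_fraction = 0,
      qc_fail = c(low_gene = 0, high_mito = 0, high_umi = 0), seed = 2)))
  flow <- cached_sim("clean6_small_flow", function()
    standard_flow(sim, resolution = 1,
                  thresholds = qc_thresholds(min_genes = 50)))
  sw <- resolution_sweep(flow$snn, resolutions = c(0.5, 1, 2), seed = 1)
  # outgoing edge weights sum to 1 for every source node
  agg <- aggregate(weight ~ from_res + from_cluster, sw$tree, sum)
  expect_equal(agg$weight, rep(1, nrow(agg)))
  expect_equal(length(sw$labels), 3L)
  # identical partitions at two resolutions give identity flow
  sw2 <- resolution_sweep(flow$snn, resolutions = c(1, 1 + 1e-9), seed = 1)
  if (identical(sw2$labels[[1]]$labels, sw2$labels[[2]]$labels))
    expect_true(all(sw2$tree$weight == 1))
  expect_error(resolution_sweep(flow$snn, resolutions = 1), "at least 2")
})

test_that("rank-sum markers match wilcox.test and exact enumeration", {
  # tie-free instance, exact path
  set.seed(13)
  n <- 14; n1 <- 6
  nm <- random_norm_matrix(n, 8, seed = 13, lambda = 5)
  v <- matrix(rnorm(n * 8, 5), n, 8)   # continuous, no ties, no zeros
  nm$values <- methods::as(Matrix::Matrix(v, sparse = TRUE),
                           "generalMatrix")
  labels <- rep(c(0, 1), c(n1, n - n1))
  res <- find_markers(nm, labels, min_pct = 0, min_log2fc = -Inf)
  for (g in 1:8) {
    x <- v[labels == 0, g]; y <- v[labels == 1, g]
    wt <- wilcox.test(x, y, exact = TRUE)$p.value
    p_pkg <- res$p[res$cluster == 0 & res$gene == nm$gene_ids[g]]
    expect_equal(p_pkg, wt, tolerance = 1e-12)
    # full enumeration oracle
    pooled <- c(x, y)
    combos <- combn(n, n1)
    U_obs <- sum(rank(pooled)[1:n1]) - n1 * (n1 + 1) / 2
    U_all <- apply(combos, 2, function(idx)
      sum(rank(pooled)[idx]) - n1 * (n1 + 1) / 2)
    mu <- n1 * (n - n1) / 2
    p_enum <- if (U_obs > mu) 2 * mean(U_all >= U_obs) else
      2 * mean(U_all <= U_obs)
    expect_equal(p_pkg, min(1, p_enum), tolerance = 1e-12)
  }
  # tied instance, normal approximation path agrees with wilcox.test
  nm2 <- random_norm_matrix(60, 10, seed = 17, lambda = 1)
  labels2 <- rep(c(0, 1), 30)
  res2 <- find_markers(nm2, labels2, min_pct = 0, min_log2fc = -Inf)
  v2 <- as.matrix(nm2$values)
  for (g in 1:10) {
    wt <- suppressWarnings(
      wilcox.test(v2[labels2 == 0, g], v2[labels2 == 1, g],
                  exact = FALSE, correct = TRUE)$p.value)
    expect_equal(res2$p[res2$cluster == 0 & res2$gene == nm2$gene_ids[g]],
                 wt, tolerance = 1e-10)
  }
})

test_that("marker fields and thresholds behave per contract", {
  # a perfect marker: expressed in every cell of cluster 0 only
  set.seed(23)
  v <- matrix(rexp(30 * 6), 30, 6)
  v[, 1] <- c(rep(3, 12), rep(0, 18))
  nm <- random_norm_matrix(30, 6, seed = 23)
  nm$values <- methods::as(Matrix::Matrix(v, sparse = TRUE),
                           "generalMatrix")
  labels <- rep(c(0, 1), c(12, 18))
  res <- find_markers(nm, labels)
  r1 <- res[res$cluster == 0 & res$gene == nm$gene_ids[1], ]
  expect_equal(r1$pct_in, 1)
  expect_equal(r1$pct_out, 0)
  expect_lt(r1$p_adj, 0.05)
  expect_true(r1$significant)
  expect_true(all(res$p_adj >= res$p))
  expect_true(all(res$pct_in >= 0 & res$pct_in <= 1))
  # log2FC definition
  ev <- expm1(v)
  l2 <- log2(mean(ev[1:12, 1]) + 1) - log2(mean(ev[13:30, 1]) + 1)
  expect_equal(r1$log2fc, l2)
  # a cluster below min size is skipped with a warning
  expect_warning(find_markers(nm, rep(c(0, 1, 2), c(2, 14, 14)),
                              min_cells = 3), "skipped")
})

test_that("label permutation keeps family-wise marker calls near alpha", {
  set.seed(29)
  nm <- random_norm_matrix(80, 40, seed = 29, lambda = 2)
  hits <- replicate(50, {
    lab <- sample(rep(c(0, 1), 40))
    sum(find_markers(nm, lab, min_pct = 0, min_log2fc = -Inf)$significant)
  })
  # Bonferroni keeps most permutation runs at zero significant genes
  expect_gte(mean(hits == 0), 0.9)
})

test_that("merging absorbs duplicate clusters and fixes marked ones", {
  sim <- cached_sim("clean6_small", function()
    simulate_atlas(simulation_design(
      n_genes = 600, n_cells = 600, types = discrete_types(4),
      doublet_rate = 0, cycling_fraction = 0,
      qc_fail = c(low_gene = 0, high_mito = 0, high_umi = 0), seed = 2)))
  flow <- cached_sim("clean6_small_flow", function()
    standard_flow(sim, resolution = 1,
                  thresholds = qc_thresholds(min_genes = 50)))
  truth <- flow$truth
  # a split planted type (duplicate cluster) is merged back
  base <- as.integer(factor(truth$true_type)) - 1L
  split_lab <- base
  g0 <- which(base == 0)
  split_lab[g0[seq_len(floor(length(g0) / 2))]] <- max(base) + 1L
  mg <- merge_unmarked_clusters(split_lab, flow$nm, hvgs = flow$hvgs)
  expect_equal(length(unique(mg$labels)), length(unique(base)))
  expect_equal(adjusted_rand(mg$labels, base), 1)
  # clusters that all carry unique markers are left untouched
  mg2 <- merge_unmarked_clusters(base, flow$nm, hvgs = flow$hvgs)
  expect_equal(adjusted_rand(mg2$labels, base), 1)
  # never increases the cluster count
  expect_lte(length(unique(mg$labels)), length(unique(split_lab)))
})
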