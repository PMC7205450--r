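# PCA with elbow selection, SNN graph, modularity clustering across a
# resolution sweep, cluster tree, marker testing, and marker-based
# cluster merging.

#' Principal component analysis on scaled HVG expression
#'
#' PCA restricted to the highly variable genes, computed by
#' eigendecomposition of the gene-gene covariance. Deterministic up to
#' sign; the sign is fixed so the largest-magnitude loading of each
#' component is positive.
#'
#' @param sm a [scale_regress()] result.
#' @param hvgs gene ids to use (default: all genes in `sm`).
#' @param n_pcs number of components.
#' @return list of class `PCADecomposition`: `embeddings` (cells x
#'   n_pcs), `loadings` (genes x n_pcs), `explained` (variance fractions
#'   over the computed spectrum), `n_pcs`.
#' @export
run_pca <- function(sm, hvgs = NULL, n_pcs = 30) {
  stopifnot(inherits(sm, "ScaledMatrix"))
  if (is.null(hvgs)) hvgs <- sm$genes
  gidx <- match(hvgs, sm$genes)
  if (anyNA(gidx)) stopf("HVG(s) missing from scaled matrix")
  X <- sm$values[, gidx, drop = FALSE]
  if (n_pcs >= min(dim(X))) stopf("n_pcs must be < min(cells, genes)")
  X <- sweep(X, 2, colMeans(X))
  cv <- crossprod(X) / (nrow(X) - 1)
  eig <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  load <- eig$vectors[, seq_len(n_pcs), drop = FALSE]
  flip <- apply(load, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  load <- sweep(load, 2, flip, "*")
  emb <- X %*% load
  dimnames(emb) <- list(sm$barcodes, paste0("PC", seq_len(n_pcs)))
  dimnames(load) <- list(hvgs, colnames(emb))
  structure(list(embeddings = emb, loadings = load,
                 explained = ev / sum(ev), n_pcs = n_pcs),
            class = "PCADecomposition")
}

#' Choose the number of components by the elbow (triangle) method
#'
#' Returns the index maximizing the perpendicular distance from the scree
#' point to the chord joining the first and last points; ties break to
#' the smallest index.
#'
#' @param explained_fractions non-increasing explained-variance fractions.
#' @return integer component index.
#' @export
choose_elbow <- function(explained_fractions) {
  f <- as.numeric(explained_fractions)
  n <- length(f)
  if (n < 3) stopf("need at least 3 components for the elbow method")
  a <- c(1, f[1])
  b <- c(n, f[n])
  chord <- b - a
  len <- sqrt(sum(chord^2))
  d <- vapply(seq_len(n), function(i) {
    v <- c(i, f[i]) - a
    abs(chord[1] * v[2] - chord[2] * v[1]) / len
  }, 0)
  if (max(d) <= 1e-12) {
    warnf("flat scree; elbow undefined, returning 1")
    return(1L)
  }
  which.max(d)
}

#' Build a shared-nearest-neighbor graph
#'
#' k-nearest neighbors per cell (Euclidean in the embedding); the SNN
#' weight of a cell pair is the Jaccard overlap of their neighbor sets
#' (each set includes the cell itself, so duplicated points get weight
#' 1). Edges with weight <= `prune` are dropped.
#'
#' @param pca a `PCADecomposition` (or a plain embedding matrix).
#' @param k neighbors per cell.
#' @param prune Jaccard pruning threshold.
#' @return list of class `SNNGraph`: `graph` (an igraph), `k`, `prune`,
#'   `n_cells`.
#' @export
build_snn <- function(pca, k = 30, prune = 1 / 15) {
  emb <- if (inherits(pca, "PCADecomposition")) pca$embeddings else
    as.matrix(pca)
  n <- nrow(emb)
  if (k >= n) stopf("k (%d) must be smaller than the cell count (%d)", k, n)
  d2 <- as.matrix(stats::dist(emb))^2
  # neighbor sets include self: self-distance 0 is always ranked first
  A <- Matrix::sparseMatrix(
    i = rep(seq_len(n), each = k + 1),
    j = as.integer(apply(d2, 1, function(r)
      order(r)[seq_len(k + 1)])),
    x = 1, dims = c(n, n))
  S <- Matrix::tcrossprod(A)            # |N_i intersect N_j|
  S <- methods::as(S, "CsparseMatrix")
  S@x <- S@x / (2 * (k + 1) - S@x)      # Jaccard
  S@x[S@x <= prune] <- 0
  S <- Matrix::drop0(S)
  Matrix::diag(S) <- 0
  S <- Matrix::drop0(S)
  g <- igraph::graph_from_adjacency_matrix(S, mode = "undirected",
                                           weighted = TRUE)
  structure(list(graph = g, k = k, prune = prune, n_cells = n),
            class = "SNNGraph")
}

#' Modularity clustering of an SNN graph
#'
#' Louvain multilevel modularity optimization at resolution `gamma`
#' (standing in for SLM; both optimize the same resolution-parameterized
#' modularity). Seed-deterministic; disconnected components are handled
#' independently by the algorithm.
#'
#' @param g an `SNNGraph`.
#' @param resolution resolution parameter.
#' @param seed RNG seed.
#' @return list of class `ClusterLabels`: `labels` (integer per cell,
#'   contiguous from 0, ordered by decreasing cluster size),
#'   `resolution`, `modularity`, `k` (number of clusters).
#' @export
cluster_modularity <- function(g, resolution = 1, seed = 1) {
  stopifnot(inherits(g, "SNNGraph"))
  if (igraph::vcount(g$graph) == 0) stopf("empty graph")
  comm <- with_seed(seed,
    igraph::cluster_louvain(g$graph, resolution = resolution))
  memb <- igraph::membership(comm)
  sizes <- sort(table(memb), decreasing = TRUE)
  relab <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  labels <- as.integer(relab[as.character(memb)])
  structure(list(labels = labels, resolution = resolution,
                 modularity = max(comm$modularity),
                 k = length(sizes)),
            class = "ClusterLabels")
}

#' Cluster at a sweep of resolutions and build the cluster tree
#'
#' Labels per resolution plus a cross-resolution overlap tree: for each
#' consecutive resolution pair, a directed edge from every
#' lower-resolution cluster to each higher-resolution cluster weighted by
#' the fraction of the lower cluster's cells that flow there (outgoing
#' weights sum to 1).
#'
#' @param g an `SNNGraph`.
#' @param resolutions numeric vector (default 0.5 to 6 by 0.5).
#' @param seed RNG seed.
#' @return list of class `ClusterSweep`: `labels` (list of
#'   `ClusterLabels`), `tree` (data.frame: from_res, from_cluster,
#'   to_res, to_cluster, weight), `k_per_resolution`, `monotone`
#'   (does K weakly increase with resolution).
#' @export
resolution_sweep <- function(g, resolutions = seq(0.5, 6, by = 0.5),
                             seed = 1) {
  if (length(resolutions) < 2) stopf("need at least 2 resolutions")
  resolutions <- sort(resolutions)
  labs <- lapply(resolutions, function(r)
    cluster_modularity(g, resolution = r, seed = seed))
  edges <- list()
  for (i in seq_len(length(resolutions) - 1)) {
    lo <- labs[[i]]$labels
    hi <- labs[[i + 1]]$labels
    tab <- table(lo, hi)
    pr <- tab / rowSums(tab)
    idx <- which(pr > 0, arr.ind = TRUE)
    edges[[i]] <- data.frame(
      from_res = resolutions[i],
      from_cluster = as.integer(rownames(tab))[idx[, 1]],
      to_res = resolutions[i + 1],
      to_cluster = as.integer(colnames(tab))[idx[, 2]],
      weight = pr[idx], stringsAsFactors = FALSE)
  }
  kk <- vapply(labs, `[[`, 0L, "k")
  structure(list(labels = labs, tree = do.call(rbind, edges),
                 resolutions = resolutions, k_per_resolution = kk,
                 monotone = all(diff(kk) >= 0)),
            class = "ClusterSweep")
}

#' Per-cluster marker genes by rank-sum test
#'
#' For each cluster: genes expressed in at least `min_pct` of its cells
#' are tested (two-sided Wilcoxon rank-sum, cluster vs all other cells);
#' log2FC compares exp-space means (`log2(mean(expm1(in)) + 1) -
#' log2(mean(expm1(out)) + 1)`); Bonferroni correction over the genes
#' tested for that cluster. A gene is a significant marker iff
#' `p_adj < alpha` and `log2FC >= min_log2fc`.
#'
#' @param nm a [lognormalize()] result.
#' @param labels integer cluster labels (or a `ClusterLabels`).
#' @param min_pct minimum in-cluster expressing fraction.
#' @param min_log2fc minimum log2 fold change.
#' @param alpha adjusted-p significance level.
#' @param min_cells clusters below this size are skipped with a warning.
#' @param .ranks precomputed [sparse_col_ranks()] of `nm$values`
#'   (internal; lets repeated calls on the same matrix skip the ranking).
#' @return data.frame of class `MarkerResult`: `gene`, `cluster`,
#'   `log2fc`, `pct_in`, `pct_out`, `p`, `p_adj`, `significant`.
#' @export
find_markers <- function(nm, labels, min_pct = 0.25, min_log2fc = 0.25,
                         alpha = 0.05, min_cells = 3, .ranks = NULL) {
  stopifnot(inherits(nm, "NormalizedMatrix"))
  if (inherits(labels, "ClusterLabels")) labels <- labels$labels
  if (length(labels) != nrow(nm$values))
    stopf("labels not aligned with cells")
  cl <- sort(unique(labels))
  if (length(cl) < 2) stopf("need at least 2 clusters")
  v <- nm$values
  ev <- v; ev@x <- expm1(ev@x)
  rk <- if (is.null(.ranks)) sparse_col_ranks(v) else .ranks
  nz <- v; nz@x <- rep(1, length(nz@x))
  out <- list()
  for (ci in cl) {
    in_idx <- which(labels == ci)
    if (length(in_idx) < min_cells) {
      warnf("cluster %s has fewer than %d cells; skipped", ci, min_cells)
      next
    }
    out_idx <- which(labels != ci)
    pct_in <- Matrix::colSums(nz[in_idx, , drop = FALSE]) / length(in_idx)
    tested <- which(pct_in >= min_pct)
    if (!length(tested)) next
    pct_out <- Matrix::colSums(nz[out_idx, tested, drop = FALSE]) /
      length(out_idx)
    mu_in <- Matrix::colMeans(ev[in_idx, tested, drop = FALSE])
    mu_out <- Matrix::colMeans(ev[out_idx, tested, drop = FALSE])
    l2fc <- log2(mu_in + 1) - log2(mu_out + 1)
    p <- ranksum_pvalues(rk$ranks[, tested, drop = FALSE],
                         rk$ties[tested], in_idx)
    p_adj <- pmin(1, p * length(tested))
    out[[length(out) + 1]] <- data.frame(
      gene = nm$gene_ids[tested], cluster = ci, log2fc = l2fc,
      pct_in = as.numeric(pct_in[tested]), pct_out = as.numeric(pct_out),
      p = p, p_adj = p_adj,
      significant = p_adj < alpha & l2fc >= min_log2fc,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("MarkerResult", "data.frame")
  res
}

#' Merge clusters lacking unique markers
#'
#' A cluster's unique markers are its significant marker genes that are
#' not significant markers of its nearest-neighbor cluster (highest
#' centroid Pearson correlation in HVG log-normalized space). Clusters
#' with no unique marker are merged into that neighbor; markers are
#' recomputed and the procedure iterates to a fixed point (at most
#' `max_iter` rounds). Never increases the cluster count.
#'
#' @param labels integer labels or `ClusterLabels`.
#' @param nm a [lognormalize()] result.
#' @param hvgs gene ids defining the correlation space (default: all).
#' @param max_iter iteration cap.
#' @param ... passed to [find_markers()].
#' @return list: `labels` (integer, relabeled contiguous from 0),
#'   `markers` (final `MarkerResult`), `merges` (data.frame log),
#'   `iterations`.
#' @export
merge_unmarked_clusters <- function(labels, nm, hvgs = NULL,
                                    max_iter = 10, ...) {
  if (inherits(labels, "ClusterLabels")) labels <- labels$labels
  stopifnot(inherits(nm, "NormalizedMatrix"))
  if (is.null(hvgs)) hvgs <- nm$gene_ids
  gidx <- match(hvgs, nm$gene_ids)
  V <- nm$values[, gidx, drop = FALSE]
  rk <- sparse_col_ranks(nm$values)
  merges <- list()
  it <- 0
  markers <- NULL
  repeat {
    it <- it + 1
    cl <- sort(unique(labels))
    if (length(cl) < 2) {
      markers <- NULL
      break
    }
    markers <- find_markers(nm, labels, .ranks = rk, ...)
    cent <- vapply(cl, function(ci)
      Matrix::colMeans(V[labels == ci, , drop = FALSE]),
      numeric(ncol(V)))
    cc <- stats::cor(cent)
    diag(cc) <- -Inf
    nn <- cl[apply(cc, 2, which.max)]
    sig <- split(markers$gene[markers$significant],
                 markers$cluster[markers$significant])
    unmarked <- cl[vapply(seq_along(cl), function(i) {
      own <- sig[[as.character(cl[i])]]
      nb <- sig[[as.character(nn[i])]]
      length(setdiff(own, nb)) == 0
    }, TRUE)]
    if (!length(unmarked) || it > max_iter) {
      if (length(unmarked) && it > max_iter)
        warnf("merge did not reach a fixed point in %d iterations",
              max_iter)
      break
    }
    for (ci in unmarked) {
      tgt <- nn[match(ci, cl)]
      if (tgt == ci || !(tgt %in% unique(labels)) ||
          !(ci %in% unique(labels))) next
      merges[[length(merges) + 1]] <-
        data.frame(iteration = it, from = ci, into = tgt)
      labels[labels == ci] <- tgt
    }
    if (!length(merges) || merges[[length(merges)]]$iteration < it) break
  }
  # contiguous relabel by decreasing size
  sizes <- sort(table(labels), decreasing = TRUE)
  relab <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  labels <- as.integer(relab[as.character(labels)])
  if (length(unique(labels)) > 1)
    markers <- find_markers(nm, labels, .ranks = rk, ...)
  list(labels = labels, markers = markers,
       merges = if (length(merges)) do.call(rbind, merges) else NULL,
       iterations = it)
}
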