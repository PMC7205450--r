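# Density-peak reclustering, principal-tree pseudotime with branches,
# NB spline tests for pseudotime- and branch-dependent expression,
# pseudotime gene modules, and marker-anchored stage boundaries.

#' Density-peak clustering
#'
#' Rodriguez-Laio style: local density `rho_i = sum_j exp(-(d_ij/d_c)^2)`
#' with `d_c` the `dc_quantile` quantile of pairwise distances; `delta_i`
#' the distance to the nearest higher-density cell (the global density
#' maximum gets the largest distance). Centers are the top `n_centers`
#' cells by `rho * delta` (or, in auto mode, cells exceeding both the
#' `rho` and `delta` thresholds); remaining cells inherit, in decreasing
#' density order, the label of their nearest higher-density neighbor.
#'
#' @param embedding cells x d matrix.
#' @param n_centers number of clusters, or `"auto"`.
#' @param dc_quantile distance quantile defining `d_c`.
#' @param rho_threshold,delta_threshold thresholds for auto mode.
#' @return list of class `ClusterLabels` with extra fields `rho`,
#'   `delta`, `centers`, `d_c`.
#' @export
densitypeak_cluster <- function(embedding, n_centers = "auto",
                                dc_quantile = 0.02,
                                rho_threshold = NULL,
                                delta_threshold = NULL) {
  emb <- as.matrix(embedding)
  n <- nrow(emb)
  if (is.numeric(n_centers) && n < n_centers)
    stopf("fewer cells than requested centers")
  d <- as.matrix(stats::dist(emb))
  off <- d[upper.tri(d)]
  if (any(off == 0)) {
    warnf("duplicate points; adding jitter to break zero distances")
    emb <- emb + matrix(stats::rnorm(length(emb), 0,
                                     1e-9 + 1e-6 * stats::sd(emb)),
                        nrow = n)
    d <- as.matrix(stats::dist(emb))
    off <- d[upper.tri(d)]
  }
  d_c <- stats::quantile(off, dc_quantile)
  if (d_c == 0) d_c <- min(off[off > 0])
  rho <- rowSums(exp(-(d / d_c)^2)) - 1   # exclude self term
  ord <- order(-rho)
  delta <- numeric(n)
  delta[ord[1]] <- max(d[ord[1], ])
  for (r in 2:n) {
    i <- ord[r]
    delta[i] <- min(d[i, ord[seq_len(r - 1)]])
  }
  if (identical(n_centers, "auto")) {
    if (is.null(rho_threshold)) rho_threshold <- stats::median(rho)
    if (is.null(delta_threshold))
      delta_threshold <- stats::quantile(delta, 0.9)
    centers <- which(rho > rho_threshold & delta > delta_threshold)
    if (!length(centers)) centers <- which.max(rho * delta)
  } else {
    centers <- order(-(rho * delta))[seq_len(n_centers)]
  }
  labels <- rep(NA_integer_, n)
  labels[centers] <- seq_along(centers) - 1L
  for (r in seq_len(n)) {
    i <- ord[r]
    if (!is.na(labels[i])) next
    higher <- ord[seq_len(r - 1)]
    labels[i] <- labels[higher[which.min(d[i, higher])]]
  }
  structure(list(labels = labels, resolution = NA_real_,
                 modularity = NA_real_, k = length(centers),
                 rho = rho, delta = delta, centers = centers, d_c = d_c),
            class = "ClusterLabels")
}

#' Principal-tree pseudotime with branch assignment
#'
#' Builds the Euclidean minimum spanning tree over state centroids,
#' orthogonally projects every cell onto its nearest tree edge, and
#' measures pseudotime as geodesic distance from the root along the
#' tree. Branch labels are the maximal unbranched tree segments (paths
#' broken at the root and at nodes of degree >= 3), so a single
#' Y-shaped lineage yields a pre-branch segment and two branch segments.
#'
#' @param embedding cells x d matrix (d >= 2).
#' @param labels state labels (integer per cell, or `ClusterLabels`).
#' @param root_spec either a state label (integer) or a numeric per-cell
#'   score (e.g. a root-marker module score); the root is the state with
#'   the highest mean score. Tied scores raise an error asking for an
#'   explicit root.
#' @return list of class `TrajectoryResult`: `pseudotime`, `branch`
#'   (character per cell), `tree` (igraph over states), `centroids`,
#'   `root_state`, `branch_points`, `labels`, `embedding`.
#' @export
build_principal_tree <- function(embedding, labels, root_spec) {
  emb <- as.matrix(embedding)
  if (ncol(emb) < 2) stopf("embedding must have at least 2 dimensions")
  if (inherits(labels, "ClusterLabels")) labels <- labels$labels
  states <- sort(unique(labels))
  if (length(states) < 2) stopf("need at least 2 states")
  cent <- t(vapply(states, function(s)
    colMeans(emb[labels == s, , drop = FALSE]), numeric(ncol(emb))))
  rownames(cent) <- as.character(states)

  # root
  if (length(root_spec) == 1 && root_spec %in% states) {
    root <- match(root_spec, states)
  } else if (length(root_spec) == nrow(emb)) {
    sc <- vapply(states, function(s) mean(root_spec[labels == s]), 0)
    top <- which(abs(sc - max(sc)) < 1e-12)
    if (length(top) > 1)
      stopf("root-marker scores tied between states %s; give an explicit root",
            paste(states[top], collapse = ", "))
    root <- top
  } else stopf("root_spec must be a state label or a per-cell score")

  dmat <- as.matrix(stats::dist(cent))
  gfull <- igraph::graph_from_adjacency_matrix(dmat, mode = "undirected",
                                               weighted = TRUE)
  tree <- igraph::mst(gfull)
  node_dist <- igraph::distances(tree, v = root)[1, ]

  # segment id per tree edge: cut paths at root and at branch points
  deg <- igraph::degree(tree)
  el <- igraph::as_edgelist(tree, names = FALSE)
  # parent = endpoint nearer the root
  parent <- ifelse(node_dist[el[, 1]] <= node_dist[el[, 2]],
                   el[, 1], el[, 2])
  child <- ifelse(parent == el[, 1], el[, 2], el[, 1])
  seg_of_edge <- integer(nrow(el))
  seg_id <- 0L
  assign_seg <- function(edge_idx, seg) seg_of_edge[edge_idx] <<- seg
  # walk down from root; start a new segment after root or a branch node
  children_of <- function(v) which(parent == v)
  queue <- lapply(children_of(root), function(e) list(edge = e, seg = NA))
  while (length(queue)) {
    item <- queue[[1]]; queue <- queue[-1]
    seg <- item$seg
    if (is.na(seg)) { seg_id <- seg_id + 1L; seg <- seg_id }
    assign_seg(item$edge, seg)
    v <- child[item$edge]
    nxt <- children_of(v)
    newseg <- deg[v] >= 3      # branch point: children start new segments
    for (e in nxt)
      queue[[length(queue) + 1]] <- list(edge = e,
                                         seg = if (newseg) NA else seg)
  }
  branch_points <- states[deg >= 3]

  # project cells onto nearest tree edge
  n <- nrow(emb)
  pt <- numeric(n)
  seg_lab <- character(n)
  a_idx <- parent; b_idx <- child
  for (i in seq_len(n)) {
    best <- Inf; best_pt <- 0; best_seg <- NA_integer_
    for (e in seq_len(nrow(el))) {
      a <- cent[a_idx[e], ]; b <- cent[b_idx[e], ]
      ab <- b - a
      L2 <- sum(ab^2)
      s <- if (L2 == 0) 0 else
        min(1, max(0, sum((emb[i, ] - a) * ab) / L2))
      p <- a + s * ab
      dd <- sum((emb[i, ] - p)^2)
      if (dd < best) {
        best <- dd
        best_pt <- node_dist[a_idx[e]] + s * sqrt(L2)
        best_seg <- seg_of_edge[e]
      }
    }
    pt[i] <- best_pt
    seg_lab[i] <- paste0("seg", best_seg)
  }
  structure(list(pseudotime = pt, branch = seg_lab, tree = tree,
                 centroids = cent, root_state = states[root],
                 branch_points = branch_points,
                 labels = labels, embedding = emb,
                 states = states),
            class = "TrajectoryResult")
}

#' @export
print.TrajectoryResult <- function(x, ...) {
  cat(sprintf(
    "TrajectoryResult: %d cells, %d states, root %s, %d branch point(s), %d segment(s)\n",
    length(x$pseudotime), length(x$states), x$root_state,
    length(x$branch_points), length(unique(x$branch))))
  invisible(x)
}

# Per-gene NB dispersion by method of moments around library-scaled
# means, floored.
nb_dispersion_mom <- function(y, lib, floor = 1e-3) {
  mu <- lib * sum(y) / sum(lib)
  a <- sum((y - mu)^2 - mu) / sum(mu^2)
  max(a, floor)
}

# Column-wise MoM dispersions with a pooled floor: per-gene moment
# estimates are unstable for low-count genes (they can collapse to
# near-Poisson and make the LRT anticonservative), so every gene's
# dispersion is floored at the across-gene median.
nb_dispersions_pooled <- function(cm, lib, keep, floor = 1e-3) {
  a <- vapply(keep, function(j)
    nb_dispersion_mom(as.numeric(cm[, j]), lib, floor), 0)
  pmax(a, stats::median(a))
}

nb_lrt <- function(y, lib, X_full, X_null, a) {
  fam <- MASS::negative.binomial(theta = 1 / a)
  off <- log(lib)
  f_full <- suppressWarnings(tryCatch(
    stats::glm.fit(X_full, y, family = fam, offset = off),
    error = function(e) NULL))
  f_null <- suppressWarnings(tryCatch(
    stats::glm.fit(X_null, y, family = fam, offset = off),
    error = function(e) NULL))
  if (is.null(f_full) || is.null(f_null) || !f_full$converged ||
      !f_null$converged)
    return(c(NA_real_, NA_real_))
  stat <- f_null$deviance - f_full$deviance
  df <- ncol(X_full) - ncol(X_null)
  c(stat, stats::pchisq(pmax(stat, 0), df, lower.tail = FALSE))
}

#' Pseudotime-dependent differential expression (NB spline LRT)
#'
#' Per gene, a negative binomial GLM (log link, log-library offset) with
#' a natural cubic spline of pseudotime is compared by likelihood-ratio
#' test against an intercept-only null; per-gene dispersion is estimated
#' by method of moments with a floor of 1e-3. Genes expressed in fewer
#' than `min_cells` cells are not tested.
#'
#' @param counts raw UMI counts for the subset (cells x genes;
#'   `CountMatrix` or sparse matrix).
#' @param pseudotime numeric per cell.
#' @param min_cells minimum expressing-cell count.
#' @param spline_df spline degrees of freedom.
#' @return data.frame of class `PseudotimeDEResult`: `gene`, `n_expressing`,
#'   `stat`, `p`, `q` (BH), `converged`.
#' @export
pseudotime_de_test <- function(counts, pseudotime, min_cells = 5,
                               spline_df = 3) {
  cm <- if (inherits(counts, "CountMatrix")) counts$counts else counts
  if (!all(is.finite(pseudotime))) stopf("non-finite pseudotime")
  if (length(pseudotime) != nrow(cm)) stopf("pseudotime not aligned")
  lib <- Matrix::rowSums(cm)
  nexpr <- Matrix::colSums(cm > 0)
  keep <- which(nexpr >= min_cells)
  S <- splines::ns(pseudotime, df = spline_df)
  X_full <- cbind(1, S)
  X_null <- matrix(1, nrow(cm), 1)
  alpha <- nb_dispersions_pooled(cm, lib, keep)
  res <- t(vapply(seq_along(keep), function(i)
    nb_lrt(as.numeric(cm[, keep[i]]), lib, X_full, X_null, alpha[i]),
    numeric(2)))
  out <- data.frame(gene = colnames(cm)[keep],
                    n_expressing = as.integer(nexpr[keep]),
                    stat = res[, 1], p = res[, 2],
                    q = stats::p.adjust(res[, 2], "BH"),
                    converged = !is.na(res[, 2]),
                    stringsAsFactors = FALSE)
  class(out) <- c("PseudotimeDEResult", "data.frame")
  out
}

#' Branch-dependent expression test
#'
#' For two branches sharing a branch point, compares a full NB model
#' `spline(t) x branch` against a shared-spline null by LRT (BH-adjusted
#' q-values). Cells are restricted to the two branch segments.
#'
#' @param counts raw counts (cells x genes) for the trajectory subset.
#' @param trajectory a `TrajectoryResult` (or list with `pseudotime`,
#'   `branch`).
#' @param branch_pair two branch labels to contrast.
#' @param min_cells minimum expressing cells (within the restricted set);
#'   also the minimum cell count per branch.
#' @param spline_df spline degrees of freedom.
#' @return data.frame of class `BranchTestResult`: `gene`,
#'   `n_expressing`, `stat`, `p`, `q`, `converged`.
#' @export
branch_test <- function(counts, trajectory, branch_pair, min_cells = 5,
                        spline_df = 3) {
  cm <- if (inherits(counts, "CountMatrix")) counts$counts else counts
  br <- trajectory$branch
  pt <- trajectory$pseudotime
  stopifnot(length(branch_pair) == 2)
  sel <- br %in% branch_pair
  if (sum(br == branch_pair[1]) < min_cells ||
      sum(br == branch_pair[2]) < min_cells)
    stopf("a branch has fewer than %d cells", min_cells)
  cm <- cm[sel, , drop = FALSE]
  pt <- pt[sel]
  bfac <- factor(br[sel], levels = sort(branch_pair))
  lib <- Matrix::rowSums(cm)
  nexpr <- Matrix::colSums(cm > 0)
  keep <- which(nexpr >= min_cells)
  S <- splines::ns(pt, df = spline_df)
  X_null <- cbind(1, S)
  b <- as.numeric(bfac) - 1
  X_full <- cbind(X_null, b, S * b)
  alpha <- nb_dispersions_pooled(cm, lib, keep)
  res <- t(vapply(seq_along(keep), function(i)
    nb_lrt(as.numeric(cm[, keep[i]]), lib, X_full, X_null, alpha[i]),
    numeric(2)))
  out <- data.frame(gene = colnames(cm)[keep],
                    n_expressing = as.integer(nexpr[keep]),
                    stat = res[, 1], p = res[, 2],
                    q = stats::p.adjust(res[, 2], "BH"),
                    converged = !is.na(res[, 2]),
                    stringsAsFactors = FALSE)
  class(out) <- c("BranchTestResult", "data.frame")
  out
}

#' Smooth per-gene expression over a pseudotime grid
#'
#' Gaussian-kernel regression of log-normalized expression on
#' pseudotime, evaluated on an even grid; bandwidth defaults to 5% of
#' the pseudotime range.
#'
#' @param nm a [lognormalize()] result (cells of the trajectory subset).
#' @param pseudotime numeric per cell.
#' @param genes gene ids to smooth.
#' @param n_grid grid resolution.
#' @param bandwidth kernel bandwidth (default `0.05 * range`).
#' @return matrix genes x n_grid with attribute `"grid"`.
#' @export
smooth_pseudotime_expr <- function(nm, pseudotime, genes, n_grid = 100,
                                   bandwidth = NULL) {
  gidx <- match(genes, nm$gene_ids)
  if (anyNA(gidx)) stopf("unknown gene id(s)")
  rng <- range(pseudotime)
  if (is.null(bandwidth)) bandwidth <- 0.05 * diff(rng)
  grid <- seq(rng[1], rng[2], length.out = n_grid)
  W <- exp(-outer(grid, pseudotime, "-")^2 / (2 * bandwidth^2))
  W <- W / rowSums(W)
  sm <- W %*% as.matrix(nm$values[, gidx, drop = FALSE])
  out <- t(sm)
  rownames(out) <- genes
  attr(out, "grid") <- grid
  out
}

#' Gene modules by cutting a pseudotime-profile dendrogram
#'
#' Ward-linkage hierarchical clustering on 1 - Pearson correlation of
#' z-scored smoothed curves, cut into `k` modules (or at `height`).
#' Deterministic and invariant to gene order.
#'
#' @param smoothed_expr genes x grid matrix (e.g. from
#'   [smooth_pseudotime_expr()]).
#' @param k number of modules (or NULL to cut at `height`).
#' @param height dendrogram cut height (used when `k` is NULL).
#' @return named integer vector gene -> module.
#' @export
gene_modules_cutree <- function(smoothed_expr, k = NULL, height = NULL) {
  M <- as.matrix(smoothed_expr)
  if (nrow(M) < 2) stopf("need at least 2 genes")
  if (!is.null(k) && k > nrow(M)) stopf("k exceeds the gene count")
  ord <- order(rownames(M))
  M <- M[ord, , drop = FALSE]          # order-invariant linkage input
  z <- t(scale(t(M)))
  z[is.na(z)] <- 0
  d <- stats::as.dist(1 - stats::cor(t(z)))
  hc <- stats::hclust(d, method = "ward.D2")
  mod <- if (!is.null(k)) stats::cutree(hc, k = k) else
    stats::cutree(hc, h = height)
  out <- mod[rownames(smoothed_expr)]
  names(out) <- rownames(smoothed_expr)
  out
}

#' Marker-anchored stage boundaries along pseudotime
#'
#' Each stage's marker-set module score (mean log-normalized expression)
#' is kernel-smoothed over pseudotime (bandwidth 5% of the range); the
#' boundary between consecutive stages is the pseudotime where the later
#' stage's smoothed score first exceeds the earlier one's. When the
#' curves never cross, the boundary falls at the maximum of the
#' later/earlier score ratio, with a warning. Intervals are contiguous,
#' non-overlapping and ordered.
#'
#' @param nm a [lognormalize()] result over the trajectory cells.
#' @param pseudotime numeric per cell.
#' @param stage_marker_sets named, ordered list of gene-id vectors.
#' @return data.frame: `stage`, `start`, `end`.
#' @export
stage_boundaries <- function(nm, pseudotime, stage_marker_sets) {
  ns <- length(stage_marker_sets)
  if (ns < 1) stopf("need at least one stage set")
  rng <- range(pseudotime)
  n_grid <- 200
  grid <- seq(rng[1], rng[2], length.out = n_grid)
  bw <- 0.05 * diff(rng)
  W <- exp(-outer(grid, pseudotime, "-")^2 / (2 * bw^2))
  W <- W / rowSums(W)
  curves <- vapply(stage_marker_sets, function(gs) {
    idx <- match(gs, nm$gene_ids)
    if (anyNA(idx)) stopf("stage set contains unknown gene id(s)")
    as.numeric(W %*% Matrix::rowMeans(nm$values[, idx, drop = FALSE]))
  }, numeric(n_grid))
  bounds <- numeric(0)
  if (ns > 1) {
    for (i in seq_len(ns - 1)) {
      later <- curves[, i + 1] > curves[, i]
      lower <- if (length(bounds)) max(bounds) else rng[1]
      cand <- which(later & grid > lower)
      if (length(cand)) {
        bounds <- c(bounds, grid[min(cand)])
      } else {
        warnf("stage curves %d/%d never cross; using score-ratio maximum",
              i, i + 1)
        ratio <- curves[, i + 1] - curves[, i]
        ok <- grid > lower
        bounds <- c(bounds, grid[ok][which.max(ratio[ok])])
      }
    }
  }
  starts <- c(rng[1], bounds)
  ends <- c(bounds, rng[2])
  data.frame(stage = names(stage_marker_sets), start = starts,
             end = ends, stringsAsFactors = FALSE)
}
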