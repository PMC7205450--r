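# Canonical correlation alignment of two datasets on shared
# high-dispersion genes, biweight-midcorrelation saturation diagnostics,
# and batch-mixing assessment.

#' Shared high-dispersion genes of two datasets
#'
#' Union of each dataset's top-`n_per_set` genes by standardized
#' dispersion, intersected with the genes detected (nonzero) in both.
#'
#' @param nm1,nm2 [lognormalize()] results.
#' @param n_per_set genes taken from each dataset's dispersion ranking.
#' @return character vector of gene ids.
#' @export
shared_dispersion_genes <- function(nm1, nm2, n_per_set = 1000) {
  common <- intersect(nm1$gene_ids, nm2$gene_ids)
  if (!length(common)) stopf("no common gene universe")
  det1 <- common[Matrix::colSums(nm1$values[, match(common, nm1$gene_ids),
                                            drop = FALSE] > 0) > 0]
  det2 <- common[Matrix::colSums(nm2$values[, match(common, nm2$gene_ids),
                                            drop = FALSE] > 0) > 0]
  det <- intersect(det1, det2)
  top_n <- function(nm) {
    st <- gene_dispersion(nm)
    st <- st[order(-st$dispersion_std), ]
    utils::head(st$gene_id[!is.na(st$dispersion_std)], n_per_set)
  }
  out <- intersect(union(top_n(nm1), top_n(nm2)), det)
  if (!length(out)) stopf("no shared dispersion genes")
  out
}

#' Canonical correlation analysis of two datasets
#'
#' Diagonal-penalized CCA on per-gene standardized expression: the
#' canonical vectors are the singular vectors of the cells1 x cells2
#' cross-product `X1 t(X2)` (computed through thin QR, so the cost is
#' governed by the gene count), and each canonical correlation is the
#' cosine between the two gene-space metagene images, which lies in
#' [0, 1] and equals 1 when a dataset is aligned with itself. Components
#' are ordered by decreasing canonical correlation; signs are fixed so
#' each metagene's largest-magnitude gene loading is positive.
#'
#' @param nm1,nm2 [lognormalize()] results.
#' @param genes shared gene set (ids present in both).
#' @param n_cv number of canonical vectors.
#' @return list of class `CCAResult`: `proj1`, `proj2` (per-dataset cell
#'   projections, unit-norm columns), `loadings1`, `loadings2`
#'   (genes x n_cv metagene loadings, unit norm), `correlations`,
#'   `singular_values` (raw cross-product singular values, same
#'   component order), `genes`.
#' @export
run_cca <- function(nm1, nm2, genes, n_cv = 20) {
  idx1 <- match(genes, nm1$gene_ids)
  idx2 <- match(genes, nm2$gene_ids)
  if (anyNA(idx1) || anyNA(idx2)) stopf("gene(s) missing from a dataset")
  std <- function(nm, idx) {
    X <- as.matrix(nm$values[, idx, drop = FALSE])
    X <- sweep(X, 2, colMeans(X))
    s <- apply(X, 2, stats::sd)
    s[s == 0] <- 1
    sweep(X, 2, s, "/")
  }
  X1 <- std(nm1, idx1)
  X2 <- std(nm2, idx2)
  if (n_cv > min(nrow(X1), nrow(X2), length(genes)))
    stopf("n_cv larger than min(cells1, cells2, genes)")
  q1 <- qr(X1); q2 <- qr(X2)
  R1 <- qr.R(q1); R2 <- qr.R(q2)
  sv <- svd(tcrossprod(R1, R2), nu = n_cv, nv = n_cv)
  U <- qr.Q(q1) %*% sv$u
  V <- qr.Q(q2) %*% sv$v
  W1 <- crossprod(X1, U)               # gene-space metagene images
  W2 <- crossprod(X2, V)
  n1 <- sqrt(colSums(W1^2)); n2 <- sqrt(colSums(W2^2))
  rho <- pmin(1, pmax(0, sv$d[seq_len(n_cv)] / (n1 * n2)))
  d_cv <- sv$d[seq_len(n_cv)]
  ord <- order(-rho)
  U <- U[, ord, drop = FALSE]; V <- V[, ord, drop = FALSE]
  W1 <- W1[, ord, drop = FALSE]; W2 <- W2[, ord, drop = FALSE]
  rho <- rho[ord]
  d_cv <- d_cv[ord]
  flip <- vapply(seq_len(n_cv), function(j)
    sign(W1[which.max(abs(W1[, j])), j]), 0)
  flip[flip == 0] <- 1
  U <- sweep(U, 2, flip, "*"); W1 <- sweep(W1, 2, flip, "*")
  V <- sweep(V, 2, flip, "*"); W2 <- sweep(W2, 2, flip, "*")
  nrm <- function(M) sweep(M, 2, sqrt(colSums(M^2)), "/")
  cvn <- paste0("CV", seq_len(n_cv))
  dimnames(U) <- list(nm1$barcodes, cvn)
  dimnames(V) <- list(nm2$barcodes, cvn)
  structure(list(proj1 = U, proj2 = V,
                 loadings1 = `dimnames<-`(nrm(W1), list(genes, cvn)),
                 loadings2 = `dimnames<-`(nrm(W2), list(genes, cvn)),
                 correlations = rho, singular_values = d_cv,
                 genes = genes, X1 = X1, X2 = X2),
            class = "CCAResult")
}

#' Biweight midcorrelation
#'
#' Robust correlation with Tukey biweights anchored at the median:
#' `u_i = (x_i - med(x)) / (9 mad(x))` (raw MAD), weight
#' `w_i = (1 - u_i^2)^2` for `|u_i| < 1` else 0; the weighted, centered
#' vectors are unit-normalized and their inner product returned. Falls
#' back to Pearson (with a warning) when either MAD is zero.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in [-1, 1].
#' @export
bicor <- function(x, y) {
  if (length(x) != length(y)) stopf("length mismatch")
  if (length(x) < 3) stopf("need at least 3 observations")
  wvec <- function(v) {
    med <- stats::median(v)
    madv <- stats::mad(v, constant = 1)
    if (madv == 0) return(NULL)
    u <- (v - med) / (9 * madv)
    w <- (1 - u^2)^2 * (abs(u) < 1)
    a <- (v - med) * w
    a / sqrt(sum(a^2))
  }
  ax <- wvec(x); ay <- wvec(y)
  if (is.null(ax) || is.null(ay)) {
    warnf("zero MAD; falling back to Pearson correlation")
    return(stats::cor(x, y))
  }
  min(1, max(-1, sum(ax * ay)))
}

#' Bicor saturation curves over canonical vectors
#'
#' For each canonical vector and dataset, the biweight midcorrelation
#' between the cells' CV projection and their metagene expression (the
#' gene-loading-weighted standardized expression). The curves are used to
#' choose how many CVs to keep: the first CV where both curves fall below
#' `floor` caps the count.
#'
#' @param cca a `CCAResult`.
#' @param floor saturation floor.
#' @return list: `curves` (n_cv x 2 matrix), `n_cv_suggested`.
#' @export
bicor_saturation <- function(cca, floor = 0.15) {
  stopifnot(inherits(cca, "CCAResult"))
  n_cv <- ncol(cca$proj1)
  if (n_cv < 2) stopf("need at least 2 canonical vectors")
  curves <- matrix(NA_real_, n_cv, 2,
                   dimnames = list(colnames(cca$proj1),
                                   c("dataset1", "dataset2")))
  for (j in seq_len(n_cv)) {
    m1 <- as.numeric(cca$X1 %*% cca$loadings1[, j])
    m2 <- as.numeric(cca$X2 %*% cca$loadings2[, j])
    curves[j, 1] <- bicor(cca$proj1[, j], m1)
    curves[j, 2] <- bicor(cca$proj2[, j], m2)
  }
  below <- which(curves[, 1] < floor & curves[, 2] < floor)
  list(curves = curves,
       n_cv_suggested = if (length(below)) min(below) - 1L else n_cv)
}

#' Batch-mixing score in aligned space
#'
#' Mean per-cell normalized Shannon entropy of batch composition among
#' the k nearest neighbors in the row-L2-normalized joint CV projection.
#' 1 = perfectly mixed, 0 = batches fully separated.
#'
#' @param cca a `CCAResult` (or a list with `proj1`, `proj2`).
#' @param batch_labels vector over rows of `rbind(proj1, proj2)`;
#'   defaults to dataset membership.
#' @param k neighbors.
#' @return numeric in [0, 1].
#' @export
mixing_score <- function(cca, batch_labels = NULL, k = 20) {
  emb <- rbind(cca$proj1, cca$proj2)
  nrm <- sqrt(rowSums(emb^2)); nrm[nrm == 0] <- 1
  emb <- emb / nrm
  n <- nrow(emb)
  if (k >= n) stopf("k must be smaller than the total cell count")
  if (is.null(batch_labels))
    batch_labels <- rep(c("d1", "d2"), c(nrow(cca$proj1), nrow(cca$proj2)))
  if (length(unique(batch_labels)) < 2)
    stopf("both batches must be present")
  d2 <- as.matrix(stats::dist(emb))^2
  diag(d2) <- Inf
  lev <- sort(unique(batch_labels))
  ent <- vapply(seq_len(n), function(i) {
    nb <- order(d2[i, ])[seq_len(k)]
    norm_entropy(batch_labels[nb], lev)
  }, 0)
  mean(ent)
}
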