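# QC metrics and filtration, log-normalization, HVG selection, module
# scoring / cell-cycle phase assignment, and covariate-regressed scaling.

#' Quality-control thresholds
#'
#' Defaults are the filtration window used for the ovary atlas: cells with
#' fewer than 775 expressed genes (fragments), more than 2,200 genes or
#' 18,000 UMIs (suspected multiplets), or more than 1% mitochondrial
#' expression (dying cells) are removed.
#'
#' @param min_genes,max_genes bounds on expressed genes per cell.
#' @param max_umi upper bound on total UMIs per cell.
#' @param max_pct_mito upper bound on mitochondrial percentage (0-100).
#' @param upper_joint if TRUE, the two upper bounds are applied jointly (a
#'   cell is removed only when it exceeds `max_genes` AND `max_umi`);
#'   default treats them as independent bounds.
#' @return list of class `QCThresholds`.
#' @export
qc_thresholds <- function(min_genes = 775, max_genes = 2200,
                          max_umi = 18000, max_pct_mito = 1.0,
                          upper_joint = FALSE) {
  stopifnot(min_genes < max_genes, min_genes > 0, max_umi > 0,
            max_pct_mito > 0)
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 max_umi = max_umi, max_pct_mito = max_pct_mito,
                 upper_joint = upper_joint),
            class = "QCThresholds")
}

#' Per-cell QC metrics
#'
#' @param cm a [count_matrix()].
#' @return data.frame with `barcode`, `n_genes` (genes with count > 0),
#'   `n_umi` (total counts) and `pct_mito` (0-100; 0 for empty cells).
#' @export
compute_qc_metrics <- function(cm) {
  stopifnot(inherits(cm, "CountMatrix"))
  n_umi <- Matrix::rowSums(cm$counts)
  n_genes <- Matrix::rowSums(cm$counts > 0)
  mito <- if (any(cm$mito_flags))
    Matrix::rowSums(cm$counts[, cm$mito_flags, drop = FALSE]) else 0
  pct_mito <- ifelse(n_umi > 0, 100 * mito / n_umi, 0)
  data.frame(barcode = cm$barcodes, n_genes = as.integer(n_genes),
             n_umi = as.numeric(n_umi), pct_mito = as.numeric(pct_mito),
             stringsAsFactors = FALSE)
}

#' Threshold filtration of cells
#'
#' Keeps a cell iff `min_genes <= n_genes <= max_genes`,
#' `n_umi <= max_umi`, and `pct_mito <= max_pct_mito` (upper bounds
#' jointly if `thr$upper_joint`). Idempotent.
#'
#' @param cm a [count_matrix()].
#' @param metrics from [compute_qc_metrics()]; recomputed if NULL.
#' @param thr a [qc_thresholds()].
#' @return list with `kept` (filtered `CountMatrix`), `keep` (logical per
#'   input cell) and `report` (cells removed per reason; reasons may
#'   overlap, `total_removed` counts distinct cells).
#' @export
filter_cells <- function(cm, metrics = NULL, thr = qc_thresholds()) {
  stopifnot(inherits(cm, "CountMatrix"), inherits(thr, "QCThresholds"))
  if (is.null(metrics)) metrics <- compute_qc_metrics(cm)
  if (nrow(metrics) != nrow(cm$counts) ||
      !identical(metrics$barcode, cm$barcodes))
    stopf("metrics are not aligned with the count matrix")
  low_gene <- metrics$n_genes < thr$min_genes
  high_gene <- metrics$n_genes > thr$max_genes
  high_umi <- metrics$n_umi > thr$max_umi
  high_mito <- metrics$pct_mito > thr$max_pct_mito
  upper <- if (thr$upper_joint) high_gene & high_umi else
    high_gene | high_umi
  remove <- low_gene | upper | high_mito
  report <- c(low_gene = sum(low_gene), high_gene = sum(high_gene),
              high_umi = sum(high_umi), high_mito = sum(high_mito),
              total_removed = sum(remove))
  if (!any(!remove))
    stopf("no cells survive filtration (removed: %s)",
          paste(names(report), report, sep = "=", collapse = ", "))
  list(kept = subset_cells(cm, cells = !remove), keep = !remove,
       report = report)
}

#' Log-normalize counts
#'
#' `x = ln(1 + scale_factor * count / n_umi)` per cell; zeros stay zero,
#' so for every cell `sum(expm1(x)) == scale_factor`.
#'
#' @param cm a [count_matrix()].
#' @param scale_factor library-size target (default 10,000).
#' @return list of class `NormalizedMatrix`: `values` (sparse cells x
#'   genes), `scale_factor`, plus the barcode/gene annotations of `cm`.
#' @export
lognormalize <- function(cm, scale_factor = 1e4) {
  stopifnot(inherits(cm, "CountMatrix"))
  n_umi <- Matrix::rowSums(cm$counts)
  if (any(n_umi == 0)) stopf("all-zero cell(s); filter before normalizing")
  v <- Matrix::Diagonal(x = scale_factor / n_umi) %*% cm$counts
  v <- methods::as(v, "CsparseMatrix")
  v@x <- log1p(v@x)
  dimnames(v) <- list(cm$barcodes, cm$gene_ids)
  structure(list(values = methods::as(v, "generalMatrix"),
                 scale_factor = scale_factor,
                 barcodes = cm$barcodes, gene_ids = cm$gene_ids,
                 gene_symbols = cm$gene_symbols,
                 mito_flags = cm$mito_flags),
            class = "NormalizedMatrix")
}

#' @export
print.NormalizedMatrix <- function(x, ...) {
  cat(sprintf("NormalizedMatrix: %d cells x %d genes (scale factor %g)\n",
              nrow(x$values), ncol(x$values), x$scale_factor))
  invisible(x)
}

#' Highly-variable-gene selection criteria
#'
#' Defaults follow the atlas study: standardized dispersion > 0.4 and
#' mean log-normalized expression in (0.01, 3), with dispersions
#' standardized within 20 equal-frequency mean bins.
#'
#' @param min_dispersion standardized-dispersion cutoff.
#' @param min_mean,max_mean mean-expression window (log-normalized units).
#' @param n_bins mean bins for dispersion standardization.
#' @return list of class `HVGCriteria`.
#' @export
hvg_criteria <- function(min_dispersion = 0.4, min_mean = 0.01,
                         max_mean = 3, n_bins = 20) {
  stopifnot(min_mean < max_mean, n_bins >= 1)
  structure(list(min_dispersion = min_dispersion, min_mean = min_mean,
                 max_mean = max_mean, n_bins = n_bins),
            class = "HVGCriteria")
}

# Per-gene mean (log space), dispersion (var/mean of expm1 values) and
# bin-standardized log dispersion.
gene_dispersion <- function(nm, n_bins = 20) {
  v <- nm$values
  n <- nrow(v)
  mean_log <- Matrix::colMeans(v)
  ev <- v; ev@x <- expm1(ev@x)
  mu <- Matrix::colMeans(ev)
  ex2 <- Matrix::colMeans(ev^2)
  varg <- (ex2 - mu^2) * n / (n - 1)
  disp <- ifelse(mu > 0 & varg > 0, varg / mu, NA_real_)
  ldisp <- log(disp)
  n_bins <- min(n_bins, max(1, sum(!is.na(disp))))
  # equal-frequency bins on gene mean
  br <- unique(stats::quantile(mean_log, probs = seq(0, 1, length.out =
                                                       n_bins + 1)))
  bin <- cut(mean_log, breaks = br, include.lowest = TRUE)
  z <- rep(NA_real_, length(disp))
  for (b in levels(bin)) {
    idx <- which(bin == b & !is.na(ldisp) & is.finite(ldisp))
    if (!length(idx)) next
    m <- mean(ldisp[idx]); s <- stats::sd(ldisp[idx])
    z[idx] <- if (is.na(s) || s == 0) 0 else (ldisp[idx] - m) / s
  }
  data.frame(gene_id = nm$gene_ids, mean = mean_log, dispersion = disp,
             dispersion_std = z, stringsAsFactors = FALSE)
}

#' Select highly variable genes
#'
#' Dispersion = variance/mean of the exp-space (expm1) normalized values,
#' log-transformed and z-scored within equal-frequency mean bins; a gene
#' is selected iff its standardized dispersion exceeds
#' `crit$min_dispersion` and its mean log-normalized expression lies in
#' `(min_mean, max_mean)`. Deterministic; constant genes are never
#' selected.
#'
#' @param nm a [lognormalize()] result.
#' @param crit an [hvg_criteria()].
#' @return character vector of selected gene ids, with the per-gene
#'   statistics table attached as attribute `"stats"`.
#' @export
select_hvg <- function(nm, crit = hvg_criteria()) {
  stopifnot(inherits(nm, "NormalizedMatrix"))
  if (nrow(nm$values) < 2) stopf("need at least 2 cells")
  if (ncol(nm$values) < crit$n_bins)
    warnf("fewer genes than bins; reducing to %d bins", ncol(nm$values))
  st <- gene_dispersion(nm, crit$n_bins)
  sel <- !is.na(st$dispersion_std) &
    st$dispersion_std > crit$min_dispersion &
    st$mean > crit$min_mean & st$mean < crit$max_mean
  structure(st$gene_id[sel], stats = st)
}

#' Score a gene module against expression-matched controls
#'
#' Mean normalized expression of the module genes minus the mean over
#' control genes drawn, `n_ctrl` per module gene, from the same
#' average-expression bin (equal-frequency bins over all genes).
#' Seed-deterministic.
#'
#' @param nm a [lognormalize()] result.
#' @param gene_set character vector of gene ids.
#' @param n_bins expression bins for control matching.
#' @param n_ctrl control genes sampled per module gene.
#' @param seed RNG seed for control sampling.
#' @return numeric per-cell score.
#' @export
score_gene_module <- function(nm, gene_set, n_bins = 25, n_ctrl = 50,
                              seed = 1) {
  stopifnot(inherits(nm, "NormalizedMatrix"))
  present <- intersect(gene_set, nm$gene_ids)
  if (!length(present)) stopf("no module genes present in the matrix")
  avg <- Matrix::colMeans(nm$values)
  br <- unique(stats::quantile(avg, probs = seq(0, 1, length.out =
                                                  n_bins + 1)))
  bin <- as.integer(cut(avg, breaks = br, include.lowest = TRUE))
  idx <- match(present, nm$gene_ids)
  ctrl <- with_seed(seed, {
    picked <- integer(0)
    for (i in idx) {
      # controls are expression-matched but never the module's own genes
      pool <- setdiff(which(bin == bin[i]), idx)
      if (!length(pool)) pool <- setdiff(seq_along(bin), idx)
      picked <- c(picked, pool[sample.int(length(pool),
                                          min(n_ctrl, length(pool)))])
    }
    unique(picked)
  })
  set_score <- Matrix::rowMeans(nm$values[, idx, drop = FALSE])
  ctrl_score <- Matrix::rowMeans(nm$values[, ctrl, drop = FALSE])
  as.numeric(set_score - ctrl_score)
}

#' Score cell-cycle programs and assign phases
#'
#' S and G2M scores via [score_gene_module()]; a cell is S when its S
#' score beats the G2M score and is positive, G2M when the G2M score is
#' at least the S score and positive, and G1 otherwise.
#' `cc_difference = g2m_score - s_score` is recorded for use as a
#' regression covariate, which keeps the cycling/non-cycling separation
#' while removing phase-internal variation.
#'
#' @param nm a [lognormalize()] result.
#' @param s_genes,g2m_genes phase gene lists (ids).
#' @param seed RNG seed for control sampling.
#' @return data.frame with `barcode`, `s_score`, `g2m_score`,
#'   `cc_difference`, `phase`.
#' @export
assign_cell_cycle <- function(nm, s_genes, g2m_genes, seed = 1) {
  if (!length(intersect(s_genes, nm$gene_ids)) ||
      !length(intersect(g2m_genes, nm$gene_ids)))
    stopf("S or G2M gene list has no overlap with the matrix")
  s <- score_gene_module(nm, s_genes, seed = seed)
  g2m <- score_gene_module(nm, g2m_genes, seed = seed + 1L)
  phase <- ifelse(s > g2m & s > 0, "S",
                  ifelse(g2m >= s & g2m > 0, "G2M", "G1"))
  data.frame(barcode = nm$barcodes, s_score = s, g2m_score = g2m,
             cc_difference = g2m - s, phase = phase,
             stringsAsFactors = FALSE)
}

#' Regress out per-cell covariates and z-score
#'
#' Per gene, ordinary least squares of log-normalized expression on the
#' covariates plus an intercept; residuals are z-scored per gene and
#' clipped at `clip_max`. The standard covariates are `n_umi`,
#' `pct_mito`, and the cell-cycle score difference.
#'
#' @param nm a [lognormalize()] result.
#' @param covariates data.frame or matrix of per-cell covariates (rows
#'   aligned to cells); NULL for plain centering/scaling.
#' @param genes restrict to these gene ids (default all).
#' @param clip_max clipping bound on z-scores.
#' @return list of class `ScaledMatrix`: `values` (dense cells x genes),
#'   `genes`, `barcodes`, `clip_max`.
#' @export
scale_regress <- function(nm, covariates = NULL, genes = NULL,
                          clip_max = 10) {
  stopifnot(inherits(nm, "NormalizedMatrix"))
  n <- nrow(nm$values)
  if (n < 3) stopf("need at least 3 cells")
  if (is.null(genes)) genes <- nm$gene_ids
  gidx <- match(genes, nm$gene_ids)
  if (anyNA(gidx)) stopf("unknown gene id(s) in `genes`")
  Y <- as.matrix(nm$values[, gidx, drop = FALSE])
  X <- matrix(1, n, 1)
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    if (nrow(cv) != n) stopf("covariates not aligned with cells")
    if (any(!is.finite(cv))) stopf("non-finite covariates")
    X <- cbind(X, cv)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warnf("dropping %d collinear covariate column(s)",
          ncol(X) - qrX$rank)
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    qrX <- qr(X)
  }
  res <- Y - X %*% qr.coef(qrX, Y)
  sds <- apply(res, 2, stats::sd)
  sds[sds == 0] <- 1
  z <- sweep(res, 2, sds, "/")
  z[z > clip_max] <- clip_max
  z[z < -clip_max] <- -clip_max
  dimnames(z) <- list(nm$barcodes, genes)
  structure(list(values = z, genes = genes, barcodes = nm$barcodes,
                 clip_max = clip_max),
            class = "ScaledMatrix")
}
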