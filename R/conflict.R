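# Marker-conflict doublet filter: flag and remove cells whose expression
# conflicts across distantly related cell-type marker panels.

#' Conflict-filter rule
#'
#' @param threshold log2-scale type-score cutoff (default 1: more than
#'   2-fold over the pseudocount baseline).
#' @param aggregation `"mean"` or `"max"` over a type's panel genes.
#' @param scope `"per-cluster"` (cleanup applied cluster by cluster
#'   against types foreign to the cluster's identity) or `"global"`
#'   (any declared conflicting pair).
#' @return list of class `ConflictRule`.
#' @export
conflict_rule <- function(threshold = 1.0,
                          aggregation = c("mean", "max"),
                          scope = c("per-cluster", "global")) {
  stopifnot(threshold > 0)
  structure(list(threshold = threshold,
                 aggregation = match.arg(aggregation),
                 scope = match.arg(scope)),
            class = "ConflictRule")
}

#' Per-cell cell-type scores from a marker panel
#'
#' `score(cell, type) = log2(1 + aggregate(expm1(x)))` over the type's
#' panel genes present in the matrix. Deterministic; independent of genes
#' outside the panel.
#'
#' @param nm a [lognormalize()] result.
#' @param panel a [marker_panel()].
#' @param aggregation `"mean"` or `"max"`.
#' @return numeric matrix, cells x types.
#' @export
score_types <- function(nm, panel, aggregation = c("mean", "max")) {
  stopifnot(inherits(nm, "NormalizedMatrix"),
            inherits(panel, "MarkerPanel"))
  aggregation <- match.arg(aggregation)
  ev <- nm$values
  ev@x <- expm1(ev@x)
  types <- panel$types
  out <- matrix(0, nrow(ev), length(types),
                dimnames = list(nm$barcodes, types))
  for (ty in types) {
    genes <- panel$entries$gene[panel$entries$cell_type == ty]
    idx <- match(genes, nm$gene_ids)
    idx <- idx[!is.na(idx)]
    if (!length(idx))
      stopf("panel type '%s' has no genes present in the matrix", ty)
    agg <- if (aggregation == "mean")
      Matrix::rowMeans(ev[, idx, drop = FALSE])
    else
      apply(as.matrix(ev[, idx, drop = FALSE]), 1, max)
    out[, ty] <- log2(1 + as.numeric(agg))
  }
  out
}

#' Flag marker-conflicting cells
#'
#' Global scope: a cell is flagged iff some declared-conflicting type
#' pair (A, B) has both scores above the threshold. Per-cluster scope:
#' each cluster gets an identity (the type with the highest mean score
#' among its cells) and a member cell is flagged iff its own-identity
#' score and the score of some type conflicting with that identity both
#' exceed the threshold.
#'
#' @param scores from [score_types()].
#' @param panel the [marker_panel()].
#' @param rule a [conflict_rule()].
#' @param labels cluster labels (required for per-cluster scope).
#' @return list of class `ConflictReport`: `flagged` (logical per cell),
#'   `scores`, `pairs` (per-cell list of conflicting pairs, as a
#'   data.frame of cell/type_a/type_b), `cluster_identity`,
#'   `removal_by_cluster`, `rule`.
#' @export
flag_conflicts <- function(scores, panel, rule = conflict_rule(),
                           labels = NULL) {
  stopifnot(inherits(panel, "MarkerPanel"), inherits(rule, "ConflictRule"))
  theta <- rule$threshold
  above <- scores > theta
  pairs <- panel$conflict_pairs
  n <- nrow(scores)
  flagged <- rep(FALSE, n)
  hit <- list()
  if (rule$scope == "per-cluster") {
    if (is.null(labels)) stopf("per-cluster scope requires cluster labels")
    if (inherits(labels, "ClusterLabels")) labels <- labels$labels
    if (length(labels) != n) stopf("labels not aligned with cells")
    cl <- sort(unique(labels))
    ident <- vapply(cl, function(ci)
      colnames(scores)[which.max(colMeans(scores[labels == ci, ,
                                                 drop = FALSE]))], "")
    names(ident) <- as.character(cl)
    own <- ident[as.character(labels)]
    for (k in seq_len(nrow(pairs))) {
      a <- pairs$type_a[k]; b <- pairs$type_b[k]
      # conflict counted when one side is the cell's cluster identity
      for (sides in list(c(a, b), c(b, a))) {
        rel <- own == sides[1] & above[, sides[1]] & above[, sides[2]]
        if (any(rel)) {
          flagged <- flagged | rel
          hit[[length(hit) + 1]] <- data.frame(
            cell = which(rel), type_a = sides[1], type_b = sides[2],
            stringsAsFactors = FALSE)
        }
      }
    }
  } else {
    ident <- NULL
    own <- NULL
    for (k in seq_len(nrow(pairs))) {
      rel <- above[, pairs$type_a[k]] & above[, pairs$type_b[k]]
      if (any(rel)) {
        flagged <- flagged | rel
        hit[[length(hit) + 1]] <- data.frame(
          cell = which(rel), type_a = pairs$type_a[k],
          type_b = pairs$type_b[k], stringsAsFactors = FALSE)
      }
    }
  }
  removal_by_cluster <- if (!is.null(labels))
    tapply(flagged, labels, sum) else NULL
  structure(list(flagged = flagged, scores = scores,
                 pairs = if (length(hit)) do.call(rbind, hit) else NULL,
                 cluster_identity = ident,
                 removal_by_cluster = removal_by_cluster,
                 rule = rule),
            class = "ConflictReport")
}

#' Partition a count matrix by the conflict flags
#'
#' @param cm the [count_matrix()] the report was computed on.
#' @param report a `ConflictReport`.
#' @return list: `high_quality` and `removed` `CountMatrix` objects
#'   (either may have zero cells; an all-flagged input yields an
#'   explicit empty high-quality matrix).
#' @export
apply_cleanup <- function(cm, report) {
  stopifnot(inherits(cm, "CountMatrix"), inherits(report, "ConflictReport"))
  if (length(report$flagged) != nrow(cm$counts))
    stopf("report not aligned with the count matrix")
  keep <- !report$flagged
  hq <- count_matrix(cm$counts[keep, , drop = FALSE], cm$barcodes[keep],
                     cm$gene_ids, cm$gene_symbols, cm$mito_flags)
  rm_ <- count_matrix(cm$counts[!keep, , drop = FALSE],
                      cm$barcodes[!keep], cm$gene_ids, cm$gene_symbols,
                      cm$mito_flags)
  if (nrow(hq$counts) == 0)
    warnf("cleanup flagged every cell; high-quality matrix is empty")
  list(high_quality = hq, removed = rm_)
}

#' Verify that cleanup retained true signal
#'
#' For each panel type, checks (a) at least one retained cell scores
#' above the threshold for its own type (no cell type eliminated), and
#' (b) retained cells scoring above threshold for a type do not also
#' exceed the threshold for a conflicting type. Also compares the HVG
#' count before and after cleanup.
#'
#' @param nm_pre,nm_post [lognormalize()] results before/after cleanup
#'   (post cells must be a subset of pre cells).
#' @param panel the [marker_panel()].
#' @param theta score threshold.
#' @param aggregation passed to [score_types()].
#' @return list: `per_type` data.frame (type, retained_pass,
#'   conflict_free), `hvg_pre`, `hvg_post`, `pass` (overall).
#' @export
retention_check <- function(nm_pre, nm_post, panel, theta = 1,
                            aggregation = "mean") {
  stopifnot(all(nm_post$barcodes %in% nm_pre$barcodes))
  sc <- score_types(nm_post, panel, aggregation)
  conf <- panel$conflict_pairs
  per_type <- data.frame(type = panel$types, retained_pass = NA,
                         conflict_free = NA, stringsAsFactors = FALSE)
  for (i in seq_along(panel$types)) {
    ty <- panel$types[i]
    ownhigh <- sc[, ty] > theta
    per_type$retained_pass[i] <- any(ownhigh)
    foes <- c(conf$type_b[conf$type_a == ty], conf$type_a[conf$type_b == ty])
    per_type$conflict_free[i] <- if (!length(foes) || !any(ownhigh)) TRUE
      else all(sc[ownhigh, foes, drop = FALSE] <= theta)
  }
  hvg_pre <- length(select_hvg(nm_pre))
  hvg_post <- length(select_hvg(nm_post))
  list(per_type = per_type, hvg_pre = hvg_pre, hvg_post = hvg_post,
       pass = all(per_type$retained_pass))
}
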