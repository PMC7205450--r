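# Data model and readers/writers: count matrices, marker panels, cell tables.

#' Construct a CountMatrix
#'
#' The package's container for droplet UMI counts: a sparse non-negative
#' integer matrix oriented cells x genes, with barcode and gene annotations
#' and a per-gene mitochondrial flag.
#'
#' @param counts sparse (or dense) non-negative integer matrix, cells x genes.
#' @param barcodes character vector of unique cell identifiers (rows).
#' @param gene_ids character vector of unique, stable gene identifiers
#'   (columns). Symbols are for display only; identity is keyed on
#'   `gene_ids`.
#' @param gene_symbols display names; defaults to `gene_ids`.
#' @param mito_flags logical per gene; defaults to symbols starting with
#'   `mito_prefix`.
#' @param mito_prefix symbol prefix marking mitochondrial-encoded genes
#'   (FlyBase convention `"mt:"`).
#' @return An object of class `CountMatrix`.
#' @export
count_matrix <- function(counts, barcodes, gene_ids,
                         gene_symbols = gene_ids,
                         mito_flags = NULL, mito_prefix = "mt:") {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if (length(barcodes) != nrow(counts))
    stopf("barcode count (%d) does not match matrix rows (%d)",
          length(barcodes), nrow(counts))
  if (length(gene_ids) != ncol(counts))
    stopf("gene count (%d) does not match matrix columns (%d)",
          length(gene_ids), ncol(counts))
  if (anyDuplicated(barcodes)) stopf("duplicate barcodes")
  if (anyDuplicated(gene_ids)) stopf("duplicate gene identifiers")
  if (length(counts@x) && (any(counts@x < 0) ||
                           any(counts@x != round(counts@x))))
    stopf("counts must be non-negative integers")
  if (is.null(mito_flags)) mito_flags <- startsWith(gene_symbols, mito_prefix)
  if (length(mito_flags) != length(gene_ids))
    stopf("mito_flags length mismatch")
  rownames(counts) <- barcodes
  colnames(counts) <- gene_ids
  structure(list(counts = counts,
                 barcodes = as.character(barcodes),
                 gene_ids = as.character(gene_ids),
                 gene_symbols = as.character(gene_symbols),
                 mito_flags = as.logical(mito_flags)),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d cells x %d genes (%d mitochondrial), %.0f UMIs\n",
              nrow(x$counts), ncol(x$counts), sum(x$mito_flags),
              sum(x$counts)))
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Subset a CountMatrix by cells and/or genes
#'
#' @param x a `CountMatrix`.
#' @param cells,genes index vectors (integer, logical, or names).
#' @return A `CountMatrix`.
#' @export
subset_cells <- function(x, cells = NULL, genes = NULL) {
  stopifnot(inherits(x, "CountMatrix"))
  if (is.null(cells)) cells <- seq_len(nrow(x$counts))
  if (is.null(genes)) genes <- seq_len(ncol(x$counts))
  if (is.character(cells)) cells <- match(cells, x$barcodes)
  if (is.character(genes)) genes <- match(genes, x$gene_ids)
  if (is.logical(cells)) cells <- which(cells)
  if (is.logical(genes)) genes <- which(genes)
  count_matrix(x$counts[cells, genes, drop = FALSE],
               x$barcodes[cells], x$gene_ids[genes],
               x$gene_symbols[genes], x$mito_flags[genes])
}

#' Read a MatrixMarket triplet count matrix with barcode/feature sidecars
#'
#' Ingests Cell Ranger-style output: a `matrix.mtx` (1-based triplet,
#' genes x cells or cells x genes on disk), a barcodes file (one barcode
#' per line) and a features file (tab-separated id, symbol, and optional
#' type columns). Orientation is normalized to cells x genes regardless of
#' the on-disk layout; all three files may be gzip-compressed.
#'
#' @param matrix_path path to the `.mtx` file.
#' @param barcodes_path path to the barcodes file.
#' @param features_path path to the features/genes file.
#' @param mito_prefix gene-symbol prefix flagging mitochondrial genes.
#' @return A [count_matrix()].
#' @export
read_mtx_triplet <- function(matrix_path, barcodes_path, features_path,
                             mito_prefix = "mt:") {
  for (p in c(matrix_path, barcodes_path, features_path))
    if (!file.exists(p)) stopf("file not found: %s", p)
  con <- open_text(matrix_path)
  on.exit(close(con), add = TRUE)
  m <- tryCatch(Matrix::readMM(con),
                error = function(e) stopf("invalid MatrixMarket file: %s",
                                          conditionMessage(e)))
  bc_con <- open_text(barcodes_path)
  barcodes <- readLines(bc_con)
  close(bc_con)
  ft_con <- open_text(features_path)
  feat <- utils::read.delim(ft_con, header = FALSE,
                            stringsAsFactors = FALSE)
  close(ft_con)
  gene_ids <- as.character(feat[[1]])
  gene_symbols <- if (ncol(feat) >= 2) as.character(feat[[2]]) else gene_ids

  nb <- length(barcodes)
  ng <- length(gene_ids)
  if (nrow(m) == ng && ncol(m) == nb) {
    m <- Matrix::t(m)                 # 10x on-disk layout: genes x cells
  } else if (!(nrow(m) == nb && ncol(m) == ng)) {
    stopf("matrix dimensions %dx%d match neither %d barcodes x %d features",
          nrow(m), ncol(m), nb, ng)
  }
  if (length(m@x) && any(m@x != round(m@x)))
    stopf("non-integer entries in count matrix")
  count_matrix(m, barcodes, gene_ids, gene_symbols,
               mito_prefix = mito_prefix)
}

#' Write a CountMatrix as MatrixMarket triplet plus sidecar files
#'
#' Inverse of [read_mtx_triplet()]; writes the 10x on-disk orientation
#' (genes x cells).
#'
#' @param x a `CountMatrix`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mtx_triplet <- function(x, dir) {
  stopifnot(inherits(x, "CountMatrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(x$counts), file.path(dir, "matrix.mtx"))
  writeLines(x$barcodes, file.path(dir, "barcodes.tsv"))
  utils::write.table(
    data.frame(x$gene_ids, x$gene_symbols, "Gene Expression"),
    file.path(dir, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Construct a marker panel
#'
#' A curated table mapping marker genes to cell types, with conflict
#' groups: types in *different* groups are declared distantly related, and
#' a cell scoring above threshold for two such types is a doublet
#' candidate. Types sharing a group (e.g. adjacent states on one lineage)
#' are exempt, preserving genuine intermediary states.
#'
#' @param entries data.frame with columns `gene`, `cell_type`,
#'   `conflict_group`.
#' @return An object of class `MarkerPanel` with the entry table and the
#'   derived set of unordered conflicting type pairs.
#' @export
marker_panel <- function(entries) {
  need <- c("gene", "cell_type", "conflict_group")
  if (!all(need %in% names(entries)))
    stopf("marker panel needs columns: %s", paste(need, collapse = ", "))
  entries <- entries[, need]
  entries[] <- lapply(entries, as.character)
  if (nrow(entries) == 0) stopf("empty marker panel")
  if (any(!nzchar(entries$gene)) || any(is.na(entries$gene)))
    stopf("blank gene in marker panel")
  if (any(!nzchar(entries$cell_type))) stopf("blank cell_type in marker panel")
  types <- unique(entries[, c("cell_type", "conflict_group")])
  if (anyDuplicated(types$cell_type))
    stopf("cell type assigned to more than one conflict group")
  pairs <- data.frame(type_a = character(0), type_b = character(0))
  tt <- types$cell_type
  gg <- types$conflict_group
  if (length(tt) > 1) {
    cmb <- utils::combn(length(tt), 2)
    keep <- gg[cmb[1, ]] != gg[cmb[2, ]]
    pairs <- data.frame(type_a = tt[cmb[1, keep]],
                        type_b = tt[cmb[2, keep]],
                        stringsAsFactors = FALSE)
  }
  structure(list(entries = entries,
                 types = tt,
                 conflict_pairs = pairs),
            class = "MarkerPanel")
}

#' @export
print.MarkerPanel <- function(x, ...) {
  cat(sprintf("MarkerPanel: %d genes, %d cell types, %d conflicting pairs\n",
              length(unique(x$entries$gene)), length(x$types),
              nrow(x$conflict_pairs)))
  invisible(x)
}

#' Read a marker panel from TSV
#'
#' Expects a header line `gene  cell_type  conflict_group`.
#'
#' @param path TSV path (may be gzipped).
#' @return A [marker_panel()].
#' @export
read_marker_panel <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  con <- open_text(path)
  on.exit(close(con), add = TRUE)
  df <- utils::read.delim(con, stringsAsFactors = FALSE)
  need <- c("gene", "cell_type", "conflict_group")
  if (!all(need %in% names(df)))
    stopf("marker panel file must have columns: %s",
          paste(need, collapse = ", "))
  if (!all(names(df) %in% need))
    stopf("unknown column(s) in marker panel: %s",
          paste(setdiff(names(df), need), collapse = ", "))
  marker_panel(df)
}

#' Write a marker panel to TSV
#' @param panel a `MarkerPanel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_marker_panel <- function(panel, path) {
  stopifnot(inherits(panel, "MarkerPanel"))
  utils::write.table(panel$entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Fixed column order of the per-cell results table.
CELL_TABLE_COLS <- c("barcode", "n_genes", "n_umi", "pct_mito", "phase",
                     "cluster", "pseudotime", "branch", "qc_pass",
                     "conflict_flag")

#' Assemble a per-cell results table
#'
#' One row per barcode, carrying QC metrics, phase, cluster, pseudotime,
#' branch and filter flags. Missing columns are filled with NA.
#'
#' @param barcode character vector of unique barcodes.
#' @param ... any of `n_genes`, `n_umi`, `pct_mito`, `phase`, `cluster`,
#'   `pseudotime`, `branch`, `qc_pass`, `conflict_flag`.
#' @return data.frame with the package's fixed column order.
#' @export
cell_table <- function(barcode, ...) {
  if (anyDuplicated(barcode)) stopf("duplicate barcodes in cell table")
  extra <- list(...)
  bad <- setdiff(names(extra), CELL_TABLE_COLS)
  if (length(bad)) stopf("unknown cell table column(s): %s",
                         paste(bad, collapse = ", "))
  out <- data.frame(barcode = as.character(barcode),
                    stringsAsFactors = FALSE)
  for (col in setdiff(CELL_TABLE_COLS, "barcode")) {
    v <- extra[[col]]
    if (is.null(v)) v <- NA
    out[[col]] <- v
  }
  if (any(!is.na(out$pct_mito) & (out$pct_mito < 0 | out$pct_mito > 100)))
    stopf("pct_mito outside [0, 100]")
  if (any(!is.na(out$pseudotime) & out$pseudotime < 0))
    stopf("negative pseudotime")
  out
}

#' Write a per-cell results table to TSV
#'
#' Fixed column order with a header; round-trips losslessly through
#' [read_cell_table()].
#'
#' @param table a data.frame from [cell_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(table, path) {
  if (!all(names(table) == CELL_TABLE_COLS))
    stopf("cell table has wrong columns; build it with cell_table()")
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a per-cell results table written by [write_cell_table()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_cell_table <- function(path) {
  con <- open_text(path)
  on.exit(close(con), add = TRUE)
  df <- utils::read.delim(con, stringsAsFactors = FALSE,
                          colClasses = c(barcode = "character"))
  if (!identical(names(df), CELL_TABLE_COLS))
    stopf("not a cell table: %s", path)
  for (col in c("phase", "branch"))
    df[[col]] <- as.character(df[[col]])
  for (col in c("qc_pass", "conflict_flag"))
    df[[col]] <- as.logical(df[[col]])
  for (col in c("n_genes", "cluster"))
    df[[col]] <- as.integer(df[[col]])
  for (col in c("n_umi", "pct_mito", "pseudotime"))
    df[[col]] <- as.numeric(df[[col]])
  df
}
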