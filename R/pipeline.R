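# Cross-cluster shared signatures and end-to-end pipeline orchestration.

#' Shared expression signature of two clusters
#'
#' Intersection of the two clusters' significant marker genes, ranked by
#' mean log-normalized expression across the cells of the two clusters;
#' the top `top_n` are returned together with the full intersection.
#' An empty intersection yields an empty (not failing) result.
#'
#' @param markers a `MarkerResult` covering both clusters.
#' @param nm the [lognormalize()] result the markers came from.
#' @param labels cluster labels aligned with `nm`.
#' @param cluster_a,cluster_b the two cluster ids.
#' @param top_n genes to report (e.g. for a heatmap).
#' @return list of class `SharedSignature`: `common` (data.frame gene,
#'   mean_expr_a, mean_expr_b, mean_expr), `top` (head of `common` by
#'   mean expression), `cluster_pair`.
#' @export
shared_signature <- function(markers, nm, labels, cluster_a, cluster_b,
                             top_n = 30) {
  if (inherits(labels, "ClusterLabels")) labels <- labels$labels
  sig_a <- markers$gene[markers$significant & markers$cluster == cluster_a]
  sig_b <- markers$gene[markers$significant & markers$cluster == cluster_b]
  common <- intersect(sig_a, sig_b)
  if (length(common)) {
    idx <- match(common, nm$gene_ids)
    ca <- labels == cluster_a
    cb <- labels == cluster_b
    ma <- Matrix::colMeans(nm$values[ca, idx, drop = FALSE])
    mb <- Matrix::colMeans(nm$values[cb, idx, drop = FALSE])
    both <- Matrix::colMeans(nm$values[ca | cb, idx, drop = FALSE])
    df <- data.frame(gene = common, mean_expr_a = as.numeric(ma),
                     mean_expr_b = as.numeric(mb),
                     mean_expr = as.numeric(both),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$mean_expr), ]
    rownames(df) <- NULL
  } else {
    df <- data.frame(gene = character(0), mean_expr_a = numeric(0),
                     mean_expr_b = numeric(0), mean_expr = numeric(0))
  }
  structure(list(common = df, top = utils::head(df, top_n),
                 cluster_pair = c(cluster_a, cluster_b)),
            class = "SharedSignature")
}

#' Default pipeline configuration
#'
#' Collects every stage's parameters. Paths: either `input_dir`
#' (MatrixMarket triplet directory) plus `panel_path`, or an in-memory
#' `counts` / `panel` pair supplied directly to [run_pipeline()].
#'
#' @param input_dir directory with matrix.mtx / barcodes.tsv /
#'   features.tsv (optional when counts are passed in memory).
#' @param panel_path marker-panel TSV (optional likewise).
#' @param mito_prefix mitochondrial symbol prefix.
#' @param thresholds a [qc_thresholds()].
#' @param hvg an [hvg_criteria()].
#' @param s_genes,g2m_genes cell-cycle gene-id lists (skip scoring when
#'   NULL).
#' @param n_pcs PCs to compute; the SNN uses `choose_elbow` unless
#'   `snn_pcs` is set.
#' @param snn_pcs PCs for the SNN graph (NULL = elbow choice).
#' @param k,prune SNN parameters.
#' @param resolutions resolution sweep.
#' @param resolution resolution used for the working partition.
#' @param conflict a [conflict_rule()].
#' @param skip_conflict run downstream on unfiltered cells.
#' @param seed master seed.
#' @return list of class `PipelineConfig`.
#' @export
pipeline_config <- function(input_dir = NULL, panel_path = NULL,
                            mito_prefix = "mt:",
                            thresholds = qc_thresholds(),
                            hvg = hvg_criteria(),
                            s_genes = NULL, g2m_genes = NULL,
                            n_pcs = 30, snn_pcs = NULL, k = 30,
                            prune = 1 / 15,
                            resolutions = seq(0.5, 6, by = 0.5),
                            resolution = 1,
                            conflict = conflict_rule(),
                            skip_conflict = FALSE,
                            seed = 1) {
  if (!is.null(input_dir) && !dir.exists(input_dir))
    stopf("input_dir does not exist: %s", input_dir)
  if (!is.null(panel_path) && !file.exists(panel_path))
    stopf("panel_path does not exist: %s", panel_path)
  structure(list(input_dir = input_dir, panel_path = panel_path,
                 mito_prefix = mito_prefix, thresholds = thresholds,
                 hvg = hvg, s_genes = s_genes, g2m_genes = g2m_genes,
                 n_pcs = n_pcs, snn_pcs = snn_pcs, k = k, prune = prune,
                 resolutions = resolutions, resolution = resolution,
                 conflict = conflict, skip_conflict = skip_conflict,
                 seed = seed),
            class = "PipelineConfig")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the atlas-construction pipeline end to end
#'
#' read -> QC -> log-normalize -> cell-cycle score/regress -> HVG -> PCA
#' -> SNN -> resolution sweep -> markers -> merge -> conflict filter ->
#' re-normalize and re-cluster the high-quality cells. Every stage
#' writes a TSV into `out_dir`, a log records parameters and cell
#' counts, and a JSON manifest lists all artifacts; reruns under the
#' same config and seed are bit-identical.
#'
#' @param config a [pipeline_config()].
#' @param out_dir artifact directory (created).
#' @param counts optional in-memory [count_matrix()] (overrides
#'   `input_dir`).
#' @param panel optional in-memory [marker_panel()] (overrides
#'   `panel_path`).
#' @return list of class `PipelineResult`: `manifest`, `cell_table`,
#'   `labels`, `markers`, plus intermediate objects (`norm`, `hvgs`,
#'   `pca`, `conflict_report`, `final`).
#' @export
run_pipeline <- function(config, out_dir, counts = NULL, panel = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (is.null(counts) && is.null(config$input_dir))
    stopf("no input: set config$input_dir or pass `counts`")
  if (is.null(panel) && is.null(config$panel_path) &&
      !config$skip_conflict)
    stopf("no marker panel: set config$panel_path, pass `panel`, or skip")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(fmt, ...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                sprintf(fmt, ...)), file = log_path, append = TRUE)
  }
  manifest <- list(seed = config$seed, stages = list())
  stage <- function(name, files, counts_in, counts_out) {
    manifest$stages[[name]] <<- list(files = basename(files),
                                     cells_in = counts_in,
                                     cells_out = counts_out)
    logf("stage %s: %d -> %d cells", name, counts_in, counts_out)
  }

  if (is.null(counts))
    counts <- read_mtx_triplet(file.path(config$input_dir, "matrix.mtx"),
                               file.path(config$input_dir, "barcodes.tsv"),
                               file.path(config$input_dir, "features.tsv"),
                               mito_prefix = config$mito_prefix)
  if (is.null(panel) && !is.null(config$panel_path))
    panel <- read_marker_panel(config$panel_path)
  n0 <- nrow(counts$counts)
  stage("ingest", character(0), n0, n0)

  metrics <- compute_qc_metrics(counts)
  f <- write_tsv(metrics, file.path(out_dir, "qc_metrics.tsv"))
  filt <- filter_cells(counts, metrics, config$thresholds)
  f2 <- write_tsv(data.frame(reason = names(filt$report),
                             cells = as.integer(filt$report)),
                  file.path(out_dir, "qc_removal_report.tsv"))
  cm <- filt$kept
  stage("qc", c(f, f2), n0, nrow(cm$counts))

  nm <- lognormalize(cm)
  cc <- NULL
  covars <- compute_qc_metrics(cm)[, c("n_umi", "pct_mito")]
  if (!is.null(config$s_genes) && !is.null(config$g2m_genes)) {
    cc <- assign_cell_cycle(nm, config$s_genes, config$g2m_genes,
                            seed = config$seed)
    covars$cc_difference <- cc$cc_difference
    write_tsv(cc, file.path(out_dir, "cell_cycle.tsv"))
  }
  hvgs <- select_hvg(nm, config$hvg)
  writeLines(hvgs, file.path(out_dir, "hvgs.txt"))
  sm <- scale_regress(nm, covariates = covars, genes = hvgs)
  stage("normalize_scale", file.path(out_dir, c("hvgs.txt")),
        nrow(cm$counts), nrow(cm$counts))

  pca <- run_pca(sm, hvgs, n_pcs = min(config$n_pcs,
                                       min(dim(sm$values)) - 1))
  n_use <- if (is.null(config$snn_pcs)) choose_elbow(pca$explained)
    else min(config$snn_pcs, pca$n_pcs)
  n_use <- max(n_use, 2)
  snn <- build_snn(pca$embeddings[, seq_len(n_use), drop = FALSE],
                   k = min(config$k, nrow(pca$embeddings) - 1),
                   prune = config$prune)
  sweep_res <- resolution_sweep(snn, config$resolutions,
                                seed = config$seed)
  write_tsv(sweep_res$tree, file.path(out_dir, "cluster_tree.tsv"))
  lab <- cluster_modularity(snn, resolution = config$resolution,
                            seed = config$seed)
  merged <- merge_unmarked_clusters(lab, nm, hvgs = hvgs)
  write_tsv(data.frame(barcode = cm$barcodes, cluster = merged$labels),
            file.path(out_dir, "clusters.tsv"))
  if (!is.null(merged$markers))
    write_tsv(merged$markers, file.path(out_dir, "markers.tsv"))
  stage("cluster", file.path(out_dir, c("cluster_tree.tsv",
                                        "clusters.tsv", "markers.tsv")),
        nrow(cm$counts), nrow(cm$counts))

  conflict_report <- NULL
  final_cm <- cm
  if (!config$skip_conflict) {
    sc <- score_types(nm, panel, config$conflict$aggregation)
    conflict_report <- flag_conflicts(sc, panel, config$conflict,
                                      labels = merged$labels)
    parts <- apply_cleanup(cm, conflict_report)
    final_cm <- parts$high_quality
    writeLines(parts$removed$barcodes,
               file.path(out_dir, "removed_barcodes.txt"))
    stage("conflict_filter",
          file.path(out_dir, "removed_barcodes.txt"),
          nrow(cm$counts), nrow(final_cm$counts))
  } else {
    logf("conflict filter skipped by config")
    manifest$skipped_conflict <- TRUE
  }

  # re-normalize and re-cluster the high-quality cells
  nm2 <- lognormalize(final_cm)
  hvgs2 <- select_hvg(nm2, config$hvg)
  keep_idx <- match(final_cm$barcodes, cm$barcodes)
  covars2 <- covars[keep_idx, , drop = FALSE]
  sm2 <- scale_regress(nm2, covariates = covars2, genes = hvgs2)
  pca2 <- run_pca(sm2, hvgs2, n_pcs = min(config$n_pcs,
                                          min(dim(sm2$values)) - 1))
  n_use2 <- if (is.null(config$snn_pcs)) choose_elbow(pca2$explained)
    else min(config$snn_pcs, pca2$n_pcs)
  n_use2 <- max(n_use2, 2)
  snn2 <- build_snn(pca2$embeddings[, seq_len(n_use2), drop = FALSE],
                    k = min(config$k, nrow(pca2$embeddings) - 1),
                    prune = config$prune)
  lab2 <- cluster_modularity(snn2, resolution = config$resolution,
                             seed = config$seed)
  merged2 <- merge_unmarked_clusters(lab2, nm2, hvgs = hvgs2)
  metrics2 <- compute_qc_metrics(final_cm)
  tab <- cell_table(final_cm$barcodes,
                    n_genes = metrics2$n_genes, n_umi = metrics2$n_umi,
                    pct_mito = metrics2$pct_mito,
                    phase = if (!is.null(cc)) cc$phase[keep_idx] else NA,
                    cluster = merged2$labels,
                    qc_pass = TRUE,
                    conflict_flag = FALSE)
  write_cell_table(tab, file.path(out_dir, "cells.tsv"))
  stage("final", file.path(out_dir, "cells.tsv"),
        nrow(final_cm$counts), nrow(final_cm$counts))

  manifest$n_clusters_final <- length(unique(merged2$labels))
  manifest$hvg_initial <- length(hvgs)
  manifest$hvg_final <- length(hvgs2)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  structure(list(manifest = manifest, cell_table = tab,
                 labels = merged2$labels, markers = merged2$markers,
                 norm = nm2, hvgs = hvgs2, pca = pca2,
                 conflict_report = conflict_report,
                 final = final_cm, sweep = sweep_res),
            class = "PipelineResult")
}
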