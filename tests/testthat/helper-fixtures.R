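# Shared fixture builders. Everything is generated in code at test time.

# Small random CountMatrix with a couple of mitochondrial genes.
random_count_matrix <- function(n_cells = 50, n_genes = 20, seed = 1,
                                lambda = 2, n_mito = 2) {
  set.seed(seed)
  m <- matrix(rpois(n_cells * n_genes, lambda), n_cells, n_genes)
  symbols <- sprintf("g%03d", seq_len(n_genes))
  if (n_mito > 0) symbols[seq_len(n_mito)] <- paste0("mt:g", seq_len(n_mito))
  count_matrix(m, sprintf("BC%04d", seq_len(n_cells)),
               sprintf("GENE%04d", seq_len(n_genes)), symbols)
}

# Normalized matrix straight from a random count matrix (no zero cells).
random_norm_matrix <- function(n_cells = 50, n_genes = 20, seed = 1,
                               lambda = 2) {
  cm <- random_count_matrix(n_cells, n_genes, seed, lambda)
  # guarantee no all-zero cells
  zero <- Matrix::rowSums(cm$counts) == 0
  if (any(zero)) {
    m <- as.matrix(cm$counts)
    m[zero, 1] <- 1
    cm <- count_matrix(m, cm$barcodes, cm$gene_ids, cm$gene_symbols)
  }
  lognormalize(cm)
}

# Example marker panel: three distantly related types plus two related
# lineage states sharing a conflict group.
example_panel <- function() {
  marker_panel(data.frame(
    gene = c("bam", "vas", "Hml", "NimC1", "Mhc", "Act57B", "upd1", "cas"),
    cell_type = c("germline", "germline", "hemocyte", "hemocyte",
                  "muscle", "muscle", "polar", "stalk"),
    conflict_group = c("g1", "g1", "g2", "g2", "g3", "g3", "g4", "g4"),
    stringsAsFactors = FALSE))
}

# The default-design simulation cache shared across test files (several
# criteria are measured on the same runs).
.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(key, builder) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- builder()
  .sim_cache[[key]]
}

# QC -> normalize -> cell cycle -> HVG -> scale -> PCA -> SNN -> Louvain
# -> merge flow used by several checks; returns intermediates.
standard_flow <- function(sim, resolution = 1, seed = 1, n_pcs = 10,
                          thresholds = qc_thresholds()) {
  fl <- filter_cells(sim$counts, thr = thresholds)
  nm <- lognormalize(fl$kept)
  truth <- sim$truth[fl$keep, ]
  m <- compute_qc_metrics(fl$kept)
  covars <- data.frame(n_umi = m$n_umi, pct_mito = m$pct_mito)
  if (length(sim$s_genes)) {
    cc <- assign_cell_cycle(nm, sim$s_genes, sim$g2m_genes, seed = seed)
    covars$cc_difference <- cc$cc_difference
  } else cc <- NULL
  hv <- select_hvg(nm)
  sm <- scale_regress(nm, covars, genes = hv)
  pca <- run_pca(sm, n_pcs = min(n_pcs, min(dim(sm$values)) - 1))
  snn <- build_snn(pca$embeddings, k = min(30, nrow(pca$embeddings) - 1))
  lab <- cluster_modularity(snn, resolution = resolution, seed = seed)
  mg <- suppressWarnings(merge_unmarked_clusters(lab, nm, hvgs = hv))
  list(filter = fl, nm = nm, truth = truth, metrics = m, cc = cc,
       hvgs = hv, sm = sm, pca = pca, snn = snn, labels = mg$labels,
       markers = mg$markers)
}

# Mixed null/signal NB count matrix for DE calibration: `g0` null genes
# and `g1` signal genes (half rising, half falling 4-fold along t)
# embedded in a larger transcriptome so the library composition stays
# stable.
de_mixture <- function(seed, n = 500, g0 = 500, g1 = 100, extra = 1000,
                       fold = 4, abundance = 0.4, branch = FALSE) {
  set.seed(seed)
  t <- runif(n)
  lib <- rlnorm(n, log(5000), 0.3)
  ng <- g0 + g1 + extra
  pg <- rgamma(ng, 0.6)
  pg[(g0 + 1):(g0 + g1)] <- pg[(g0 + 1):(g0 + g1)] * abundance
  pg <- pg / sum(pg)
  mu <- outer(lib, pg)
  shape <- plogis((t - 0.5) / 0.08)
  up <- (g0 + 1):(g0 + g1 / 2)
  dn <- (g0 + g1 / 2 + 1):(g0 + g1)
  if (branch) {
    br <- sample(c("A", "B"), n, TRUE)
    mu[, up] <- mu[, up] * ifelse(br == "A", fold, 1)^shape
    mu[, dn] <- mu[, dn] * ifelse(br == "B", fold, 1)^shape
  } else {
    br <- NULL
    mu[, up] <- mu[, up] * fold^shape
    mu[, dn] <- mu[, dn] * fold^(-shape)
  }
  cnt <- matrix(rnbinom(n * ng, size = 4, mu = mu), n)
  colnames(cnt) <- paste0("g", seq_len(ng))
  list(cm = Matrix::Matrix(cnt, sparse = TRUE), t = t, branch = br,
       null_genes = paste0("g", seq_len(g0)),
       signal_genes = paste0("g", (g0 + 1):(g0 + g1)))
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

# Trajectory reconstruction used by trajectory checks.
reconstruct_trajectory <- function(sim, n_centers = 8, n_pcs = 4) {
  nm <- lognormalize(sim$counts)
  hv <- select_hvg(nm)
  m <- compute_qc_metrics(sim$counts)
  sm <- scale_regress(nm, data.frame(n_umi = m$n_umi,
                                     pct_mito = m$pct_mito), genes = hv)
  pca <- run_pca(sm, n_pcs = 10)
  emb <- pca$embeddings[, seq_len(n_pcs)]
  dp <- densitypeak_cluster(emb, n_centers = n_centers)
  gi <- sim$gene_info
  root_genes <- gi$gene_id[gi$role == "lineage_early"]
  rs <- Matrix::rowMeans(nm$values[, match(root_genes, nm$gene_ids)])
  tr <- build_principal_tree(emb, dp, root_spec = as.numeric(rs))
  list(nm = nm, trajectory = tr)
}

branch_accuracy <- function(tr, truth) {
  post <- truth$branch %in% c("A", "B")
  tab <- table(tr$branch[post], truth$branch[post])
  sum(apply(tab, 1, max)) / sum(tab)
}
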