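test_that("QC metrics match a dense brute-force recomputation", {
  cm <- random_count_matrix(50, 20, seed = 8)
  m <- compute_qc_metrics(cm)
  dense <- as.matrix(cm$counts)
  expect_equal(m$n_genes, as.integer(rowSums(dense > 0)))
  expect_equal(m$n_umi, unname(rowSums(dense)))
  mito <- rowSums(dense[, cm$mito_flags, drop = FALSE])
  expect_equal(m$pct_mito, unname(ifelse(rowSums(dense) > 0,
                                         100 * mito / rowSums(dense), 0)))
  # worked example: cell [0, 5, 3] with gene 3 mitochondrial
  cm2 <- count_matrix(matrix(c(0, 5, 3), 1, 3), "bc",
                      c("a", "b", "c"), c("a", "b", "mt:c"))
  m2 <- compute_qc_metrics(cm2)
  expect_equal(unlist(m2[, -1]), c(n_genes = 2, n_umi = 8, pct_mito = 37.5))
  # all-zero cell yields zeros
  cm3 <- count_matrix(matrix(0, 1, 3), "bc", c("a", "b", "c"))
  expect_equal(unlist(compute_qc_metrics(cm3)[, -1]),
               c(n_genes = 0, n_umi = 0, pct_mito = 0))
})

test_that("filtration applies the threshold window and reports reasons", {
  cm <- count_matrix(matrix(1, 2, 3), c("bad", "good"),
                     c("a", "b", "c"))
  mk <- function(n_genes, n_umi, pct_mito = 0) {
    data.frame(barcode = c("bad", "good"),
               n_genes = c(n_genes, 1000), n_umi = c(n_umi, 5000),
               pct_mito = c(pct_mito, 0.2))
  }
  thr <- qc_thresholds()
  removed_as <- function(metrics, thr. = thr) {
    fl <- filter_cells(cm, metrics, thr.)
    list(keep = fl$keep, report = fl$report)
  }
  # below the 775-gene floor
  r <- removed_as(mk(700, 5000))
  expect_equal(r$keep, c(FALSE, TRUE))
  expect_equal(unname(r$report["low_gene"]), 1)
  # disjunctive upper bounds: 2,201 genes alone removes the cell
  expect_equal(removed_as(mk(2201, 5000))$keep, c(FALSE, TRUE))
  # conjunctive reading keeps it unless both upper bounds are exceeded
  thrj <- qc_thresholds(upper_joint = TRUE)
  expect_equal(removed_as(mk(2201, 5000), thrj)$keep, c(TRUE, TRUE))
  expect_equal(removed_as(mk(2201, 19000), thrj)$keep, c(FALSE, TRUE))
  # mitochondrial gate at 1%
  expect_equal(removed_as(mk(1000, 5000, pct_mito = 1.5))$keep,
               c(FALSE, TRUE))
})

test_that("filtration is idempotent and removes exactly the planted cells", {
  sim <- cached_sim("default7", function()
    simulate_atlas(simulation_design(seed = 7)))
  fl <- filter_cells(sim$counts)
  expect_identical(which(!fl$keep), which(sim$truth$qc_fail))
  expect_equal(unname(fl$report["total_removed"]), sum(sim$truth$qc_fail))
  fl2 <- filter_cells(fl$kept)
  expect_equal(unname(fl2$report["total_removed"]), 0)
  expect_identical(fl2$kept$barcodes, fl$kept$barcodes)
})

test_that("lognormalize matches the scalar formula and keeps zeros", {
  cm <- random_count_matrix(20, 10, seed = 3, lambda = 3)
  nm <- lognormalize(cm)
  dense <- as.matrix(cm$counts)
  tot <- rowSums(dense)
  oracle <- log1p(1e4 * dense / tot)
  expect_equal(as.matrix(nm$values), oracle, ignore_attr = TRUE)
  expect_identical(as.matrix(nm$values) == 0, dense == 0,
                   ignore_attr = TRUE)
  # single nonzero gene hits the closed form
  cm1 <- count_matrix(matrix(c(10, 0), 1, 2), "bc", c("a", "b"))
  expect_equal(as.numeric(lognormalize(cm1)$values[1, 1]), log(1 + 1e4))
  # row-sum invariant
  rs <- Matrix::rowSums(expm1(as.matrix(nm$values)))
  expect_lt(max(abs(rs - 1e4)) / 1e4, 1e-6)
  # all-zero cells are rejected
  cm0 <- count_matrix(matrix(c(0, 0, 0, 2), 2, 2), c("a", "b"),
                      c("g1", "g2"))
  expect_error(lognormalize(cm0), "all-zero")
})

test_that("HVG selection recovers planted variable genes in a realistic
           abundance spectrum", {
  # transcriptome-like fixture: most genes near-silent (below the mean
  # window), a moderate null tier, and planted bimodal variable genes
  set.seed(31)
  n <- 600
  lib <- rlnorm(n, log(5000), 0.2)
  p_rare <- runif(550, 1e-7, 3e-7)
  p_null <- runif(400, 2e-5, 5e-4)
  # bimodal genes: off half / 8x-on half, overall mean matched to the
  # null tier so every mean bin stays null-dominated
  p_var <- runif(50, 1e-4, 5e-4) / 4.5
  p <- c(p_rare, p_null, p_var)
  mu <- outer(lib, p)
  on <- sample(c(TRUE, FALSE), n, TRUE)
  mu[on, 951:1000] <- mu[on, 951:1000] * 8
  cnt <- matrix(rnbinom(n * 1000, size = 4, mu = mu), n)
  ids <- sprintf("G%04d", 1:1000)
  cm <- count_matrix(cnt, sprintf("c%03d", 1:n), ids)
  nm <- lognormalize(cm)
  hv <- select_hvg(nm)
  planted <- ids[951:1000]
  expect_gte(mean(planted %in% hv), 0.9)                  # sensitivity
  expect_gte(mean(!(ids[1:950] %in% hv)), 0.9)            # specificity
})

test_that("HVG selection finds planted atlas programs, deterministically", {
  sim <- cached_sim("default7", function()
    simulate_atlas(simulation_design(seed = 7)))
  fl <- filter_cells(sim$counts)
  nm <- lognormalize(fl$kept)
  hv <- select_hvg(nm)
  gi <- sim$gene_info
  planted <- gi$gene_id[gi$role %in% c("marker", "s_phase", "g2m_phase")]
  expect_gte(mean(planted %in% hv), 0.9)          # sensitivity
  # permuting cell order leaves the selection unchanged
  set.seed(1)
  perm <- sample(nrow(nm$values))
  nm_p <- nm
  nm_p$values <- nm$values[perm, ]
  nm_p$barcodes <- nm$barcodes[perm]
  expect_setequal(select_hvg(nm_p), hv)
  # constant genes are never selected
  m <- matrix(rpois(600, 3), 30, 20)
  m[, 1] <- 5
  cmc <- count_matrix(m, sprintf("b%02d", 1:30), sprintf("g%02d", 1:20))
  expect_false("g01" %in% select_hvg(lognormalize(cmc),
                                     hvg_criteria(n_bins = 4)))
})

test_that("module scores are centered under a null set and linear", {
  nm <- random_norm_matrix(80, 60, seed = 12, lambda = 2)
  set.seed(2)
  null_set <- sample(nm$gene_ids, 10)
  sc <- score_gene_module(nm, null_set, n_bins = 10, seed = 5)
  expect_lt(abs(mean(sc)), 3 * sd(sc) / sqrt(length(sc)) + 0.05)
  # determinism under the seed
  expect_identical(sc, score_gene_module(nm, null_set, n_bins = 10,
                                         seed = 5))
  # adding +1 to the set genes in one cell raises its score by exactly 1
  # (set means are far from other genes so the control bins are stable)
  vals <- as.matrix(nm$values)
  vals[, 1:10] <- vals[, 1:10] + 5
  nm2 <- nm
  nm2$values <- methods::as(Matrix::Matrix(vals, sparse = TRUE),
                            "generalMatrix")
  s_before <- score_gene_module(nm2, nm$gene_ids[1:10], n_bins = 10,
                                seed = 5)
  vals[3, 1:10] <- vals[3, 1:10] + 1
  nm3 <- nm2
  nm3$values <- methods::as(Matrix::Matrix(vals, sparse = TRUE),
                            "generalMatrix")
  s_after <- score_gene_module(nm3, nm$gene_ids[1:10], n_bins = 10,
                               seed = 5)
  expect_equal(s_after[3] - s_before[3], 1)
  expect_equal(s_after[-3], s_before[-3])
  expect_error(score_gene_module(nm, c("nope1", "nope2")), "no module")
})

test_that("cell-cycle scoring separates planted phases and follows the rule", {
  sim <- cached_sim("default7", function()
    simulate_atlas(simulation_design(seed = 7)))
  fl <- filter_cells(sim$counts)
  nm <- lognormalize(fl$kept)
  truth <- sim$truth[fl$keep, ]
  cc <- assign_cell_cycle(nm, sim$s_genes, sim$g2m_genes, seed = 1)
  sing <- !truth$is_doublet
  expect_gte(mean((cc$phase == truth$phase)[sing]), 0.8)
  # planted S cells score above non-cycling cells (AUC)
  s <- cc$s_score[sing]; ph <- truth$phase[sing]
  pos <- ph == "S"
  r <- rank(s)
  auc <- (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) /
    (sum(pos) * sum(!pos))
  expect_gte(auc, 0.9)
  # the decision rule itself
  expect_equal(with(cc, phase[s_score > g2m_score & s_score > 0][1]), "S")
  dec <- function(s, g) if (s > g & s > 0) "S" else
    if (g >= s & g > 0) "G2M" else "G1"
  expect_equal(dec(0.5, -0.1), "S")
  expect_equal(dec(-0.2, -0.1), "G1")
  expect_equal(dec(0.3, 0.4), "G2M")
  expect_error(assign_cell_cycle(nm, c("zz1"), sim$g2m_genes), "overlap")
})

test_that("phase assignment is invariant to adding a constant everywhere", {
  nm <- random_norm_matrix(60, 40, seed = 14)
  s_set <- nm$gene_ids[1:8]
  g_set <- nm$gene_ids[9:16]
  cc1 <- assign_cell_cycle(nm, s_set, g_set, seed = 2)
  nm2 <- nm
  v <- as.matrix(nm$values) + 1
  nm2$values <- methods::as(Matrix::Matrix(v, sparse = TRUE),
                            "generalMatrix")
  cc2 <- assign_cell_cycle(nm2, s_set, g_set, seed = 2)
  expect_identical(cc1$phase, cc2$phase)
})

test_that("scale_regress matches the normal-equations oracle", {
  nm <- random_norm_matrix(30, 10, seed = 6, lambda = 4)
  set.seed(7)
  cov <- data.frame(a = rnorm(30), b = runif(30))
  sm <- scale_regress(nm, cov, clip_max = 1e6)
  Y <- as.matrix(nm$values)
  X <- cbind(1, as.matrix(cov))
  beta <- solve(t(X) %*% X, t(X) %*% Y)
  res <- Y - X %*% beta
  oracle <- scale(res, center = FALSE, scale = apply(res, 2, sd))
  expect_equal(unname(sm$values), unname(oracle), tolerance = 1e-8,
               ignore_attr = TRUE)
  # residuals orthogonal to every covariate
  for (j in 1:2)
    expect_lt(max(abs(crossprod(sm$values, X[, j + 1]))), 1e-6 * 30)
})

test_that("scale_regress handles null and collinear covariates", {
  nm <- random_norm_matrix(25, 8, seed = 9)
  # constant covariate: equivalent to plain centering and scaling
  sm <- suppressWarnings(scale_regress(nm, data.frame(c = rep(2, 25))))
  plain <- scale_regress(nm)
  expect_equal(sm$values, plain$values)
  # gene exactly linear in a covariate has ~zero residuals
  x <- rnorm(25)
  v <- as.matrix(nm$values)
  v[, 1] <- 2 + 3 * x
  nm2 <- nm
  nm2$values <- methods::as(Matrix::Matrix(v, sparse = TRUE),
                            "generalMatrix")
  Y <- as.matrix(nm2$values)
  X <- cbind(1, x)
  res <- Y - X %*% solve(t(X) %*% X, t(X) %*% Y)
  expect_lt(sd(res[, 1]), 1e-8)
  # collinear covariates are dropped with a warning
  expect_warning(scale_regress(nm, data.frame(a = x, b = 2 * x)),
                 "collinear")
})
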